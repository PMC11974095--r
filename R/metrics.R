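## Unordered (max, min) representation of a list of per-cell profiles.
unordered_mats <- function(profiles) {
  h1 <- do.call(rbind, lapply(profiles, `[[`, "hap1"))
  h2 <- do.call(rbind, lapply(profiles, `[[`, "hap2"))
  list(hi = pmax(h1, h2), lo = pmin(h1, h2))
}

check_grid <- function(pred, truth, weights) {
  if (length(pred) != length(truth))
    stopf("metrics: prediction and truth differ in cell count")
  L <- length(pred[[1]]$hap1)
  if (length(truth[[1]]$hap1) != L)
    stopf("metrics: prediction and truth are on different segment grids")
  if (is.null(weights)) weights <- rep(1, L)
  if (length(weights) != L) stopf("metrics: weights length != L")
  weights
}

#' Allele-specific accuracy on fixed-size bins
#'
#' Average over cells and bins of the indicator that the unordered
#' allele-specific copy number pair is predicted exactly: both the larger
#' and the smaller of the two haplotype copy numbers must match. Segment
#' predictions are projected to fixed-size bins by weighting each segment
#' by the number of bins it covers (`weights`, defaulting to the segment
#' table's `n_bins` or to 1 per segment).
#'
#' @param pred,truth lists of per-cell [cn_profile()]s on the same segment
#'   grid.
#' @param weights per-segment bin counts.
#' @return proportion in `[0, 1]`.
#' @export
cn_accuracy <- function(pred, truth, weights = NULL) {
  weights <- check_grid(pred, truth, weights)
  p <- unordered_mats(pred); t <- unordered_mats(truth)
  hit <- (p$hi == t$hi) & (p$lo == t$lo)
  mean(hit %*% weights / sum(weights))
}

#' Allele-specific L1 error on fixed-size bins
#'
#' Average over cells and bins of
#' `|max(a,b) - max(a',b')| + |min(a,b) - min(a',b')|`; zero exactly when
#' [cn_accuracy()] is 1 on the same inputs.
#' @inheritParams cn_accuracy
#' @return nonnegative mean error in copies per bin.
#' @export
cn_l1_error <- function(pred, truth, weights = NULL) {
  weights <- check_grid(pred, truth, weights)
  p <- unordered_mats(pred); t <- unordered_mats(truth)
  err <- abs(p$hi - t$hi) + abs(p$lo - t$lo)
  mean(err %*% weights / sum(weights))
}

#' SNV read-count tables
#'
#' Long-format table of somatic SNV read counts: one row per (SNV, cell)
#' with the containing segment index, the cell's group label
#' (sample/section), and variant/reference read counts.
#'
#' @param snv_id SNV identifiers.
#' @param segment 1-based containing segment index per row.
#' @param cell_id cell identifiers.
#' @param group group (sample/section) label per row.
#' @param var_reads,ref_reads nonnegative integer read counts.
#' @return data.frame of class `evocn_snvs`.
#' @export
snv_table <- function(snv_id, segment, cell_id, group, var_reads,
                      ref_reads) {
  if (any(var_reads < 0) || any(ref_reads < 0))
    stopf("snv table: negative read counts")
  n <- max(length(snv_id), length(cell_id))
  snv_id <- rep_len(snv_id, n); segment <- rep_len(segment, n)
  cell_id <- rep_len(cell_id, n); group <- rep_len(group, n)
  var_reads <- rep_len(var_reads, n); ref_reads <- rep_len(ref_reads, n)
  seg_per_snv <- tapply(segment, snv_id, function(x) length(unique(x)))
  if (any(seg_per_snv > 1))
    stopf("snv table: an SNV maps to more than one segment")
  df <- data.frame(snv_id = as.character(snv_id),
                   segment = as.integer(segment),
                   cell_id = as.character(cell_id),
                   group = as.character(group),
                   var_reads = as.integer(var_reads),
                   ref_reads = as.integer(ref_reads),
                   stringsAsFactors = FALSE)
  class(df) <- c("evocn_snvs", "data.frame")
  df
}

#' Filter SNVs to likely truncal ones
#'
#' Keeps SNVs present (at least one variant read) in at least `min_cells`
#' cells in each of at least `min_groups` groups — the signature of a
#' mutation predating the divergence of the samples.
#'
#' @param snvs an [snv_table()].
#' @param min_cells minimum cells with a variant read per group.
#' @param min_groups minimum number of groups meeting `min_cells`.
#' @return the filtered [snv_table()].
#' @export
truncal_filter <- function(snvs, min_cells = 5L, min_groups = 1L) {
  present <- snvs$var_reads >= 1L
  per <- stats::aggregate(present, by = list(snv_id = snvs$snv_id,
                                             group = snvs$group), FUN = sum)
  ok_groups <- stats::aggregate(per$x >= min_cells,
                                by = list(snv_id = per$snv_id), FUN = sum)
  keep <- ok_groups$snv_id[ok_groups$x >= min_groups]
  out <- snvs[snvs$snv_id %in% keep, , drop = FALSE]
  class(out) <- class(snvs)
  out
}

## Log-likelihood of one method's calls for all SNVs: for each SNV, the
## binomial log-likelihood of every cell's (variant, reference) reads with
## success probability hap / total at the SNV's segment, maximised over the
## two haplotype hypotheses.
snv_loglik_per_site <- function(snvs, calls, cell_ids, error_rate) {
  cell_idx <- match(snvs$cell_id, cell_ids)
  if (anyNA(cell_idx)) stopf("snv_llr: SNV table names unknown cells")
  h1 <- vapply(seq_len(nrow(snvs)), function(r)
    calls[[cell_idx[r]]]$hap1[snvs$segment[r]], numeric(1))
  h2 <- vapply(seq_len(nrow(snvs)), function(r)
    calls[[cell_idx[r]]]$hap2[snvs$segment[r]], numeric(1))
  tot <- h1 + h2
  clamp <- function(p) pmin(pmax(p, error_rate), 1 - error_rate)
  pA <- ifelse(tot > 0, clamp(h1 / pmax(tot, 1)), error_rate)
  pB <- ifelse(tot > 0, clamp(h2 / pmax(tot, 1)), error_rate)
  n <- snvs$var_reads + snvs$ref_reads
  llA <- stats::dbinom(snvs$var_reads, n, pA, log = TRUE)
  llB <- stats::dbinom(snvs$var_reads, n, pB, log = TRUE)
  byA <- tapply(llA, snvs$snv_id, sum)
  byB <- tapply(llB, snvs$snv_id, sum)
  pmax(byA, byB)     # maximum over the two haplotype hypotheses
}

#' Truncal-SNV log-likelihood ratio between two call sets
#'
#' For each SNV, computes the probability of all cells' variant/reference
#' reads under the copy numbers of each call set, assuming the SNV lies on
#' all copies of one haplotype (the better of the two haplotype hypotheses
#' is taken, since phase is unknown). Per-read variant probabilities are
#' `hap / (hap1 + hap2)`, clamped to `[error_rate, 1 - error_rate]` (and
#' `error_rate` on total copy zero). Positive values support `calls_a`,
#' negative values `calls_b`; call sets differing only by a constant
#' haplotype ratio are indistinguishable.
#'
#' @param snvs an [snv_table()].
#' @param calls_a,calls_b lists of per-cell [cn_profile()]s.
#' @param cell_ids cell identifiers aligning the call lists with the SNV
#'   table.
#' @param error_rate per-read error floor (default 0.01).
#' @return list with `total` (summed LLR) and `per_snv` (named vector).
#' @export
snv_llr <- function(snvs, calls_a, calls_b, cell_ids,
                    error_rate = 0.01) {
  lla <- snv_loglik_per_site(snvs, calls_a, cell_ids, error_rate)
  llb <- snv_loglik_per_site(snvs, calls_b, cell_ids, error_rate)
  per <- lla - llb
  list(total = sum(per), per_snv = per)
}

#' Bootstrap confidence for a total LLR
#'
#' Resamples SNVs with replacement; the p-value is the fraction of
#' resampled totals crossing zero (one-sided, doubled for two-sided
#' reporting) and the interval is the percentile interval of the resampled
#' totals.
#'
#' @param per_snv per-SNV LLR values.
#' @param n_boot bootstrap replicates (default 10,000).
#' @param conf interval coverage (default 0.95).
#' @return list with `p_value`, `interval`, `boot_totals`.
#' @export
bootstrap_llr <- function(per_snv, n_boot = 10000L, conf = 0.95) {
  n <- length(per_snv)
  if (n == 0L) stopf("bootstrap_llr: no SNVs")
  totals <- vapply(seq_len(n_boot), function(b)
    sum(per_snv[sample.int(n, n, replace = TRUE)]), numeric(1))
  obs <- sum(per_snv)
  p_one <- if (obs >= 0) mean(totals <= 0) else mean(totals >= 0)
  alpha <- (1 - conf) / 2
  list(p_value = min(1, 2 * p_one),
       interval = unname(stats::quantile(totals, c(alpha, 1 - alpha))),
       boot_totals = totals)
}

#' Pooled VAF histogram for one copy number state
#'
#' For diagnostics: pooled variant allele frequency of each SNV over the
#' cells whose assigned profile at the SNV's segment matches the unordered
#' copy number pair `state`; truncal SNVs on a single haplotype produce
#' modes at `hap / total` for the two possible haplotype assignments.
#'
#' @param snvs an [snv_table()].
#' @param calls list of per-cell [cn_profile()]s.
#' @param cell_ids cell identifiers aligning `calls` with the table.
#' @param state unordered copy pair, e.g. `c(2, 1)`.
#' @param breaks histogram breaks on `[0, 1]`.
#' @return object of class `histogram` (empty counts when no SNV matches).
#' @export
vaf_histogram <- function(snvs, calls, cell_ids, state = c(2, 1),
                          breaks = seq(0, 1, by = 0.05)) {
  cell_idx <- match(snvs$cell_id, cell_ids)
  h1 <- vapply(seq_len(nrow(snvs)), function(r)
    calls[[cell_idx[r]]]$hap1[snvs$segment[r]], numeric(1))
  h2 <- vapply(seq_len(nrow(snvs)), function(r)
    calls[[cell_idx[r]]]$hap2[snvs$segment[r]], numeric(1))
  match_state <- pmax(h1, h2) == max(state) & pmin(h1, h2) == min(state)
  d <- snvs[match_state & (snvs$var_reads + snvs$ref_reads) > 0, ,
            drop = FALSE]
  if (nrow(d) == 0L) {
    h <- graphics::hist(numeric(0), breaks = breaks, plot = FALSE)
    return(h)
  }
  v <- tapply(d$var_reads, d$snv_id, sum)
  n <- tapply(d$var_reads + d$ref_reads, d$snv_id, sum)
  graphics::hist(as.numeric(v / n), breaks = breaks, plot = FALSE)
}
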