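#' Per-cell scaling factor estimation
#'
#' Estimates the per-copy read depth `c` of one cell on a candidate grid.
#' Low-noise segments (read-depth variance below the 25th percentile for the
#' cell; all segments if that set is empty) are scored under the read-depth
#' Gaussian at the best small integer total copy number per segment, and the
#' grid argmax is returned. A mild complexity penalty favours scalings that
#' put the cell near total copy 2 unless the fit improves by a configured
#' log-likelihood margin, the standard guard against the inherent c-vs-2c
#' (ploidy/WGD) ambiguity of depth-only scaling. Exact score ties are broken
#' toward the smaller scaling.
#'
#' @param ctx a [cell_context()] (the `c` field is ignored).
#' @param candidate_grid positive candidate scalings; defaults to 100
#'   log-spaced values spanning mean-depth/4.5 to 1.05 x mean-depth
#'   (implied mean ploidies of about 1 to 4.5), wide enough that
#'   genome-doubled cells with additional gains remain representable while
#'   excluding implausible high-ploidy interpretations that overfit noise.
#' @param max_total largest integer total copy considered when scoring.
#' @param ploidy_margin parsimony penalty in nats per segment per unit
#'   `|log2|` deviation of the implied mean total copy from 2; decides only
#'   scalings the full likelihood cannot separate (e.g. all-even profiles).
#' @return the selected scaling factor.
#' @export
estimate_scaling <- function(ctx, candidate_grid = NULL, max_total = 8L,
                             ploidy_margin = 1) {
  mean_depth <- mean(ctx$r)
  if (is.null(candidate_grid)) {
    if (mean_depth <= 0) return(1)
    candidate_grid <- exp(seq(log(mean_depth / 4.5), log(mean_depth * 1.05),
                              length.out = 100))
  }
  if (length(candidate_grid) == 0L) stopf("estimate_scaling: empty grid")
  candidate_grid <- sort(candidate_grid)
  low <- ctx$sr < stats::quantile(ctx$sr, 0.25)
  if (!any(low)) low <- rep(TRUE, length(ctx$sr))
  r <- ctx$r[low]; sr <- ctx$sr[low]
  ## refine each candidate beyond grid resolution: alternate best integer
  ## totals with the weighted least-squares scaling until a fixed point
  refine <- function(cc) {
    for (rep in 1:10) {
      t_best <- pmin(max_total, pmax(0, round(r / cc)))
      den <- sum(t_best^2 / sr)
      if (den == 0) break
      cc_new <- sum(r * t_best / sr) / den
      if (!is.finite(cc_new) || cc_new <= 0 ||
          abs(cc_new - cc) < 1e-12 * cc) break
      cc <- cc_new
    }
    cc
  }
  cand <- vapply(candidate_grid, refine, numeric(1))
  cand <- sort(unique(round(cand, 6)))
  cand <- cand[cand > 0]
  ## Depth-only scores identify the shortlist; the depth Gaussian cannot
  ## separate a scaling from its integer multiples (genome doubling), so
  ## the shortlist is re-scored with the full depth + BAF likelihood of
  ## the best copy number pair per segment, plus the ploidy penalty.
  totals <- 0:max_total
  depth_score <- vapply(cand, function(cc) {
    resid <- outer(r, cc * totals, `-`)^2          # n_low x totals
    sum(apply(-resid / (2 * sr) - 0.5 * log(2 * pi * sr), 1, max))
  }, numeric(1))
  keep <- order(depth_score, decreasing = TRUE)[seq_len(min(8, length(cand)))]
  cand <- cand[keep]
  full <- vapply(cand, function(cc) best_pair_loglik(ctx, cc, max_total),
                 numeric(1))
  penalty <- ploidy_margin * length(ctx$r) *
    abs(log2(pmax(mean_depth, 1e-12) / (2 * cand)))
  s <- full - penalty
  smax <- max(s)
  which_tied <- s >= smax - 1e-9
  cand[which.min(ifelse(which_tied, cand, Inf))]   # ties -> smaller c
}

## Log-density per segment at the best (a1, a2) pair each, given scaling
## cc; summed, this is the objective that call_naive_profile maximises.
best_pair_loglik_by_segment <- function(ctx, cc, max_total = 8L) {
  pairs <- naive_pair_table(max_total)
  pairs <- pairs[pairs[, 1] + pairs[, 2] <= max_total, , drop = FALSE]
  tot <- pairs[, 1] + pairs[, 2]
  muB <- ifelse(tot > 0, pairs[, 2] / pmax(tot, 1L), 0.5)
  llR <- -outer(cc * tot, ctx$r, `-`)^2 /
    matrix(2 * ctx$sr, nrow(pairs), length(ctx$r), byrow = TRUE)
  llB <- -outer(muB, ctx$b, `-`)^2 /
    matrix(2 * ctx$sb, nrow(pairs), length(ctx$b), byrow = TRUE)
  const <- -0.5 * log(2 * pi * ctx$sr) - 0.5 * log(2 * pi * ctx$sb)
  apply(llR + llB, 2, max) + const
}

best_pair_loglik <- function(ctx, cc, max_total = 8L) {
  sum(best_pair_loglik_by_segment(ctx, cc, max_total))
}

## Fixed enumeration order over (a1, a2) pairs: pairs with a1 >= a2 come
## first so that strict-improvement argmax breaks b = 0.5 ties toward
## a1 >= a2 deterministically.
naive_pair_table <- function(c_max) {
  a1 <- rep(0:c_max, each = c_max + 1L)
  a2 <- rep(0:c_max, times = c_max + 1L)
  ord <- order(a1 < a2, a1 + a2, a1)
  cbind(a1 = a1[ord], a2 = a2[ord])
}

#' Independent maximum-likelihood profile call for one cell
#'
#' Per segment (independently, which is exact given the scaling factor),
#' selects the ordered copy number pair maximising the joint read-depth and
#' BAF log-density. This is a brute-force argmax over all
#' `(c_max + 1)^2` pairs.
#'
#' @param ctx a [cell_context()].
#' @param c scaling factor (e.g. from [estimate_scaling()]).
#' @param c_max per-haplotype copy number cap.
#' @return a [cn_profile()].
#' @export
call_naive_profile <- function(ctx, c, c_max = 19L) {
  pairs <- naive_pair_table(c_max)
  tot <- pairs[, 1] + pairs[, 2]
  muB <- ifelse(tot > 0, pairs[, 2] / pmax(tot, 1L), 0.5)
  ## npairs x L score matrix
  llR <- -outer(c * tot, ctx$r, `-`)^2 /
    matrix(2 * ctx$sr, nrow(pairs), length(ctx$r), byrow = TRUE)
  llB <- -outer(muB, ctx$b, `-`)^2 /
    matrix(2 * ctx$sb, nrow(pairs), length(ctx$b), byrow = TRUE)
  ll <- llR + llB
  ## first value within tolerance of the maximum = earliest in preference
  ## order (a1 >= a2 pairs first), robust to float asymmetry of exact ties
  best <- apply(ll, 2, function(col) which(col >= max(col) - 1e-9)[1])
  cn_profile(pairs[best, 1], pairs[best, 2], c_max = c_max)
}

#' Initial per-cell copy number estimation
#'
#' For every cell: estimate the scaling factor from low-noise segments, then
#' call the maximum-likelihood profile segment-by-segment. These independent
#' per-cell calls initialise and guide the trajectory-policy training and
#' serve as a baseline caller in their own right.
#'
#' @param obs an [observation_set()].
#' @param c_max per-haplotype copy number cap.
#' @param candidate_grid optional shared scaling grid (default: per-cell
#'   grid as in [estimate_scaling()]).
#' @param consensus_margin per-segment log-likelihood slack within which a
#'   cell's scaling is considered ambiguous between the diploid and
#'   genome-doubled interpretation, in which case the cohort's majority
#'   interpretation is adopted (set to `NA` to disable harmonisation).
#' @return Object of class `evocn_naive`: list with `profiles` (per-cell
#'   [cn_profile()]s), `scaling` (length-N vector), and `loglik` (per-cell
#'   data log-likelihood at the called profile).
#' @export
call_naive <- function(obs, c_max = 19L, candidate_grid = NULL,
                       consensus_margin = 0.25) {
  N <- n_cells(obs)
  profiles <- vector("list", N)
  scaling <- numeric(N)
  loglik <- numeric(N)
  for (s in seq_len(N)) {
    ctx <- cell_context_from_obs(obs, s)
    cc <- estimate_scaling(ctx, candidate_grid)
    P <- call_naive_profile(ctx, cc, c_max = c_max)
    ctx$c <- cc
    profiles[[s]] <- P
    scaling[s] <- cc
    loglik[s] <- data_loglik(ctx, P)
  }
  ## Cohort resolution of the diploid-vs-genome-doubled ambiguity. A cell
  ## whose profile is (near-)even fits its depth and BAF data almost
  ## identically under scaling c (higher ploidy) and 2c (lower ploidy), and
  ## at realistic noise the per-cell likelihood gap between the two
  ## interpretations is swamped by the extra fit freedom of the finer
  ## copy-number grid. What does separate them is consistency: a genuine
  ## genome doubling leaves the same odd-copy segments poorly explained by
  ## the low interpretation in every cell, whereas noise-driven gains fall
  ## on different segments per cell. The cohort is flagged genome-doubled
  ## when some segment's mean per-cell likelihood gap between the
  ## interpretations exceeds `wgd_evidence` nats; every cell then adopts
  ## the cohort interpretation unless its own data contradict it by more
  ## than `consensus_margin` nats per segment.
  if (!is.na(consensus_margin) && N > 1L) {
    L <- ncol(obs$R)
    ploidy <- rowMeans(obs$R) / scaling
    c_low <- ifelse(ploidy < 3, scaling, 2 * scaling)   # ploidy-near-2 scaling
    c_high <- c_low / 2
    gap <- matrix(0, N, L)    # per segment: ll(high) - ll(low)
    ll_low <- numeric(N); ll_high <- numeric(N)
    for (s in seq_len(N)) {
      ctx <- cell_context_from_obs(obs, s)
      gl <- best_pair_loglik_by_segment(ctx, c_low[s])
      gh <- best_pair_loglik_by_segment(ctx, c_high[s])
      gap[s, ] <- gh - gl
      ll_low[s] <- sum(gl); ll_high[s] <- sum(gh)
    }
    ## Flag genome doubling when some segment shows a strong (> 3 nats)
    ## gap in a sizeable fraction of cells, or a large mean gap; under
    ## pure noise both statistics stay far below these thresholds.
    cohort_high <- max(colMeans(gap > 3)) > 0.15 || max(colMeans(gap)) > 2
    for (s in seq_len(N)) {
      pick_high <- if (cohort_high)
        ll_high[s] >= ll_low[s] - consensus_margin * L
      else ll_high[s] - ll_low[s] > 4 * consensus_margin * L
      cc <- if (pick_high) c_high[s] else c_low[s]
      if (abs(cc - scaling[s]) > 1e-12 * cc) {
        ctx <- cell_context_from_obs(obs, s)
        ctx$c <- cc
        scaling[s] <- cc
        profiles[[s]] <- call_naive_profile(ctx, cc, c_max = c_max)
        loglik[s] <- data_loglik(ctx, profiles[[s]])
      }
    }
    ## Rescue of residual ploidy outliers: cells whose implied ploidy sits
    ## far from the cohort median (e.g. a 3:2 scaling flip that neither
    ## the per-cell penalty nor the factor-2 harmonisation can reach) are
    ## offered a scaling refined towards the cohort ploidy and adopt it
    ## unless their own data prefer the outlier reading by a wide margin.
    ploidy <- rowMeans(obs$R) / scaling
    p_med <- stats::median(ploidy)
    for (s in seq_len(N)) {
      if (abs(log2(ploidy[s] / p_med)) <= 0.3) next
      ctx <- cell_context_from_obs(obs, s)
      cc <- mean(ctx$r) / p_med
      for (rep in 1:10) {     # local WLS refinement at the cohort ploidy
        t_best <- pmax(0, round(ctx$r / cc))
        den <- sum(t_best^2 / ctx$sr)
        if (den == 0) break
        cc_new <- sum(ctx$r * t_best / ctx$sr) / den
        if (!is.finite(cc_new) || cc_new <= 0 ||
            abs(cc_new - cc) < 1e-12 * cc) break
        cc <- cc_new
      }
      if (best_pair_loglik(ctx, cc) >=
            best_pair_loglik(ctx, scaling[s]) - 2 * consensus_margin * L) {
        ctx$c <- cc
        scaling[s] <- cc
        profiles[[s]] <- call_naive_profile(ctx, cc, c_max = c_max)
        loglik[s] <- data_loglik(ctx, profiles[[s]])
      }
    }
  }
  structure(list(profiles = profiles, scaling = scaling, loglik = loglik,
                 cell_ids = obs$cell_ids),
            class = "evocn_naive")
}

## Replace the observation set's scaling factors with the estimates.
apply_naive_scaling <- function(obs, naive) {
  obs$scaling <- naive$scaling
  obs
}
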