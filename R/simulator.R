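## Approximate relative autosome lengths (Mb), used to apportion bins.
AUTOSOME_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                 133, 114, 107, 102, 90, 83, 80, 59, 63, 47, 51)

#' Simulation configuration
#'
#' Settings for the fitness-driven tumour evolution simulator. Defaults
#' describe the full-scale study conditions: 1000 cells and 27,283 bins of
#' 100kb across the 22 autosomes (sex chromosomes excluded), a clone tree
#' grown by sequential CNAs with fitness-modulated clone sizes, and
#' emission of read depths, phased allele counts, and variance matrices.
#'
#' @param n_cells number of sampled cells (default 1000).
#' @param n_bins number of 100kb bins (default 27,283).
#' @param n_cna_events CNA events on the clone tree (default 150).
#' @param truncal_wgd whether the founding clone carries a whole-genome
#'   duplication.
#' @param fitness_increase_prob probability that a CNA increases its
#'   clone's fitness; controls intra-tumour heterogeneity (higher values
#'   concentrate cells on fewer fit clones).
#' @param fitness_boost_rate rate of the exponential fitness multiplier
#'   (`1 + rexp(rate)`) applied on a fitness increase; the default 0.4
#'   (mean multiplier 3.5) makes fitness increases translate into strong
#'   clone expansions, so `fitness_increase_prob` spans low to high
#'   intra-tumour heterogeneity.
#' @param cna_length_mean mean CNA length in bins (geometric).
#' @param value_probs probabilities of event values -2, -1, +1, +2.
#' @param depth_sd_per_bin per-bin read-depth standard deviation in copy
#'   units at scaling 1; segment-level noise scales with
#'   `1/sqrt(bins per segment)`.
#' @param snp_reads_per_bin mean phased allele reads per bin (Poisson).
#' @param scaling_cv log-normal coefficient of variation of per-cell
#'   scaling factors around 1.
#' @param merge_segments collapse bins into segments delimited by the union
#'   of ground-truth CNA breakpoints (TRUE) or keep one segment per bin.
#' @param c_max per-haplotype copy number cap.
#' @param v_floor variance floor for emitted variance matrices.
#' @return list of class `evocn_sim_config`.
#' @export
sim_config <- function(n_cells = 1000L, n_bins = 27283L,
                       n_cna_events = 150L, truncal_wgd = FALSE,
                       fitness_increase_prob = 0.5,
                       fitness_boost_rate = 0.4,
                       cna_length_mean = 200,
                       value_probs = c(0.1, 0.4, 0.4, 0.1),
                       depth_sd_per_bin = 0.6,
                       snp_reads_per_bin = 2,
                       scaling_cv = 0.1,
                       merge_segments = TRUE,
                       c_max = 19L, v_floor = 1e-6) {
  stopifnot(n_cells > 0, n_bins >= 22, n_cna_events >= 0,
            fitness_increase_prob >= 0, fitness_increase_prob <= 1,
            length(value_probs) == 4, all(value_probs >= 0))
  cfg <- list(n_cells = as.integer(n_cells), n_bins = as.integer(n_bins),
              n_cna_events = as.integer(n_cna_events),
              truncal_wgd = isTRUE(truncal_wgd),
              fitness_increase_prob = fitness_increase_prob,
              fitness_boost_rate = fitness_boost_rate,
              cna_length_mean = cna_length_mean,
              value_probs = value_probs / sum(value_probs),
              depth_sd_per_bin = depth_sd_per_bin,
              snp_reads_per_bin = snp_reads_per_bin,
              scaling_cv = scaling_cv,
              merge_segments = isTRUE(merge_segments),
              c_max = as.integer(c_max), v_floor = v_floor)
  ## apportion bins to 22 autosomes proportionally to physical length
  w <- AUTOSOME_MB / sum(AUTOSOME_MB)
  nb <- pmax(1L, as.integer(round(w * cfg$n_bins)))
  nb[1] <- nb[1] + cfg$n_bins - sum(nb)
  cfg$chrom_bins <- nb
  cfg$bin_chrom <- rep(seq_along(nb), nb)
  class(cfg) <- "evocn_sim_config"
  cfg
}

#' Simulate a clone tree
#'
#' Grows a tree of clones from a founding clone (normal, or genome
#' duplicated when `truncal_wgd`). Each step picks an existing clone with
#' probability proportional to its fitness, draws a valid bin-level CNA
#' (geometric interval length clipped at the chromosome end, uniform
#' haplotype, value from -2..+2 weighted toward single-copy events), and
#' creates a child clone; with probability `fitness_increase_prob` the
#' child's fitness is multiplied by `1 + rexp(fitness_boost_rate)`.
#'
#' @param config an [sim_config()].
#' @return list of class `evocn_clone_tree` with `nodes` (per clone:
#'   bin-level `hap1`/`hap2`, `fitness`, `parent`, `event`) and
#'   `breakpoints` (sorted union of event boundaries, in bins).
#' @export
simulate_tree <- function(config) {
  nb <- config$n_bins
  root_cn <- if (config$truncal_wgd) 2L else 1L
  nodes <- list(list(hap1 = rep(root_cn, nb), hap2 = rep(root_cn, nb),
                     fitness = 1, parent = NA_integer_, event = NULL))
  chrom_end <- cumsum(config$chrom_bins)
  breakpoints <- integer()
  values <- c(-2L, -1L, 1L, 2L)
  for (k in seq_len(config$n_cna_events)) {
    parent <- sample.int(length(nodes), 1L,
                         prob = vapply(nodes, `[[`, numeric(1), "fitness"))
    pn <- nodes[[parent]]
    event <- NULL
    for (try in 1:100) {
      start <- sample.int(nb, 1L)
      len <- 1L + stats::rgeom(1L, 1 / config$cna_length_mean)
      end <- min(start + len - 1L, chrom_end[config$bin_chrom[start]])
      hap <- sample.int(2L, 1L)
      value <- sample(values, 1L, prob = config$value_probs)
      x <- (if (hap == 1L) pn$hap1 else pn$hap2)[start:end]
      if (min(x) + value >= 0L && max(x) + value <= config$c_max) {
        event <- list(hap = hap, start = start, end = end, value = value)
        break
      }
    }
    if (is.null(event)) next    # clone saturated; skip this event
    child <- pn
    idx <- event$start:event$end
    if (event$hap == 1L) child$hap1[idx] <- child$hap1[idx] + event$value
    else child$hap2[idx] <- child$hap2[idx] + event$value
    child$parent <- parent
    child$event <- event
    if (stats::runif(1) < config$fitness_increase_prob)
      child$fitness <- pn$fitness * (1 + stats::rexp(1, config$fitness_boost_rate))
    nodes[[length(nodes) + 1L]] <- child
    breakpoints <- c(breakpoints, event$start, event$end + 1L)
  }
  structure(list(nodes = nodes,
                 breakpoints = sort(unique(breakpoints)),
                 config = config),
            class = "evocn_clone_tree")
}

#' Sample cells from a clone tree
#'
#' Multinomial over clones with probabilities proportional to fitness.
#' @param tree an `evocn_clone_tree`.
#' @param n_cells number of cells.
#' @return list with `clone` (clone index per cell) and
#'   `n_unique_profiles` (distinct bin-level profiles among sampled cells).
#' @export
sample_cells <- function(tree, n_cells) {
  fit <- vapply(tree$nodes, `[[`, numeric(1), "fitness")
  clone <- sample.int(length(tree$nodes), n_cells, replace = TRUE,
                      prob = fit)
  keys <- vapply(tree$nodes, function(n)
    paste(c(n$hap1, n$hap2), collapse = ","), character(1))
  list(clone = clone, n_unique_profiles = length(unique(keys[clone])))
}

## Segment table from the union of ground-truth breakpoints (or per-bin).
segmentation_from_tree <- function(tree) {
  config <- tree$config
  chrom_start <- cumsum(c(0L, config$chrom_bins[-length(config$chrom_bins)])) + 1L
  cuts <- if (config$merge_segments)
    sort(unique(c(chrom_start, tree$breakpoints))) else seq_len(config$n_bins)
  cuts <- cuts[cuts <= config$n_bins]
  starts <- cuts
  ends <- c(cuts[-1] - 1L, config$n_bins)
  ## split any segment that would span a chromosome boundary (breakpoint
  ## unions always contain chromosome starts, so only defensive here)
  chrom <- config$bin_chrom[starts]
  segment_table(chrom = sprintf("chr%d", chrom),
                start = (starts - 1L) * 1e5, end = ends * 1e5,
                n_bins = ends - starts + 1L)
}

#' Emit observation matrices for sampled cells
#'
#' Per cell: a log-normal scaling factor around 1; segment-level read
#' depths drawn from truncated Gaussians centred on scaling times total
#' copy, with variance `(depth_sd_per_bin * scaling)^2 / bins`; phased
#' allele counts binomial with success probability `hap2 / total` (0.5 at
#' total zero) and Poisson allele coverage. The exact read-depth variances
#' and the balanced-allele binomial BAF variances are emitted alongside.
#'
#' @param tree an `evocn_clone_tree`.
#' @param cells result of [sample_cells()].
#' @param segments segment table from the same tree.
#' @return list with `obs` (an [observation_set()]) and `truth` (per-cell
#'   segment-level [cn_profile()]s plus clone labels and the ground-truth
#'   unique-profile count).
#' @export
emit_observations <- function(tree, cells, segments) {
  config <- tree$config
  N <- length(cells$clone)
  L <- n_segments(segments)
  seg_first_bin <- as.integer(segments$start / 1e5) + 1L
  profiles <- lapply(cells$clone, function(k) {
    n <- tree$nodes[[k]]
    cn_profile(n$hap1[seg_first_bin], n$hap2[seg_first_bin],
               c_max = config$c_max)
  })
  scaling <- exp(stats::rnorm(N, mean = 0, sd = config$scaling_cv))
  tot <- do.call(rbind, lapply(profiles, total_copy))        # N x L
  muB <- do.call(rbind, lapply(profiles, baf_mean))
  m_bins <- matrix(segments$n_bins, N, L, byrow = TRUE)
  sigmaR <- pmax((config$depth_sd_per_bin * scaling)^2 / m_bins,
                 config$v_floor)
  R <- pmax(0, stats::rnorm(N * L, mean = scaling * tot,
                            sd = sqrt(sigmaR)))
  R <- matrix(R, N, L)
  n_allele <- matrix(stats::rpois(N * L, lambda = config$snp_reads_per_bin *
                                    m_bins), N, L)
  A2 <- matrix(stats::rbinom(N * L, size = n_allele, prob = muB), N, L)
  A <- array(0, dim = c(N, L, 2))
  A[, , 1] <- n_allele - A2
  A[, , 2] <- A2
  sigmaB <- pmax(0.25 / pmax(n_allele, 1), config$v_floor)
  obs <- observation_set(R, segments, A = A, sigmaR = sigmaR,
                         sigmaB = sigmaB, scaling = NULL)
  list(obs = obs,
       truth = list(profiles = profiles, clone = cells$clone,
                    scaling = scaling,
                    n_unique_profiles = cells$n_unique_profiles))
}

#' Simulate a complete dataset
#'
#' Tree growth, cell sampling, breakpoint segmentation, and observation
#' emission in one call.
#' @param config an [sim_config()].
#' @param seed RNG seed.
#' @return list with `obs`, `truth`, `segments`, `tree`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  tree <- simulate_tree(config)
  cells <- sample_cells(tree, config$n_cells)
  segments <- segmentation_from_tree(tree)
  em <- emit_observations(tree, cells, segments)
  list(obs = em$obs, truth = em$truth, segments = segments, tree = tree)
}
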