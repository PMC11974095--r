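## Shared fixtures: tiny segment tables, policies, and observation sets
## built in code.

tiny_segments <- function(L = 4, n_chrom = 2) {
  per <- rep(ceiling(L / n_chrom), n_chrom)
  per[n_chrom] <- L - sum(per[-n_chrom])
  chrom <- rep(sprintf("chr%d", seq_len(n_chrom)), per)
  start <- unlist(lapply(per, function(k) (seq_len(k) - 1) * 1e5))
  segment_table(chrom, start, start + 1e5)
}

one_chrom_segments <- function(L) {
  segment_table(rep("chr1", L), (seq_len(L) - 1) * 1e5, seq_len(L) * 1e5)
}

tiny_policy <- function(L = 2, c_max = 2, vmax = 1, seed = 11,
                        embed_dim = 6, n_conv = 2, stop_bias = 1) {
  policy_new(one_chrom_segments(L), c_max = c_max, vmax = vmax,
             n_levels = c_max + 1L, embed_dim = embed_dim, n_conv = n_conv,
             seed = seed, stop_bias = stop_bias)
}

## Observation set generated directly from given per-cell profiles with
## Gaussian depth noise and binomial allele counts.
obs_from_profiles <- function(profiles, segments, scaling = NULL,
                              depth_sd = 0.05, snp_depth = 200,
                              seed = 1) {
  set.seed(seed)
  N <- length(profiles)
  L <- n_segments(segments)
  if (is.null(scaling)) scaling <- rep(1, N)
  tot <- do.call(rbind, lapply(profiles, function(p) p$hap1 + p$hap2))
  muB <- do.call(rbind, lapply(profiles, function(p) {
    t <- p$hap1 + p$hap2
    ifelse(t > 0, p$hap2 / pmax(t, 1), 0.5)
  }))
  sigmaR <- matrix(depth_sd^2, N, L)
  R <- matrix(pmax(0, stats::rnorm(N * L, scaling * tot, depth_sd)), N, L)
  n_allele <- matrix(stats::rpois(N * L, snp_depth), N, L)
  A2 <- matrix(stats::rbinom(N * L, n_allele, muB), N, L)
  A <- array(0, dim = c(N, L, 2))
  A[, , 1] <- n_allele - A2
  A[, , 2] <- A2
  observation_set(R, segments, A = A, sigmaR = sigmaR,
                  sigmaB = pmax(0.25 / pmax(n_allele, 1), 1e-6),
                  scaling = scaling)
}

random_profile <- function(L, c_max = 4) {
  cn_profile(sample(0:c_max, L, replace = TRUE),
             sample(0:c_max, L, replace = TRUE), c_max = c_max)
}

make_tiny_trainer <- function(seed = 50, N = 4, L = 3, depth_sd = 0.05) {
  set.seed(seed)
  seg <- one_chrom_segments(L)
  truth <- list(cn_profile(c(2, 1, 1), c(1, 1, 1), c_max = 4),
                cn_profile(c(2, 1, 1), c(1, 1, 1), c_max = 4),
                cn_profile(c(1, 1, 0), c(1, 1, 1), c_max = 4),
                cn_profile(rep(1, 3), rep(1, 3), c_max = 4))[seq_len(N)]
  obs <- obs_from_profiles(truth, seg, depth_sd = depth_sd, seed = seed)
  naive <- call_naive(obs, c_max = 4)
  obs <- evocn:::apply_naive_scaling(obs, naive)
  policy <- policy_new(seg, c_max = 4, vmax = 2, n_levels = 5,
                       embed_dim = 8, n_conv = 2, seed = seed)
  trainer_init(policy, obs, naive, max_len = 6)
}

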