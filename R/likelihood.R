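#' Per-cell likelihood context
#'
#' Bundles one cell's measurements for the Gaussian observation model: read
#' depths `r` with variances `sr`, BAFs `b` with variances `sb`, and the
#' cell-specific scaling factor `c` linking total copy number to expected
#' depth.
#'
#' @param r,b length-L numeric vectors of read depths and BAFs.
#' @param sr,sb length-L strictly positive variance vectors.
#' @param c positive scaling factor.
#' @return Object of class `evocn_cell_ctx`.
#' @export
cell_context <- function(r, b, sr, sb, c = 1) {
  L <- length(r)
  if (length(b) != L || length(sr) != L || length(sb) != L)
    stopf("cell context: vector lengths differ")
  if (any(sr <= 0) || any(sb <= 0)) stopf("cell context: variances must be positive")
  if (c <= 0) stopf("cell context: scaling must be positive")
  structure(list(r = as.numeric(r), b = as.numeric(b),
                 sr = as.numeric(sr), sb = as.numeric(sb), c = as.numeric(c)),
            class = "evocn_cell_ctx")
}

cell_context_from_obs <- function(obs, s) {
  cell_context(obs$R[s, ], obs$B[s, ], obs$sigmaR[s, ], obs$sigmaB[s, ],
               c = obs$scaling[s])
}

## Expected BAF per segment: hap2 / total, with the neutral 0.5 convention
## at total copy zero (the ratio is undefined there and the segment should
## carry no allelic information).
baf_mean <- function(profile) {
  tot <- total_copy(profile)
  ifelse(tot > 0, profile$hap2 / pmax(tot, 1L), 0.5)
}

#' Read-depth log-likelihood of a profile for one cell
#'
#' Independent Gaussians per segment with mean `c * (hap1 + hap2)` and
#' variance `sr`.
#' @param ctx a [cell_context()].
#' @param profile a [cn_profile()].
#' @return log probability (finite for positive variances).
#' @export
read_depth_loglik <- function(ctx, profile) {
  if (length(profile$hap1) != length(ctx$r))
    stopf("read_depth_loglik: profile length does not match context")
  mu <- ctx$c * total_copy(profile)
  sum(-0.5 * log(2 * pi * ctx$sr) - (ctx$r - mu)^2 / (2 * ctx$sr))
}

#' BAF log-likelihood of a profile for one cell
#'
#' Independent Gaussians per segment with mean `hap2 / (hap1 + hap2)`
#' (0.5 at total copy zero) and variance `sb`.
#' @inheritParams read_depth_loglik
#' @export
baf_loglik <- function(ctx, profile) {
  if (length(profile$hap1) != length(ctx$b))
    stopf("baf_loglik: profile length does not match context")
  mu <- baf_mean(profile)
  sum(-0.5 * log(2 * pi * ctx$sb) - (ctx$b - mu)^2 / (2 * ctx$sb))
}

#' Joint data log-likelihood of a profile for one cell
#'
#' Read depth and BAF are modelled as independent given the profile, so the
#' joint log-likelihood is the sum of the two terms.
#' @inheritParams read_depth_loglik
#' @export
data_loglik <- function(ctx, profile) {
  read_depth_loglik(ctx, profile) + baf_loglik(ctx, profile)
}

#' Marginal log-likelihood of one cell under a profile prior
#'
#' `log sum_P prior(P) * Pr(data | P)` computed in log space over a finite
#' (sub-)normalised mapping from candidate profiles to probabilities.
#'
#' @param ctx a [cell_context()].
#' @param profiles list of candidate [cn_profile()]s.
#' @param prior numeric vector of probabilities, one per candidate.
#' @export
marginal_loglik <- function(ctx, profiles, prior) {
  if (length(profiles) == 0L) stopf("marginal_loglik: empty prior")
  if (length(prior) != length(profiles))
    stopf("marginal_loglik: prior length does not match profiles")
  keep <- prior > 0
  if (!any(keep)) stopf("marginal_loglik: prior has no mass")
  ll <- vapply(profiles[keep], function(p) data_loglik(ctx, p), numeric(1))
  logsumexp(log(prior[keep]) + ll)
}

#' Dataset log-likelihood under a profile prior
#'
#' Sum over cells of the per-cell marginal log-likelihood.
#' @param obs an [observation_set()].
#' @inheritParams marginal_loglik
#' @export
dataset_loglik <- function(obs, profiles, prior) {
  sum(vapply(seq_len(n_cells(obs)), function(s) {
    marginal_loglik(cell_context_from_obs(obs, s), profiles, prior)
  }, numeric(1)))
}

## Vectorised data log-likelihood of one profile for every cell: returns a
## length-N vector. Equivalent to data_loglik applied per cell but computed
## with matrix operations; used heavily by the trainer.
loglik_all_cells <- function(obs, profile) {
  tot <- total_copy(profile)
  muR <- outer(obs$scaling, tot)                      # N x L
  llR <- rowSums(-0.5 * log(2 * pi * obs$sigmaR) -
                   (obs$R - muR)^2 / (2 * obs$sigmaR))
  muB <- baf_mean(profile)
  llB <- rowSums(-0.5 * log(2 * pi * obs$sigmaB) -
                   sweep(obs$B, 2, muB)^2 / (2 * obs$sigmaB))
  llR + llB
}
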