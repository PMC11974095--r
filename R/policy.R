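#' Convolutional trajectory policy
#'
#' The generative model over CNA trajectories. Given the current copy number
#' profile, the network factorises the probability of the next event into
#' (i) a start head over segments plus two extra logits for "stop" and
#' whole-genome duplication, (ii) an end head over segments conditioned on
#' the start, and (iii) a joint (haplotype, value) head conditioned on start
#' and end. The profile is one-hot encoded per haplotype (copy numbers
#' clipped at `n_levels - 1`), the two haplotype encodings are concatenated
#' per segment, a width-5 length-preserving convolution maps the
#' `2 * n_levels` input channels to `n_conv` channels, and the flattened,
#' tanh-activated result is mapped by a dense layer to an `embed_dim`
#' embedding. One-hot start/end positions share a dense positional embedding
#' that is added to the profile embedding before the end and value heads.
#' Each head applies tanh then a dense layer; a masked softmax restricts
#' probabilities to valid actions (results within `[0, c_max]`, intervals
#' within one chromosome) and renormalises.
#'
#' Defaults follow the production architecture: 20 one-hot copy levels,
#' width-5 convolution from 40 to 10 channels (400 convolution weights per
#' output offset), and a 500-dimensional embedding. Smaller settings are
#' available for enumeration tests.
#'
#' @param segments segment table defining L and chromosome blocks.
#' @param c_max per-haplotype copy number cap for profiles (default 19).
#' @param vmax largest absolute event value (default 5).
#' @param n_levels one-hot alphabet size for copy numbers (default 20).
#' @param n_conv convolution output channels (default 10).
#' @param embed_dim embedding dimension (default 500).
#' @param init_sd standard deviation of the random weight initialisation.
#' @param stop_bias initial bias of the stop logit; positive so untrained
#'   trajectories are short.
#' @param seed optional integer seed for reproducible initialisation.
#' @return Object of class `evocn_policy`.
#' @export
policy_new <- function(segments, c_max = 19L, vmax = 5L, n_levels = 20L,
                       embed_dim = 500L, n_conv = 10L, init_sd = 0.05,
                       stop_bias = 2, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- n_segments(segments)
  cin <- 2L * n_levels
  nvals <- 2L * vmax
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = init_sd), nr, nc)
  params <- list(
    conv_w = array(stats::rnorm(5L * cin * n_conv, sd = init_sd),
                   dim = c(5L, cin, n_conv)),
    conv_b = rep(0, n_conv),
    emb_w = rmat(embed_dim, n_conv * L),
    emb_b = rep(0, embed_dim),
    pos_w = rmat(embed_dim, L),
    pos_b = rep(0, embed_dim),
    start_w = rmat(L + 2L, embed_dim),
    start_b = c(rep(0, L), stop_bias, 0),
    end_w = rmat(L, embed_dim),
    end_b = rep(0, L),
    val_w = rmat(2L * nvals, embed_dim),
    val_b = rep(0, 2L * nvals))
  structure(list(segments = segments, L = L, c_max = as.integer(c_max),
                 vmax = as.integer(vmax), n_levels = as.integer(n_levels),
                 n_conv = as.integer(n_conv), embed_dim = as.integer(embed_dim),
                 params = params),
            class = "evocn_policy")
}

## Index of (hap, value) in the value head's logit vector.
value_index <- function(policy, hap, value) {
  vals <- value_set(policy$vmax)
  (hap - 1L) * length(vals) + match(value, vals)
}

STOP_IDX <- function(policy) policy$L + 1L
WGD_IDX <- function(policy) policy$L + 2L

## ---- Forward pass ---------------------------------------------------------

## One-hot encode a profile into an (L + 4) x (2 * n_levels) zero-padded
## matrix (padding 2 on both sides keeps the convolution length-preserving).
profile_onehot_padded <- function(policy, profile) {
  L <- policy$L; nl <- policy$n_levels
  X <- matrix(0, L + 4L, 2L * nl)
  h1 <- pmin(profile$hap1, nl - 1L)
  h2 <- pmin(profile$hap2, nl - 1L)
  X[cbind(seq_len(L) + 2L, h1 + 1L)] <- 1
  X[cbind(seq_len(L) + 2L, nl + h2 + 1L)] <- 1
  X
}

## Profile embedding with cached intermediates (Xpad, tanh activations, E).
embed_profile_full <- function(policy, profile, cache = NULL) {
  key <- profile_key(profile)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  p <- policy$params
  L <- policy$L
  Xpad <- profile_onehot_padded(policy, profile)
  H <- matrix(rep(p$conv_b, each = L), L, policy$n_conv)
  for (d in 1:5)
    H <- H + Xpad[d:(d + L - 1L), , drop = FALSE] %*% p$conv_w[d, , ]
  tH <- tanh(as.vector(t(H)))              # segment-major flatten
  E <- as.vector(p$emb_w %*% tH + p$emb_b)
  out <- list(Xpad = Xpad, tH = tH, E = E, profile = profile)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Profile embedding
#'
#' Deterministic `embed_dim`-vector summarising a copy number profile
#' (values above `n_levels - 1` are clipped before one-hot encoding).
#' @param policy an [policy_new()] object.
#' @param profile a [cn_profile()].
#' @export
embed_profile <- function(policy, profile) {
  embed_profile_full(policy, profile)$E
}

masked_softmax <- function(logits, mask) {
  z <- ifelse(mask, logits, -Inf)
  m <- max(z)
  e <- exp(z - m)
  e / sum(e)
}

#' Start/stop/WGD distribution at a profile
#'
#' Normalised distribution over `L + 2` actions: choose a start segment,
#' stop, or whole-genome duplication. WGD is masked when doubling would
#' exceed `c_max`; segments with no valid continuation are masked.
#' @inheritParams embed_profile
#' @param cache optional environment for embedding reuse.
#' @return numeric vector of length `L + 2` summing to 1 (names
#'   `seg_1..seg_L`, `stop`, `wgd`).
#' @export
start_distribution <- function(policy, profile, cache = NULL) {
  emb <- embed_profile_full(policy, profile, cache)
  p <- policy$params
  a <- tanh(emb$E)
  logits <- as.vector(p$start_w %*% a + p$start_b)
  mask <- c(valid_starts(profile, policy$vmax), TRUE, wgd_valid(profile))
  out <- masked_softmax(logits, mask)
  names(out) <- c(sprintf("seg_%d", seq_len(policy$L)), "stop", "wgd")
  out
}

#' End-position distribution given a start
#'
#' Softmax over segments masked to the start's chromosome with index at
#' least `start` (and at least one valid value for the interval).
#' @inheritParams start_distribution
#' @param start 1-based start segment index.
#' @export
end_distribution <- function(policy, profile, start, cache = NULL) {
  emb <- embed_profile_full(policy, profile, cache)
  p <- policy$params
  e <- emb$E + p$pos_w[, start] + p$pos_b
  a <- tanh(e)
  logits <- as.vector(p$end_w %*% a + p$end_b)
  masked_softmax(logits, valid_ends(profile, start, policy$segments,
                                    policy$vmax))
}

#' (haplotype, value) distribution given an interval
#'
#' Softmax over the `2 * 2 * vmax` (haplotype, value) pairs, masked to
#' pairs keeping every segment of `[start, end]` within `[0, c_max]`.
#' @inheritParams end_distribution
#' @param end 1-based end segment index.
#' @export
value_distribution <- function(policy, profile, start, end, cache = NULL) {
  emb <- embed_profile_full(policy, profile, cache)
  p <- policy$params
  e <- emb$E + p$pos_w[, start] + p$pos_w[, end] + 2 * p$pos_b
  a <- tanh(e)
  logits <- as.vector(p$val_w %*% a + p$val_b)
  mask <- valid_hap_values(profile, start, end, policy$vmax)
  if (!any(mask)) stopf("value_distribution: interval admits no valid value")
  masked_softmax(logits, mask)
}

## Log-probability of one CNA tuple at a profile.
action_logprob <- function(policy, profile, cna, cache = NULL) {
  sd <- start_distribution(policy, profile, cache)
  if (cna$wgd == 1L) return(log(sd[[WGD_IDX(policy)]]))
  ed <- end_distribution(policy, profile, cna$start, cache)
  vd <- value_distribution(policy, profile, cna$start, cna$end, cache)
  log(sd[[cna$start]]) + log(ed[[cna$end]]) +
    log(vd[[value_index(policy, cna$hap, cna$value)]])
}

stop_logprob <- function(policy, profile, cache = NULL) {
  log(start_distribution(policy, profile, cache)[[STOP_IDX(policy)]])
}

#' Sample a trajectory from the policy
#'
#' Ancestral sampling of (start | stop | WGD), end, and (haplotype, value)
#' per step until the stop action or `max_len` events. Uses R's RNG, so
#' results are reproducible under `set.seed()`.
#'
#' @param policy an [policy_new()] object.
#' @param max_len maximum number of events (stop is forced there).
#' @param cache optional embedding cache environment.
#' @return list with `events` (list of [cna_tuple()]) and `logprob`, the
#'   log-probability of the sampled sequence (identical to
#'   [sequence_logprob()] of the result).
#' @export
sample_trajectory <- function(policy, max_len = 40L, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  P <- normal_profile(policy$L, c_max = policy$c_max)
  events <- list()
  lp <- 0
  for (step in seq_len(max_len + 1L)) {
    sd <- start_distribution(policy, P, cache)
    if (length(events) == max_len) {            # forced stop at the horizon
      lp <- lp + log(sd[[STOP_IDX(policy)]])
      break
    }
    k <- sample.int(length(sd), 1L, prob = sd)
    lp <- lp + log(sd[[k]])
    if (k == STOP_IDX(policy)) break
    if (k == WGD_IDX(policy)) {
      cna <- cna_tuple(wgd = 1L)
    } else {
      ed <- end_distribution(policy, P, k, cache)
      e <- sample.int(length(ed), 1L, prob = ed)
      lp <- lp + log(ed[[e]])
      vd <- value_distribution(policy, P, k, e, cache)
      vi <- sample.int(length(vd), 1L, prob = vd)
      lp <- lp + log(vd[[vi]])
      vals <- value_set(policy$vmax)
      hap <- if (vi <= length(vals)) 1L else 2L
      cna <- cna_tuple(0L, hap, k, e, vals[((vi - 1L) %% length(vals)) + 1L])
    }
    events[[length(events) + 1L]] <- cna
    P <- apply_cna(P, cna, policy$segments)
  }
  list(events = events, logprob = lp)
}

## ---- Gradients ------------------------------------------------------------

## Zero gradient accumulator matching the parameter list, plus deferred
## profile-embedding cotangents (summed per unique profile so the expensive
## embedding backward runs once per profile per flush).
grad_zero <- function(policy) {
  g <- lapply(policy$params, function(x) x * 0)   # preserves shape exactly
  env <- new.env(parent = emptyenv())
  env$g <- g
  env$dE <- new.env(parent = emptyenv())
  env$profiles <- new.env(parent = emptyenv())
  env
}

## Backward of one head: accumulates head weight grads, returns the
## cotangent of the pre-tanh input embedding.
head_backward <- function(policy, gacc, w_name, b_name, a, dlogits) {
  p <- policy$params
  gacc$g[[w_name]] <- gacc$g[[w_name]] + outer(dlogits, a)
  gacc$g[[b_name]] <- gacc$g[[b_name]] + dlogits
  (1 - a^2) * as.vector(crossprod(p[[w_name]], dlogits))
}

## d log softmax(logits)[k] / d logits  (masked entries get 0).
dlogits_categorical <- function(probs, k, mask) {
  d <- -probs
  d[k] <- d[k] + 1
  d[!mask] <- 0
  d
}

add_dE <- function(gacc, profile, de) {
  key <- profile_key(profile)
  cur <- gacc$dE[[key]]
  gacc$dE[[key]] <- if (is.null(cur)) de else cur + de
  if (is.null(gacc$profiles[[key]])) gacc$profiles[[key]] <- profile
}

## Accumulate coef * d log p(step action) / d theta for one step.
## action: list(kind = "stop"|"wgd"|"cna", cna = tuple or NULL).
step_grad <- function(policy, gacc, profile, action, coef, cache) {
  emb <- embed_profile_full(policy, profile, cache)
  p <- policy$params
  ## start head
  sdist <- start_distribution(policy, profile, cache)
  mask <- c(valid_starts(profile, policy$vmax), TRUE, wgd_valid(profile))
  k <- switch(action$kind, stop = STOP_IDX(policy), wgd = WGD_IDX(policy),
              cna = action$cna$start)
  a <- tanh(emb$E)
  de <- head_backward(policy, gacc, "start_w", "start_b", a,
                      dlogits = coef * dlogits_categorical(sdist, k, mask))
  add_dE(gacc, profile, de)
  if (action$kind != "cna") return(invisible())
  cna <- action$cna
  ## end head
  ed <- end_distribution(policy, profile, cna$start, cache)
  emask <- valid_ends(profile, cna$start, policy$segments, policy$vmax)
  e_in <- emb$E + p$pos_w[, cna$start] + p$pos_b
  a <- tanh(e_in)
  de <- head_backward(policy, gacc, "end_w", "end_b", a,
                      dlogits = coef * dlogits_categorical(ed, cna$end, emask))
  add_dE(gacc, profile, de)
  gacc$g$pos_w[, cna$start] <- gacc$g$pos_w[, cna$start] + de
  gacc$g$pos_b <- gacc$g$pos_b + de
  ## value head
  vd <- value_distribution(policy, profile, cna$start, cna$end, cache)
  vmask <- valid_hap_values(profile, cna$start, cna$end, policy$vmax)
  vi <- value_index(policy, cna$hap, cna$value)
  v_in <- emb$E + p$pos_w[, cna$start] + p$pos_w[, cna$end] + 2 * p$pos_b
  a <- tanh(v_in)
  de <- head_backward(policy, gacc, "val_w", "val_b", a,
                      dlogits = coef * dlogits_categorical(vd, vi, vmask))
  add_dE(gacc, profile, de)
  gacc$g$pos_w[, cna$start] <- gacc$g$pos_w[, cna$start] + de
  gacc$g$pos_w[, cna$end] <- gacc$g$pos_w[, cna$end] + de
  gacc$g$pos_b <- gacc$g$pos_b + 2 * de
  invisible()
}

## Accumulate coef * d log p(G) / d theta.
sequence_grad <- function(policy, gacc, G, coef, cache) {
  P <- normal_profile(policy$L, c_max = policy$c_max)
  for (cna in G) {
    act <- if (cna$wgd == 1L) list(kind = "wgd", cna = cna)
      else list(kind = "cna", cna = cna)
    step_grad(policy, gacc, P, act, coef, cache)
    P <- apply_cna(P, cna, policy$segments)
  }
  step_grad(policy, gacc, P, list(kind = "stop"), coef, cache)
  invisible()
}

## Run the deferred embedding backward for every touched profile and clear
## the pending cotangents.
flush_profile_grads <- function(policy, gacc, cache) {
  p <- policy$params
  L <- policy$L
  for (key in ls(gacc$dE)) {
    dE <- gacc$dE[[key]]
    emb <- embed_profile_full(policy, gacc$profiles[[key]], cache)
    gacc$g$emb_w <- gacc$g$emb_w + outer(dE, emb$tH)
    gacc$g$emb_b <- gacc$g$emb_b + dE
    dt <- as.vector(crossprod(p$emb_w, dE))
    df <- (1 - emb$tH^2) * dt
    dH <- t(matrix(df, nrow = policy$n_conv))   # L x n_conv
    for (d in 1:5) {
      rows <- emb$Xpad[d:(d + L - 1L), , drop = FALSE]
      gacc$g$conv_w[d, , ] <- gacc$g$conv_w[d, , ] + crossprod(rows, dH)
    }
    gacc$g$conv_b <- gacc$g$conv_b + colSums(dH)
    rm(list = key, envir = gacc$dE)
  }
  invisible(gacc)
}

## Full gradient of sum_i coefs[i] * log p(G_list[[i]]) as a parameter list.
trajectory_grads <- function(policy, G_list, coefs, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  gacc <- grad_zero(policy)
  for (i in seq_along(G_list))
    sequence_grad(policy, gacc, G_list[[i]], coefs[i], cache)
  flush_profile_grads(policy, gacc, cache)
  gacc$g
}

## ---- Parameter vector helpers (tests, optimisers) -------------------------

params_flatten <- function(params) unlist(params, use.names = FALSE)

params_unflatten <- function(template, x) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- x[pos + seq_len(n)]
    out[[nm]] <- if (is.null(dim(template[[nm]]))) v
      else array(v, dim = dim(template[[nm]]))
    pos <- pos + n
  }
  out
}
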