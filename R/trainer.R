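#' Canonical decomposition of a profile into a generating sequence
#'
#' Deterministic sequence of CNA events reconstructing a profile from the
#' normal diploid genome: a whole-genome duplication is prepended when the
#' median total copy number is at least 3, then each haplotype's maximal
#' runs of constant difference from the post-WGD baseline (within
#' chromosome blocks, genome order, haplotype 1 first) become interval
#' events; runs whose difference exceeds the value cap are chunked into
#' several events of value at most `vmax` in magnitude. The decomposition of
#' the normal profile is the empty sequence.
#'
#' @param profile target [cn_profile()].
#' @param segments segment table.
#' @param vmax value cap of the action space.
#' @return list of [cna_tuple()]s.
#' @export
canonical_decomposition <- function(profile, segments, vmax = 5L) {
  events <- list()
  base <- 1L
  if (stats::median(total_copy(profile)) > 3) {
    events[[1L]] <- cna_tuple(wgd = 1L)
    base <- 2L
  }
  blk <- chrom_block(segments)
  for (h in 1:2) {
    d <- (if (h == 1L) profile$hap1 else profile$hap2) - base
    r <- rle(paste(blk, d))          # runs of constant diff within chromosome
    pos <- 1L
    for (j in seq_along(r$lengths)) {
      len <- r$lengths[j]
      dj <- d[pos]
      while (dj != 0L) {
        v <- max(-vmax, min(vmax, dj))
        events[[length(events) + 1L]] <-
          cna_tuple(0L, h, pos, pos + len - 1L, v)
        dj <- dj - v
      }
      pos <- pos + len
    }
  }
  events
}

#' Neighbourhood-consensus denoising of per-cell profiles
#'
#' For each cell, takes the segment-wise modal copy number pair over the
#' cells whose profiles agree with it on at least `threshold` of segments
#' (always including the cell itself). Independent per-cell calling errors
#' fall on different segments in different cells of a clone, so the local
#' mode recovers the shared clone profile while genuinely distinct cells
#' (few similar neighbours) keep their own calls. Used to seed the
#' trajectory guidance with plausible consensus profiles; it never enters
#' the final assignment directly.
#'
#' @param profiles list of per-cell [cn_profile()]s.
#' @param threshold minimum fraction of agreeing segments for a cell to
#'   join another cell's neighbourhood (default 0.8).
#' @param passes number of denoising passes; later passes operate on the
#'   previous pass's output, whose sharpened agreement pulls fragmented
#'   neighbourhoods together (default 1).
#' @return list of denoised per-cell [cn_profile()]s.
#' @export
consensus_denoise <- function(profiles, threshold = 0.8, passes = 1L) {
  N <- length(profiles)
  if (N == 1L) return(profiles)
  L <- length(profiles[[1]]$hap1)
  c_max <- profiles[[1]]$c_max
  for (pass in seq_len(passes)) {
    M <- do.call(rbind, lapply(profiles, function(p) c(p$hap1, p$hap2)))
    key <- M[, seq_len(L)] * (c_max + 1L) + M[, L + seq_len(L)]
    agree <- matrix(0, N, N)      # pairwise fraction of agreeing segments
    for (i in seq_len(N))
      agree[i, ] <- rowMeans(key == rep(key[i, ], each = N))
    profiles <- lapply(seq_len(N), function(i) {
      nb <- which(agree[i, ] >= threshold)
      h1 <- integer(L); h2 <- integer(L)
      for (j in seq_len(L)) {
        tab <- sort(table(key[nb, j]), decreasing = TRUE)
        kk <- as.integer(names(tab)[1])
        h1[j] <- kk %/% (c_max + 1L)
        h2[j] <- kk %% (c_max + 1L)
      }
      cn_profile(h1, h2, c_max = c_max)
    })
  }
  profiles
}

## ---- Trainer state --------------------------------------------------------

#' Initialise the trainer from the naive calls
#'
#' Builds the trainer state: the policy, the profile cache seeded with the
#' canonical decompositions of the initialiser's per-cell profiles (and the
#' normal profile), per-cell data log-likelihood vectors for the cached
#' profiles, and the running per-cell marginal-likelihood estimates.
#'
#' @param policy an [policy_new()] object.
#' @param obs an [observation_set()] whose `scaling` has been set (see
#'   [call_naive()]).
#' @param naive an `evocn_naive` result guiding the optimisation.
#' @param lr Adam learning rate.
#' @param epsilon_start,epsilon_end mixture weight of the guided proposal,
#'   decayed linearly over the iteration budget.
#' @param guide_frac fraction of the iteration budget over which the
#'   annealed guidance (behaviour-cloning) gradient on canonical guide
#'   sequences is active.
#' @param max_len trajectory length cap during sampling.
#' @param refresh_every cached sequence log-probabilities are recomputed
#'   under the current parameters every this many iterations.
#' @return Object of class `evocn_trainer`.
#' @export
trainer_init <- function(policy, obs, naive, lr = 1e-3,
                         epsilon_start = 0.5, epsilon_end = 0.1,
                         guide_frac = 0.6, max_len = 40L,
                         refresh_every = 25L) {
  state <- structure(list(policy = policy, obs = obs, naive = naive,
                          lr = lr, epsilon_start = epsilon_start,
                          epsilon_end = epsilon_end, guide_frac = guide_frac,
                          max_len = as.integer(max_len),
                          refresh_every = as.integer(refresh_every),
                          iteration = 0L),
                     class = "evocn_trainer")
  state$cache <- new.env(parent = emptyenv())   # profile key -> record
  state$adam <- list(m = lapply(policy$params, function(x) x * 0),
                     v = lapply(policy$params, function(x) x * 0),
                     t = 0L)
  ## canonical guide sequences: one per cell for the raw initial profiles
  ## plus one per cell for their neighbourhood-consensus denoised versions,
  ## so the proposal can reach shared clone profiles that no single cell's
  ## independent call hits exactly
  guide_profiles <- c(naive$profiles, consensus_denoise(naive$profiles))
  canon <- lapply(guide_profiles, canonical_decomposition,
                  segments = policy$segments, vmax = policy$vmax)
  state$canon_seqs <- canon
  state$canon_keys <- vapply(canon, sequence_key, character(1))
  state$canon_tab <- table(state$canon_keys)
  emb_cache <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(canon)) {
    key <- profile_key(guide_profiles[[i]])
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    cache_insert(state, guide_profiles[[i]], canon[[i]],
                 sequence_logprob(canon[[i]], policy, emb_cache))
  }
  Pnorm <- normal_profile(policy$L, c_max = policy$c_max)
  if (is.null(state$cache[[profile_key(Pnorm)]]))
    cache_insert(state, Pnorm, list(),
                 sequence_logprob(list(), policy, emb_cache))
  state <- update_marginals(state)
  state$log <- data.frame(iteration = integer(), est_loglik = numeric(),
                          mean_reward = numeric(), cache_size = integer())
  state
}

## Insert or improve a cached profile record.
cache_insert <- function(state, profile, events, lp) {
  key <- profile_key(profile)
  rec <- state$cache[[key]]
  if (is.null(rec)) {
    state$cache[[key]] <- list(profile = profile, events = events, lp = lp,
                               ll = loglik_all_cells(state$obs, profile))
  } else if (lp > rec$lp) {
    rec$lp <- lp; rec$events <- events
    state$cache[[key]] <- rec
  }
  invisible(state)
}

## Recompute cached best-sequence log-probabilities under the current
## parameters. The cache can grow into hundreds of profiles of which only
## a fraction carries any marginal mass; refreshing is restricted to the
## `max_profiles` most important ones (by stale sequence probability plus
## best relative per-cell fit), a documented bias/cost trade-off. Passing
## Inf refreshes everything (done once before inference).
refresh_cache_lps <- function(state, emb_cache, max_profiles = 150L) {
  keys <- ls(state$cache)
  if (length(keys) > max_profiles) {
    lps <- vapply(keys, function(k) state$cache[[k]]$lp, numeric(1))
    rel_fit <- vapply(keys, function(k) {
      ll <- state$cache[[k]]$ll
      if (is.null(state$log_marginals)) max(ll)
      else max(ll - state$log_marginals)
    }, numeric(1))
    imp <- lps + rel_fit
    keys <- keys[order(imp, decreasing = TRUE)[seq_len(max_profiles)]]
  }
  for (key in keys) {
    rec <- state$cache[[key]]
    rec$lp <- sequence_logprob(rec$events, state$policy, emb_cache)
    state$cache[[key]] <- rec
  }
  state
}

#' Refresh the per-cell marginal-likelihood estimates from the cache
#'
#' The marginal `Pr(data_s | theta)` is estimated by renormalising the
#' cached best-sequence probabilities over all cached profiles and mixing
#' the cached per-cell likelihoods:
#' `m_s = sum_P qhat(P) Pr(data_s | P)`. The estimate never falls below the
#' largest single-profile contribution (it is a sum of positive terms), so
#' rewards stay finite.
#'
#' @param state an `evocn_trainer`.
#' @return the state with updated `log_marginals` (length-N, log scale).
#' @export
update_marginals <- function(state) {
  keys <- ls(state$cache)
  if (length(keys) == 0L) stopf("update_marginals: empty profile cache")
  lps <- vapply(keys, function(k) state$cache[[k]]$lp, numeric(1))
  logq <- lps - logsumexp(lps)
  LL <- do.call(rbind, lapply(keys, function(k) state$cache[[k]]$ll))
  M <- logq + LL                      # K x N, column = cell
  state$log_marginals <- apply(M, 2, logsumexp)
  state
}

#' Trajectory reward
#'
#' Sum over cells of the ratio between the data likelihood under the
#' trajectory's generated profile and the current marginal-likelihood
#' estimate, computed in log space per cell before exponentiating.
#'
#' @param G generating sequence (list of [cna_tuple()]s) or a
#'   [cn_profile()].
#' @param state an `evocn_trainer` with initialised marginal estimates.
#' @return nonnegative scalar reward.
#' @export
reward <- function(G, state) {
  profile <- if (inherits(G, "evocn_profile")) G
    else apply_sequence(G, state$policy$segments, c_max = state$policy$c_max)
  key <- profile_key(profile)
  rec <- state$cache[[key]]
  ll <- if (!is.null(rec)) rec$ll else loglik_all_cells(state$obs, profile)
  sum(safe_exp(ll - state$log_marginals))
}

current_epsilon <- function(state, total_iters) {
  f <- min(1, state$iteration / max(1, total_iters))
  state$epsilon_start + f * (state$epsilon_end - state$epsilon_start)
}

current_guide_weight <- function(state, total_iters) {
  horizon <- max(1, round(state$guide_frac * total_iters))
  max(0, 1 - state$iteration / horizon)
}

#' Draw one trajectory from the guided mixture proposal
#'
#' With probability `epsilon` emits the canonical decomposition of the
#' naive profile of a uniformly chosen cell; otherwise samples from the
#' current policy. The returned proposal log-density accounts for both
#' branches of the mixture, so importance weights
#' `Pr(G | theta) / q(G)` are exact (and equal to 1 when `epsilon = 0`).
#'
#' @param state an `evocn_trainer`.
#' @param epsilon mixing probability in `[0, 1]`.
#' @param emb_cache embedding cache for the current parameters.
#' @return list with `events`, `logprob` (policy log-probability),
#'   `q_log` (proposal log-density), `guided` (logical).
#' @export
guided_proposal <- function(state, epsilon, emb_cache) {
  guided <- stats::runif(1) < epsilon
  if (guided) {
    u <- sample.int(length(state$canon_seqs), 1L)
    events <- state$canon_seqs[[u]]
    key <- state$canon_keys[u]
    lp <- sequence_logprob(events, state$policy, emb_cache)
  } else {
    tr <- sample_trajectory(state$policy, state$max_len, emb_cache)
    events <- tr$events
    lp <- tr$logprob
    key <- sequence_key(events)
  }
  hit <- match(key, names(state$canon_tab))
  n_canon <- if (is.na(hit)) 0L else as.integer(state$canon_tab[hit])
  q_naive <- n_canon / length(state$canon_seqs)
  q_log <- if (epsilon >= 1) log(q_naive)
    else logsumexp(c(log(epsilon) + log(q_naive), log1p(-epsilon) + lp))
  list(events = events, logprob = lp, q_log = q_log, guided = guided)
}

adam_update <- function(state, grads, clip_norm = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (!is.finite(gn)) stopf("train_step: non-finite gradient (norm = %g)", gn)
  scale <- if (gn > clip_norm) clip_norm / gn else 1
  ad <- state$adam
  ad$t <- ad$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    ad$m[[nm]] <- b1 * ad$m[[nm]] + (1 - b1) * g
    ad$v[[nm]] <- b2 * ad$v[[nm]] + (1 - b2) * g^2
    mhat <- ad$m[[nm]] / (1 - b1^ad$t)
    vhat <- ad$v[[nm]] / (1 - b2^ad$t)
    ## gradient ascent on the objective
    state$policy$params[[nm]] <- state$policy$params[[nm]] +
      state$lr * mhat / (sqrt(vhat) + eps)
  }
  state$adam <- ad
  state
}

#' One reinforcement-learning update
#'
#' Draws a batch of trajectories from the guided mixture proposal, computes
#' rewards against the current marginal estimates (held constant in the
#' gradient), forms the importance-weighted policy-gradient estimate
#' `mean_b r(G_b) w(G_b) grad log Pr(G_b | theta)` plus the annealed
#' guidance term, ascends it with Adam (global-norm clipping), inserts the
#' generated profiles into the cache, and refreshes the marginal estimates.
#'
#' @param state an `evocn_trainer`.
#' @param batch_size number of trajectories per update.
#' @param epsilon guided-proposal mixing probability.
#' @param guide_weight coefficient of the guidance gradient term.
#' @return the updated state.
#' @export
train_step <- function(state, batch_size = 32L, epsilon = 0.5,
                       guide_weight = 0) {
  emb_cache <- new.env(parent = emptyenv())
  if (state$iteration %% state$refresh_every == 0L)
    state <- refresh_cache_lps(state, emb_cache)
  state <- update_marginals(state)

  draws <- lapply(seq_len(batch_size), function(b)
    guided_proposal(state, epsilon, emb_cache))
  profiles <- lapply(draws, function(d)
    apply_sequence(d$events, state$policy$segments,
                   c_max = state$policy$c_max))
  rewards <- vapply(profiles, function(P) reward(P, state), numeric(1))
  weights <- vapply(draws, function(d) exp(d$logprob - d$q_log), numeric(1))
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("train_step: invalid importance weight")
  guided <- vapply(draws, `[[`, logical(1), "guided")
  coefs <- rewards * weights / batch_size +
    ifelse(guided, guide_weight / batch_size, 0)

  keep <- abs(coefs) > 0
  if (any(keep)) {
    grads <- trajectory_grads(state$policy,
                              lapply(draws[keep], `[[`, "events"),
                              coefs[keep], emb_cache)
    state <- adam_update(state, grads)
  }
  for (b in seq_len(batch_size))
    cache_insert(state, profiles[[b]], draws[[b]]$events, draws[[b]]$logprob)

  state$iteration <- state$iteration + 1L
  state$log <- rbind(state$log, data.frame(
    iteration = state$iteration,
    est_loglik = sum(state$log_marginals),
    mean_reward = mean(rewards),
    cache_size = length(ls(state$cache))))
  state
}

#' Train the trajectory policy
#'
#' Full training driver: builds the policy and trainer state from the
#' observations and naive calls, then runs [train_step()] for up to `iters`
#' iterations with a linearly decayed proposal mixing probability and an
#' annealed guidance weight, stopping early when the estimated dataset
#' log-likelihood improves by less than `tol` over `patience` iterations.
#'
#' @param obs an [observation_set()].
#' @param naive result of [call_naive()]; its scaling factors are copied
#'   into `obs`.
#' @param iters iteration budget (default 2000).
#' @param batch_size trajectories per update (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param epsilon_start,epsilon_end guided-proposal schedule.
#' @param max_len trajectory length cap.
#' @param tol,patience early-stopping rule.
#' @param seed RNG seed for the whole run (initialisation and sampling).
#' @param embed_dim,n_conv network size knobs (defaults 500 and 10).
#' @param verbose print progress every 50 iterations.
#' @return trained `evocn_trainer` state.
#' @export
rl_train <- function(obs, naive, iters = 2000L, batch_size = 32L, lr = 1e-3,
                     epsilon_start = 0.5, epsilon_end = 0.1, max_len = 40L,
                     tol = 1e-4, patience = 100L, seed = 1L,
                     embed_dim = 500L, n_conv = 10L, verbose = FALSE) {
  set.seed(seed)
  obs <- apply_naive_scaling(obs, naive)
  policy <- policy_new(obs$segments, c_max = naive$profiles[[1]]$c_max,
                       embed_dim = embed_dim, n_conv = n_conv)
  state <- trainer_init(policy, obs, naive, lr = lr,
                        epsilon_start = epsilon_start,
                        epsilon_end = epsilon_end, max_len = max_len)
  best <- -Inf; best_iter <- 0L
  for (it in seq_len(iters)) {
    state <- train_step(state, batch_size = batch_size,
                        epsilon = current_epsilon(state, iters),
                        guide_weight = current_guide_weight(state, iters))
    cur <- state$log$est_loglik[nrow(state$log)]
    if (cur > best + tol) { best <- cur; best_iter <- it }
    if (verbose && it %% 50L == 0L)
      message(sprintf("iter %d  est loglik %.2f  cache %d", it, cur,
                      state$log$cache_size[nrow(state$log)]))
    if (it - best_iter >= patience) break
  }
  ## bring all cached sequence probabilities up to date with the final
  ## parameters before inference uses them as the profile prior
  state <- refresh_cache_lps(state, new.env(parent = emptyenv()),
                             max_profiles = Inf)
  state <- update_marginals(state)
  state
}
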