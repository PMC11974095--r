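## Maximum-likelihood profile for a set of cells jointly (per segment,
## argmax over copy number pairs of the summed log-densities).
ml_profile_for_cells <- function(obs, cells, c_max = 19L) {
  pairs <- naive_pair_table(c_max)
  tot <- pairs[, 1] + pairs[, 2]
  muB <- ifelse(tot > 0, pairs[, 2] / pmax(tot, 1L), 0.5)
  L <- ncol(obs$R)
  score <- matrix(0, nrow(pairs), L)
  for (s in cells) {
    score <- score -
      outer(obs$scaling[s] * tot, obs$R[s, ], `-`)^2 /
        matrix(2 * obs$sigmaR[s, ], nrow(pairs), L, byrow = TRUE) -
      outer(muB, obs$B[s, ], `-`)^2 /
        matrix(2 * obs$sigmaB[s, ], nrow(pairs), L, byrow = TRUE)
  }
  best <- apply(score, 2, function(col) which(col >= max(col) - 1e-9)[1])
  cn_profile(pairs[best, 1], pairs[best, 2], c_max = c_max)
}

## Per-cell, per-segment log-density of given profiles (pair chosen by the
## profile), used to find segments where a cell's data contradict its
## assigned profile.
segment_loglik_cell <- function(obs, s, profile) {
  tot <- total_copy(profile)
  muB <- baf_mean(profile)
  -(obs$R[s, ] - obs$scaling[s] * tot)^2 / (2 * obs$sigmaR[s, ]) -
    (obs$B[s, ] - muB)^2 / (2 * obs$sigmaB[s, ])
}

add_candidate <- function(state, pool, have, P, emb_cache) {
  k <- profile_key(P)
  if (!is.null(have[[k]])) return(pool)
  have[[k]] <- TRUE
  rec <- state$cache[[k]]
  if (is.null(rec)) {
    events <- canonical_decomposition(P, state$policy$segments,
                                      state$policy$vmax)
    rec <- list(profile = P, events = events,
                lp = sequence_logprob(events, state$policy, emb_cache),
                ll = loglik_all_cells(state$obs, P))
  }
  c(pool, list(rec))
}

#' Assign a copy number profile to every cell
#'
#' For each cell, selects from the candidate pool the profile maximising
#' the sum of its generative log-probability — approximated by the
#' best-found generating-sequence log-probability, a lower bound of the
#' full profile probability — and the cell's data log-likelihood. The pool
#' contains every cached profile (which includes all initialiser profiles);
#' optional refinement rounds enlarge it with (i) joint maximum-likelihood
#' profiles of the current clones and (ii) per-cell hybrids in which
#' segments whose data strongly contradict the assigned profile revert to
#' the cell's own best call. Enlarging the pool can only increase the
#' per-cell objective; whether cells merge into clones remains arbitrated
#' by the trajectory prior against the likelihood, never by clustering.
#' Ties break by lexicographic profile order, so assignment is
#' deterministic and permutation-equivariant across cells.
#'
#' @param state a trained `evocn_trainer` (see [rl_train()]).
#' @param extra_profiles optional list of additional candidate
#'   [cn_profile()]s to place in the pool.
#' @param refine_rounds pool-enrichment rounds (default 2; 0 restricts the
#'   argmax to the cached pool).
#' @param gap_threshold per-segment log-likelihood contradiction (nats)
#'   above which a hybrid candidate reverts a segment to the cell's own
#'   best call.
#' @return Object of class `evocn_calls`: list with `profiles` (per-cell
#'   [cn_profile()]), `score` (per-cell assignment score), `clone` (integer
#'   labels over identical profiles), `n_unique`, `cell_ids`.
#' @export
assign_profiles <- function(state, extra_profiles = NULL,
                            refine_rounds = 2L, gap_threshold = 4) {
  keys <- ls(state$cache)
  pool <- lapply(keys, function(k) state$cache[[k]])
  have <- new.env(parent = emptyenv())
  emb_cache <- new.env(parent = emptyenv())
  for (k in keys) have[[k]] <- TRUE
  for (P in extra_profiles %||% list())
    pool <- add_candidate(state, pool, have, P, emb_cache)
  if (length(pool) == 0L) stopf("assign_profiles: empty candidate pool")
  c_max <- state$policy$c_max
  N <- n_cells(state$obs)

  pick_assignment <- function(pool) {
    ## lexicographic order over profile vectors: first maximum wins ties
    mats <- do.call(rbind, lapply(pool, function(r)
      c(r$profile$hap1, r$profile$hap2)))
    ord <- do.call(order, as.data.frame(mats))
    pool <- pool[ord]
    S <- do.call(rbind, lapply(pool, function(r) r$lp + r$ll))  # K x N
    pick <- apply(S, 2, which.max)
    list(pool = pool, pick = pick,
         score = S[cbind(pick, seq_len(ncol(S)))])
  }

  asg <- pick_assignment(pool)
  for (round in seq_len(refine_rounds)) {
    profiles <- lapply(asg$pick, function(k) asg$pool[[k]]$profile)
    pkeys <- vapply(profiles, profile_key, character(1))
    ## joint ML profile per current clone of two or more cells
    for (k in unique(pkeys[duplicated(pkeys)])) {
      members <- which(pkeys == k)
      pool <- add_candidate(state, pool, have,
                            ml_profile_for_cells(state$obs, members, c_max),
                            emb_cache)
    }
    ## fragmented clones: for pairs of assigned profiles that are nearly
    ## identical, offer the joint ML profile of the union of their cells,
    ## letting the prior decide whether the fragments are one clone
    uk <- unique(pkeys)
    if (length(uk) > 1L) {
      reps <- lapply(uk, function(k) profiles[[match(k, pkeys)]])
      for (a in seq_along(uk)[-1]) for (b in seq_len(a - 1L)) {
        d <- sum(abs(reps[[a]]$hap1 - reps[[b]]$hap1)) +
          sum(abs(reps[[a]]$hap2 - reps[[b]]$hap2))
        if (d > 0 && d <= 6) {
          members <- which(pkeys %in% uk[c(a, b)])
          pool <- add_candidate(state, pool, have,
                                ml_profile_for_cells(state$obs, members,
                                                     c_max),
                                emb_cache)
        }
      }
    }
    ## per-cell hybrids: revert strongly contradicted segments
    for (s in seq_len(N)) {
      P <- profiles[[s]]
      own <- call_naive_profile(cell_context_from_obs(state$obs, s),
                                state$obs$scaling[s], c_max = c_max)
      gap <- segment_loglik_cell(state$obs, s, own) -
        segment_loglik_cell(state$obs, s, P)
      fix <- gap > gap_threshold
      if (any(fix)) {
        h1 <- P$hap1; h2 <- P$hap2
        h1[fix] <- own$hap1[fix]; h2[fix] <- own$hap2[fix]
        pool <- add_candidate(state, pool, have,
                              cn_profile(h1, h2, c_max = c_max), emb_cache)
      }
    }
    asg <- pick_assignment(pool)
  }
  profiles <- lapply(asg$pick, function(k) asg$pool[[k]]$profile)
  pkeys <- vapply(profiles, profile_key, character(1))
  clone <- as.integer(factor(pkeys, levels = unique(pkeys)))
  structure(list(profiles = profiles, score = asg$score, clone = clone,
                 n_unique = length(unique(pkeys)),
                 cell_ids = state$obs$cell_ids),
            class = "evocn_calls")
}

#' Clone summary of a call set
#'
#' Groups cells by identical assigned profile ("clone" in the strict
#' sense), returning clone sizes in descending order with per-clone
#' consensus profiles.
#'
#' @param calls an `evocn_calls` object (see [assign_profiles()]).
#' @return list with `table` (data.frame: clone, size), `profiles` (one
#'   consensus [cn_profile()] per clone, in table order), and `n_unique`.
#' @export
summarize_clones <- function(calls) {
  keys <- vapply(calls$profiles, profile_key, character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  profiles <- lapply(names(tab), function(k)
    calls$profiles[[match(k, keys)]])
  list(table = data.frame(clone = seq_along(tab),
                          size = as.integer(tab),
                          row.names = NULL),
       profiles = profiles,
       n_unique = length(tab))
}
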