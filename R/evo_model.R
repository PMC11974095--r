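#' CNA tuples and generating sequences
#'
#' A CNA tuple is one mutation event: either a whole-genome duplication
#' (every copy number doubles) or an interval event adding a signed integer
#' `value` to one haplotype over segments `start..end` of a single
#' chromosome. A generating sequence is an ordered list of tuples whose
#' application to the normal diploid profile yields a profile; the empty
#' sequence yields the normal profile itself.
#'
#' @param wgd 0 or 1; when 1 the remaining fields are ignored.
#' @param hap haplotype 1 or 2.
#' @param start,end 1-based segment indices, `start <= end`, same chromosome.
#' @param value nonzero integer change in copy number, `|value| <= 5` by
#'   default convention.
#' @return Object of class `evocn_cna`.
#' @export
cna_tuple <- function(wgd = 0L, hap = 1L, start = 1L, end = start,
                      value = 1L) {
  wgd <- as.integer(wgd)
  if (!wgd %in% c(0L, 1L)) stopf("cna tuple: wgd must be 0 or 1")
  if (wgd == 0L) {
    if (!hap %in% c(1L, 2L)) stopf("cna tuple: hap must be 1 or 2")
    if (start > end) stopf("cna tuple: start must be <= end")
    if (value == 0L) stopf("cna tuple: value 0 is not an event")
  }
  structure(list(wgd = wgd, hap = as.integer(hap), start = as.integer(start),
                 end = as.integer(end), value = as.integer(value)),
            class = "evocn_cna")
}

cna_key <- function(c) {
  if (c$wgd == 1L) "W" else sprintf("%d:%d-%d:%+d", c$hap, c$start, c$end, c$value)
}

sequence_key <- function(G) {
  if (length(G) == 0L) "" else paste(vapply(G, cna_key, character(1)),
                                     collapse = ";")
}

#' Apply one CNA tuple to a profile
#'
#' WGD doubles both haplotypes on every segment; an interval event adds
#' `value` to the chosen haplotype on `start..end` and leaves everything
#' else unchanged. The result must stay within `[0, c_max]` and the interval
#' must lie on one chromosome; violations raise errors (samplers mask such
#' actions instead of attempting them).
#'
#' @param profile a [cn_profile()].
#' @param cna a [cna_tuple()].
#' @param segments segment table defining chromosome blocks.
#' @return The mutated [cn_profile()].
#' @export
apply_cna <- function(profile, cna, segments) {
  c_max <- profile$c_max
  if (cna$wgd == 1L) {
    h1 <- 2L * profile$hap1; h2 <- 2L * profile$hap2
    if (max(h1, h2) > c_max)
      stopf("apply_cna: whole-genome duplication exceeds c_max")
    return(cn_profile(h1, h2, c_max = c_max))
  }
  L <- length(profile$hap1)
  if (cna$start < 1L || cna$end > L)
    stopf("apply_cna: interval outside [1, L]")
  if (!same_chromosome(segments, cna$start, cna$end))
    stopf("apply_cna: interval crosses a chromosome boundary")
  idx <- cna$start:cna$end
  h1 <- profile$hap1; h2 <- profile$hap2
  if (cna$hap == 1L) h1[idx] <- h1[idx] + cna$value
  else h2[idx] <- h2[idx] + cna$value
  if (min(h1, h2) < 0L || max(h1, h2) > c_max)
    stopf("apply_cna: result leaves [0, c_max]")
  cn_profile(h1, h2, c_max = c_max)
}

#' Apply a generating sequence to the normal profile
#'
#' Left-fold of [apply_cna()] starting from the normal diploid profile;
#' the empty sequence returns the normal profile.
#'
#' @param G list of [cna_tuple()]s.
#' @param segments segment table.
#' @param c_max per-haplotype copy number cap.
#' @export
apply_sequence <- function(G, segments, c_max = 19L) {
  P <- normal_profile(n_segments(segments), c_max = c_max)
  for (c in G) P <- apply_cna(P, c, segments)
  P
}

## ---- Action validity ------------------------------------------------------

## Values in the action space: -vmax..-1, 1..vmax (0 excluded: a no-op would
## inflate trajectory space without changing the generated profile).
value_set <- function(vmax = 5L) c(-(vmax:1), 1:vmax)

wgd_valid <- function(profile) {
  2L * max(profile$hap1, profile$hap2) <= profile$c_max
}

## Logical vector over value_set x hap (hap1 block then hap2 block):
## TRUE where adding the value keeps all segments of [start, end] in range.
valid_hap_values <- function(profile, start, end, vmax = 5L) {
  vals <- value_set(vmax)
  idx <- start:end
  ok <- logical(2L * length(vals))
  for (h in 1:2) {
    x <- if (h == 1L) profile$hap1[idx] else profile$hap2[idx]
    lo <- min(x); hi <- max(x)
    ok[(h - 1L) * length(vals) + seq_along(vals)] <-
      (lo + vals >= 0L) & (hi + vals <= profile$c_max)
  }
  ok
}

## Starts from which at least one (end, hap, value) action exists: the
## single-segment interval always admits +1 or -1 on some haplotype unless
## a haplotype is pinned at both bounds (possible only when c_max = 0).
valid_starts <- function(profile, vmax = 5L) {
  ok1 <- profile$hap1 > 0L | profile$hap1 < profile$c_max
  ok2 <- profile$hap2 > 0L | profile$hap2 < profile$c_max
  ok1 | ok2
}

## Ends reachable from `start`: same chromosome, index >= start, and at
## least one (hap, value) keeps the whole interval in range. An interval
## admits a value on haplotype h iff its running minimum allows -1 or its
## running maximum allows +1 (larger magnitudes only relax nothing).
valid_ends <- function(profile, start, segments, vmax = 5L) {
  L <- length(profile$hap1)
  last <- block_end_index(segments)[start]
  idx <- start:last
  ok1 <- cummin(profile$hap1[idx]) >= 1L |
    cummax(profile$hap1[idx]) <= profile$c_max - 1L
  ok2 <- cummin(profile$hap2[idx]) >= 1L |
    cummax(profile$hap2[idx]) <= profile$c_max - 1L
  ok <- logical(L)
  ok[idx] <- ok1 | ok2
  ok
}

## All valid CNA tuples at a profile (enumeration oracle for tiny instances).
enumerate_actions <- function(profile, segments, vmax = 5L) {
  out <- list()
  if (wgd_valid(profile)) out[[length(out) + 1L]] <- cna_tuple(wgd = 1L)
  vals <- value_set(vmax)
  for (j in which(valid_starts(profile, vmax))) {
    for (e in which(valid_ends(profile, j, segments, vmax))) {
      ok <- valid_hap_values(profile, j, e, vmax)
      for (k in which(ok)) {
        h <- if (k <= length(vals)) 1L else 2L
        v <- vals[((k - 1L) %% length(vals)) + 1L]
        out[[length(out) + 1L]] <- cna_tuple(0L, h, j, e, v)
      }
    }
  }
  out
}

#' Log-probability of a generating sequence under a policy
#'
#' Factorises as the product over steps of the policy's event probability
#' given the profile generated so far, times the stop probability at the
#' final profile.
#'
#' @param G list of [cna_tuple()]s (may be empty).
#' @param policy an [evocn_policy()].
#' @param cache optional environment reusing profile embeddings across calls.
#' @return log probability.
#' @export
sequence_logprob <- function(G, policy, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  P <- normal_profile(policy$L, c_max = policy$c_max)
  lp <- 0
  for (c in G) {
    lp <- lp + action_logprob(policy, P, c, cache)
    P <- apply_cna(P, c, policy$segments)
  }
  lp + stop_logprob(policy, P, cache)
}

## ---- Enumeration oracles --------------------------------------------------

## All generating sequences of length <= max_len, with log-probabilities.
## Returns a list of records (events, key, logprob, profile). When
## `force_stop_at_horizon` is TRUE, trajectories of length max_len take
## stop probability 1 (a finite-horizon model whose trajectory probabilities
## sum to exactly 1); otherwise the stop head is always used and the
## enumeration covers only the stop-terminated mass.
enumerate_sequences <- function(policy, max_len,
                                force_stop_at_horizon = FALSE,
                                max_sequences = 250000L) {
  cache <- new.env(parent = emptyenv())
  out <- list()
  recurse <- function(G, P, lp, depth) {
    stop_lp <- if (force_stop_at_horizon && depth == max_len) 0
      else stop_logprob(policy, P, cache)
    out[[length(out) + 1L]] <<- list(events = G, key = sequence_key(G),
                                     logprob = lp + stop_lp,
                                     profile = P)
    if (length(out) > max_sequences)
      stopf("enumerate_sequences: enumeration budget exceeded")
    if (depth == max_len) return()
    for (a in enumerate_actions(P, policy$segments, policy$vmax)) {
      alp <- action_logprob(policy, P, a, cache)
      recurse(c(G, list(a)), apply_cna(P, a, policy$segments), lp + alp,
              depth + 1L)
    }
  }
  recurse(list(), normal_profile(policy$L, c_max = policy$c_max), 0, 0L)
  out
}

#' Exact (truncated) profile probability by enumeration
#'
#' Sums the probabilities of every generating sequence of length at most
#' `max_len` that generates `profile`. A lower bound of the full profile
#' probability (which sums over sequences of any length); monotone
#' non-decreasing in `max_len`. Intended as a test oracle on tiny instances.
#'
#' @param profile target [cn_profile()].
#' @param policy an [evocn_policy()].
#' @param max_len enumeration horizon.
#' @export
profile_prob_exact <- function(profile, policy, max_len) {
  seqs <- enumerate_sequences(policy, max_len)
  key <- profile_key(profile)
  lp <- vapply(seqs, function(s) {
    if (profile_key(s$profile) == key) s$logprob else -Inf
  }, numeric(1))
  exp(logsumexp(lp))
}
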