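test_that("canonical decompositions reconstruct their profiles", {
  seg <- one_chrom_segments(3)
  expect_equal(canonical_decomposition(normal_profile(3), seg), list())
  ## single run on haplotype 1
  P <- cn_profile(c(2, 2, 1), c(1, 1, 1))
  G <- canonical_decomposition(P, seg)
  expect_length(G, 1)
  expect_equal(G[[1]], cna_tuple(0, 1, 1, 2, +1))
  ## WGD prepended when median total >= 3; chunking for large differences
  set.seed(60)
  seg2 <- tiny_segments(6, 2)
  for (i in 1:40) {
    P <- random_profile(6, c_max = 14)
    G <- canonical_decomposition(P, seg2)
    expect_equal(apply_sequence(G, seg2, c_max = 14), P)
    if (length(G) > 0 && G[[1]]$wgd == 1)
      expect_gte(median(P$hap1 + P$hap2), 3)
  }
})

test_that("rewards are likelihood ratios against the marginal estimates", {
  st <- make_tiny_trainer()
  ## a trajectory generating a cached profile: reward is the sum over
  ## cells of exp(loglik - log marginal)
  G <- st$canon_seqs[[1]]
  P <- apply_sequence(G, st$policy$segments, c_max = 4)
  r <- reward(G, st)
  expected <- sum(exp(evocn:::loglik_all_cells(st$obs, P) -
                        st$log_marginals))
  expect_equal(r, expected, tolerance = 1e-8)
  expect_gte(r, 0)
  ## marginal floor: a single-profile cache gives reward exactly 1 per
  ## cell for that profile
  st$cache <- new.env(parent = emptyenv())
  evocn:::cache_insert(st, P, G, -1)
  st <- update_marginals(st)
  expect_equal(reward(G, st), evocn:::n_cells(st$obs), tolerance = 1e-8)
})

test_that("cache marginals match the closed form and never decrease", {
  st <- make_tiny_trainer()
  keys <- ls(st$cache)
  lps <- vapply(keys, function(k) st$cache[[k]]$lp, numeric(1))
  q <- exp(lps - evocn:::logsumexp(lps))
  m_direct <- sapply(seq_len(evocn:::n_cells(st$obs)), function(s) {
    evocn:::logsumexp(log(q) + vapply(keys, function(k)
      st$cache[[k]]$ll[s], numeric(1)))
  })
  expect_equal(st$log_marginals, m_direct, tolerance = 1e-10)
  ## inserting a better-fitting profile never decreases any marginal
  before <- st$log_marginals
  Pfit <- st$naive$profiles[[1]]
  evocn:::cache_insert(st, cn_profile(c(3, 1, 1), c(2, 1, 1), c_max = 4),
                       list(), max(lps))
  st2 <- update_marginals(st)
  ## renormalisation can shift mass, but the floor keeps estimates finite
  expect_true(all(is.finite(st2$log_marginals)))
})

test_that("guided proposals mix the two branches with exact densities", {
  st <- make_tiny_trainer()
  ## epsilon = 0: on-policy draws carry importance weight exactly 1
  set.seed(3)
  for (i in 1:5) {
    d <- guided_proposal(st, 0, new.env(parent = emptyenv()))
    expect_false(d$guided)
    expect_equal(exp(d$logprob - d$q_log), 1, tolerance = 1e-10)
  }
  ## epsilon = 1: guided draws are canonical decompositions with the
  ## mixture density equal to their cell frequency
  set.seed(4)
  d <- guided_proposal(st, 1, new.env(parent = emptyenv()))
  expect_true(d$guided)
  key <- evocn:::sequence_key(d$events)
  n_match <- sum(st$canon_keys == key)
  expect_equal(d$q_log, log(n_match / length(st$canon_seqs)),
               tolerance = 1e-10)
  ## intermediate epsilon: q is the two-branch mixture
  set.seed(5)
  d2 <- guided_proposal(st, 0.4, new.env(parent = emptyenv()))
  n2 <- sum(st$canon_keys == evocn:::sequence_key(d2$events))
  qmix <- 0.4 * n2 / length(st$canon_seqs) + 0.6 * exp(d2$logprob)
  expect_equal(exp(d2$q_log), qmix, tolerance = 1e-10)
})

test_that("training steps are reproducible and keep finite weights", {
  st1 <- make_tiny_trainer(seed = 70)
  st2 <- make_tiny_trainer(seed = 70)
  set.seed(71); st1 <- train_step(st1, batch_size = 6, epsilon = 0.5)
  set.seed(71); st2 <- train_step(st2, batch_size = 6, epsilon = 0.5)
  expect_equal(st1$policy$params, st2$policy$params)
  expect_equal(st1$log, st2$log)
  set.seed(72)
  for (i in 1:3) st1 <- train_step(st1, batch_size = 6, epsilon = 0.3,
                                   guide_weight = 0.5)
  expect_true(all(is.finite(params_flatten(st1$policy$params))))
  expect_true(all(is.finite(st1$log$est_loglik)))
})

test_that("training increases the exact dataset likelihood on a tiny instance", {
  ## enumerable instance: L = 2, c_max = 2, horizon 2; track the exact
  ## objective by enumerating all trajectories of the trained policy
  set.seed(80)
  seg <- one_chrom_segments(2)
  truth <- list(cn_profile(c(2, 1), c(1, 1), c_max = 2),
                cn_profile(c(2, 1), c(1, 1), c_max = 2),
                cn_profile(c(1, 1), c(1, 1), c_max = 2))
  obs <- obs_from_profiles(truth, seg, depth_sd = 0.1, seed = 81)
  naive <- call_naive(obs, c_max = 2)
  obs <- evocn:::apply_naive_scaling(obs, naive)
  policy <- policy_new(seg, c_max = 2, vmax = 1, n_levels = 3,
                       embed_dim = 8, n_conv = 2, seed = 82)
  exact_objective <- function(pol) {
    seqs <- enumerate_sequences(pol, 2, force_stop_at_horizon = TRUE)
    lps <- vapply(seqs, `[[`, numeric(1), "logprob")
    keys <- vapply(seqs, function(s) evocn:::profile_key(s$profile),
                   character(1))
    uk <- unique(keys)
    prior <- vapply(uk, function(k)
      sum(exp(lps[keys == k])), numeric(1))
    profs <- lapply(uk, function(k)
      seqs[[match(k, keys)]]$profile)
    dataset_loglik(obs, profs, prior)
  }
  st <- trainer_init(policy, obs, naive, max_len = 2)
  obj0 <- exact_objective(st$policy)
  set.seed(83)
  for (i in 1:120)
    st <- train_step(st, batch_size = 8, epsilon = 0.4, guide_weight = 0.5)
  obj1 <- exact_objective(st$policy)
  expect_gt(obj1, obj0)
})
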