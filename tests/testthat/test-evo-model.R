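test_that("single CNA application follows the doubling/interval rules", {
  seg <- one_chrom_segments(60)
  P <- normal_profile(60)
  ## interval amplification of haplotype 1 over segments 35..50
  Q <- apply_cna(P, cna_tuple(0, 1, 35, 50, +1), seg)
  expect_equal(Q$hap1[35:50], rep(2L, 16))
  expect_equal(Q$hap1[-(35:50)], rep(1L, 44))
  expect_equal(Q$hap2, rep(1L, 60))
  ## whole-genome duplication doubles everything
  W <- apply_cna(Q, cna_tuple(wgd = 1), seg)
  expect_equal(W$hap1, 2L * Q$hap1)
  expect_equal(W$hap2, rep(2L, 60))
  ## an event and its negation cancel
  back <- apply_cna(Q, cna_tuple(0, 1, 35, 50, -1), seg)
  expect_equal(back, P)
})

test_that("invalid CNA applications are rejected", {
  seg <- tiny_segments(4, 2)   # chr1: 1-2, chr2: 3-4
  P <- normal_profile(4, c_max = 3)
  expect_error(apply_cna(P, cna_tuple(0, 1, 2, 3, 1), seg), "chromosome")
  expect_error(apply_cna(P, cna_tuple(0, 1, 1, 1, -2), seg), "leaves")
  expect_error(apply_cna(cn_profile(rep(2, 4), rep(2, 4), c_max = 3),
                         cna_tuple(wgd = 1), seg), "c_max")
  expect_error(cna_tuple(0, 1, 2, 1, 1), "start must be")
  expect_error(cna_tuple(0, 1, 1, 1, 0), "value 0")
})

test_that("sequence application is a left fold and order-sensitive", {
  seg <- one_chrom_segments(2)
  expect_equal(apply_sequence(list(), seg), normal_profile(2))
  G <- list(cna_tuple(wgd = 1), cna_tuple(0, 1, 1, 1, +1))
  P <- apply_sequence(G, seg)
  expect_equal(P$hap1, c(3L, 2L))
  expect_equal(P$hap2, c(2L, 2L))
  ## reversed order gives a different profile ((1+1) doubled = 4, not 3)
  Prev <- apply_sequence(rev(G), seg)
  expect_equal(Prev$hap1, c(4L, 2L))
  expect_false(isTRUE(all.equal(P, Prev)))
})

test_that("trajectory probabilities conserve mass at a fixed horizon", {
  pol <- tiny_policy(L = 2, c_max = 2, vmax = 1)
  seqs <- enumerate_sequences(pol, max_len = 2,
                              force_stop_at_horizon = TRUE)
  total <- sum(exp(vapply(seqs, `[[`, numeric(1), "logprob")))
  expect_equal(total, 1, tolerance = 1e-10)
  ## every enumerated sequence respects the copy number bounds
  for (s in seqs) {
    expect_true(all(s$profile$hap1 >= 0 & s$profile$hap1 <= 2))
    expect_true(all(s$profile$hap2 >= 0 & s$profile$hap2 <= 2))
  }
  ## without forcing, the stop-terminated mass is strictly below 1
  open_mass <- sum(exp(vapply(
    enumerate_sequences(pol, 2), `[[`, numeric(1), "logprob")))
  expect_lt(open_mass, 1)
  expect_gt(open_mass, 0)
})

test_that("sequence log-probability is consistent with sampling and enumeration", {
  pol <- tiny_policy(L = 2, c_max = 2, vmax = 1, seed = 21)
  ## empty sequence: just the stop probability at the normal profile
  expect_equal(sequence_logprob(list(), pol),
               log(start_distribution(pol, normal_profile(2, 2))[["stop"]]))
  set.seed(31)
  for (i in 1:10) {
    tr <- sample_trajectory(pol, max_len = 3)
    expect_equal(sequence_logprob(tr$events, pol), tr$logprob,
                 tolerance = 1e-10)
  }
  ## fixed seed reproduces the identical trajectory
  set.seed(99); a <- sample_trajectory(pol, max_len = 4)
  set.seed(99); b <- sample_trajectory(pol, max_len = 4)
  expect_equal(a, b)
})

test_that("truncated profile probability is monotone and bounded", {
  pol <- tiny_policy(L = 1, c_max = 2, vmax = 1, seed = 13)
  Pn <- normal_profile(1, c_max = 2)
  p0 <- profile_prob_exact(Pn, pol, 0)
  expect_equal(p0, start_distribution(pol, Pn)[["stop"]])
  probs <- sapply(0:3, function(h) profile_prob_exact(Pn, pol, h))
  expect_true(all(diff(probs) >= -1e-12))
  expect_true(all(probs <= 1))
})

test_that("Monte-Carlo trajectory sampling agrees with enumeration", {
  pol <- tiny_policy(L = 2, c_max = 2, vmax = 1, seed = 17, stop_bias = 0.5)
  target <- cn_profile(c(2, 1), c(1, 1), c_max = 2)
  ## stop-terminated mass on the target within 2 events: trajectories of
  ## length <= 2 sampled with a longer horizon terminate via the stop head,
  ## so their hit rate estimates profile_prob_exact unbiasedly
  exact <- profile_prob_exact(target, pol, 2)
  set.seed(123)
  n <- 6000
  hits <- sum(replicate(n, {
    tr <- sample_trajectory(pol, max_len = 3)
    P <- apply_sequence(tr$events, pol$segments, c_max = 2)
    length(tr$events) <= 2 &&
      identical(P$hap1, target$hap1) && identical(P$hap2, target$hap2)
  }))
  phat <- hits / n
  se <- sqrt(max(phat * (1 - phat), 1e-6) / n)
  expect_lt(abs(phat - exact), 3 * se)
})
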