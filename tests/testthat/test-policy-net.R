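test_that("profile embedding clips, is deterministic, and is 500-dim by default", {
  seg <- one_chrom_segments(8)
  pol <- policy_new(seg, seed = 5)    # production-size network
  expect_equal(pol$embed_dim, 500L)
  P <- normal_profile(8)
  e1 <- embed_profile(pol, P)
  expect_length(e1, 500)
  expect_equal(e1, embed_profile(pol, P))
  ## copy numbers above 19 are clipped before one-hot encoding
  hi <- cn_profile(rep(25, 8), rep(19, 8), c_max = 30)
  lo <- cn_profile(rep(19, 8), rep(19, 8), c_max = 30)
  expect_equal(embed_profile(pol, hi), embed_profile(pol, lo))
  ## a local change moves the embedding (generic weights)
  P2 <- cn_profile(c(rep(1, 7), 2), rep(1, 8))
  expect_gt(max(abs(embed_profile(pol, P2) - e1)), 0)
})

test_that("head distributions are masked simplices", {
  pol <- tiny_policy(L = 4, c_max = 3, vmax = 2, seed = 8)
  pol$segments <- tiny_segments(4, 2)   # chr1: 1-2, chr2: 3-4
  P <- normal_profile(4, c_max = 3)
  sd1 <- start_distribution(pol, P)
  expect_equal(sum(sd1), 1, tolerance = 1e-9)
  expect_true(all(sd1 >= 0))
  expect_length(sd1, 6)
  ## WGD is masked when doubling would exceed the cap
  Phi <- cn_profile(rep(2, 4), rep(2, 4), c_max = 3)
  sd2 <- start_distribution(pol, Phi)
  expect_equal(sd2[["wgd"]], 0)
  expect_equal(sum(sd2), 1, tolerance = 1e-9)
  ## end mass stays on the start chromosome, at or after the start
  ed <- end_distribution(pol, P, 3)
  expect_equal(ed[1:2], c(0, 0))
  expect_equal(sum(ed[3:4]), 1, tolerance = 1e-9)
  ed_last <- end_distribution(pol, P, 4)
  expect_equal(ed_last[4], 1)
  ## value head: 2 * 2 * vmax entries; -2 is invalid on a diploid interval
  vd <- value_distribution(pol, P, 1, 2)
  expect_length(vd, 8)
  expect_equal(sum(vd), 1, tolerance = 1e-9)
  vals <- c(-(2:1), 1:2)
  expect_equal(vd[[which(vals == -2)]], 0)        # hap1 value -2 masked
  expect_gt(vd[[which(vals == -1)]], 0)           # -1 allowed
})

test_that("sampled trajectories are valid and reproducible", {
  pol <- tiny_policy(L = 3, c_max = 2, vmax = 1, seed = 4, stop_bias = 0)
  set.seed(77)
  for (i in 1:20) {
    tr <- sample_trajectory(pol, max_len = 5)
    P <- normal_profile(3, c_max = 2)
    for (cna in tr$events) P <- apply_cna(P, cna, pol$segments)
    expect_true(all(P$hap1 >= 0 & P$hap1 <= 2))
    expect_lte(length(tr$events), 5)
  }
})

test_that("empirical stop rate matches the stop head probability", {
  pol <- tiny_policy(L = 2, c_max = 2, vmax = 1, seed = 3, stop_bias = 1)
  p_stop <- start_distribution(pol, normal_profile(2, 2))[["stop"]]
  set.seed(11)
  n <- 10000
  stopped <- sum(replicate(n, {
    length(sample_trajectory(pol, max_len = 1)$events) == 0
  }))
  se <- sqrt(p_stop * (1 - p_stop) / n)
  expect_lt(abs(stopped / n - p_stop), 3 * se)
})

test_that("analytic trajectory gradients match finite differences", {
  pol <- tiny_policy(L = 4, c_max = 3, vmax = 2, seed = 2,
                     embed_dim = 5, n_conv = 2)
  pol$segments <- tiny_segments(4, 2)
  G <- list(cna_tuple(wgd = 1), cna_tuple(0, 2, 1, 2, +1),
            cna_tuple(0, 1, 3, 4, -2))
  g <- params_flatten(trajectory_grads(pol, list(G), 1))
  x0 <- params_flatten(pol$params)
  f <- function(x) {
    p2 <- pol
    p2$params <- params_unflatten(pol$params, x)
    sequence_logprob(G, p2)
  }
  eps <- 1e-5
  set.seed(6)
  idx <- sort(sample(seq_along(x0), 80))
  num <- vapply(idx, function(i) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx]))
  expect_lt(max(rel), 1e-4)
  ## gradients of a weighted pair of sequences add linearly
  G2 <- list(cna_tuple(0, 1, 1, 1, +1))
  g_pair <- trajectory_grads(pol, list(G, G2), c(0.3, 0.7))
  g_a <- trajectory_grads(pol, list(G), 0.3)
  g_b <- trajectory_grads(pol, list(G2), 0.7)
  expect_equal(params_flatten(g_pair),
               params_flatten(g_a) + params_flatten(g_b),
               tolerance = 1e-10)
})

test_that("embedding dimension is invariant to genome length", {
  for (L in c(10, 50, 120)) {
    pol <- policy_new(one_chrom_segments(L), embed_dim = 32, n_conv = 3,
                      seed = 1)
    expect_length(embed_profile(pol, normal_profile(L)), 32)
  }
})
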