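test_that("read depth log-likelihood matches the Gaussian closed form", {
  ctx <- cell_context(r = 2, b = 0.5, sr = 1, sb = 1, c = 1)
  P <- normal_profile(1)
  ## zero residual: just the normalising constant
  expect_equal(read_depth_loglik(ctx, P), -0.5 * log(2 * pi))
  ## r = 0 against mean 2: constant minus 2
  ctx0 <- cell_context(r = 0, b = 0.5, sr = 1, sb = 1, c = 1)
  expect_equal(read_depth_loglik(ctx0, P), -0.5 * log(2 * pi) - 2)
})

test_that("likelihoods equal an independent dense Gaussian evaluation", {
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(2:6, 1)
    P <- random_profile(L, c_max = 3)
    ctx <- cell_context(r = runif(L, 0, 8), b = runif(L),
                        sr = runif(L, 0.1, 2), sb = runif(L, 0.01, 0.2),
                        c = runif(1, 0.5, 2))
    tot <- P$hap1 + P$hap2
    muB <- ifelse(tot > 0, P$hap2 / pmax(tot, 1), 0.5)
    oracle <- sum(dnorm(ctx$r, ctx$c * tot, sqrt(ctx$sr), log = TRUE)) +
      sum(dnorm(ctx$b, muB, sqrt(ctx$sb), log = TRUE))
    expect_equal(data_loglik(ctx, P), oracle, tolerance = 1e-12)
    expect_equal(data_loglik(ctx, P),
                 read_depth_loglik(ctx, P) + baf_loglik(ctx, P))
  }
})

test_that("BAF mean handles total copy zero and haplotype swap symmetry", {
  ctx <- cell_context(r = 1, b = 1 / 3, sr = 1, sb = 0.01, c = 1)
  P21 <- cn_profile(2, 1)
  ## residual term vanishes at the matching mean: only constants remain
  expect_equal(baf_loglik(ctx, P21), -0.5 * log(2 * pi * 0.01))
  ctx05 <- cell_context(r = 0, b = 0.5, sr = 1, sb = 0.01, c = 1)
  expect_equal(baf_loglik(ctx05, cn_profile(0, 0)),
               -0.5 * log(2 * pi * 0.01))
  set.seed(7)
  for (rep in 1:25) {
    L <- sample(1:5, 1)
    P <- random_profile(L)
    Pswap <- cn_profile(P$hap2, P$hap1, c_max = P$c_max)
    b <- runif(L)
    ctx1 <- cell_context(runif(L, 0, 6), b, runif(L, .1, 1),
                         runif(L, .01, .1), c = 1.3)
    ctx2 <- ctx1; ctx2$b <- 1 - b
    expect_equal(data_loglik(ctx1, P), data_loglik(ctx2, Pswap))
  }
})

test_that("noise-free data is maximised at the generating profile", {
  L <- 3
  seg <- one_chrom_segments(L)
  P_true <- cn_profile(c(2, 1, 3), c(1, 1, 0), c_max = 3)
  tot <- P_true$hap1 + P_true$hap2
  ctx <- cell_context(r = tot, b = P_true$hap2 / tot,
                      sr = rep(0.01, L), sb = rep(0.001, L), c = 1)
  ## brute force over the full bounded profile space
  grid <- expand.grid(replicate(2 * L, 0:3, simplify = FALSE))
  ll <- apply(grid, 1, function(g)
    data_loglik(ctx, cn_profile(g[1:L], g[(L + 1):(2 * L)], c_max = 3)))
  best <- grid[which.max(ll), ]
  expect_equal(unlist(best[1:L], use.names = FALSE), P_true$hap1)
  expect_equal(unlist(best[(L + 1):(2 * L)], use.names = FALSE),
               P_true$hap2)
  ## unimodal decrease as depth moves away from the mean
  devs <- sapply(c(0, .2, .5, 1), function(d) {
    c2 <- ctx; c2$r <- tot + d
    data_loglik(c2, P_true)
  })
  expect_true(all(diff(devs) < 0))
})

test_that("marginal log-likelihood reduces correctly and matches enumeration", {
  L <- 2
  P_true <- cn_profile(c(2, 1), c(1, 1), c_max = 2)
  ctx <- cell_context(r = c(3, 2), b = c(1 / 3, 1 / 2),
                      sr = rep(0.5, 2), sb = rep(0.05, 2), c = 1)
  ## delta prior
  expect_equal(marginal_loglik(ctx, list(P_true), 1),
               data_loglik(ctx, P_true))
  ## uniform prior over the full tiny space vs direct summation
  grid <- expand.grid(replicate(4, 0:2, simplify = FALSE))
  profs <- apply(grid, 1, function(g)
    cn_profile(g[1:2], g[3:4], c_max = 2), simplify = FALSE)
  prior <- rep(1 / length(profs), length(profs))
  direct <- log(sum(sapply(profs, function(p)
    exp(data_loglik(ctx, p))) / length(profs)))
  expect_equal(marginal_loglik(ctx, profs, prior), direct,
               tolerance = 1e-10)
  ## zero-probability entries are inert
  expect_equal(marginal_loglik(ctx, c(profs, list(P_true)), c(prior, 0)),
               marginal_loglik(ctx, profs, prior))
  expect_error(marginal_loglik(ctx, list(), numeric(0)), "empty")
})

test_that("dataset log-likelihood sums per-cell marginals", {
  seg <- tiny_segments(3, 1)
  profiles <- list(cn_profile(c(1, 2, 1), c(1, 1, 1)),
                   cn_profile(c(1, 1, 1), c(1, 1, 1)),
                   cn_profile(c(2, 2, 0), c(1, 1, 0)))
  obs <- obs_from_profiles(profiles, seg, seed = 3)
  pool <- unique(profiles)
  prior <- rep(1 / length(pool), length(pool))
  expected <- sum(sapply(1:3, function(s)
    marginal_loglik(evocn:::cell_context_from_obs(obs, s), pool, prior)))
  expect_equal(dataset_loglik(obs, pool, prior), expected)
  expect_equal(
    dataset_loglik(obs, pool, prior) -
      sum(sapply(2:3, function(s)
        marginal_loglik(evocn:::cell_context_from_obs(obs, s), pool, prior))),
    marginal_loglik(evocn:::cell_context_from_obs(obs, 1), pool, prior))
})

test_that("vectorised all-cell log-likelihood matches the per-cell path", {
  seg <- tiny_segments(5, 2)
  profiles <- lapply(1:4, function(i) random_profile(5, 3))
  obs <- obs_from_profiles(profiles, seg, scaling = runif(4, .5, 2),
                           seed = 9)
  P <- random_profile(5, 3)
  vec <- evocn:::loglik_all_cells(obs, P)
  per <- sapply(1:4, function(s)
    data_loglik(evocn:::cell_context_from_obs(obs, s), P))
  expect_equal(vec, per, tolerance = 1e-10)
})
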