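test_that("accuracy and L1 follow the unordered-pair definitions", {
  p <- list(cn_profile(c(2, 2, 0), c(1, 0, 0)))
  t <- list(cn_profile(c(1, 1, 2), c(2, 1, 1)))
  ## per segment: (2,1) vs (1,2) match; (2,0) vs (1,1) differ; (0,0) vs (2,1)
  expect_equal(cn_accuracy(p, t), 1 / 3)
  expect_equal(cn_l1_error(p, t), (0 + 2 + 3) / 3)
  expect_equal(cn_accuracy(t, t), 1)
  expect_equal(cn_l1_error(t, t), 0)
  ## bin weights reweight segments
  expect_equal(cn_accuracy(p, t, weights = c(2, 1, 1)), 0.5)
})

test_that("metric identities hold on randomised inputs", {
  set.seed(20)
  for (rep in 1:300) {
    L <- sample(2:6, 1)
    N <- sample(1:4, 1)
    pred <- lapply(seq_len(N), function(i) random_profile(L, 3))
    truth <- lapply(seq_len(N), function(i) random_profile(L, 3))
    acc <- cn_accuracy(pred, truth)
    l1 <- cn_l1_error(pred, truth)
    expect_gte(acc, 0); expect_lte(acc, 1); expect_gte(l1, 0)
    ## equivalence: zero L1 iff perfect accuracy
    expect_equal(l1 == 0, acc == 1)
    ## unordered-pair symmetry: swapping haplotypes changes nothing
    swapped <- lapply(pred, function(p)
      cn_profile(p$hap2, p$hap1, c_max = p$c_max))
    expect_equal(cn_accuracy(swapped, truth), acc)
    expect_equal(cn_l1_error(swapped, truth), l1)
    ## consistent cell reordering is invariant
    o <- sample(N)
    expect_equal(cn_accuracy(pred[o], truth[o]), acc)
  }
})

make_snvs <- function(n_snv, cells, segments_of_snv, groups, calls,
                      hap = 1, reads = 6, error = 0, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(snv = seq_len(n_snv), cell = seq_along(cells))
  seg <- segments_of_snv[rows$snv]
  p <- vapply(seq_len(nrow(rows)), function(r) {
    prof <- calls[[rows$cell[r]]]
    h <- c(prof$hap1[seg[r]], prof$hap2[seg[r]])
    tot <- sum(h)
    if (tot == 0) error else min(max(h[hap] / tot, error), 1 - error)
  }, numeric(1))
  n <- rpois(nrow(rows), reads)
  v <- rbinom(nrow(rows), n, p)
  snv_table(snv_id = sprintf("s%03d", rows$snv), segment = seg,
            cell_id = cells[rows$cell], group = groups[rows$cell],
            var_reads = v, ref_reads = n - v)
}

test_that("truncal filtering counts cells with variant reads per group", {
  snvs <- snv_table(
    snv_id = rep(c("a", "b"), each = 6),
    segment = 1,
    cell_id = rep(sprintf("c%d", 1:6), 2),
    group = rep(rep(c("g1", "g2"), each = 3), 2),
    var_reads = c(1, 1, 1, 1, 1, 1,   # a: 3 cells in both groups
                  1, 1, 0, 0, 0, 0),  # b: 2 cells in g1 only
    ref_reads = rep(5, 12))
  kept <- truncal_filter(snvs, min_cells = 3, min_groups = 2)
  expect_equal(unique(kept$snv_id), "a")
  kept2 <- truncal_filter(snvs, min_cells = 2, min_groups = 1)
  expect_setequal(unique(kept2$snv_id), c("a", "b"))
  expect_equal(nrow(truncal_filter(snvs, min_cells = 0, min_groups = 0)),
               nrow(snvs))
})

test_that("SNV LLR is zero on identical calls, antisymmetric, and scale-blind", {
  seg <- one_chrom_segments(3)
  cells <- sprintf("c%d", 1:5)
  calls_a <- lapply(1:5, function(i) cn_profile(c(2, 1, 3), c(1, 1, 0)))
  calls_b <- lapply(1:5, function(i) cn_profile(c(1, 2, 2), c(1, 0, 1)))
  snvs <- make_snvs(20, cells, rep(1:3, length.out = 20),
                    rep("g1", 5), calls_a, seed = 3)
  expect_equal(snv_llr(snvs, calls_a, calls_a, cells)$total, 0)
  ab <- snv_llr(snvs, calls_a, calls_b, cells)
  ba <- snv_llr(snvs, calls_b, calls_a, cells)
  expect_equal(ab$total, -ba$total)
  expect_equal(ab$per_snv, -ba$per_snv)
  ## profiles differing by a constant haplotype factor are identical
  doubled <- lapply(calls_a, function(p)
    cn_profile(2 * p$hap1, 2 * p$hap2, c_max = 19))
  expect_equal(snv_llr(snvs, calls_a, doubled, cells)$total, 0,
               tolerance = 1e-9)
})

test_that("single-cell binomial LLR matches the hand computation", {
  seg <- one_chrom_segments(1)
  cells <- "c1"
  calls_21 <- list(cn_profile(2, 1))
  calls_11 <- list(cn_profile(1, 1))
  snvs <- snv_table("s1", 1, "c1", "g", var_reads = 2, ref_reads = 1)
  ## 2 variant + 1 reference reads; on (2,1) the better haplotype gives
  ## p = 2/3; on (1,1) p = 1/2. Binomial coefficients cancel in the ratio.
  expected <- (2 * log(2 / 3) + log(1 / 3)) - 3 * log(1 / 2)
  got <- snv_llr(snvs, calls_21, calls_11, cells)
  expect_equal(got$total, expected, tolerance = 1e-9)
})

test_that("LLR favours generating profiles as SNV count grows", {
  seg <- one_chrom_segments(4)
  cells <- sprintf("c%d", 1:8)
  truth <- lapply(1:8, function(i) cn_profile(c(2, 1, 3, 2), c(1, 1, 1, 0)))
  corrupted <- lapply(truth, function(p)
    cn_profile(c(1, 1, 2, 1), c(1, 1, 2, 1)))
  snvs <- make_snvs(60, cells, rep(1:4, length.out = 60), rep("g", 8),
                    truth, reads = 8, error = 0.01, seed = 9)
  res <- snv_llr(snvs, truth, corrupted, cells)
  expect_gt(res$total, 0)
  ## bootstrap: all-positive per-SNV values pin the p-value at the floor
  b1 <- bootstrap_llr(rep(1, 50), n_boot = 500)
  expect_lt(b1$p_value, 1 / 500)
  set.seed(5)
  sym <- c(rnorm(500))
  b2 <- bootstrap_llr(sym, n_boot = 2000)
  expect_gt(b2$p_value, 0.2)
  set.seed(8); i1 <- bootstrap_llr(res$per_snv, n_boot = 300)$interval
  set.seed(8); i2 <- bootstrap_llr(res$per_snv, n_boot = 300)$interval
  expect_equal(i1, i2)
})

test_that("VAF histograms select matching copy states and conserve mass", {
  cells <- sprintf("c%d", 1:6)
  calls <- lapply(1:6, function(i) cn_profile(c(2, 1), c(1, 1)))
  snvs <- make_snvs(40, cells, rep(1:2, length.out = 40), rep("g", 6),
                    calls, hap = 1, reads = 30, error = 0, seed = 12)
  h <- vaf_histogram(snvs, calls, cells, state = c(2, 1))
  ## 20 SNVs sit on the (2,1) segment; all are counted once
  expect_equal(sum(h$counts), 20)
  ## truncal SNVs on haplotype 1 of (2,1) pool near VAF 2/3
  expect_gt(sum(h$counts[h$mids > 0.55 & h$mids < 0.8]), 15)
  ## empty selection is an empty histogram, not an error
  h0 <- vaf_histogram(snvs, calls, cells, state = c(5, 5))
  expect_equal(sum(h0$counts), 0)
})
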