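# Differential usage: normalization, dispersion, Wald test, BH, signed
# fold changes, MAPQ filtering.

test_that("median-of-ratios matches hand-derived factors", {
  m <- cbind(s1 = c(10, 20, 40), s2 = c(10, 20, 40))
  expect_equal(unname(median_of_ratios(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  expect_equal(unname(median_of_ratios(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # the estimator is invariant to global rescaling (ratio structure is
  # all that matters), and scaling one sample scales the factor ratio
  expect_equal(median_of_ratios(m2 * 10), median_of_ratios(m2))
  m3 <- m2; m3[, 2] <- m3[, 2] * 3
  r_before <- median_of_ratios(m2)[2] / median_of_ratios(m2)[1]
  r_after <- median_of_ratios(m3)[2] / median_of_ratios(m3)[1]
  expect_equal(unname(r_after / r_before), 3, tolerance = 1e-12)

  zeros <- cbind(c(0, 5), c(3, 0))
  expect_error(median_of_ratios(zeros), "pseudo-reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  sim <- simulate_count_matrix(n_sites = 401, dispersion = 0.1,
                               mean_range = c(50, 500), seed = 77)
  counts <- sim$counts
  counts[, 3] <- counts[, 3] * 2L          # introduce depth imbalance
  counts <- counts[rowSums(counts > 0) == ncol(counts), , drop = FALSE]
  # with an even number of all-positive rows the two middle ratios are
  # averaged arithmetically here and geometrically (log scale) in DESeq2;
  # keep an odd row count so both medians pick the same element
  if (nrow(counts) %% 2 == 0) counts <- counts[-1, , drop = FALSE]
  ours <- median_of_ratios(counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("dispersion estimation recovers the simulated regime", {
  sim <- simulate_count_matrix(n_sites = 2000, dispersion = 0.1, seed = 5)
  sf <- median_of_ratios(sim$counts)
  a <- estimate_dispersion(sim$counts, sf, sim$condition)
  expect_gt(median(a), 0.05)
  expect_lt(median(a), 0.2)

  pois <- simulate_count_matrix(n_sites = 2000, dispersion = 0,
                                mean_range = c(50, 500), seed = 6)
  sfp <- median_of_ratios(pois$counts)
  ap <- estimate_dispersion(pois$counts, sfp, pois$condition)
  expect_lt(median(ap), 0.01)

  flat <- matrix(100, nrow = 50, ncol = 8)
  af <- estimate_dispersion(flat, rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(af, rep(1e-8, 50))
})

test_that("the Wald test behaves at the null and on degenerate sites", {
  m <- matrix(1000L, nrow = 3, ncol = 8)
  res <- nb_wald_test(m, rep(1, 8), rep(1e-8, 3),
                      rep(c("treated", "control"), each = 4))
  expect_equal(res$log2_fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3), tolerance = 1e-9)

  z <- matrix(0L, nrow = 2, ncol = 8)
  rz <- nb_wald_test(z, rep(1, 8), rep(0.1, 2),
                     rep(c("treated", "control"), each = 4))
  expect_identical(rz$log2_fc, c(0, 0))
  expect_identical(rz$p_value, c(1, 1))
})

test_that("null simulation holds its nominal type-I error", {
  sim <- simulate_count_matrix(n_sites = 2000, dispersion = 0.1, seed = 301)
  de <- run_de(sim$counts, sim$condition, params = de_params(mapq_min = 0))
  rate <- mean(de$results$p_value < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("signed fold changes follow the reporting convention", {
  expect_identical(signed_fold_change(8, 2, pseudocount = 0), 4)
  expect_identical(signed_fold_change(2, 8, pseudocount = 0), -4)
  expect_identical(signed_fold_change(5, 5, pseudocount = 0), 1)
  expect_identical(signed_fold_change(0, 0), 1)
  expect_equal(signed_fold_change(c(8, 2), c(2, 8), pseudocount = 0),
               c(4, -4))
})

test_that("swapping condition labels negates fold changes, keeps p-values", {
  sim <- simulate_count_matrix(n_sites = 300, dispersion = 0.1,
                               n_de = 30, log2_effect = 2, seed = 44)
  p <- de_params(mapq_min = 0)
  de1 <- run_de(sim$counts, sim$condition, params = p)
  swapped <- ifelse(sim$condition == "treated", "control", "treated")
  de2 <- run_de(sim$counts, swapped, params = p)
  expect_equal(de2$results$log2_fc, -de1$results$log2_fc, tolerance = 1e-12)
  expect_equal(de2$results$p_value, de1$results$p_value, tolerance = 1e-12)
  expect_equal(sign(de2$results$signed_fc), -sign(de1$results$signed_fc))
})

test_that("planted effects are detected and their size recovered", {
  sim <- simulate_count_matrix(n_sites = 400, dispersion = 0.1,
                               mean_range = c(200, 200), n_de = 20,
                               log2_effect = 2, seed = 99)
  de <- run_de(sim$counts, sim$condition, params = de_params(mapq_min = 0))
  hit <- de$results$p_adj < 0.1
  expect_gte(sum(hit & sim$is_de), 16)
  err <- de$results$log2_fc[sim$is_de] - sim$log2_effect[sim$is_de]
  expect_lt(median(abs(err)), 0.25)
  # signed_fc sign matches the mean comparison for every site
  r <- de$results
  expect_true(all(sign(r$signed_fc) ==
                    ifelse(r$mean_treated >= r$mean_control, 1, -1)))
  expect_true(all(r$p_adj >= r$p_value - 1e-12))
})

test_that("the MAPQ rule fails strictly below 70 and drives removal", {
  res <- data.frame(p_adj = c(0.01, 0.01, 0.5),
                    mean_mapq = c(70, 69.9, 10))
  mq <- mapq_filter(res, de_params())
  expect_identical(mq$results$passed_mapq, c(TRUE, FALSE, FALSE))
  # only *significant* failing sites are removed
  expect_identical(nrow(mq$removed), 1L)

  # naive-mapper data (MAPQ 60 by convention) all fail at the default 70
  res2 <- data.frame(p_adj = rep(0.01, 4), mean_mapq = rep(60, 4))
  expect_identical(mapq_filter(res2, de_params())$n_removed, 4L)
  expect_identical(mapq_filter(res2, de_params(mapq_min = 0))$n_removed, 0L)
})
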