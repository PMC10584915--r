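test_that("mean pairwise similarity averages the upper triangle", {
  z <- matrix(0, 3, 3)
  expect_equal(mean_pairwise_similarity(z), 0)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.6
  expect_equal(mean_pairwise_similarity(m), 0.4)
  expect_error(mean_pairwise_similarity(matrix(0, 1, 1)), "at least 2")
  # agrees with a direct sum on a synthetic consensus run
  fam <- make_family(sim_config(n_species = 3, seed = 13))
  cons <- run_consensus(filter_variants(fam$variant_set)$variant_set)
  dn <- distance_matrix(cons$per_species, normalize = TRUE)
  expect_equal(mean_pairwise_similarity(dn),
               sum(dn[upper.tri(dn)]) / choose(nrow(dn), 2))
})

test_that("the pooled t-test reproduces the published clade comparisons", {
  met <- c(0.38, 0.29, 0.22, 0.37)
  tt1 <- two_sample_ttest(met, c(0.58, 0.44, 0.48, 0.46))
  expect_equal(tt1$p_value, 0.0115, tolerance = 0.0005 / 0.0115)
  expect_equal(tt1$degrees_of_freedom, 6L)
  tt2 <- two_sample_ttest(met, c(0.63, 0.58, 0.48))
  expect_equal(tt2$p_value, 0.0077, tolerance = 0.0005 / 0.0077)
  expect_equal(tt2$degrees_of_freedom, 5L)
})

test_that("the t statistic behaves under sample swap and degeneracy", {
  a <- c(0.1, 0.2, 0.35)
  b <- c(0.5, 0.6, 0.62, 0.7)
  ab <- two_sample_ttest(a, b)
  ba <- two_sample_ttest(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  eq <- two_sample_ttest(c(1, 1), c(1, 1))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "zero pooled variance")
  same <- two_sample_ttest(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the t-test matches the reference implementation to 1e-10", {
  set.seed(99)
  for (r in 1:25) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1))
    mine <- two_sample_ttest(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$degrees_of_freedom, unname(ref$parameter))
  }
})

test_that("box-plot summaries follow the midpoint quartile convention", {
  b <- boxplot_summary(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q1, 2.75) # type-5 (midpoint) interpolation
  expect_equal(b$q3, 7.25)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 9)
  expect_length(b$outliers, 0L)
  const <- boxplot_summary(rep(2.5, 6))
  expect_equal(const$median, 2.5)
  expect_equal(const$q1, const$q3)
  expect_length(const$outliers, 0L)
  out <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)
  expect_true(out$q1 <= out$median && out$median <= out$q3)
})

test_that("the shipped similarity tables load with the printed values", {
  tabs <- snrna_similarity_tables()
  expect_equal(tabs$major$metazoa, c(0.38, 0.29, 0.22, 0.37))
  expect_equal(tabs$major$rna, c("U1", "U2", "U4", "U5"))
  expect_equal(tabs$minor$metazoa_minor, c(0.63, 0.58, 0.48))
  cc <- clade_comparisons()
  expect_equal(nrow(cc), 5L)
  expect_true(all(cc$p_value > 0 & cc$p_value < 1))
})
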