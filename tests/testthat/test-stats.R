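test_that("progression regression reproduces exact and null cases", {
  ranks <- rep(1:5, each = 4)
  exact <- 2 - 0.5 * ranks
  r <- progression_regression(exact, ranks)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, -0.5, tolerance = 1e-12)
  expect_error(progression_regression(exact, rep(2, 20)), "constant")
  expect_error(progression_regression(1:2, 1:2), "3 conditions")
  # null generator: the slope CI covers 0 in at least 90% of replicates
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    y <- rnorm(84)
    rk <- sample(1:5, 84, replace = TRUE)
    ci <- stats::confint(stats::lm(y ~ rk))[2, ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("one-way ANOVA reproduces the hand-computed example", {
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(1:3, each = 3)
  r <- anova_oneway(v, g)
  expect_equal(r$statistic, 21, tolerance = 1e-12)   # SSB/2 = 21, SSW/6 = 1
  expect_identical(r$df, c(2L, 6L))
  expect_equal(anova_oneway(rep(5, 9), g)$statistic, 0)
  expect_error(anova_oneway(v, rep(1, 9)), "2 groups")
})

test_that("ANOVA with two groups equals the squared equal-variance t statistic", {
  set.seed(14)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  f <- anova_oneway(c(x, y), rep(1:2, c(12, 15)))$statistic
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-10)
})

test_that("chi-square test matches hand computations and published counts", {
  r <- chi_square_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20, tolerance = 1e-12)
  # injured/uninjured by cluster: 8/17, 5/13, 5/4, 3/3, 12/3
  tab <- rbind(injured = c(8, 5, 5, 3, 12), uninjured = c(17, 13, 4, 3, 3))
  r2 <- chi_square_independence(tab)
  expect_lt(abs(r2$p_value - 0.02), 0.005)
  expect_identical(r2$df, 4L)
  # identical row proportions -> zero statistic
  expect_equal(chi_square_independence(rbind(c(10, 20), c(5, 10)))$statistic,
               0, tolerance = 1e-12)
  # invariance to row/column permutation
  perm <- tab[2:1, c(3, 1, 5, 2, 4)]
  expect_equal(chi_square_independence(perm)$statistic, r2$statistic)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chi_square_independence(matrix(1:3, 1)), "2 x 2")
})

test_that("ANOVA and chi-square p-values are calibrated under the null", {
  set.seed(15)
  p_anova <- vapply(1:400, function(i) {
    anova_oneway(rnorm(40), rep(1:4, each = 10))$p_value
  }, numeric(1))
  ks <- stats::ks.test(p_anova, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_true(all(p_anova >= 0 & p_anova <= 1))
})

test_that("the comparison table tests each covariate appropriately", {
  set.seed(16)
  d <- data.frame(
    progression_rank = rep(1:3, each = 10),
    ppv = rep(c(10, 12, 20), each = 10) + rnorm(30),
    injured = rep(c(FALSE, FALSE, TRUE), each = 10)
  )
  d$injured[c(1, 25)] <- c(TRUE, FALSE)
  tab <- cluster_comparison_table(d, covariates = c("ppv", "injured"))
  expect_identical(tab$test, c("anova", "chi_square"))
  expect_lt(tab$p_value[1], 0.001)
  by <- attr(tab, "by_cluster")$ppv
  expect_equal(by$mean[by$cluster == "3"], mean(d$ppv[21:30]))
  expect_identical(attr(tab, "meta")$p_adjusted, "none")
})

test_that("excluding a cluster removes its influence without touching the rest", {
  set.seed(17)
  d <- data.frame(
    progression_rank = rep(1:4, each = 8),
    co = c(rnorm(24, 5, 0.5), rnorm(8, 9, 0.5))   # only cluster 4 differs
  )
  full <- cluster_comparison_table(d, covariates = "co")
  sens <- sensitivity_excluding_cluster(d, exclude = 4, covariates = "co")
  expect_lt(full$p_value, 0.001)
  expect_gt(sens$p_value, 0.05)
  by_full <- attr(full, "by_cluster")$co
  by_sens <- attr(sens, "by_cluster")$co
  expect_equal(by_sens$mean, by_full$mean[by_full$cluster != "4"])
  expect_error(sensitivity_excluding_cluster(d, exclude = 9, covariates = "co"),
               "not present")
  d2 <- d[d$progression_rank <= 2, ]
  expect_error(sensitivity_excluding_cluster(d2, exclude = 2, covariates = "co"),
               "fewer than 2")
})

test_that("the mixed model recovers generating parameters and flags degeneracy", {
  est <- vapply(1:10, function(s) {
    fit_mixed_progression(simulate_progression_cohort(seed = s))$random_sd
  }, numeric(1))
  expect_gte(mean(est), 0.4)
  expect_lte(mean(est), 1.1)
  # zero-effect generator: fixed slopes centred on zero
  sl <- vapply(1:10, function(s) {
    d <- simulate_progression_cohort(seed = 100 + s, slope_pf = 0, slope_ppv = 0)
    fit_mixed_progression(d)$fixed$estimate[1]
  }, numeric(1))
  expect_lt(abs(mean(sl)), 0.02)
  # single animal: degenerate random effect flagged, not raised
  d1 <- simulate_progression_cohort(seed = 1, n_animals = 1)
  f1 <- fit_mixed_progression(d1)
  expect_true(f1$singular)
  expect_true(is.na(f1$random_sd))
})

test_that("AIC subset selection prefers the generating covariates", {
  d <- simulate_progression_cohort(seed = 23, slope_pf = -0.08, slope_ppv = 0.1,
                                   noise_sd = 0.5)
  sel <- select_fixed_effects(d)
  expect_identical(sel$terms[1], "pf_kpa+ppv_pct")
})

test_that("mechanical power follows the simplified PCV formula", {
  expect_equal(mechanical_power_pcv(10, 0, 18, 11), 0)
  expect_equal(mechanical_power_pcv(10, 0.397, 18, 11), 11.3, tolerance = 0.005)
  expect_equal(mechanical_power_pcv(10, 0.8, 18, 11),
               2 * mechanical_power_pcv(10, 0.4, 18, 11))
  expect_error(mechanical_power_pcv(10, -1, 18, 11), "nonnegative")
})
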