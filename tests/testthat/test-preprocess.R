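# Build a fully synthetic piecewise-linear trace for exact alignment checks:
# decline at -1 mmHg/s through the hold, kink at restart + kink_offset, rise
# at +5 mmHg/s.
piecewise_trace <- function(kink_offset = 1.0, rise_slope = 5, flat = FALSE) {
  dt <- 0.1
  t <- seq(0, 700, by = dt)
  hold_start <- 660
  restart <- 680
  pao2 <- rep(300, length(t))
  in_hold <- t >= hold_start
  pao2[in_hold] <- 300 - 1 * (t[in_hold] - hold_start)
  kink <- restart + kink_offset
  after <- t >= kink
  if (flat) {
    pao2[t >= restart] <- pao2[sum(t < restart)]
  } else {
    pao2[after] <- (300 - (kink - hold_start)) + rise_slope * (t[after] - kink)
  }
  paw <- 5 + ifelse(t < hold_start & (t %% 60) < 20, 10, 0)
  structure(list(t = t, pao2 = pao2, paw = paw,
                 breath_hold_window = c(hold_start, restart),
                 ventilation_restart_s = restart, fs = 10, rr = 10,
                 condition_id = "PW"), class = "pao2_trace")
}

test_that("a noiseless kink is located exactly by the two-line construction", {
  al <- detect_alignment_offset(piecewise_trace(kink_offset = 1.0))
  expect_true(al$alignable)
  expect_equal(al$offset, 1.0, tolerance = 1e-6)
  al2 <- detect_alignment_offset(piecewise_trace(kink_offset = 2.3))
  expect_equal(al2$offset, 2.3, tolerance = 1e-6)
})

test_that("a flat recovery is unalignable", {
  al <- detect_alignment_offset(piecewise_trace(flat = TRUE))
  expect_false(al$alignable)
  expect_true(is.na(al$offset))
})

test_that("a trace without a breath-hold window is rejected", {
  tr <- piecewise_trace()
  tr$breath_hold_window <- c(NA_real_, NA_real_)
  expect_error(detect_alignment_offset(tr), "breath-hold")
})

test_that("alignment offset is recovered within 0.2 s on noisy traces", {
  errs <- vapply(1:15, function(i) {
    set.seed(500 + i)
    off <- min(2.5, max(0.5, rnorm(1, 1.23, 0.23)))
    sp <- condition_spec("x", "A1", snr_db = 30, true_offset = off,
                         morphology = morphology_params(runif(1), 0.6))
    tr <- simulate_condition(sp, seed = 500 + i)$trace
    detect_alignment_offset(tr)$offset - off
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.2), 0.9)
})

test_that("segmentation extracts 10 x 600 aligned breaths", {
  tr <- simulate_condition(condition_spec("x", "A1"), seed = 9)$trace
  m <- segment_breaths(tr, offset = 1.2)
  expect_identical(dim(m), c(10L, 600L))
  # a perfectly periodic noiseless trace gives identical rows
  sp <- condition_spec("x", "A1", snr_db = 60, cardiac_amp = 0, drift_slope = 0)
  tr2 <- simulate_condition(sp, seed = 10)$trace
  tr2$pao2 <- 300 + 20 * sin(2 * pi * tr2$t / 60)   # exact periodic signal
  m2 <- segment_breaths(tr2, offset = 0)
  expect_lt(max(apply(m2, 2, function(col) diff(range(col)))), 1e-9)
})

test_that("segmentation is equivariant to whole-breath shifts", {
  sp <- condition_spec("x", "A1", snr_db = 60, cardiac_amp = 0, drift_slope = 0)
  tr <- simulate_condition(sp, seed = 12)$trace
  tr$pao2 <- cos(2 * pi * tr$t / 60) + 0.3 * sin(4 * pi * tr$t / 60)
  m1 <- segment_breaths(tr, offset = 0)
  # drop the first breath: same breaths are re-extracted (last 10 of 10 vs 11)
  shift <- 600
  tr2 <- tr
  tr2$t <- tr$t[-seq_len(shift)] - 60
  tr2$pao2 <- tr$pao2[-seq_len(shift)]
  tr2$paw <- tr$paw[-seq_len(shift)]
  tr2$breath_hold_window <- tr$breath_hold_window - 60
  tr2$ventilation_restart_s <- tr$ventilation_restart_s - 60
  m2 <- segment_breaths(tr2, offset = 0)
  expect_equal(unclass(m1)[2:10, ], unclass(m2)[1:9, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("detrending removes exactly a line from a plain series", {
  t <- seq_len(500)
  expect_equal(detrend_linear(3 + 0.25 * t), rep(0, 500), tolerance = 1e-9)
  x <- cos(2 * pi * (t - 250.5) / 50)   # even about the centre: OLS slope 0
  expect_equal(detrend_linear(x), x - mean(x), tolerance = 1e-9)
  # injected slope is re-estimated by the OLS fit within 0.01
  y <- sin(2 * pi * t / 50) + 0.5 * t
  slope_hat <- coef(stats::lm(y ~ t))[2]
  expect_equal(unname(slope_hat), 0.5, tolerance = 0.01)
  expect_equal(detrend_linear(rep(7, 10)), rep(0, 10))
  expect_error(detrend_linear(1), "2 samples")
})

test_that("matrix detrending recovers a drift without aliasing the waveform", {
  sp <- condition_spec("x", "A1", snr_db = 60, cardiac_amp = 0,
                       drift_slope = 0.02,
                       morphology = morphology_params(0.3, 0.8, -0.7, c(0.32, 0)))
  tr <- simulate_condition(sp, seed = 13)$trace
  m <- segment_breaths(tr, offset = 1.2)
  d <- detrend_linear(m)
  # rows of the detrended matrix are near-identical: drift fully removed and
  # no step offsets introduced between breaths
  expect_lt(mean(apply(d, 2, stats::sd)), 0.1)
  expect_equal(mean(d), 0, tolerance = 1e-9)
})

test_that("median aggregation is robust to one corrupted breath", {
  breath <- sin(2 * pi * (0:599) / 600)
  m <- matrix(rep(breath, 10), 10, byrow = TRUE)
  expect_equal(aggregate_median_breath(m), breath, tolerance = 1e-12)
  m[4, ] <- m[4, ] + 50
  expect_equal(aggregate_median_breath(m), breath, tolerance = 1e-9)
  expect_equal(aggregate_median_breath(matrix(2, 5, 10)), rep(2, 10))
  expect_error(aggregate_median_breath(m[1:2, ]), "3 breaths")
})

test_that("median aggregation attenuates a cardiac ripple at least 10-fold", {
  t <- (0:5999) * 0.1
  cardiac <- sin(2 * pi * (117.3 / 60) * t)
  m <- matrix(cardiac, 10, 600, byrow = TRUE)
  med <- aggregate_median_breath(m)
  expect_lt(max(abs(med)), max(abs(cardiac)) / 10)
})

test_that("normalization is exact and affine-invariant", {
  breath <- 300 + 25 * sin(2 * pi * (0:599) / 600)
  nb <- normalize_breath(breath, "c1")
  expect_equal(mean(nb$values), 0, tolerance = 1e-10)
  expect_equal(stats::sd(nb$values), 1, tolerance = 1e-10)
  expect_equal(nb$raw_mean, 300, tolerance = 1e-9)
  nb2 <- normalize_breath(10 * breath + 100)
  expect_equal(nb2$values, nb$values, tolerance = 1e-9)
  # idempotence: renormalizing the normalized values changes nothing
  nb3 <- normalize_breath(nb$values * 1 + 0)
  expect_equal(nb3$values, nb$values, tolerance = 1e-12)
  expect_error(normalize_breath(rep(5, 600)), "zero standard deviation")
})

test_that("SNR estimation hits its fixed points", {
  breath <- sin(2 * pi * (0:599) / 600)
  clean <- structure(matrix(rep(breath, 10), 10, byrow = TRUE),
                     class = c("breath_matrix", "matrix"))
  expect_equal(estimate_snr_db(clean), 60)   # noiseless cap
  # residual variance equal to signal variance -> 0 dB; antisymmetric
  # residuals (rows 1-5 = +z, rows 6-10 = -z) leave the median untouched
  set.seed(1)
  z <- matrix(rnorm(5 * 600), 5)
  z <- z - mean(z)
  z <- z * sqrt(stats::var(breath) / mean(z^2))
  noisy <- unclass(clean)
  noisy[1:5, ] <- noisy[1:5, ] + z
  noisy[6:10, ] <- noisy[6:10, ] - z
  expect_equal(estimate_snr_db(structure(noisy, class = c("breath_matrix", "matrix"))),
               0, tolerance = 0.05)
})

test_that("exclusion filters use strict thresholds and a fixed reason order", {
  df <- data.frame(
    condition_id = c("a", "b", "c", "d", "e"),
    trough = c(100.0, 99.9, 90, 150, 150),
    snr_db = c(25, 25, 15, 19.9, 25),
    alignable = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    offset = c(1, 1, NA, 1, NA)
  )
  rep_ <- apply_exclusion_filters(df)
  expect_identical(rep_$included, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # boundary trough of exactly 100 mmHg is included (strict <)
  expect_identical(rep_$reason[1], "none")
  # first failing criterion wins: trough before snr before alignment
  expect_identical(rep_$reason[3], "trough")
  expect_identical(rep_$reason[4], "snr")
  expect_identical(rep_$reason[5], "unalignable")
  expect_identical(sum(rep_$included) + sum(!rep_$included), 5L)
})
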