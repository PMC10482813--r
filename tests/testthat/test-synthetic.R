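spec_default <- function(...) {
  condition_spec("T1", "A1",
                 morphology = morphology_params(0.3, 0.8, -0.7, c(0.32, 0)),
                 ...)
}

test_that("simulated traces have the documented layout", {
  sim <- simulate_condition(spec_default(), seed = 11)
  tr <- sim$trace
  expect_s3_class(tr, "pao2_trace")
  expect_equal(diff(tr$t)[1], 0.1, tolerance = 1e-12)
  expect_equal(max(abs(diff(tr$t) - 0.1)), 0, tolerance = 1e-9)
  # post-restart segment: 10 breaths x 60 s x 10 Hz
  expect_identical(sum(tr$t >= tr$ventilation_restart_s), 6000L)
  # breath hold: 20 s of zero-flow airway pressure at PEEP
  hold <- tr$breath_hold_window
  expect_equal(diff(hold), 20)
  in_hold <- tr$t >= hold[1] & tr$t < hold[2]
  expect_true(all(tr$paw[in_hold] == min(tr$paw)))
})

test_that("the breath-hold PaO2 decline is monotone in trend", {
  sim <- simulate_condition(spec_default(snr_db = 35), seed = 3)
  tr <- sim$trace
  hold <- tr$breath_hold_window
  idx <- tr$t >= hold[1] & tr$t < hold[2]
  fit <- stats::lm(tr$pao2[idx] ~ tr$t[idx])
  expect_lt(coef(fit)[2], -1)   # clear downward trend, mmHg/s
})

test_that("clean conditions keep the trough above 100 mmHg", {
  sim <- simulate_condition(spec_default(mean_pao2 = 300, osc_amplitude = 20),
                            seed = 5)
  tr <- sim$trace
  pre <- tr$t < tr$breath_hold_window[1]
  expect_gt(min(tr$pao2[pre]), 100)
})

test_that("simulation is a pure function of (spec, seed)", {
  s1 <- simulate_condition(spec_default(), seed = 7)
  s2 <- simulate_condition(spec_default(), seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_condition(spec_default(), seed = 8)
  expect_false(identical(s1$trace$pao2, s3$trace$pao2))
  expect_error(simulate_condition(spec_default()), "seed")
})

test_that("realized SNR matches the dial within 1.5 dB across 10-40 dB", {
  for (dial in c(10, 20, 30, 40)) {
    est <- vapply(1:3, function(s) {
      tr <- simulate_condition(spec_default(snr_db = dial), seed = 100 + s)$trace
      preprocess_condition(tr)$snr_db
    }, numeric(1))
    expect_true(all(abs(est - dial) <= 1.5),
                info = sprintf("dial %d dB -> %s", dial,
                               paste(round(est, 2), collapse = ", ")))
  }
})

test_that("factorial cohorts have one condition per cell and are reproducible", {
  co <- generate_cohort(seed = 21, simulate_traces = FALSE)
  expect_identical(length(co$specs), 84L)                 # 7 x 4 x 3
  expect_identical(nrow(co$truth), 84L)
  expect_identical(sum(co$manifest$animal_id == "A1"), 12L) # 12 per animal
  expect_false(anyDuplicated(co$manifest$condition_id) > 0)
  co2 <- generate_cohort(seed = 21, simulate_traces = FALSE)
  expect_identical(co, co2)
  tiny <- generate_cohort(seed = 1, n_animals = 1, peep_levels = 5,
                          vt_levels = 10, simulate_traces = FALSE)
  expect_identical(length(tiny$specs), 1L)
})

test_that("the exclusions preset flags 3+3+5 distinct conditions", {
  co <- preset_exclusions_cohort(seed = 31, simulate_traces = FALSE)
  tab <- table(co$truth$force_exclusion)
  expect_identical(as.integer(tab[c("trough", "snr", "unalignable")]),
                   as.integer(c(3, 3, 5)))
  expect_identical(as.integer(tab["none"]), 73L)
  co2 <- preset_exclusions_cohort(seed = 31, simulate_traces = FALSE)
  expect_identical(co$truth$force_exclusion, co2$truth$force_exclusion)
})

test_that("simulated covariates track the progression coordinate", {
  co <- generate_cohort(seed = 41, simulate_traces = FALSE)
  m <- co$manifest
  th <- co$truth$theta
  expect_gt(stats::cor(m$ppv_pct, th), 0)   # positive PPV slope by default
  expect_lt(stats::cor(m$pf_kpa, th), 0)    # PF ratio falls along progression
  # zero-effect generator: slope CI covers 0 in most replicates
  cover <- vapply(1:40, function(s) {
    cv <- simulate_covariates(co$truth,
                              effects = list(
                                pf = c(intercept = 45, slope = 0, animal_sd = 0, noise_sd = 5),
                                ppv = c(intercept = 11, slope = 0, animal_sd = 0, noise_sd = 3),
                                co = c(intercept = 4.4, slope = 0, animal_sd = 0, noise_sd = 0.7)
                              ), seed = s)
    ci <- stats::confint(stats::lm(cv$ppv_pct ~ th))[2, ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("mixed-model generator recovers its own random-intercept SD", {
  est <- vapply(1:8, function(s) {
    fit_mixed_progression(simulate_progression_cohort(seed = s))$random_sd
  }, numeric(1))
  expect_gte(mean(est), 0.4)
  expect_lte(mean(est), 1.1)
})
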