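#' Specification of one simulated ventilatory condition
#'
#' Collects the physiological and signal-quality parameters used by
#' [simulate_condition()] to synthesize one PaO2 / airway-pressure recording.
#'
#' @param condition_id,animal_id identifiers (strings).
#' @param peep positive end-expiratory pressure, cmH2O.
#' @param vt_per_kg tidal volume, mL/kg.
#' @param injured logical, experimental lung injury status of the animal.
#' @param mean_pao2 mean PaO2 during tidal ventilation, mmHg.
#' @param osc_amplitude oscillation amplitude (SD-scale, i.e. the SD of the
#'   oscillatory component), mmHg.
#' @param drift_slope slow linear PaO2 drift, mmHg/s.
#' @param snr_db target signal-to-noise ratio of the oscillation, decibels,
#'   defined exactly as estimated by [estimate_snr_db()].
#' @param cardiac_rate heart rate, beats/min; must exceed the respiratory
#'   rate. Non-integer rates dephase the cardiac ripple across breaths.
#' @param cardiac_amp cardiac ripple amplitude, mmHg (capped so that total
#'   non-respiratory variance matches `snr_db`).
#' @param morphology a [morphology_params()] object.
#' @param force_exclusion one of `"none"`, `"trough"`, `"snr"`,
#'   `"unalignable"`; constructs a trace violating the corresponding
#'   inclusion criterion.
#' @param true_offset lag between inspiration onset (airway pressure) and the
#'   PaO2 response, seconds.
#' @return object of class `condition_spec`.
#' @export
condition_spec <- function(condition_id, animal_id, peep = 8, vt_per_kg = 10,
                           injured = FALSE, mean_pao2 = 300, osc_amplitude = 20,
                           drift_slope = 0, snr_db = 30, cardiac_rate = 117.3,
                           cardiac_amp = 0.05 * osc_amplitude,
                           morphology = morphology_params(0),
                           force_exclusion = c("none", "trough", "snr", "unalignable"),
                           true_offset = 1.2) {
  force_exclusion <- match.arg(force_exclusion)
  stopifnot(mean_pao2 - osc_amplitude > 0, true_offset >= 0,
            osc_amplitude > 0, snr_db > 0, cardiac_rate > 10)
  if (!inherits(morphology, "morphology_params")) {
    morphology <- do.call(morphology_params, as.list(morphology))
  }
  structure(list(
    condition_id = as.character(condition_id),
    animal_id = as.character(animal_id),
    peep = peep, vt_per_kg = vt_per_kg, injured = isTRUE(injured),
    mean_pao2 = mean_pao2, osc_amplitude = osc_amplitude,
    drift_slope = drift_slope, snr_db = snr_db,
    cardiac_rate = cardiac_rate, cardiac_amp = cardiac_amp,
    morphology = morphology, force_exclusion = force_exclusion,
    true_offset = true_offset
  ), class = "condition_spec")
}

#' Simulate the PaO2 / airway-pressure trace for one ventilatory condition
#'
#' Builds a 10 Hz recording with the layout used throughout the pipeline:
#' `n_breaths + 1` breaths of steady tidal ventilation, a 20 s end-expiratory
#' breath hold during which PaO2 declines linearly at zero flow, and
#' `n_post_breaths` breaths after the restart of ventilation. The PaO2 rise
#' after the restart is delayed by `true_offset` and recovers exponentially
#' toward the tidal signal, producing the change point used for alignment.
#' The tidal PaO2 is `mean_pao2 + osc_amplitude * template` (the template
#' shifted by `true_offset` relative to the inspiration onsets) plus linear
#' drift, a cardiac-frequency ripple and white noise; ripple and noise are
#' jointly scaled so that the oscillation signal-to-noise ratio equals
#' `snr_db` as measured by [estimate_snr_db()] (cardiac variance is capped at
#' 10\% of the noise budget).
#'
#' `force_exclusion` overrides: `"trough"` lowers the mean PaO2 so the raw
#' trough falls below 100 mmHg, `"snr"` caps the target SNR at 15 dB, and
#' `"unalignable"` suppresses the post-restart recovery (flat signal, no
#' change point).
#'
#' @param spec a [condition_spec()].
#' @param seed integer seed; required (generation is a pure function of
#'   `(spec, seed)`).
#' @param n_breaths number of steady pre-hold breaths to guarantee available
#'   for extraction (one extra is generated).
#' @param n_post_breaths breaths generated after the restart.
#' @param hold_duration_s breath-hold length, seconds.
#' @param hold_decline_rate PaO2 decline during the hold, mmHg/s.
#' @param recovery_tau time constant of the post-restart PaO2 recovery, s.
#' @param grid canonical grid from [breath_grid()].
#' @return list with elements `trace` (class `pao2_trace`: `t`, `pao2`, `paw`,
#'   `breath_hold_window`, `ventilation_restart_s`, `fs`, `rr`,
#'   `condition_id`) and `truth` (one-row data frame with the generating
#'   parameters actually realized).
#' @export
simulate_condition <- function(spec, seed, n_breaths = 10, n_post_breaths = 10,
                               hold_duration_s = 20, hold_decline_rate = 2.5,
                               recovery_tau = 2.5, grid = breath_grid()) {
  stopifnot(inherits(spec, "condition_spec"))
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("simulate_condition() requires a seed: generation must be reproducible",
         call. = FALSE)
  }
  with_seed(seed, {
    dt <- grid$dt
    period <- grid$period
    npb <- grid$n

    mean_pao2 <- spec$mean_pao2
    amp <- spec$osc_amplitude
    snr_db <- spec$snr_db
    if (spec$force_exclusion == "trough") {
      # place the raw trough well below 100 mmHg but keep PaO2 positive
      mean_pao2 <- 85 + 1.5 * amp
    }
    if (spec$force_exclusion == "snr") snr_db <- min(snr_db, 15)

    n_pre <- (n_breaths + 1) * npb
    n_hold <- as.integer(round(hold_duration_s / dt))
    n_post <- n_post_breaths * npb
    n_tot <- n_pre + n_hold + n_post
    t <- (seq_len(n_tot) - 1) * dt
    hold_start <- n_pre * dt
    restart <- hold_start + n_hold * dt
    onset <- restart + spec$true_offset

    template <- breath_template(spec$morphology, n_samples = npb,
                                insp_fraction = grid$insp_fraction)
    # oscillation phase lags the ventilator by true_offset
    phase_pre <- ((t - spec$true_offset) %% period) / period
    phase_post <- ((t - restart - spec$true_offset) %% period) / period
    idx_pre <- pmin(npb, floor(phase_pre * npb) + 1L)
    idx_post <- pmin(npb, floor(phase_post * npb) + 1L)

    drift <- spec$drift_slope * (t - hold_start / 2)
    steady_pre <- mean_pao2 + drift + amp * template[idx_pre]

    pao2 <- steady_pre
    in_hold <- t >= hold_start & t < restart
    pao2[in_hold] <- steady_pre[sum(t < hold_start)] -
      hold_decline_rate * (t[in_hold] - hold_start)
    hold_end_val <- steady_pre[sum(t < hold_start)] -
      hold_decline_rate * (restart - hold_start)
    post <- t >= restart
    if (spec$force_exclusion == "unalignable") {
      # signal damped: no recovery, no oscillation after the restart
      pao2[post] <- hold_end_val
    } else {
      # the decline continues until the PaO2 response at restart + true_offset;
      # from there the mean level recovers exponentially while the oscillation
      # ramps back in over osc_ramp_tau (cyclic recruitment re-establishing)
      tp <- t[post]
      dec <- hold_end_val - hold_decline_rate * (tp - restart)
      p_onset <- hold_end_val - hold_decline_rate * spec$true_offset
      deficit <- (mean_pao2 + spec$drift_slope * (onset - hold_start / 2)) - p_onset
      osc_ramp_tau <- 4 * recovery_tau
      recov <- (mean_pao2 + drift[post]) -
        deficit * exp(-(tp - onset) / recovery_tau) +
        (1 - exp(-(tp - onset) / osc_ramp_tau)) * amp * template[idx_post[post]]
      pao2[post] <- ifelse(tp < onset, dec, recov)
    }

    # noise budget: total non-respiratory variance for the requested SNR,
    # split between cardiac ripple (capped at 10%) and white noise
    resid_var <- amp^2 * 10^(-snr_db / 10)
    cardiac_var <- min(spec$cardiac_amp^2 / 2, 0.1 * resid_var)
    white_sd <- sqrt(resid_var - cardiac_var)
    cardiac <- sqrt(2 * cardiac_var) * sin(2 * pi * spec$cardiac_rate / 60 * t)
    pao2 <- pao2 + cardiac + rnorm(n_tot, 0, white_sd)

    # airway pressure: square wave, inspiratory plateau = peep + driving
    driving <- 1.2 * spec$vt_per_kg
    breath_phase <- ifelse(t < hold_start, (t %% period) / period,
                           ((t - restart) %% period) / period)
    paw <- spec$peep + ifelse(breath_phase < grid$insp_fraction, driving, 0)
    paw[in_hold] <- spec$peep

    trace <- structure(list(
      t = t, pao2 = pao2, paw = paw,
      breath_hold_window = c(hold_start, restart),
      ventilation_restart_s = restart,
      fs = grid$fs, rr = grid$rr, condition_id = spec$condition_id
    ), class = "pao2_trace")

    truth <- data.frame(
      condition_id = spec$condition_id, animal_id = spec$animal_id,
      theta = spec$morphology$theta,
      true_offset = spec$true_offset, snr_db = snr_db,
      mean_pao2 = mean_pao2, osc_amplitude = amp,
      force_exclusion = spec$force_exclusion,
      stringsAsFactors = FALSE
    )
    list(trace = trace, truth = truth)
  })
}

#' Generate a factorial cohort of simulated ventilatory conditions
#'
#' Builds the full crossing of animals, PEEP and tidal-volume levels (one
#' condition per cell; 7 animals x PEEP \{5, 8, 10, 12\} x VT \{7, 10, 15\}
#' gives the 84-condition default), randomizes the condition order within each
#' animal, assigns a morphology archetype to every condition, jitters the
#' archetype parameters per condition, draws physiological nuisance parameters
#' (mean PaO2, amplitude, drift, SNR, cardiac rate, alignment lag) and
#' simulates every trace. Optionally a set of cells is designated to violate
#' each exclusion criterion.
#'
#' The generator is a pure function of its arguments and `seed`: the same call
#' yields a byte-identical cohort.
#'
#' @param seed master integer seed.
#' @param n_animals number of animals (IDs `A1`, `A2`, ...).
#' @param peep_levels,vt_levels factorial levels (cmH2O; mL/kg).
#' @param n_injured number of lung-injured animals (drawn at random).
#' @param morphology_rule `"cycle"` assigns archetypes 1..5 cyclically over
#'   each animal's randomized condition order; `"random"` samples uniformly.
#' @param exclusions named integer vector
#'   `c(trough = , snr = , unalignable = )`: number of conditions forced to
#'   violate each criterion, assigned to distinct randomly chosen cells.
#' @param snr_range target SNR range, dB, sampled uniformly per condition.
#' @param amp_range oscillation amplitude range, mmHg.
#' @param offset_mean,offset_sd alignment-lag distribution (s), truncated to
#'   \[0.5, 2.5\].
#' @param jitter named morphology jitter SDs (see
#'   `pao2morph:::morphology_jitter_defaults`).
#' @param simulate_traces set `FALSE` to return specs and truth only.
#' @param ... passed to [simulate_condition()].
#' @return object of class `pao2_cohort`: list with `specs` (list of
#'   [condition_spec()]), `traces` (list of `pao2_trace` or NULL), `truth`
#'   (data frame, one row per condition: archetype, theta, offset, SNR,
#'   exclusion flag), and `manifest` (data frame of design columns plus
#'   covariates from [simulate_covariates()]).
#' @export
generate_cohort <- function(seed, n_animals = 7,
                            peep_levels = c(5, 8, 10, 12),
                            vt_levels = c(7, 10, 15),
                            n_injured = 3,
                            morphology_rule = c("cycle", "random"),
                            exclusions = c(trough = 0, snr = 0, unalignable = 0),
                            snr_range = c(25, 35), amp_range = c(10, 30),
                            offset_mean = 1.23, offset_sd = 0.23,
                            jitter = morphology_jitter_defaults(),
                            simulate_traces = TRUE, ...) {
  morphology_rule <- match.arg(morphology_rule)
  stopifnot(n_animals >= 1, length(peep_levels) >= 1, length(vt_levels) >= 1)
  excl <- c(trough = 0, snr = 0, unalignable = 0)
  excl[names(exclusions)] <- exclusions
  ar <- morphology_archetypes()

  design <- with_seed(derive_seed(seed, "design"), {
    rows <- list()
    injured_animals <- sample(seq_len(n_animals), min(n_injured, n_animals))
    for (a in seq_len(n_animals)) {
      cells <- expand.grid(peep = peep_levels, vt = vt_levels,
                           KEEP.OUT.ATTRS = FALSE)
      cells <- cells[sample(nrow(cells)), , drop = FALSE]
      cells$animal_id <- sprintf("A%d", a)
      cells$injured <- a %in% injured_animals
      cells$order <- seq_len(nrow(cells))
      rows[[a]] <- cells
    }
    d <- do.call(rbind, rows)
    d$condition_id <- sprintf("%s_C%02d", d$animal_id, d$order)
    if (anyDuplicated(d$condition_id)) stop("duplicate condition_id")
    d$archetype <- if (morphology_rule == "cycle") {
      ((d$order - 1L) %% 5L) + 1L
    } else {
      sample(1:5, nrow(d), replace = TRUE)
    }
    d$force_exclusion <- "none"
    n_flag <- sum(excl)
    if (n_flag > 0) {
      if (n_flag > nrow(d)) stop("more exclusion flags than conditions")
      flagged <- sample(nrow(d), n_flag)
      d$force_exclusion[flagged] <- rep(names(excl), times = excl)
    }
    d
  })

  specs <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    specs[[i]] <- with_seed(derive_seed(seed, paste0("spec_", design$condition_id[i])), {
      amp <- runif(1, amp_range[1], amp_range[2])
      morph <- morphology_params(
        theta = min(1, max(0, ar$theta[design$archetype[i]] + rnorm(1, 0, jitter[["theta"]]))),
        biphasic_weight = min(1, max(0, ar$biphasic_weight[design$archetype[i]] +
                                       rnorm(1, 0, jitter[["biphasic_weight"]]))),
        harmonic_phase = ar$harmonic_phase[design$archetype[i]] +
          rnorm(1, 0, jitter[["harmonic_phase"]]),
        shape3 = c(ar$shape3_cos[design$archetype[i]] + rnorm(1, 0, jitter[["shape3_cos"]]),
                   ar$shape3_sin[design$archetype[i]] + rnorm(1, 0, jitter[["shape3_sin"]]))
      )
      condition_spec(
        condition_id = design$condition_id[i], animal_id = design$animal_id[i],
        peep = design$peep[i], vt_per_kg = design$vt[i],
        injured = design$injured[i],
        mean_pao2 = runif(1, 120 + 1.8 * amp, 460),
        osc_amplitude = amp,
        drift_slope = runif(1, -0.02, 0.02),
        snr_db = runif(1, snr_range[1], snr_range[2]),
        cardiac_rate = runif(1, 110, 146),
        morphology = morph,
        force_exclusion = design$force_exclusion[i],
        true_offset = min(2.5, max(0.5, rnorm(1, offset_mean, offset_sd)))
      )
    })
  }

  traces <- NULL
  truth <- vector("list", length(specs))
  if (simulate_traces) {
    traces <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      sim <- simulate_condition(specs[[i]],
                                seed = derive_seed(seed, paste0("trace_", specs[[i]]$condition_id)),
                                ...)
      traces[[i]] <- sim$trace
      truth[[i]] <- sim$truth
    }
    names(traces) <- design$condition_id
  } else {
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      truth[[i]] <- data.frame(
        condition_id = s$condition_id, animal_id = s$animal_id,
        theta = s$morphology$theta, true_offset = s$true_offset,
        snr_db = s$snr_db, mean_pao2 = s$mean_pao2,
        osc_amplitude = s$osc_amplitude, force_exclusion = s$force_exclusion,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, truth)
  truth$archetype <- design$archetype

  manifest <- data.frame(
    condition_id = design$condition_id, animal_id = design$animal_id,
    peep_cmH2O = design$peep, vt_ml_per_kg = design$vt,
    injured = design$injured, stringsAsFactors = FALSE
  )
  covar <- simulate_covariates(truth, design = manifest,
                               seed = derive_seed(seed, "covariates"))
  manifest <- cbind(manifest, covar)

  structure(list(specs = specs, traces = traces, truth = truth,
                 manifest = manifest, seed = seed),
            class = "pao2_cohort")
}

#' Preset cohort with designated exclusion violations
#'
#' The standard 84-condition factorial (7 animals x 4 PEEP x 3 VT) in which
#' exactly 3 conditions are constructed to violate the trough criterion, 3 the
#' signal-to-noise criterion and 5 the alignability criterion (each violation
#' on a distinct condition), leaving 73 conditions that pass all three
#' inclusion filters.
#'
#' @param seed master integer seed.
#' @param ... passed to [generate_cohort()].
#' @return a `pao2_cohort`.
#' @export
preset_exclusions_cohort <- function(seed, ...) {
  generate_cohort(seed, exclusions = c(trough = 3, snr = 3, unalignable = 5),
                  ...)
}

#' Validation cohort built from the five morphology archetypes
#'
#' A compact cohort for method-validation experiments: `n_per_archetype`
#' conditions per archetype (75 by default), spread over `n_animals` animals,
#' with no forced exclusion violations. Used by the recovery experiments that
#' check cluster-number selection and cluster assignment against ground truth.
#'
#' @param seed master integer seed.
#' @param n_per_archetype conditions per archetype.
#' @param n_animals animals the conditions are attributed to.
#' @param snr_range target SNR range, dB.
#' @param ... passed to [generate_cohort()] / [simulate_condition()].
#' @return a `pao2_cohort`.
#' @export
archetype_cohort <- function(seed, n_per_archetype = 15, n_animals = 5,
                             snr_range = c(25, 35), ...) {
  n_cond <- 5 * n_per_archetype
  stopifnot(n_cond %% n_animals == 0)
  per_animal <- n_cond / n_animals
  # a factorial with per_animal cells per animal; archetypes cycle within
  generate_cohort(seed, n_animals = n_animals,
                  peep_levels = seq_len(per_animal), vt_levels = 1,
                  snr_range = snr_range, ...)
}

#' Simulate cluster-associated cardiorespiratory covariates
#'
#' Generates per-condition covariates as linear functions of the morphology
#' progression coordinate `theta` plus a per-animal random intercept and
#' Gaussian noise: PaO2/FiO2 ratio (kPa, decreasing along the progression),
#' pulse pressure variation (%, increasing), and cardiac output (L/min).
#' Plateau and driving pressure are derived from the design (driving pressure
#' = 1.2 cmH2O per mL/kg of tidal volume) and mechanical power from
#' [mechanical_power_pcv()] assuming 30 kg body weight. The generating
#' parameters are attached as attribute `"params"` for recovery tests.
#'
#' @param truth cohort truth table (needs `condition_id`, `animal_id`,
#'   `theta`).
#' @param design data frame with `peep_cmH2O`, `vt_ml_per_kg` per condition
#'   (same order), or NULL to skip the derived mechanics columns.
#' @param effects list of generating parameters: elements `pf`, `ppv`, `co`,
#'   each `c(intercept, slope, animal_sd, noise_sd)` (slope per unit theta).
#' @param seed integer seed.
#' @return data frame of covariates (one row per condition), with attribute
#'   `"params"`.
#' @export
simulate_covariates <- function(truth, design = NULL,
                                effects = list(
                                  pf = c(intercept = 45, slope = -20, animal_sd = 4, noise_sd = 5),
                                  ppv = c(intercept = 11, slope = 9, animal_sd = 2, noise_sd = 3),
                                  co = c(intercept = 4.4, slope = 0.8, animal_sd = 0.5, noise_sd = 0.7)
                                ), seed) {
  stopifnot(nrow(truth) >= 1)
  with_seed(seed, {
    animals <- unique(truth$animal_id)
    draw <- function(p) {
      u <- stats::setNames(rnorm(length(animals), 0, p[["animal_sd"]]), animals)
      pmax(0.1, p[["intercept"]] + p[["slope"]] * truth$theta +
             u[truth$animal_id] + rnorm(nrow(truth), 0, p[["noise_sd"]]))
    }
    out <- data.frame(
      pf_kpa = draw(effects$pf),
      ppv_pct = draw(effects$ppv),
      cardiac_output_lmin = draw(effects$co)
    )
    if (!is.null(design)) {
      driving <- 1.2 * design$vt_ml_per_kg
      out$plateau_cmH2O <- design$peep_cmH2O + driving
      out$driving_cmH2O <- driving
      out$mech_power_jmin <- mechanical_power_pcv(
        rr = 10, vt = design$vt_ml_per_kg * 30 / 1000,
        delta_p_insp = driving, peep = design$peep_cmH2O)
    }
    attr(out, "params") <- effects
    out
  })
}

#' Simulate a progression outcome with an animal random intercept
#'
#' Direct generator for validating the mixed-effects progression model: a
#' continuous cluster-progression outcome is built as
#' `intercept + slope_pf * PF + slope_ppv * PPV + u_animal + noise`, with
#' `u_animal ~ N(0, animal_sd^2)`. Defaults mirror the exploratory analysis
#' this models: 7 animals x 12 conditions, gradients -0.06 ranks/kPa and
#' 0.065 ranks/% and an animal SD of 0.75 ranks.
#'
#' @param seed integer seed.
#' @param n_animals,conditions_per_animal cohort shape.
#' @param intercept fixed intercept (ranks).
#' @param slope_pf,slope_ppv fixed-effect gradients (ranks/kPa, ranks/%).
#' @param animal_sd SD of the per-animal random intercept (ranks).
#' @param noise_sd residual SD (ranks).
#' @return data frame with `animal_id`, `pf_kpa`, `ppv_pct`, `progression`.
#' @export
simulate_progression_cohort <- function(seed, n_animals = 7,
                                        conditions_per_animal = 12,
                                        intercept = 3.5, slope_pf = -0.06,
                                        slope_ppv = 0.065, animal_sd = 0.75,
                                        noise_sd = 0.8) {
  with_seed(seed, {
    n <- n_animals * conditions_per_animal
    animal <- rep(sprintf("A%d", seq_len(n_animals)), each = conditions_per_animal)
    u <- stats::setNames(rnorm(n_animals, 0, animal_sd),
                         sprintf("A%d", seq_len(n_animals)))
    pf <- runif(n, 20, 60)
    ppv <- runif(n, 5, 25)
    y <- intercept + slope_pf * pf + slope_ppv * ppv + u[animal] +
      rnorm(n, 0, noise_sd)
    data.frame(animal_id = animal, pf_kpa = pf, ppv_pct = ppv,
               progression = y, stringsAsFactors = FALSE)
  })
}
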