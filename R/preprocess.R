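#' Alignment configuration
#'
#' Tunable parameters of the change-point detector used to align the PaO2
#' signal with the phases of ventilation.
#'
#' @param decline_fit_window seconds of the late breath hold used to fit the
#'   decline line.
#' @param k_sigma change-point threshold in multiples of the decline residual
#'   SD.
#' @param m_consec consecutive samples required above threshold.
#' @param min_offset,max_offset plausibility bounds on the offset, seconds.
#' @param rise_window seconds of signal after the detected change used to fit
#'   the rise line.
#' @param search_window seconds after the restart searched for a change point.
#' @param min_rise_slope minimum rise slope (mmHg/s) for a recovery to count
#'   as a genuine change point; rejects flat, damped recoveries.
#' @return list of class `alignment_config`.
#' @export
alignment_config <- function(decline_fit_window = 5, k_sigma = 3, m_consec = 5,
                             min_offset = 0.2, max_offset = 5, rise_window = 1.5,
                             search_window = 8, min_rise_slope = 1) {
  structure(as.list(environment()), class = "alignment_config")
}

# least-squares line fit returning slope/intercept/residual SD
fit_line <- function(x, y) {
  X <- cbind(1, x)
  cf <- stats::lm.fit(X, y)$coefficients
  r <- y - X %*% cf
  list(intercept = cf[[1]], slope = cf[[2]],
       sigma = if (length(y) > 2) stats::sd(r) else 0)
}

#' Detect the ventilation-to-PaO2 alignment offset
#'
#' Locates the first increase in PaO2 after the steady decline during an
#' end-expiratory breath hold, relative to the restart of ventilation. A line
#' is fitted to the final `decline_fit_window` seconds of the hold; the change
#' point is the first post-restart time at which PaO2 exceeds the extrapolated
#' decline line by more than `k_sigma` residual SDs for at least `m_consec`
#' consecutive samples. The estimate is refined to sub-sample precision by
#' intersecting the decline line with a rise line fitted over the
#' `rise_window` seconds following the detection (the classical
#' two-straight-lines construction), and this intersection alone is used as a
#' fallback when no discrete change point exists. Recoveries whose rise slope
#' is below `min_rise_slope` or whose offset falls outside
#' `[min_offset, max_offset]` are declared unalignable.
#'
#' @param trace a `pao2_trace` (needs `breath_hold_window` and
#'   `ventilation_restart_s`).
#' @param config an [alignment_config()].
#' @return list of class `alignment_result`: `offset` (s, NA if unalignable),
#'   `method` (`"change_point"` or `"two_line_intersection"`), `alignable`,
#'   `diagnostics` (decline residual SD, slopes).
#' @export
detect_alignment_offset <- function(trace, config = alignment_config()) {
  if (is.null(trace$breath_hold_window) || anyNA(trace$breath_hold_window)) {
    stop("trace has no breath-hold window", call. = FALSE)
  }
  hold <- trace$breath_hold_window
  restart <- trace$ventilation_restart_s
  t <- trace$t
  y <- trace$pao2

  dec_idx <- which(t >= hold[2] - config$decline_fit_window & t < hold[2])
  if (length(dec_idx) < 5) stop("breath-hold window too short for decline fit",
                                call. = FALSE)
  dec <- fit_line(t[dec_idx], y[dec_idx])

  post_idx <- which(t >= restart & t <= restart + config$search_window)
  deviation <- y[post_idx] - (dec$intercept + dec$slope * t[post_idx])
  thr <- max(config$k_sigma * dec$sigma, 1e-6)

  above <- deviation > thr
  run <- 0L
  t_detect <- NA_real_
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= config$m_consec) {
      t_detect <- t[post_idx[i - config$m_consec + 1L]]
      break
    }
  }

  result <- function(offset, method, alignable, rise_slope = NA_real_) {
    structure(list(offset = offset, method = method, alignable = alignable,
                   diagnostics = list(decline_sigma = dec$sigma,
                                      decline_slope = dec$slope,
                                      rise_slope = rise_slope)),
              class = "alignment_result")
  }

  two_line <- function(t_from) {
    rise_idx <- which(t >= t_from & t <= t_from + config$rise_window)
    if (length(rise_idx) < 3) return(NULL)
    rise <- fit_line(t[rise_idx], y[rise_idx])
    if (!is.finite(rise$slope) || rise$slope < config$min_rise_slope ||
        rise$slope <= dec$slope) return(NULL)
    t_x <- (dec$intercept - rise$intercept) / (rise$slope - dec$slope)
    list(t_x = t_x, slope = rise$slope)
  }

  if (!is.na(t_detect)) {
    # back-track to the first sample of the contiguous raised stretch
    i0 <- match(t_detect, t[post_idx])
    while (i0 > 1 && deviation[i0 - 1] > max(dec$sigma, 1e-9)) i0 <- i0 - 1
    t_back <- t[post_idx[i0]]
    # sub-sample refinement: intersect the decline line with the rise line,
    # re-fitting the rise once from the intersection (tangent at the kink)
    tl <- two_line(t_back)
    if (!is.null(tl) && tl$t_x >= restart - 0.5 && tl$t_x <= t_detect) {
      tl2 <- two_line(max(tl$t_x, restart))
      if (!is.null(tl2) && tl2$t_x >= restart - 0.5 && tl2$t_x <= t_detect) {
        tl <- tl2
      }
    }
    if (is.null(tl)) {
      return(result(NA_real_, "change_point", FALSE))
    }
    offset <- if (tl$t_x >= restart - 0.5 && tl$t_x <= t_detect) {
      tl$t_x - restart
    } else {
      t_back - restart
    }
    ok <- offset >= config$min_offset && offset <= config$max_offset
    return(result(if (ok) offset else NA_real_, "change_point", ok, tl$slope))
  }

  # no discrete change point: two-line intersection over the
  # maximum-gradient window of the recovery
  nw <- as.integer(round(config$rise_window * trace$fs))
  if (length(post_idx) > nw + 1) {
    slopes <- vapply(seq_len(length(post_idx) - nw), function(i) {
      (y[post_idx[i + nw]] - y[post_idx[i]]) / (t[post_idx[i + nw]] - t[post_idx[i]])
    }, numeric(1))
    tl <- two_line(t[post_idx[which.max(slopes)]])
    if (!is.null(tl)) {
      offset <- tl$t_x - restart
      ok <- offset >= config$min_offset && offset <= config$max_offset
      return(result(if (ok) offset else NA_real_, "two_line_intersection", ok,
                    tl$slope))
    }
  }
  result(NA_real_, "two_line_intersection", FALSE)
}

#' Extract aligned breaths from the pre-hold tidal ventilation
#'
#' Identifies inspiration onsets from the airway-pressure trace, applies the
#' alignment offset (rounded to the nearest sample) retrospectively to the
#' tidal ventilation immediately before the breath hold, and extracts the last
#' `n_breaths` complete breaths, each resampled onto the canonical breath grid
#' (600 samples at the defaults).
#'
#' @param trace a `pao2_trace`.
#' @param offset alignment offset, seconds.
#' @param n_breaths breaths to extract.
#' @param grid canonical grid from [breath_grid()].
#' @return matrix of class `breath_matrix`, `n_breaths` rows x `grid$n`
#'   columns (mmHg, not detrended), with attributes `grid` and `onsets`.
#' @export
segment_breaths <- function(trace, offset, n_breaths = 10, grid = breath_grid()) {
  stopifnot(is.finite(offset), offset >= 0)
  dt <- 1 / trace$fs
  npb <- grid$n
  hold_start <- trace$breath_hold_window[1]

  # inspiration onsets: upward paw transitions before the hold
  paw <- trace$paw
  mid <- (max(paw) + min(paw)) / 2
  up <- which(diff(paw > mid) == 1) + 1L
  onsets <- trace$t[up]
  onsets <- c(if (paw[1] > mid) trace$t[1] else numeric(0), onsets)
  off_r <- round(offset / dt) * dt
  onsets <- onsets[onsets + off_r + npb * dt <= hold_start + dt / 2]
  if (length(onsets) < n_breaths) {
    stop(sprintf("only %d complete pre-hold breaths available (%d requested)",
                 length(onsets), n_breaths), call. = FALSE)
  }
  onsets <- utils::tail(onsets, n_breaths)

  m <- matrix(NA_real_, n_breaths, npb)
  for (i in seq_len(n_breaths)) {
    start <- as.integer(round((onsets[i] + off_r) / dt)) + 1L
    m[i, ] <- trace$pao2[start:(start + npb - 1L)]
  }
  structure(m, class = c("breath_matrix", "matrix"), grid = grid,
            onsets = onsets)
}

#' Remove the linear trend from a breath series
#'
#' Subtracts an ordinary-least-squares line over the whole ten-breath signal,
#' leaving a zero-mean detrended series. For a plain vector the line is the
#' OLS fit to all samples. For a `breath_matrix` the drift slope is estimated
#' from the per-breath mean levels (one point per breath at the breath
#' centre): for a periodic waveform superposed on a linear drift this
#' estimator recovers the drift exactly, whereas a sample-wise OLS fit would
#' alias the asymmetry of the respiratory waveform into a spurious slope and
#' re-distribute it as step offsets between breaths.
#'
#' @param x numeric vector, or a `breath_matrix`.
#' @return object of the same shape, detrended. Constant input gives zeros.
#' @export
detrend_linear <- function(x) {
  if (inherits(x, "breath_matrix")) {
    n <- nrow(x); p <- ncol(x)
    means <- rowMeans(x)
    centers <- (seq_len(n) - 1) * p + (p + 1) / 2   # sample index of breath centre
    f <- fit_line(centers, means)
    idx <- matrix(seq_len(n * p), n, p, byrow = TRUE)
    out <- x
    out[, ] <- unclass(x) - (f$intercept + f$slope * idx)
    out[, ] <- unclass(out) - mean(out)
    return(out)
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to detrend", call. = FALSE)
  i <- seq_len(n)
  sxx <- sum((i - mean(i))^2)
  slope <- if (sxx > 0) sum((i - mean(i)) * (x - mean(x))) / sxx else 0
  x - mean(x) - slope * (i - mean(i))
}

#' Aggregate breaths into a single median breath
#'
#' Combines the rows of a breath matrix into one breath by taking the median
#' of each timepoint across breaths, suppressing components that are not
#' phase-locked to the respiratory cycle (cardiac-frequency ripple, noise).
#'
#' @param matrix a `breath_matrix` (or plain matrix), breaths in rows.
#' @return numeric vector of length `ncol(matrix)`.
#' @export
aggregate_median_breath <- function(matrix) {
  if (nrow(matrix) < 3) stop("need at least 3 breaths to aggregate", call. = FALSE)
  apply(unclass(matrix), 2, stats::median)
}

#' Normalize a breath to standard-deviation units
#'
#' Converts the aggregated breath from mmHg into multiples of its own standard
#' deviation (mean removed), so that shapes can be compared across conditions
#' independent of oscillation amplitude and absolute PaO2.
#'
#' @param breath numeric vector, mmHg.
#' @param condition_id optional identifier carried along.
#' @return list of class `normalized_breath`: `values` (mean 0, SD 1),
#'   `raw_mean`, `raw_sd`, `condition_id`.
#' @export
normalize_breath <- function(breath, condition_id = NA_character_) {
  m <- mean(breath)
  s <- stats::sd(breath)
  if (!is.finite(s) || s < 1e-12) {
    stop("degenerate breath: zero standard deviation", call. = FALSE)
  }
  structure(list(values = (breath - m) / s, raw_mean = m, raw_sd = s,
                 condition_id = condition_id), class = "normalized_breath")
}

#' Estimate the oscillation signal-to-noise ratio
#'
#' SNR (dB) of the respiratory-locked oscillation: the variance over time of
#' the per-timepoint median breath, against the variance of the residuals
#' (each breath minus the median breath, pooled over all breaths and
#' timepoints). The matrix should be detrended first. Capped at +60 dB when
#' the residual variance is numerically zero.
#'
#' @param matrix a detrended `breath_matrix`.
#' @return SNR in decibels.
#' @export
estimate_snr_db <- function(matrix) {
  if (nrow(matrix) < 3) stop("need at least 3 breaths for SNR estimation",
                             call. = FALSE)
  med <- apply(unclass(matrix), 2, stats::median)
  resid <- sweep(unclass(matrix), 2, med)
  v_r <- stats::var(as.vector(resid))
  if (!is.finite(v_r) || v_r < 1e-12) return(60)
  min(60, 10 * log10(stats::var(med) / v_r))
}

#' Preprocess one condition end to end
#'
#' Runs alignment, segmentation, detrending, SNR estimation, median
#' aggregation and normalization for a single trace, collecting the
#' per-condition quantities the exclusion filters need. When the trace is
#' unalignable, the breaths are still extracted at zero offset so that trough
#' and SNR can be reported.
#'
#' @param trace a `pao2_trace`.
#' @param n_breaths breaths to extract.
#' @param align_config an [alignment_config()].
#' @param grid canonical grid.
#' @return list: `condition_id`, `alignment` ([detect_alignment_offset()]
#'   result), `trough` (mmHg, min of the raw extracted segment), `snr_db`,
#'   `normalized` ([normalize_breath()] result), `matrix` (detrended breaths).
#' @export
preprocess_condition <- function(trace, n_breaths = 10,
                                 align_config = alignment_config(),
                                 grid = breath_grid()) {
  al <- detect_alignment_offset(trace, align_config)
  off <- if (isTRUE(al$alignable)) al$offset else 0
  raw <- segment_breaths(trace, offset = off, n_breaths = n_breaths, grid = grid)
  trough <- min(raw)
  det <- detrend_linear(raw)
  snr <- estimate_snr_db(det)
  med <- aggregate_median_breath(det)
  norm <- if (stats::sd(med) > 1e-12) {
    normalize_breath(med, condition_id = trace$condition_id)
  } else NULL
  list(condition_id = trace$condition_id, alignment = al, trough = trough,
       snr_db = snr, normalized = norm, matrix = det)
}

#' Apply the three inclusion criteria to a cohort
#'
#' A condition is excluded iff its raw trough is below `trough_mmhg` (strict
#' inequality), its SNR is below `snr_db`, or it could not be aligned with the
#' phases of ventilation. Reasons are evaluated in the fixed order trough,
#' SNR, alignment, and the first failure is recorded.
#'
#' @param results list of [preprocess_condition()] results, or a data frame
#'   with columns `condition_id`, `trough`, `snr_db`, `alignable`, `offset`.
#' @param trough_mmhg trough threshold, mmHg (default 100).
#' @param snr_db SNR threshold, dB (default 20).
#' @return data frame of class `inclusion_report`: `condition_id`, `included`,
#'   `reason` (`none`, `trough_below_100mmHg`-style labels), `trough_mmHg`,
#'   `snr_db`, `offset_s`.
#' @export
apply_exclusion_filters <- function(results, trough_mmhg = 100, snr_db = 20) {
  df <- if (is.data.frame(results)) results else data.frame(
    condition_id = vapply(results, `[[`, "", "condition_id"),
    trough = vapply(results, `[[`, 0, "trough"),
    snr_db = vapply(results, `[[`, 0, "snr_db"),
    alignable = vapply(results, function(r) isTRUE(r$alignment$alignable), TRUE),
    offset = vapply(results, function(r) {
      o <- r$alignment$offset; if (is.null(o)) NA_real_ else o
    }, 0),
    stringsAsFactors = FALSE
  )
  reason <- ifelse(df$trough < trough_mmhg, "trough",
            ifelse(df$snr_db < snr_db, "snr",
            ifelse(!df$alignable, "unalignable", "none")))
  out <- data.frame(
    condition_id = df$condition_id,
    included = reason == "none",
    reason = reason,
    trough_mmHg = df$trough,
    snr_db = df$snr_db,
    offset_s = df$offset,
    stringsAsFactors = FALSE
  )
  class(out) <- c("inclusion_report", "data.frame")
  out
}
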