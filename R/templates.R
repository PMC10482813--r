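#' Morphology parameters for a single-breath PaO2 oscillation template
#'
#' Parametrizes the continuum of intra-tidal PaO2 oscillation shapes from
#' ventilation-dependent (`theta = 0`: PaO2 rises through inspiration, peaks
#' at the inspiration-to-expiration transition, falls through expiration) to
#' inverted, perfusion-dependent (`theta = 1`: the pointwise negation). A
#' second harmonic of adjustable weight and phase creates the biphasic
#' intermediate shapes with two peaks per breath; a pair of third-harmonic
#' shape coefficients adds fine structure (peak sharpening/skew) independent
#' of the progression coordinate.
#'
#' @param theta progression coordinate in \[0, 1\]; 0 = ventilation-dependent,
#'   1 = inverted.
#' @param biphasic_weight amplitude of the second-harmonic component relative
#'   to the fundamental, in \[0, 1\].
#' @param harmonic_phase phase offset of the second harmonic, radians.
#' @param shape3 numeric length-2: cosine and sine coefficients of a
#'   third-harmonic shape term (default none).
#' @return object of class `morphology_params`.
#' @seealso [breath_template()], [morphology_archetypes()]
#' @export
morphology_params <- function(theta, biphasic_weight = 0, harmonic_phase = 0,
                              shape3 = c(0, 0)) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("theta must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(biphasic_weight) || length(biphasic_weight) != 1 ||
      is.na(biphasic_weight) || biphasic_weight < 0 || biphasic_weight > 1) {
    stop("biphasic_weight must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(harmonic_phase), length(harmonic_phase) == 1,
            is.numeric(shape3), length(shape3) == 2, all(is.finite(shape3)))
  structure(list(theta = theta, biphasic_weight = biphasic_weight,
                 harmonic_phase = harmonic_phase, shape3 = as.numeric(shape3)),
            class = "morphology_params")
}

# Asymmetric fundamental: rises trough-to-peak over inspiration, falls back
# over expiration, peak exactly at the inspiration->expiration transition.
# `phase` in [0, 1) is breath phase; returns a zero-mean, unit-SD wave.
base_wave <- function(phase, insp_fraction) {
  out <- numeric(length(phase))
  insp <- phase < insp_fraction
  out[insp] <- -cos(pi * phase[insp] / insp_fraction)
  out[!insp] <- cos(pi * (phase[!insp] - insp_fraction) / (1 - insp_fraction))
  out / stats::sd(out)
}

#' Single-breath oscillation template
#'
#' Evaluates the unit-variance morphology template on the canonical breath
#' grid. The waveform is a mixture of an asymmetric fundamental (scaled by
#' `1 - 2*theta`, so `theta = 0` gives the ventilation-dependent shape and
#' `theta = 1` its exact negation), a second harmonic whose amplitude is
#' `biphasic_weight` plus a transition bump `transition_weight * sin(pi*theta)`
#' (so mid-continuum shapes remain biphasic rather than collapsing to zero),
#' and a third-harmonic term with coefficients `shape3`. The result is
#' standardized to mean 0, SD 1.
#'
#' @param morphology a [morphology_params()] object (or a list with the same
#'   fields).
#' @param n_samples number of samples in one breath (default 600).
#' @param insp_fraction inspiratory fraction of the breath (I:E 1:2 = 1/3).
#' @param transition_weight amplitude of the `sin(pi*theta)` second-harmonic
#'   transition bump; keeps the theta continuum non-degenerate at
#'   `theta = 0.5` when `biphasic_weight = 0`.
#' @return numeric vector of length `n_samples`, mean 0 and SD 1.
#' @examples
#' tpl <- breath_template(morphology_params(0))
#' which.max(tpl) # 201: the end-inspiration sample (1-based)
#' @export
breath_template <- function(morphology, n_samples = 600, insp_fraction = 1 / 3,
                            transition_weight = 0.55) {
  if (!inherits(morphology, "morphology_params")) {
    morphology <- do.call(morphology_params, as.list(morphology))
  }
  stopifnot(n_samples >= 4, insp_fraction > 0, insp_fraction < 1)
  phase <- (seq_len(n_samples) - 1) / n_samples
  b <- base_wave(phase, insp_fraction)
  th <- morphology$theta
  w2 <- morphology$biphasic_weight + transition_weight * sin(pi * th)
  raw <- (1 - 2 * th) * b +
    w2 * sqrt(2) * cos(4 * pi * (phase - insp_fraction) + morphology$harmonic_phase) +
    morphology$shape3[1] * sqrt(2) * cos(6 * pi * (phase - insp_fraction)) +
    morphology$shape3[2] * sqrt(2) * sin(6 * pi * (phase - insp_fraction))
  s <- stats::sd(raw)
  if (!is.finite(s) || s < 1e-9) {
    stop("degenerate template: parameters give a (near-)constant waveform",
         call. = FALSE)
  }
  (raw - mean(raw)) / s
}

#' Five morphology archetypes along the progression continuum
#'
#' Fixed parameter sets defining five discrete oscillation morphologies
#' ordered along the progression from ventilation-dependent (rank 1) through
#' biphasic intermediates to inverted, perfusion-dependent (rank 5). These are
#' the ground-truth classes used by the cohort simulator: the extremes are
#' (near-)monophasic, the intermediates show two peaks and two troughs per
#' breath, and the third-harmonic skew alternates across the intermediate
#' ranks so that no pair of archetypes differs in only one shape dimension.
#'
#' @return data frame with columns `archetype` (progression rank 1..5),
#'   `theta`, `biphasic_weight`, `harmonic_phase`, `shape3_cos`, `shape3_sin`,
#'   `label`.
#' @export
morphology_archetypes <- function() {
  data.frame(
    archetype = 1:5,
    theta = c(0, 0.3, 0.5, 0.7, 1),
    biphasic_weight = c(0.25, 0.8, 0.95, 0.8, 0.25),
    harmonic_phase = c(0, -0.7, 0, 0.7, 0),
    shape3_cos = c(0, 0.32, -0.5, 0.32, 0),
    shape3_sin = c(0, 0, 0, 0, 0),
    label = c("ventilation-dependent", "biphasic early",
              "biphasic balanced", "biphasic late", "inverted"),
    stringsAsFactors = FALSE
  )
}

# Morphology jitter SDs used by the cohort generator: per-condition spread
# around the archetype parameters (theta, biphasic_weight, harmonic_phase,
# shape3 cos / sin).
morphology_jitter_defaults <- function() {
  c(theta = 0.035, biphasic_weight = 0.07, harmonic_phase = 0.15,
    shape3_cos = 0.12, shape3_sin = 0.33)
}
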