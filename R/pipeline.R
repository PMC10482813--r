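#' Pipeline run configuration
#'
#' One master seed is expanded into independent per-stage streams (cohort
#' simulation, Monte-Carlo clustering, final clustering), so that changing the
#' iteration count of one stage never perturbs another.
#'
#' @param seed master integer seed (mandatory).
#' @param trough_mmhg,snr_db exclusion thresholds.
#' @param var_threshold variance fraction the retained components must explain.
#' @param k_range candidate cluster counts; NULL = 1..K_retained.
#' @param n_iterations Monte-Carlo iterations per candidate k.
#' @param n_starts initializations for the final k-means.
#' @param tie_rule cluster-count tie rule (see [select_k_monte_carlo()]).
#' @param n_breaths breaths extracted per condition.
#' @param units PaO2 units of input signal files (`"mmHg"` or `"kPa"`).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, trough_mmhg = 100, snr_db = 20,
                       var_threshold = 0.95, k_range = NULL,
                       n_iterations = 10000, n_starts = 100,
                       tie_rule = "within_sd_largest", n_breaths = 10,
                       units = c("mmHg", "kPa")) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a master seed is mandatory", call. = FALSE)
  }
  units <- match.arg(units)
  stopifnot(trough_mmhg > 0, snr_db > 0, var_threshold > 0, var_threshold <= 1)
  structure(list(seed = as.integer(seed), trough_mmhg = trough_mmhg,
                 snr_db = snr_db, var_threshold = var_threshold,
                 k_range = k_range, n_iterations = n_iterations,
                 n_starts = n_starts, tie_rule = tie_rule,
                 n_breaths = n_breaths, units = units),
            class = "run_config")
}

#' Run the full morphology-discovery pipeline
#'
#' Orchestrates preprocessing, exclusion filtering, FPCA, Monte-Carlo
#' AIC-guided cluster-number selection, final clustering with progression
#' ordering and the downstream statistics for one cohort. The cohort can be a
#' [generate_cohort()] object or a directory of signal CSVs plus a manifest
#' (see [read_signal_csv()]). With the same configuration and cohort the run
#' is fully deterministic.
#'
#' @param cohort a `pao2_cohort`, or NULL to read from `signals_dir`.
#' @param config a [run_config()].
#' @param signals_dir,manifest directory of per-condition signal CSVs named
#'   `<condition_id>.csv` and the cohort manifest (path or data frame);
#'   used when `cohort` is NULL.
#' @param out_dir optional directory; when given, all artifacts are written
#'   there as CSV/JSON ([write_run_artifacts()]).
#' @return list of class `pao2_run`: `inclusion` (inclusion report), `fpca`,
#'   `k_retained`, `selection`, `clustering`, `assignments` (data frame),
#'   `regression` (per retained component), `comparison`, `mixed_model`,
#'   `summary` (named list).
#' @export
run_pipeline <- function(cohort = NULL, config, signals_dir = NULL,
                         manifest = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(signals_dir) || is.null(manifest)) {
      stop("either a cohort or signals_dir + manifest must be given",
           call. = FALSE)
    }
    if (is.character(manifest)) manifest <- utils::read.csv(manifest)
    traces <- lapply(manifest$condition_id, function(id) {
      path <- file.path(signals_dir, paste0(id, ".csv"))
      if (!file.exists(path)) {
        stop(sprintf("signal file missing for condition '%s': %s", id, path),
             call. = FALSE)
      }
      read_signal_csv(path, condition_id = id, units = config$units)
    })
    names(traces) <- manifest$condition_id
    cohort <- structure(list(traces = traces, manifest = manifest,
                             truth = NULL, specs = NULL, seed = NA),
                        class = "pao2_cohort")
  }

  ## stage 1: per-condition preprocessing + exclusion filters
  pre <- lapply(cohort$traces, preprocess_condition, n_breaths = config$n_breaths)
  inclusion <- apply_exclusion_filters(pre, trough_mmhg = config$trough_mmhg,
                                       snr_db = config$snr_db)
  keep <- inclusion$included & !vapply(pre, function(r) is.null(r$normalized), TRUE)
  included <- pre[keep]
  if (sum(keep) < 2) stop("fewer than 2 conditions pass the inclusion criteria",
                          call. = FALSE)
  curves <- do.call(rbind, lapply(included, function(r) r$normalized$values))
  rownames(curves) <- vapply(included, `[[`, "", "condition_id")

  ## stage 2: FPCA and component retention
  model <- fit_fpca(curves)
  k_retained <- n_components_for_threshold(model, config$var_threshold)
  scores <- model$scores[, seq_len(k_retained), drop = FALSE]

  ## stage 3: cluster-number selection and final clustering
  k_range <- if (is.null(config$k_range)) seq_len(k_retained) else config$k_range
  selection <- select_k_monte_carlo(scores, k_range = k_range,
                                    n_iterations = config$n_iterations,
                                    seed = derive_seed(config$seed, "mc_kmeans"),
                                    tie_rule = config$tie_rule)
  clustering <- finalize_clustering(scores, selection$chosen_k,
                                    seed = derive_seed(config$seed, "final_kmeans"),
                                    n_starts = config$n_starts, curves = curves)

  assignments <- data.frame(condition_id = rownames(curves),
                            cluster = clustering$assignments,
                            progression_rank = clustering$progression_rank,
                            stringsAsFactors = FALSE)
  assignments <- cbind(assignments, as.data.frame(scores))

  ## stage 4: statistics
  regression <- lapply(seq_len(k_retained), function(k) {
    progression_regression(scores[, k], assignments$progression_rank,
                           component = k)
  })

  comparison <- NULL
  mixed <- NULL
  if (!is.null(cohort$manifest)) {
    mf <- merge(assignments, cohort$manifest, by = "condition_id", sort = FALSE)
    covs <- intersect(c("pf_kpa", "ppv_pct", "cardiac_output_lmin",
                        "plateau_cmH2O", "driving_cmH2O", "mech_power_jmin",
                        "injured"), names(mf))
    if (length(covs) >= 1 && clustering$k >= 2) {
      comparison <- tryCatch(
        cluster_comparison_table(mf, covariates = covs),
        error = function(e) NULL)
    }
    mm_covs <- intersect(c("pf_kpa", "ppv_pct"), names(mf))
    if (length(mm_covs) == 2 && "animal_id" %in% names(mf)) {
      mf$progression <- mf$progression_rank
      mixed <- tryCatch(fit_mixed_progression(mf), error = function(e) NULL)
    }
  }

  run <- structure(list(
    inclusion = inclusion, fpca = model, k_retained = k_retained,
    selection = selection, clustering = clustering, assignments = assignments,
    regression = regression, comparison = comparison, mixed_model = mixed,
    summary = list(
      schema_version = "1",
      seed = config$seed,
      n_conditions = length(pre),
      n_included = sum(inclusion$included),
      exclusions_by_reason = as.list(table(inclusion$reason[!inclusion$included])),
      var_threshold = config$var_threshold,
      k_retained = k_retained,
      chosen_k = selection$chosen_k,
      cluster_sizes = clustering$sizes,
      pc1_regression_r_squared = regression[[1]]$r_squared
    )
  ), class = "pao2_run")

  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.pao2_run <- function(x, ...) {
  s <- x$summary
  cat("PaO2 oscillation morphology pipeline run\n")
  cat(sprintf("  conditions: %d (%d included)\n", s$n_conditions, s$n_included))
  cat(sprintf("  components retained (>=%g%% variance): %d\n",
              100 * s$var_threshold, s$k_retained))
  cat(sprintf("  chosen clusters: %d (sizes %s)\n", s$chosen_k,
              paste(s$cluster_sizes, collapse = "/")))
  cat(sprintf("  PC1 ~ progression R^2: %.3f\n", s$pc1_regression_r_squared))
  invisible(x)
}

#' Read a signal CSV
#'
#' Expects columns `t_s`, `pao2_mmHg` (or `pao2_kpa`, converted at 7.50062
#' mmHg/kPa) and `paw_cmH2O` on a uniform time grid. The breath-hold window
#' and ventilation restart are reconstructed from the airway-pressure trace:
#' the hold is the longest gap between inspiration onsets, the restart the
#' first onset after it.
#'
#' @param path CSV path.
#' @param condition_id identifier attached to the trace.
#' @param units expected PaO2 unit (`"mmHg"` or `"kPa"`); used when both
#'   column spellings are absent.
#' @return a `pao2_trace`.
#' @export
read_signal_csv <- function(path, condition_id = NA_character_,
                            units = "mmHg") {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"t_s" %in% names(df)) stop("missing column t_s in ", path, call. = FALSE)
  pao2 <- if ("pao2_mmHg" %in% names(df)) {
    df$pao2_mmHg
  } else if ("pao2_kpa" %in% names(df)) {
    kpa_to_mmhg(df$pao2_kpa)
  } else stop("missing PaO2 column (pao2_mmHg or pao2_kpa) in ", path,
              call. = FALSE)
  if (!"paw_cmH2O" %in% names(df)) {
    stop("missing column paw_cmH2O in ", path, call. = FALSE)
  }
  dt <- diff(df$t_s)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6)) {
    bad <- which(abs(dt - dt[1]) > 1e-6)[1]
    stop(sprintf("non-uniform time grid in %s near line %d", path,
                 bad + 2L), call. = FALSE)
  }
  fs <- 1 / dt[1]

  # reconstruct hold window and restart from paw
  paw <- df$paw_cmH2O
  mid <- (max(paw) + min(paw)) / 2
  up <- which(diff(paw > mid) == 1) + 1L
  onsets <- df$t_s[up]
  onsets <- c(if (paw[1] > mid) df$t_s[1] else numeric(0), onsets)
  hold_window <- c(NA_real_, NA_real_)
  restart <- NA_real_
  if (length(onsets) >= 2) {
    gaps <- diff(onsets)
    period <- stats::median(gaps)
    g <- which.max(gaps)
    if (gaps[g] > 1.2 * period) {
      hold_window <- c(onsets[g] + period, onsets[g + 1])
      restart <- onsets[g + 1]
    }
  }
  structure(list(t = df$t_s, pao2 = pao2, paw = paw,
                 breath_hold_window = hold_window,
                 ventilation_restart_s = restart,
                 fs = fs, rr = 600 / (if (length(onsets) >= 2) stats::median(diff(onsets)) else 60),
                 condition_id = condition_id),
            class = "pao2_trace")
}

#' Write a signal CSV
#'
#' @param trace a `pao2_trace`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_signal_csv <- function(trace, path) {
  df <- data.frame(t_s = sprintf("%.10g", trace$t),
                   pao2_mmHg = sprintf("%.10g", trace$pao2),
                   paw_cmH2O = sprintf("%.10g", trace$paw))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all cohort signals and the manifest
#'
#' One CSV per condition (`<condition_id>.csv`, header
#' `t_s,pao2_mmHg,paw_cmH2O`), the manifest as `manifest.csv` and the ground
#' truth as `truth.json`.
#'
#' @param cohort a `pao2_cohort` with simulated traces.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pao2_cohort"), !is.null(cohort$traces))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort$traces) {
    write_signal_csv(tr, file.path(dir, paste0(tr$condition_id, ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write pipeline artifacts
#'
#' Serializes a [run_pipeline()] result to plain-text artifacts:
#' `inclusion_report.csv`, `fpca_model.json` (grid, mean curve, eigenfunction
#' matrix, eigenvalues), `scores.csv`, `aic_table.csv`, `assignments.csv`,
#' `cluster_means.csv`, `progression_regression.json`, `mixed_model.json` and
#' `summary.json`.
#'
#' @param run a `pao2_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  stopifnot(inherits(run, "pao2_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$inclusion, file.path(dir, "inclusion_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1", grid_dt = run$fpca$grid_dt, mu = run$fpca$mu,
         lambda = run$fpca$lambda, var_frac = run$fpca$var_frac,
         phi = apply(run$fpca$phi, 2, identity, simplify = FALSE)),
    file.path(dir, "fpca_model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(condition_id = rownames(run$fpca$scores),
                              run$fpca$scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(run$selection$table, file.path(dir, "aic_table.csv"),
                   row.names = FALSE)
  utils::write.csv(run$assignments, file.path(dir, "assignments.csv"),
                   row.names = FALSE)
  if (!is.null(run$clustering$cluster_means)) {
    utils::write.csv(as.data.frame(run$clustering$cluster_means),
                     file.path(dir, "cluster_means.csv"), row.names = FALSE)
  }
  jsonlite::write_json(lapply(run$regression, unclass),
                       file.path(dir, "progression_regression.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$mixed_model)) {
    jsonlite::write_json(unclass(run$mixed_model),
                         file.path(dir, "mixed_model.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$comparison)) {
    utils::write.csv(run$comparison, file.path(dir, "cluster_comparison.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Diagnostic plot of per-cluster mean breaths
#'
#' Base-graphics overlay of the cluster mean normalized breaths in progression
#' order, with the inspiration window shaded.
#'
#' @param clustering an `ordered_clustering` with `cluster_means`.
#' @param grid canonical grid.
#' @export
plot_cluster_means <- function(clustering, grid = breath_grid()) {
  cm <- clustering$cluster_means
  if (is.null(cm)) stop("clustering has no mean curves", call. = FALSE)
  t <- (seq_len(nrow(cm)) - 1) * grid$dt
  graphics::matplot(t, cm[, order(clustering$rank_of_cluster)], type = "l",
                    lty = 1, xlab = "breath time (s)",
                    ylab = "PaO2 (SD units)",
                    main = "Cluster mean breaths (progression order)")
  graphics::abline(v = grid$insp_end, lty = 2)
  invisible(NULL)
}
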