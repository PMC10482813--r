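#' Regression of principal component scores on the cluster progression
#'
#' Ordinary least squares of a component's scores on the progression rank
#' treated as a continuous variable, quantifying how strongly the ordered
#' morphology progression expresses itself in that component.
#'
#' @param scores numeric vector of per-condition scores for one component.
#' @param ranks per-condition progression rank (1..K).
#' @param component component index, carried into the result.
#' @return list of class `progression_regression`: `component`, `slope`,
#'   `intercept`, `r_squared`, `p_value`.
#' @export
progression_regression <- function(scores, ranks, component = 1L) {
  stopifnot(length(scores) == length(ranks))
  if (length(scores) < 3) stop("need at least 3 conditions", call. = FALSE)
  if (length(unique(ranks)) < 2) stop("ranks are constant", call. = FALSE)
  fit <- stats::lm(scores ~ ranks)
  sm <- suppressWarnings(summary(fit))
  structure(list(component = component,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4]),
            class = "progression_regression")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of a covariate across clusters.
#'
#' @param values numeric covariate, one per condition.
#' @param groups cluster labels.
#' @return list: `statistic` (F), `p_value`, `df` (between, within).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  keep <- is.finite(values)
  df <- c(nlevels(groups) - 1L, sum(keep) - nlevels(groups))
  if (stats::var(values[keep]) < 1e-24) {
    # no variation at all: zero between-group signal
    return(list(statistic = 0, p_value = 1, df = df))
  }
  a <- suppressWarnings(stats::anova(stats::lm(values[keep] ~ groups[keep])))
  list(statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1],
       df = c(a$Df[1], a$Df[2]))
}

#' Pearson chi-square test of independence
#'
#' Chi-square test (no continuity correction) on a clusters x categories
#' contingency table, df = (r-1)(c-1).
#'
#' @param table matrix of nonnegative counts, >= 2 rows and columns.
#' @return list: `statistic`, `p_value`, `df`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has a zero marginal", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' Covariates-by-cluster comparison table
#'
#' Tests the association between cluster membership and each covariate:
#' one-way ANOVA for numeric covariates, chi-square for logical/categorical
#' ones. Per-cluster means and SDs (or counts) are attached; clusters are
#' ordered by progression rank. No multiple-testing adjustment is applied
#' across covariates (`p_adjusted = "none"` in the metadata).
#'
#' @param data data frame, one row per condition.
#' @param cluster_col name of the cluster / progression-rank column.
#' @param covariates names of covariate columns to test.
#' @return data frame of class `cluster_comparison`: one row per covariate
#'   with `test`, `statistic`, `p_value`; per-cluster summaries in attribute
#'   `"by_cluster"`, metadata in attribute `"meta"`.
#' @export
cluster_comparison_table <- function(data, cluster_col = "progression_rank",
                                     covariates) {
  stopifnot(cluster_col %in% names(data), all(covariates %in% names(data)))
  cl <- factor(data[[cluster_col]], levels = sort(unique(data[[cluster_col]])))
  if (nlevels(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  rows <- list(); by_cluster <- list()
  for (v in covariates) {
    x <- data[[v]]
    if (is.numeric(x)) {
      r <- anova_oneway(x, cl)
      rows[[v]] <- data.frame(covariate = v, test = "anova",
                              statistic = r$statistic, p_value = r$p_value,
                              stringsAsFactors = FALSE)
      by_cluster[[v]] <- do.call(rbind, lapply(levels(cl), function(g) {
        data.frame(covariate = v, cluster = g,
                   mean = mean(x[cl == g], na.rm = TRUE),
                   sd = stats::sd(x[cl == g]), n = sum(cl == g),
                   stringsAsFactors = FALSE)
      }))
    } else {
      tab <- table(cl, factor(x))
      r <- chi_square_independence(tab)
      rows[[v]] <- data.frame(covariate = v, test = "chi_square",
                              statistic = r$statistic, p_value = r$p_value,
                              stringsAsFactors = FALSE)
      by_cluster[[v]] <- as.data.frame(tab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "by_cluster") <- by_cluster
  attr(out, "meta") <- list(p_adjusted = "none", cluster_col = cluster_col)
  class(out) <- c("cluster_comparison", "data.frame")
  out
}

#' Sensitivity analysis excluding one cluster
#'
#' Recomputes the covariates-by-cluster comparison after removing all
#' conditions of one cluster, to check whether an association is driven by a
#' single (e.g. single-animal-dominated) cluster.
#'
#' @inheritParams cluster_comparison_table
#' @param exclude cluster label to drop.
#' @return a `cluster_comparison` for the remaining clusters.
#' @export
sensitivity_excluding_cluster <- function(data, exclude,
                                          cluster_col = "progression_rank",
                                          covariates) {
  if (!exclude %in% data[[cluster_col]]) {
    stop(sprintf("cluster '%s' not present", exclude), call. = FALSE)
  }
  rest <- data[data[[cluster_col]] != exclude, , drop = FALSE]
  if (length(unique(rest[[cluster_col]])) < 2) {
    stop("fewer than 2 clusters remain after exclusion", call. = FALSE)
  }
  cluster_comparison_table(rest, cluster_col = cluster_col,
                           covariates = covariates)
}

#' Mixed-effects model of the cluster progression
#'
#' Linear mixed model with the (continuous) progression rank as outcome,
#' selected cardiorespiratory covariates as fixed effects and a random
#' intercept per animal, fitted by REML via [lme4::lmer()]. Degenerate random
#' effects (single animal, singular fit) are flagged, not raised.
#'
#' @param data data frame with the outcome, covariates and grouping column.
#' @param outcome outcome column name (continuous progression).
#' @param fixed character vector of fixed-effect covariate columns.
#' @param group grouping column (animal ID).
#' @return list of class `mixed_model_fit`: `fixed` (data frame `term`,
#'   `estimate`, `se`, `p_value`), `random_sd` (animal-intercept SD),
#'   `residual_sd`, `singular`, `reml_criterion`, `n_groups`.
#' @export
fit_mixed_progression <- function(data, outcome = "progression",
                                  fixed = c("pf_kpa", "ppv_pct"),
                                  group = "animal_id") {
  stopifnot(outcome %in% names(data), all(fixed %in% names(data)),
            group %in% names(data))
  n_groups <- length(unique(data[[group]]))
  if (n_groups < 2) {
    return(structure(list(fixed = NULL, random_sd = NA_real_,
                          residual_sd = stats::sd(data[[outcome]]),
                          singular = TRUE, reml_criterion = NA_real_,
                          n_groups = n_groups),
                     class = "mixed_model_fit"))
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "),
                                 "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  random_sd <- vc$sdcor[vc$grp == group][1]
  residual_sd <- vc$sdcor[vc$grp == "Residual"][1]
  cf <- summary(fit)$coefficients
  # Wald p-values from the t statistic against a normal reference
  fixed_df <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                         se = cf[, "Std. Error"],
                         p_value = 2 * stats::pnorm(-abs(cf[, "t value"])),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fixed = fixed_df[fixed_df$term != "(Intercept)", ],
                 random_sd = random_sd, residual_sd = residual_sd,
                 singular = lme4::isSingular(fit),
                 reml_criterion = unname(summary(fit)$AICtab[["REML"]]),
                 n_groups = n_groups),
            class = "mixed_model_fit")
}

#' AIC-guided fixed-effect subset selection
#'
#' Fits the mixed progression model by maximum likelihood for every subset of
#' the candidate fixed effects (including the intercept-only model) and ranks
#' the subsets by AIC.
#'
#' @inheritParams fit_mixed_progression
#' @param candidates candidate fixed-effect columns (at most 10).
#' @return data frame with `terms`, `aic`, ordered best first.
#' @export
select_fixed_effects <- function(data, outcome = "progression",
                                 candidates = c("pf_kpa", "ppv_pct"),
                                 group = "animal_id") {
  stopifnot(length(candidates) <= 10)
  subsets <- unlist(lapply(0:length(candidates), function(k) {
    utils::combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    rhs <- if (length(s)) paste(s, collapse = " + ") else "1"
    fml <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 |", group, ")"))
    fit <- lme4::lmer(fml, data = data, REML = FALSE)
    data.frame(terms = if (length(s)) paste(s, collapse = "+") else "(intercept)",
               aic = stats::AIC(fit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), ]
}

#' Mechanical power under pressure-control ventilation
#'
#' Simplified mechanical-power formula for pressure-control ventilation:
#' `MP = 0.098 * RR * VT * (dP_insp + PEEP)` in J/min, with VT in litres and
#' pressures in cmH2O.
#'
#' @param rr respiratory rate, breaths/min.
#' @param vt tidal volume, litres.
#' @param delta_p_insp inspiratory driving pressure, cmH2O.
#' @param peep positive end-expiratory pressure, cmH2O.
#' @return mechanical power, J/min (vectorized).
#' @examples
#' mechanical_power_pcv(10, 0.397, 18, 11) # 11.3 J/min
#' @export
mechanical_power_pcv <- function(rr, vt, delta_p_insp, peep) {
  if (any(c(rr, vt, delta_p_insp, peep) < 0)) {
    stop("all inputs must be nonnegative", call. = FALSE)
  }
  0.098 * rr * vt * (delta_p_insp + peep)
}
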