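#' Prevalence summary of PIM and PPO flags
#'
#' Tabulates, per outcome kind, the number and percentage of admissions
#' with at least one flag, the strata with exactly 1, 2, 3 and 4-or-more
#' flags, and the per-rule prevalence as a percentage of *all* admissions.
#' Percentages are count / `n_admissions` x 100, reported to one decimal.
#'
#' @param flags flag table (`admission_id`, `rule_id`, `kind`), as from
#'   [screen_cohort()].
#' @param n_admissions total number of screened admissions (the
#'   denominator; must be at least the number of flagged admissions).
#' @return An `ipp_prevalence` object: list with `overall` (tibble:
#'   `kind`, `stratum` in `ge1`/`1`/`2`/`3`/`4plus`, `n`, `pct`) and
#'   `per_rule` (tibble: `rule_id`, `kind`, `n`, `pct`, `rank` within
#'   kind by descending prevalence).
#' @export
prevalence_summary <- function(flags, n_admissions) {
  if (n_admissions == 0) stop("n_admissions is zero: percentages undefined")
  flags <- dplyr::distinct(tibble::as_tibble(flags),
                           .data$admission_id, .data$rule_id, .data$kind)
  for (kd in unique(flags$kind)) {
    if (dplyr::n_distinct(flags$admission_id[flags$kind == kd]) > n_admissions) {
      stop("more flagged admissions than n_admissions for kind ", kd)
    }
  }
  pct <- function(k) round(100 * k / n_admissions, 1)
  overall <- lapply(c("PIM", "PPO"), function(kd) {
    per_adm <- table(flags$admission_id[flags$kind == kd])
    strata <- c(
      ge1 = length(per_adm),
      `1` = sum(per_adm == 1), `2` = sum(per_adm == 2),
      `3` = sum(per_adm == 3), `4plus` = sum(per_adm >= 4)
    )
    tibble::tibble(kind = kd, stratum = names(strata),
                   n = as.integer(unname(strata)), pct = unname(pct(strata)))
  })
  per_rule <- flags |>
    dplyr::count(.data$rule_id, .data$kind, name = "n") |>
    dplyr::group_by(.data$kind) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$rule_id, .by_group = TRUE) |>
    dplyr::mutate(pct = pct(.data$n), rank = dplyr::row_number()) |>
    dplyr::ungroup()
  structure(list(overall = dplyr::bind_rows(overall), per_rule = per_rule,
                 n_admissions = n_admissions),
            class = "ipp_prevalence")
}

#' @export
print.ipp_prevalence <- function(x, ...) {
  cat(sprintf("<ipp_prevalence> %d admissions\n", x$n_admissions))
  ge1 <- x$overall[x$overall$stratum == "ge1", ]
  for (i in seq_len(nrow(ge1))) {
    cat(sprintf("  at least 1 %s: %.1f%% (%d)\n",
                ge1$kind[i], ge1$pct[i], ge1$n[i]))
  }
  invisible(x)
}

#' Confounder adjustment set for each association variable
#'
#' Returns the DAG-derived adjustment set used in the multivariate model
#' of each of the eight association variables (covariate names follow the
#' feature table produced by [compute_admission_features()]).
#'
#' @param variable one of `"gender"`, `"age_years"`, `"n_medications"`,
#'   `"n_diagnoses"`, `"charlson_weighted"`, `"los_days"`,
#'   `"n_departments"`, `"n_prescribing_specialties"`.
#' @return Character vector of covariates to adjust for.
#' @export
adjustment_set <- function(variable) {
  sets <- list(
    gender = "age_years",
    age_years = "gender",
    n_medications = c("age_years", "los_days", "n_diagnoses",
                      "charlson_weighted", "gender", "n_departments",
                      "n_prescribing_specialties"),
    n_diagnoses = c("age_years", "gender"),
    charlson_weighted = c("age_years", "gender"),
    los_days = c("age_years", "n_diagnoses", "charlson_weighted", "gender",
                 "n_departments"),
    n_departments = c("age_years", "n_diagnoses", "charlson_weighted",
                      "gender"),
    n_prescribing_specialties = c("age_years", "los_days", "n_diagnoses",
                                  "charlson_weighted", "gender",
                                  "n_departments")
  )
  if (!variable %in% names(sets)) {
    stop("unknown association variable: ", variable)
  }
  sets[[variable]]
}

#' Average predictive comparison for a model covariate
#'
#' For a continuous covariate: the mean predicted outcome probability over
#' all rows with the covariate overwritten to its observed 75th
#' percentile, minus the same mean at the 25th percentile (linear
#' interpolation quantiles); other covariates keep their observed values.
#' For `gender`: mean prediction with every row set to female minus every
#' row set to male.
#'
#' @param fit a converged [fit_gee_logistic()] fit.
#' @param variable covariate name (must be in the model).
#' @param data the analysis data set used to compute percentiles and to
#'   average predictions over (normally the data the model was fitted on).
#' @return An `ipp_apc` list: `variable`, `apc_value`, and the percentile
#'   pair (`p25`, `p75`) or binary levels used.
#' @export
compute_apc <- function(fit, variable, data) {
  stopifnot(inherits(fit, "ipp_gee"))
  if (!fit$converged) stop("fit did not converge")
  if (!variable %in% all.vars(delete.response(fit$terms))) {
    stop("variable not in model: ", variable)
  }
  if (variable == "gender") {
    d1 <- d0 <- data
    d1$gender <- "female"
    d0$gender <- "male"
    apc <- mean(predict(fit, d1)) - mean(predict(fit, d0))
    out <- list(variable = variable, apc_value = apc,
                levels = c("female", "male"))
  } else {
    qs <- quantile(data[[variable]], c(0.25, 0.75), type = 7, names = FALSE)
    if (diff(qs) == 0) {
      warning("zero interquartile range for ", variable, "; APC is 0")
      return(structure(list(variable = variable, apc_value = 0,
                            p25 = qs[1], p75 = qs[2]), class = "ipp_apc"))
    }
    dhi <- dlo <- data
    dhi[[variable]] <- qs[2]
    dlo[[variable]] <- qs[1]
    apc <- mean(predict(fit, dhi)) - mean(predict(fit, dlo))
    out <- list(variable = variable, apc_value = apc, p25 = qs[1], p75 = qs[2])
  }
  structure(out, class = "ipp_apc")
}

#' @export
print.ipp_apc <- function(x, ...) {
  cat(sprintf("APC(%s) = %.3f\n", x$variable, x$apc_value))
  invisible(x)
}

outcome_vector <- function(flags, features, kind = NULL, rule_subset = NULL) {
  f <- tibble::as_tibble(flags)
  if (!is.null(rule_subset)) f <- f[f$rule_id %in% rule_subset, , drop = FALSE]
  if (!is.null(kind)) f <- f[f$kind == kind, , drop = FALSE]
  as.integer(features$admission_id %in% f$admission_id)
}

prep_model_data <- function(features, scale_map = covariate_scale_map()) {
  d <- apply_covariate_scaling(tibble::as_tibble(features), scale_map)
  d$gender <- factor(d$gender, levels = c("male", "female"))
  d
}

the_eight <- function() {
  c("gender", "age_years", "n_medications", "n_diagnoses",
    "charlson_weighted", "los_days", "n_departments",
    "n_prescribing_specialties")
}

#' Crude and adjusted associations of the eight variables with PIMs/PPOs
#'
#' For one outcome kind, fits per variable a univariate (crude) and a
#' multivariate (adjusted by its [adjustment_set()]) clustered logistic
#' model, and computes the average predictive comparison from the adjusted
#' fit. Age enters per 5 years and length of stay per 5 days
#' ([covariate_scale_map()]); gender is female vs male.
#'
#' @param flags flag table from [screen_cohort()].
#' @param features feature table from [compute_admission_features()].
#' @param kind `"PIM"` or `"PPO"`.
#' @param working_corr passed to [fit_gee_logistic()].
#' @return Tibble with one row per variable: crude and adjusted OR with
#'   95% CI and p-value, and the adjusted APC.
#' @export
association_analysis <- function(flags, features, kind = c("PIM", "PPO"),
                                 working_corr = "exchangeable") {
  kind <- match.arg(kind)
  d <- prep_model_data(features)
  d$.y <- outcome_vector(flags, features, kind = kind)
  rows <- lapply(the_eight(), function(v) {
    term <- if (v == "gender") "genderfemale" else v
    crude <- fit_gee_logistic(as.formula(paste(".y ~", v)), d,
                              id = "cluster_id", working_corr = working_corr)
    adj_form <- as.formula(paste(".y ~", paste(c(v, adjustment_set(v)),
                                               collapse = " + ")))
    adj <- fit_gee_logistic(adj_form, d, id = "cluster_id",
                            working_corr = working_corr)
    apc <- compute_apc(adj, v, d)
    tibble::tibble(
      variable = v, kind = kind,
      crude_or = crude$or[[term]],
      crude_ci_lower = crude$ci_lower[[term]],
      crude_ci_upper = crude$ci_upper[[term]],
      crude_p = crude$p_value[[term]],
      adjusted_or = adj$or[[term]],
      adjusted_ci_lower = adj$ci_lower[[term]],
      adjusted_ci_upper = adj$ci_upper[[term]],
      adjusted_p = adj$p_value[[term]],
      adjusted_apc = apc$apc_value
    )
  })
  dplyr::bind_rows(rows)
}

#' Time trends in PIM/PPO prevalence
#'
#' Clustered logistic models of the per-admission flag indicator on
#' continuous admission time (years since the window start), giving a
#' per-year odds ratio; optionally adjusted for the eight association
#' covariates. With `rule_subset`, one model is fitted per listed rule
#' (flag = that rule triggered); otherwise one model per outcome kind
#' (flag = at least one PIM / at least one PPO).
#'
#' @param flags flag table from [screen_cohort()].
#' @param features feature table from [compute_admission_features()].
#' @param adjusted add the eight covariates to the model.
#' @param rule_subset optional character vector of rule ids.
#' @param working_corr passed to [fit_gee_logistic()].
#' @return List with `fits` (named list of `ipp_gee`) and `trends`
#'   (tibble: `outcome`, `adjusted`, `per_year_or`, `ci_lower`,
#'   `ci_upper`, `p_value`).
#' @export
trend_analysis <- function(flags, features, adjusted = FALSE,
                           rule_subset = NULL, working_corr = "exchangeable") {
  if (diff(range(features$time_years)) <= 0) {
    stop("time_years has zero span; no trend estimable")
  }
  d <- prep_model_data(features)
  targets <- if (is.null(rule_subset)) {
    list(PIM = list(kind = "PIM", rules = NULL),
         PPO = list(kind = "PPO", rules = NULL))
  } else {
    setNames(lapply(rule_subset, function(r) list(kind = NULL, rules = r)),
             rule_subset)
  }
  rhs <- if (adjusted) paste(c("time_years", the_eight()), collapse = " + ")
         else "time_years"
  fits <- lapply(targets, function(tg) {
    d$.y <- outcome_vector(flags, features, kind = tg$kind,
                           rule_subset = tg$rules)
    fit_gee_logistic(as.formula(paste(".y ~", rhs)), d, id = "cluster_id",
                     working_corr = working_corr)
  })
  trends <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(
      outcome = nm, adjusted = adjusted,
      per_year_or = f$or[["time_years"]],
      ci_lower = f$ci_lower[["time_years"]],
      ci_upper = f$ci_upper[["time_years"]],
      p_value = f$p_value[["time_years"]]
    )
  }))
  list(fits = fits, trends = trends)
}

#' Per-admission predicted probability over calendar time
#'
#' Evaluates a fitted trend model on every admission and orders the
#' predictions by admission time, adding a locally smoothed summary curve
#' for plotting.
#'
#' @param fit a converged `ipp_gee` fit containing `time_years`.
#' @param features the feature table to predict on (scaled the same way
#'   the model was fitted; use the data returned alongside the fit).
#' @return Tibble ordered by `time_years` with columns `admission_id`,
#'   `time_years`, `predicted`, `smoothed` (lowess, f = 0.3).
#' @export
predicted_probability_curve <- function(fit, features) {
  pr <- predict(fit, features, type = "response")
  out <- tibble::tibble(
    admission_id = features$admission_id,
    time_years = features$time_years,
    predicted = pr
  )
  out <- out[order(out$time_years), ]
  if (diff(range(out$time_years)) > 0 && stats::var(out$predicted) > 0) {
    sm <- lowess(out$time_years, out$predicted, f = 0.3)
    out$smoothed <- sm$y
  } else {
    out$smoothed <- out$predicted
  }
  out
}
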