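#' Cohort characteristics table
#'
#' Summarises an included cohort in the layout of a standard
#' characteristics table: gender split, age mean (SD), stay length,
#' in-hospital death, medication burden, top-10 ATC level-2 classes,
#' diagnosis and Charlson summaries, comorbidity/risk-factor rates, and
#' department/specialty counts.
#'
#' @param x an included [cohort()].
#' @param features matching feature table (computed if omitted).
#' @return Tibble with columns `characteristic`, `value`, `n`.
#' @export
cohort_characteristics <- function(x, features = NULL) {
  stopifnot(inherits(x, "ipp_cohort"))
  if (is.null(features)) features <- compute_admission_features(x)
  n <- nrow(x$admissions)
  med_iqr <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  pct_n <- function(k) sprintf("%.1f (%d)", 100 * k / n, k)
  rows <- list(
    c("admissions", as.character(n), n),
    c("unique_patients", as.character(dplyr::n_distinct(x$admissions$patient_id)),
      dplyr::n_distinct(x$admissions$patient_id)),
    c("female_pct", pct_n(sum(features$gender == "female")),
      sum(features$gender == "female")),
    c("age_mean_sd", sprintf("%.1f (%.2f)", mean(features$age_years),
                             sd(features$age_years)), n),
    c("los_days_median_iqr", med_iqr(features$los_days), n),
    c("died_pct", pct_n(sum(x$admissions$death_flag)), sum(x$admissions$death_flag)),
    c("n_medications_median_iqr", med_iqr(features$n_medications), n),
    c("n_diagnoses_median_iqr", med_iqr(features$n_diagnoses), n),
    c("charlson_median_iqr", med_iqr(features$charlson_weighted), n),
    c("n_departments_median_iqr", med_iqr(features$n_departments), n),
    c("n_specialties_median_iqr", med_iqr(features$n_prescribing_specialties), n)
  )
  out <- tibble::tibble(
    characteristic = vapply(rows, `[[`, character(1), 1),
    value = vapply(rows, `[[`, character(1), 2),
    n = as.integer(vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)))
  )
  # top-10 administered ATC level-2 classes
  cls <- unique(tibble::tibble(admission_id = x$medications$admission_id,
                               class = substr(x$medications$atc_code, 1, 3)))
  cls_n <- sort(table(cls$class), decreasing = TRUE)
  top <- head(cls_n, 10)
  atc_rows <- tibble::tibble(
    characteristic = paste0("atc_", names(top), "_pct"),
    value = vapply(as.integer(top), pct_n, character(1)),
    n = as.integer(top)
  )
  # comorbidity / risk-factor prevalences
  rs <- x$risk_scores
  fall_n <- dplyr::n_distinct(rs$admission_id[rs$kind == "fall_risk" & rs$value == 1])
  deli_n <- dplyr::n_distinct(rs$admission_id[rs$kind == "doss_delirium" & rs$value >= 3])
  lab <- x$labs[x$labs$analyte == "egfr", ]
  low_kid <- tapply(lab$value, lab$admission_id, min)
  kid_n <- sum(low_kid < 50)
  dx_n <- sort(table(unique(x$diagnoses)$concept), decreasing = TRUE)
  cond_rows <- tibble::tibble(
    characteristic = paste0("cond_", names(dx_n), "_pct"),
    value = vapply(as.integer(dx_n), pct_n, character(1)),
    n = as.integer(dx_n)
  )
  risk_rows <- tibble::tibble(
    characteristic = c("fall_risk_pct", "delirium_risk_pct", "low_egfr_pct"),
    value = c(pct_n(fall_n), pct_n(deli_n), pct_n(kid_n)),
    n = as.integer(c(fall_n, deli_n, kid_n))
  )
  dplyr::bind_rows(out, atc_rows, risk_rows, cond_rows)
}

prevalence_to_tables <- function(prev) {
  list(overall = prev$overall, per_rule = prev$per_rule)
}

#' Run the full simulate/screen/analyze/report pipeline
#'
#' Orchestrates the end-to-end analysis: obtain a cohort (either loaded
#' from CSV tables or generated synthetically), apply inclusion criteria,
#' derive features, screen with a rule catalog, tabulate prevalences, fit
#' crude/adjusted association models with APCs, fit unadjusted and
#' adjusted time-trend models, and write all artifacts to `out_dir`:
#' `features.csv`, `flags.csv`, `table1.csv` (cohort characteristics),
#' `table2_overall.csv` / `table2_per_rule.csv` (prevalence),
#' `table3.csv` (associations), `trends.csv`, `figure1.png` (predicted
#' probability over time) and `manifest.json` (seed, catalog version,
#' package version). Any stage failure aborts with the stage name; partial
#' outputs are removed.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{input_dir}{directory of cohort CSVs (exclusive with
#'       `sim_params`).}
#'     \item{sim_params}{an `ipp_gen_params` for synthetic generation
#'       (exclusive with `input_dir`).}
#'     \item{rules}{rule catalog path (default: shipped catalog).}
#'     \item{seed}{integer seed (default 42).}
#'     \item{out_dir}{output directory.}
#'     \item{associations, trends, figure}{logical toggles (default TRUE).}
#'   }
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `features`, `flags`, `prevalence`, `associations`, `trends`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(
    list(input_dir = NULL, sim_params = NULL, rules = default_catalog_path(),
         seed = 42L, out_dir = "ipp_output", associations = TRUE,
         trends = TRUE, figure = TRUE),
    config
  )
  if (is.null(cfg$input_dir) == is.null(cfg$sim_params)) {
    stop("config must supply exactly one of input_dir or sim_params")
  }
  if (!file.exists(cfg$rules)) stop("rule catalog file not found: ", cfg$rules)
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(obj, file) {
    p <- file.path(out_dir, file)
    readr::write_csv(obj, p, progress = FALSE)
    written <<- c(written, p)
    p
  }

  catalog <- stage("rules", parse_rule_catalog(cfg$rules))
  co <- stage("cohort", {
    if (!is.null(cfg$input_dir)) {
      apply_inclusion(load_cohort(cfg$input_dir))
    } else {
      generate_cohort(cfg$sim_params, seed = cfg$seed)$cohort
    }
  })
  features <- stage("features", compute_admission_features(co))
  flags <- stage("screen", screen_cohort(catalog, co))
  prev <- stage("prevalence", prevalence_summary(flags, nrow(features)))

  emit(features, "features.csv")
  emit(flags, "flags.csv")
  emit(cohort_characteristics(co, features), "table1.csv")
  emit(prev$overall, "table2_overall.csv")
  emit(prev$per_rule, "table2_per_rule.csv")

  assoc <- NULL
  if (isTRUE(cfg$associations)) {
    assoc <- stage("associations", dplyr::bind_rows(
      association_analysis(flags, features, "PIM"),
      association_analysis(flags, features, "PPO")
    ))
    emit(assoc, "table3.csv")
  }
  trends <- NULL
  if (isTRUE(cfg$trends)) {
    trends <- stage("trends", {
      unadj <- trend_analysis(flags, features, adjusted = FALSE)
      adj <- trend_analysis(flags, features, adjusted = TRUE)
      top5 <- prev$per_rule |>
        dplyr::filter(.data$rank <= 5) |>
        dplyr::pull(.data$rule_id)
      rules_tr <- trend_analysis(flags, features, adjusted = FALSE,
                                 rule_subset = top5)
      list(table = dplyr::bind_rows(unadj$trends, adj$trends, rules_tr$trends),
           unadjusted_fits = unadj$fits)
    })
    emit(trends$table, "trends.csv")
    if (isTRUE(cfg$figure)) {
      stage("figure", {
        d <- prep_model_data(features)
        curves <- dplyr::bind_rows(lapply(c("PIM", "PPO"), function(kd) {
          cv <- predicted_probability_curve(trends$unadjusted_fits[[kd]], d)
          cv$outcome <- kd
          cv
        }))
        gp <- ggplot2::ggplot(curves,
                              ggplot2::aes(x = .data$time_years,
                                           y = .data$predicted,
                                           colour = .data$outcome)) +
          ggplot2::geom_point(alpha = 0.05, size = 0.3) +
          ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 1) +
          ggplot2::labs(x = "Years since window start",
                        y = "Predicted probability of >= 1 flag",
                        colour = NULL) +
          ggplot2::theme_minimal()
        p <- file.path(out_dir, "figure1.png")
        ggplot2::ggsave(p, gp, width = 7, height = 4.5, dpi = 150)
        written <<- c(written, p)
      })
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ippscreen")),
    seed = cfg$seed,
    catalog_version = catalog$version,
    catalog_path = cfg$rules,
    n_admissions = nrow(features),
    generated = !is.null(cfg$sim_params),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = co, features = features, flags = flags,
                 prevalence = prev, associations = assoc, trends = trends,
                 manifest = manifest))
}
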