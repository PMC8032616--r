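#' Admission-level EHR cohort container
#'
#' A cohort bundles the five admission-level event tables used throughout
#' the package: admissions (demographics, timing, department trajectory,
#' in-hospital death), medication administrations (ATC level-5 code,
#' timestamp, prescriber specialty), coded diagnoses (condition concepts
#' from the shipped vocabulary), laboratory results (eGFR in ml/min, LDL in
#' mmol/l) and risk scores (fall-risk flag, DOSS delirium score). All
#' foreign keys must resolve to `admissions$admission_id`.
#'
#' Timestamps are `POSIXct` (UTC). The `departments` column of `admissions`
#' is a semicolon-separated sequence of department identifiers in entry
#' order.
#'
#' @param admissions tibble with columns `admission_id`, `patient_id`,
#'   `gender` (`"female"`/`"male"`), `age_at_admission` (years),
#'   `admit_time`, `discharge_time`, `departments`, `death_flag`.
#' @param medications tibble with columns `admission_id`, `atc_code`
#'   (7-character ATC level-5), `admin_time`, `prescriber_specialty`.
#' @param diagnoses tibble with columns `admission_id`, `concept`.
#' @param labs tibble with columns `admission_id`, `analyte`, `value`,
#'   `method`, `time`.
#' @param risk_scores tibble with columns `admission_id`, `kind`
#'   (`"fall_risk"` or `"doss_delirium"`), `value`, `time`.
#' @param validate validate invariants on construction (default `TRUE`).
#'
#' @return An object of class `ipp_cohort`: a list of the five tables plus
#'   a `validation` attribute describing row-level rejections.
#' @export
cohort <- function(admissions, medications, diagnoses, labs, risk_scores,
                   validate = TRUE) {
  x <- structure(
    list(
      admissions = tibble::as_tibble(admissions),
      medications = tibble::as_tibble(medications),
      diagnoses = tibble::as_tibble(diagnoses),
      labs = tibble::as_tibble(labs),
      risk_scores = tibble::as_tibble(risk_scores)
    ),
    class = "ipp_cohort",
    validation = list(rejected = tibble::tibble(
      table = character(), row = integer(), reason = character()
    ))
  )
  if (validate) x <- validate_cohort(x) else x
  x
}

#' @export
print.ipp_cohort <- function(x, ...) {
  cat("<ipp_cohort>\n")
  cat(sprintf("  admissions:  %d (patients: %d)\n",
              nrow(x$admissions), dplyr::n_distinct(x$admissions$patient_id)))
  cat(sprintf("  medications: %d rows, diagnoses: %d, labs: %d, risk scores: %d\n",
              nrow(x$medications), nrow(x$diagnoses), nrow(x$labs),
              nrow(x$risk_scores)))
  rej <- attr(x, "validation")$rejected
  if (nrow(rej) > 0) cat(sprintf("  rejected rows: %d (see validation_report())\n", nrow(rej)))
  invisible(x)
}

# ATC level-5: letter, 2 digits, 2 letters, 2 digits (e.g. N05BA01)
ATC5_PATTERN <- "^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$"

#' Validate a cohort's structural invariants
#'
#' Enforces unique admission ids, resolvable foreign keys (fatal),
#' chronology (`discharge_time > admit_time`, fatal) and row-level rules:
#' medication rows with a malformed ATC level-5 code or an administration
#' time outside the admission interval are rejected and recorded, as are
#' labs with negative values and fall-risk scores outside `{0, 1}`.
#'
#' @param x an [cohort()] object.
#' @return The cohort with offending rows removed; rejections are recorded
#'   in the `validation` attribute (see [validation_report()]).
#' @export
validate_cohort <- function(x) {
  adm <- x$admissions
  if (anyDuplicated(adm$admission_id)) {
    stop("duplicate admission_id in admissions table: ",
         paste(unique(adm$admission_id[duplicated(adm$admission_id)]), collapse = ", "))
  }
  if (any(adm$discharge_time <= adm$admit_time)) {
    bad <- adm$admission_id[adm$discharge_time <= adm$admit_time]
    stop("discharge_time not after admit_time for admission(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  for (tab in c("medications", "diagnoses", "labs", "risk_scores")) {
    unresolved <- setdiff(x[[tab]]$admission_id, adm$admission_id)
    if (length(unresolved) > 0) {
      stop("unresolvable admission_id in ", tab, ": ",
           paste(head(unresolved, 5), collapse = ", "))
    }
  }

  rejected <- list()
  med <- x$medications
  if (nrow(med) > 0) {
    bad_atc <- !grepl(ATC5_PATTERN, med$atc_code)
    idx <- match(med$admission_id, adm$admission_id)
    out_of_stay <- med$admin_time < adm$admit_time[idx] |
      med$admin_time >= adm$discharge_time[idx]
    out_of_stay[is.na(out_of_stay)] <- TRUE
    drop <- bad_atc | out_of_stay
    if (any(drop)) {
      rejected$medications <- tibble::tibble(
        table = "medications",
        row = which(drop),
        reason = ifelse(bad_atc[drop], "malformed ATC level-5 code",
                        "administration time outside admission interval")
      )
      x$medications <- med[!drop, , drop = FALSE]
    }
  }
  lab <- x$labs
  if (nrow(lab) > 0) {
    drop <- !is.finite(lab$value) | lab$value < 0
    if (any(drop)) {
      rejected$labs <- tibble::tibble(
        table = "labs", row = which(drop), reason = "negative or missing lab value"
      )
      x$labs <- lab[!drop, , drop = FALSE]
    }
  }
  rs <- x$risk_scores
  if (nrow(rs) > 0) {
    drop <- rs$kind == "fall_risk" & !(rs$value %in% c(0, 1))
    if (any(drop)) {
      rejected$risk_scores <- tibble::tibble(
        table = "risk_scores", row = which(drop), reason = "fall_risk value not in {0,1}"
      )
      x$risk_scores <- rs[!drop, , drop = FALSE]
    }
  }
  prev <- attr(x, "validation")$rejected
  attr(x, "validation") <- list(
    rejected = dplyr::bind_rows(prev, dplyr::bind_rows(rejected))
  )
  x
}

#' Row-level validation report for a cohort
#'
#' @param x an [cohort()] object.
#' @return A tibble with one row per rejected input row: `table`, `row`
#'   (position in the original table) and `reason`.
#' @export
validation_report <- function(x) {
  stopifnot(inherits(x, "ipp_cohort"))
  attr(x, "validation")$rejected
}

cohort_schemas <- function() {
  list(
    admissions = readr::cols(
      admission_id = readr::col_character(),
      patient_id = readr::col_character(),
      gender = readr::col_character(),
      age_at_admission = readr::col_double(),
      admit_time = readr::col_datetime(format = ""),
      discharge_time = readr::col_datetime(format = ""),
      departments = readr::col_character(),
      death_flag = readr::col_logical()
    ),
    medications = readr::cols(
      admission_id = readr::col_character(),
      atc_code = readr::col_character(),
      admin_time = readr::col_datetime(format = ""),
      prescriber_specialty = readr::col_character()
    ),
    diagnoses = readr::cols(
      admission_id = readr::col_character(),
      concept = readr::col_character()
    ),
    labs = readr::cols(
      admission_id = readr::col_character(),
      analyte = readr::col_character(),
      value = readr::col_double(),
      method = readr::col_character(),
      time = readr::col_datetime(format = "")
    ),
    risk_scores = readr::cols(
      admission_id = readr::col_character(),
      kind = readr::col_character(),
      value = readr::col_double(),
      time = readr::col_datetime(format = "")
    )
  )
}

#' Load a cohort from CSV event tables
#'
#' Reads the five documented CSV tables (UTF-8, comma-separated, ISO-8601
#' timestamps in UTC) and returns a validated cohort. Rows failing row-level
#' rules (malformed ATC codes, administrations outside the stay, negative
#' lab values) are rejected and recorded in the validation report; missing
#' files and unresolvable foreign keys are fatal.
#'
#' @param paths named list or character vector with elements `admissions`,
#'   `medications`, `diagnoses`, `labs`, `risk_scores` giving file paths.
#'   A single directory path may be given instead, in which case the files
#'   `admissions.csv`, ..., `risk_scores.csv` are expected inside it.
#' @return A validated [cohort()].
#' @seealso [write_cohort()], [validation_report()]
#' @export
load_cohort <- function(paths) {
  tables <- c("admissions", "medications", "diagnoses", "labs", "risk_scores")
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(tables, ".csv")), tables)
  }
  paths <- as.list(paths)
  missing <- setdiff(tables, names(paths))
  if (length(missing) > 0) stop("missing table path(s): ", paste(missing, collapse = ", "))
  schemas <- cohort_schemas()
  read1 <- function(tab) {
    p <- paths[[tab]]
    if (!file.exists(p)) stop("missing file for table '", tab, "': ", p)
    x <- readr::read_csv(p, col_types = schemas[[tab]], progress = FALSE)
    expected <- names(schemas[[tab]]$cols)
    if (!all(expected %in% names(x))) {
      stop("table '", tab, "' is missing column(s): ",
           paste(setdiff(expected, names(x)), collapse = ", "))
    }
    x[expected]
  }
  tabs <- lapply(setNames(tables, tables), read1)
  cohort(tabs$admissions, tabs$medications, tabs$diagnoses, tabs$labs,
         tabs$risk_scores)
}

#' Write a cohort to CSV event tables
#'
#' Inverse of [load_cohort()]: writes the five tables with the documented
#' headers and ISO-8601 UTC timestamps, so that reloading reproduces the
#' cohort field-for-field.
#'
#' @param x an [cohort()] object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ipp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- character()
  for (tab in names(x)) {
    d <- x[[tab]]
    for (cn in names(d)) {
      if (inherits(d[[cn]], "POSIXct")) d[[cn]] <- fmt_time(d[[cn]])
    }
    p <- file.path(dir, paste0(tab, ".csv"))
    readr::write_csv(d, p, progress = FALSE)
    paths[tab] <- p
  }
  invisible(paths)
}

#' Apply the study inclusion criteria to a cohort
#'
#' Retains admissions that (i) lasted at least 24 hours, (ii) belong to a
#' patient aged at least 70 years at admission, and (iii) fall entirely
#' inside the reference window: admission date on/after the window start
#' and discharge date strictly before the window end. Event rows of
#' excluded admissions are dropped as well. Filtering is idempotent.
#'
#' @param x an [cohort()] object.
#' @param window length-2 `POSIXct` (or coercible) vector
#'   `c(start, end)`; defaults to the 4-year study window
#'   2015-11-01 to 2019-11-01.
#' @return The filtered cohort, with an `inclusion` attribute listing
#'   exclusion counts by reason and the window used.
#' @export
apply_inclusion <- function(x, window = default_window()) {
  stopifnot(inherits(x, "ipp_cohort"))
  window <- as.POSIXct(window, tz = "UTC")
  adm <- x$admissions
  dur_ok <- as.numeric(difftime(adm$discharge_time, adm$admit_time, units = "hours")) >= 24
  age_ok <- adm$age_at_admission >= 70
  win_ok <- adm$admit_time >= window[1] & adm$discharge_time < window[2]
  keep <- dur_ok & age_ok & win_ok
  excl <- c(
    duration_lt_24h = sum(!dur_ok),
    age_lt_70 = sum(dur_ok & !age_ok),
    outside_window = sum(dur_ok & age_ok & !win_ok)
  )
  if (!any(keep)) warning("no admissions satisfy the inclusion criteria")
  ids <- adm$admission_id[keep]
  x$admissions <- adm[keep, , drop = FALSE]
  for (tab in c("medications", "diagnoses", "labs", "risk_scores")) {
    x[[tab]] <- x[[tab]][x[[tab]]$admission_id %in% ids, , drop = FALSE]
  }
  attr(x, "inclusion") <- list(window = window, excluded = excl,
                               n_included = sum(keep))
  x
}

#' Default 4-year study reference window
#'
#' Admission dates from 1 November 2015 (inclusive) to discharge dates
#' before 1 November 2019.
#'
#' @return Length-2 `POSIXct` vector (UTC).
#' @export
default_window <- function() {
  as.POSIXct(c("2015-11-01 00:00:00", "2019-11-01 00:00:00"), tz = "UTC")
}
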