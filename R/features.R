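#' Match an ATC code against a hierarchy prefix
#'
#' The WHO ATC classification is hierarchical by string prefix: a level-5
#' chemical-substance code such as `N05BA01` belongs to class `N05BA`
#' (benzodiazepines), `N05B`, `N05` (psycholeptics), and `N`. Matching is
#' case-insensitive.
#'
#' @param code character vector of ATC codes (any level).
#' @param pattern a single ATC prefix, 1-7 characters.
#' @return Logical vector: does `code` start with `pattern`?
#' @examples
#' atc_match("N05BA01", "N05BA") # TRUE
#' atc_match("N05BA01", "N05C")  # FALSE
#' @export
atc_match <- function(code, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1,
            nchar(pattern) >= 1, nchar(pattern) <= 7)
  startsWith(toupper(code), toupper(pattern))
}

#' Drug exposure window for an ATC prefix
#'
#' Medication administrations are point events; criteria reason about
#' ongoing use. The exposure window for a drug class is the interval from
#' the first to the last administration matching the ATC prefix, extended
#' by a persistence allowance (`grace`) after the last administration.
#'
#' @param times `POSIXct` administration times of one admission.
#' @param codes ATC level-5 codes aligned with `times`.
#' @param pattern ATC prefix (1-7 characters).
#' @param grace_hours persistence allowance after the last administration,
#'   in hours (default 24).
#' @return `NULL` if no administration matches, otherwise a length-2
#'   `POSIXct` vector `c(first, last + grace)`.
#' @export
exposure_window <- function(times, codes, pattern, grace_hours = 24) {
  hit <- atc_match(codes, pattern)
  if (!any(hit)) return(NULL)
  t <- times[hit]
  c(min(t), max(t) + grace_hours * 3600)
}

#' Shipped condition-concept vocabulary
#'
#' The internal controlled vocabulary of condition concepts used by
#' diagnoses and rule predicates. Real ICD-10 extracts can be mapped onto
#' it with [icd10_to_concept()]. The pseudo-concepts `fall_risk` and
#' `delirium_risk` are resolved against the risk-score table rather than
#' the diagnosis table (fall-risk flag = 1; DOSS >= 3).
#'
#' @return Tibble with columns `concept`, `charlson` (logical: enters the
#'   weighted Charlson score) and `description`.
#' @export
concept_vocabulary <- function() {
  p <- system.file("extdata", "concept_vocabulary.csv", package = "ippscreen")
  readr::read_csv(p, col_types = "clc", progress = FALSE)
}

#' Shipped Charlson weight table
#'
#' Original Charlson weights (1, 2, 3 or 6 per condition), restricted to
#' the concepts present in the shipped vocabulary. Override by passing a
#' different weight table to [compute_charlson()].
#'
#' @return Tibble with columns `concept`, `weight`.
#' @export
charlson_weights <- function() {
  p <- system.file("extdata", "charlson_weights.csv", package = "ippscreen")
  readr::read_csv(p, col_types = "ci", progress = FALSE)
}

#' Map ICD-10 codes to condition concepts
#'
#' Longest-prefix lookup against the shipped `icd10_to_concept` table, so
#' registry extracts coded in ICD-10 can be converted to the internal
#' concept vocabulary.
#'
#' @param icd10 character vector of ICD-10 codes (e.g. `"I50.1"`).
#' @return Character vector of concepts (`NA` where no prefix matches).
#' @export
icd10_to_concept <- function(icd10) {
  p <- system.file("extdata", "icd10_to_concept.csv", package = "ippscreen")
  map <- readr::read_csv(p, col_types = "cc", progress = FALSE)
  map <- map[order(-nchar(map$icd10_prefix)), ]
  code <- toupper(gsub("\\.", "", icd10))
  out <- rep(NA_character_, length(code))
  for (i in seq_len(nrow(map))) {
    hit <- is.na(out) & startsWith(code, map$icd10_prefix[i])
    out[hit] <- map$concept[i]
  }
  out
}

#' Weighted Charlson comorbidity score
#'
#' Sums condition weights over the distinct Charlson conditions present.
#' Concepts absent from the weight table contribute 0 (reported once via
#' a message).
#'
#' @param concepts character vector of condition concepts (one admission).
#' @param weights weight table as from [charlson_weights()].
#' @return Integer score.
#' @examples
#' compute_charlson(c("heart_failure", "diabetes", "heart_failure"))
#' @export
compute_charlson <- function(concepts, weights = charlson_weights()) {
  concepts <- unique(concepts)
  if (length(concepts) == 0) return(0L)
  w <- weights$weight[match(concepts, weights$concept)]
  unknown <- concepts[is.na(w)]
  w[is.na(w)] <- 0L
  if (length(unknown) > 0) {
    message("concepts without Charlson weight treated as 0: ",
            paste(unique(unknown), collapse = ", "))
  }
  as.integer(sum(w))
}

#' Derive the per-admission covariate table
#'
#' Computes one row per admission with the eight analysis covariates plus
#' the admission-year time index and the clustering id:
#' \describe{
#'   \item{age_years}{age at admission (years, >= 70 after inclusion).}
#'   \item{gender}{`"female"` / `"male"`.}
#'   \item{n_medications}{distinct ATC level-5 codes administered during
#'     the stay (duplicate administrations of a code count once).}
#'   \item{n_diagnoses}{distinct condition concepts.}
#'   \item{charlson_weighted}{weighted Charlson score over the admission's
#'     distinct Charlson conditions.}
#'   \item{los_days}{length of stay in days.}
#'   \item{n_departments}{distinct departments in the stay trajectory.}
#'   \item{n_prescribing_specialties}{distinct prescriber specialties over
#'     the admission's medication rows (0 when no medication).}
#'   \item{time_years}{continuous years since `window_start`
#'     (days / 365.25).}
#'   \item{cluster_id}{the patient id (unit of clustering).}
#' }
#'
#' @param x an included [cohort()].
#' @param window_start origin for `time_years`; defaults to the start of
#'   the inclusion window recorded by [apply_inclusion()], else the
#'   earliest admission.
#' @param weights Charlson weight table.
#' @return Tibble with one row per admission (`admission_id` first).
#' @export
compute_admission_features <- function(x, window_start = NULL,
                                       weights = charlson_weights()) {
  stopifnot(inherits(x, "ipp_cohort"))
  adm <- x$admissions
  if (is.null(window_start)) {
    inc <- attr(x, "inclusion")
    window_start <- if (!is.null(inc)) inc$window[1] else suppressWarnings(min(adm$admit_time))
  }
  med_by <- x$medications |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(
      n_medications = dplyr::n_distinct(.data$atc_code),
      n_prescribing_specialties = dplyr::n_distinct(.data$prescriber_specialty),
      .groups = "drop"
    )
  dx_by <- x$diagnoses |>
    dplyr::distinct(.data$admission_id, .data$concept) |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(n_diagnoses = dplyr::n(), .groups = "drop")

  # charlson: weight lookup on distinct (admission, concept) pairs then sum
  dx_u <- dplyr::distinct(x$diagnoses, .data$admission_id, .data$concept)
  dx_u$w <- weights$weight[match(dx_u$concept, weights$concept)]
  dx_u$w[is.na(dx_u$w)] <- 0L
  ch_by <- dx_u |>
    dplyr::group_by(.data$admission_id) |>
    dplyr::summarise(charlson_weighted = as.integer(sum(.data$w)), .groups = "drop")

  n_dept <- vapply(strsplit(adm$departments, ";", fixed = TRUE),
                   function(d) length(unique(d[nzchar(d)])), integer(1))

  out <- tibble::tibble(
    admission_id = adm$admission_id,
    age_years = adm$age_at_admission,
    gender = adm$gender,
    n_medications = 0L,
    n_diagnoses = 0L,
    charlson_weighted = 0L,
    los_days = as.numeric(difftime(adm$discharge_time, adm$admit_time, units = "days")),
    n_departments = pmax(n_dept, 1L),
    n_prescribing_specialties = 0L,
    time_years = as.numeric(difftime(adm$admit_time, window_start, units = "days")) / 365.25,
    cluster_id = adm$patient_id
  )
  i <- match(med_by$admission_id, out$admission_id)
  out$n_medications[i] <- med_by$n_medications
  out$n_prescribing_specialties[i] <- med_by$n_prescribing_specialties
  i <- match(dx_by$admission_id, out$admission_id)
  out$n_diagnoses[i] <- dx_by$n_diagnoses
  i <- match(ch_by$admission_id, out$admission_id)
  out$charlson_weighted[i] <- ch_by$charlson_weighted
  out
}
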