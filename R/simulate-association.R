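# Direct feature-level simulation for association and trend model testing:
# draws the per-admission covariate table (no event materialization) and
# binary outcomes from a user-specified marginal logistic model with
# patient-level random intercepts. Because the intercepts are integrated
# out by the logit-normal location solver, the *marginal* success
# probability equals plogis(X beta) exactly, which is the estimand of the
# clustered (GEE) logistic model - so fitted coefficients are directly
# comparable to the simulation truth.

#' Scale map applied to covariates before model fitting
#'
#' Age enters association models per 5 years and length of stay per
#' 5 days; all other covariates enter per unit.
#'
#' @return Named numeric vector of divisors.
#' @export
covariate_scale_map <- function() c(age_years = 5, los_days = 5)

apply_covariate_scaling <- function(data, scale_map = covariate_scale_map()) {
  for (v in intersect(names(scale_map), names(data))) {
    data[[v]] <- data[[v]] / scale_map[[v]]
  }
  data
}

#' Simulate a feature table with known outcome-model truth
#'
#' Generates a per-admission covariate table mirroring the marginal
#' distributions of the full cohort generator (patient clustering, age,
#' gender, medication/diagnosis counts, Charlson score, stay length,
#' department and specialty counts, admission time) and draws a binary
#' outcome per admission from the logistic model defined by
#' `coefficients`, with patient random intercepts of standard deviation
#' `re_sd`. Coefficients apply to the *scaled* covariates (see
#' [covariate_scale_map()]); `gender` enters as an indicator for female.
#'
#' @param params an `ipp_gen_params` (sampling distributions are reused).
#' @param coefficients named numeric vector: `"(Intercept)"` plus any of
#'   `age_years`, `genderfemale`, `n_medications`, `n_diagnoses`,
#'   `charlson_weighted`, `los_days`, `n_departments`,
#'   `n_prescribing_specialties`, `time_years`.
#' @param seed RNG seed.
#' @param n number of admissions (default `params$n_admissions`).
#' @param re_sd patient random-intercept SD on the logit scale (default
#'   `params$re_sd`; set 0 for independent outcomes).
#' @param casemix_drift optional named vector of per-year additive mean
#'   drifts for count covariates (e.g.
#'   `c(n_medications = 1.5, n_diagnoses = 0.4)`), used to build
#'   confounded time-trend scenarios.
#' @return List with `features` (tibble, FeatureTable layout plus
#'   `admission_id`) and `outcome` (0/1 integer vector).
#' @export
generate_association_cohort <- function(params = default_params_table1(),
                                        coefficients,
                                        seed = 1L,
                                        n = params$n_admissions,
                                        re_sd = params$re_sd,
                                        casemix_drift = NULL) {
  stopifnot(is.numeric(coefficients), "(Intercept)" %in% names(coefficients),
            all(is.finite(coefficients)))
  set.seed(seed)
  n_pat <- max(1L, as.integer(round(n * params$n_patients / params$n_admissions)))
  k_per_pat <- assign_patients(n, n_pat)
  pat <- rep(seq_len(n_pat), k_per_pat)
  window_years <- as.numeric(difftime(params$window[2], params$window[1],
                                      units = "days")) / 365.25

  time_years <- runif(n, 0, window_years)
  drift <- function(v) {
    d <- casemix_drift[[v]]
    if (is.null(d) || d == 0) 0L else rpois(n, pmax(d, 0) * time_years)
  }
  features <- tibble::tibble(
    admission_id = sprintf("A%06d", seq_len(n)),
    age_years = rtruncnorm_lower(n_pat, params$age$mu, params$age$sigma,
                                 params$age$lower)[pat],
    gender = ifelse((runif(n_pat) < params$p_female)[pat], "female", "male"),
    n_medications = rnbinom(n, size = params$med_count$size,
                            mu = params$med_count$mu) + drift("n_medications"),
    n_diagnoses = rpois(n, 5) + drift("n_diagnoses"),
    charlson_weighted = rnbinom(n, size = 1.1, mu = 1.5),
    los_days = rlnorm_trunc(n, params$los$meanlog, params$los$sdlog,
                            params$los$lower),
    n_departments = 1L + rpois(n, params$dept_lambda),
    n_prescribing_specialties = 1L + rpois(n, params$specialty_lambda),
    time_years = time_years,
    cluster_id = sprintf("P%05d", pat)
  )

  scaled <- apply_covariate_scaling(features)
  eta <- rep(coefficients[["(Intercept)"]], n)
  for (v in setdiff(names(coefficients), "(Intercept)")) {
    x <- if (v == "genderfemale") as.numeric(scaled$gender == "female")
         else scaled[[v]]
    if (is.null(x)) stop("unknown covariate in coefficients: ", v)
    eta <- eta + coefficients[[v]] * x
  }
  if (re_sd > 0) {
    adjuster <- marginal_logit_adjuster(re_sd)
    u <- rnorm(n_pat, 0, re_sd)[pat]
    p <- plogis(adjuster(pmin(pmax(eta, -13), 13)) + u)
  } else {
    p <- plogis(eta)
  }
  list(features = features, outcome = as.integer(runif(n) < p))
}
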