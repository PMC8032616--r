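test_that("prevalence strata aggregate to the at-least-one count and percent", {
  flags <- dplyr::bind_rows(
    strata_flags(c(4526, 2522, 1211, 1009), "PIM"),
    strata_flags(c(4986, 2580, 1230, 899), "PPO", offset = 20000)
  )
  prev <- prevalence_summary(flags, 16687)
  pim <- prev$overall[prev$overall$kind == "PIM", ]
  expect_equal(pim$n[pim$stratum == "ge1"], 9268L)
  expect_equal(pim$pct[pim$stratum == "ge1"], 55.5)
  ppo <- prev$overall[prev$overall$kind == "PPO", ]
  expect_equal(ppo$n[ppo$stratum == "ge1"], 9695L)
  expect_equal(ppo$pct[ppo$stratum == "ge1"], 58.1)
  # strata conservation identity
  for (tab in list(pim, ppo)) {
    expect_equal(sum(tab$n[tab$stratum != "ge1"]), tab$n[tab$stratum == "ge1"])
  }
})

test_that("prevalence handles empty input and rejects a zero denominator", {
  empty <- tibble::tibble(admission_id = character(), rule_id = character(),
                          kind = character())
  prev <- prevalence_summary(empty, 100)
  expect_true(all(prev$overall$n == 0))
  expect_true(all(prev$overall$pct == 0))
  expect_error(prevalence_summary(empty, 0), "zero")
  # duplicated (admission, rule) pairs count once
  dup <- tibble::tibble(admission_id = c("A1", "A1"), rule_id = "r1",
                        kind = "PIM")
  expect_equal(prevalence_summary(dup, 10)$per_rule$n, 1L)
})

test_that("strata conservation holds on random flag tables", {
  set.seed(500)
  for (i in 1:10) {
    n_adm <- sample(50:300, 1)
    n_rules <- sample(2:8, 1)
    flags <- tibble::tibble(
      admission_id = sprintf("A%03d", sample(n_adm, 400, replace = TRUE)),
      rule_id = paste0("r", sample(n_rules, 400, replace = TRUE)),
      kind = sample(c("PIM", "PPO"), 400, replace = TRUE)
    )
    # a rule id is either PIM or PPO, never both
    flags$kind <- c("PIM", "PPO")[(as.integer(sub("r", "", flags$rule_id)) %% 2) + 1]
    prev <- prevalence_summary(flags, n_adm)
    for (kd in c("PIM", "PPO")) {
      tab <- prev$overall[prev$overall$kind == kd, ]
      expect_equal(sum(tab$n[tab$stratum != "ge1"]), tab$n[tab$stratum == "ge1"])
    }
    expect_true(all(prev$per_rule$pct <= 100))
  }
})

test_that("adjustment sets reproduce the documented per-variable confounders", {
  expect_equal(adjustment_set("gender"), "age_years")
  expect_equal(adjustment_set("age_years"), "gender")
  expect_setequal(adjustment_set("n_medications"),
                  c("age_years", "los_days", "n_diagnoses", "charlson_weighted",
                    "gender", "n_departments", "n_prescribing_specialties"))
  expect_setequal(adjustment_set("n_diagnoses"), c("age_years", "gender"))
  expect_setequal(adjustment_set("charlson_weighted"), c("age_years", "gender"))
  expect_setequal(adjustment_set("los_days"),
                  c("age_years", "n_diagnoses", "charlson_weighted", "gender",
                    "n_departments"))
  expect_setequal(adjustment_set("n_departments"),
                  c("age_years", "n_diagnoses", "charlson_weighted", "gender"))
  expect_setequal(adjustment_set("n_prescribing_specialties"),
                  c("age_years", "los_days", "n_diagnoses", "charlson_weighted",
                    "gender", "n_departments"))
  expect_error(adjustment_set("shoe_size"), "unknown")
})

test_that("APC equals the longhand two-mean computation on a small fixture", {
  set.seed(600)
  n <- 18
  d <- data.frame(
    x = round(runif(n, 0, 10), 1),
    w = round(rnorm(n), 2),
    gender = rep(c("male", "female"), length.out = n),
    id = seq_len(n)
  )
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.25 * d$x))
  if (length(unique(d$y)) < 2) d$y[1:2] <- c(0, 1)
  d$gender <- factor(d$gender, levels = c("male", "female"))
  fit <- fit_gee_logistic(y ~ x + w + gender, d, id = "id")
  apc <- compute_apc(fit, "x", d)
  # longhand: plogis over explicit row-by-row linear predictors
  b <- fit$coefficients
  qs <- quantile(d$x, c(0.25, 0.75), type = 7, names = FALSE)
  pr <- function(xval) {
    p <- numeric(n)
    for (i in seq_len(n)) {
      p[i] <- plogis(b[["(Intercept)"]] + b[["x"]] * xval + b[["w"]] * d$w[i] +
                       b[["genderfemale"]] * (d$gender[i] == "female"))
    }
    mean(p)
  }
  expect_equal(apc$apc_value, pr(qs[2]) - pr(qs[1]), tolerance = 1e-12)
  expect_equal(c(apc$p25, apc$p75), qs)
  # binary gender contrast
  apc_g <- compute_apc(fit, "gender", d)
  pr_g <- function(level) {
    mean(plogis(b[["(Intercept)"]] + b[["x"]] * d$x + b[["w"]] * d$w +
                  b[["genderfemale"]] * (level == "female")))
  }
  expect_equal(apc_g$apc_value, pr_g("female") - pr_g("male"), tolerance = 1e-12)
  expect_lte(abs(apc_g$apc_value), 1)
})

test_that("APC sign and degenerate cases behave as documented", {
  set.seed(601)
  d <- data.frame(x = rnorm(40), id = 1:40)
  d$y <- rbinom(40, 1, plogis(0.8 * d$x))
  if (length(unique(d$y)) < 2) d$y[1:2] <- c(0, 1)
  fit <- fit_gee_logistic(y ~ x, d, id = "id")
  apc <- compute_apc(fit, "x", d)
  # positive coefficient and p75 > p25 imply positive APC
  if (fit$coefficients[["x"]] > 0) expect_gt(apc$apc_value, 0)
  # zero IQR -> APC 0 with a warning
  d$z <- 5
  d$z[1] <- 5 # still constant IQR but not constant? keep constant column out of model
  fit2 <- fit_gee_logistic(y ~ x, d, id = "id")
  d2 <- d
  d2$x[] <- c(rep(1, 35), 2, 3, 4, 5, 6) # IQR is zero at these values
  expect_warning(res <- compute_apc(fit2, "x", d2), "zero interquartile")
  expect_equal(res$apc_value, 0)
  expect_error(compute_apc(fit2, "w", d), "not in model")
})

test_that("predicted probability curves are bounded, ordered and flat for null models", {
  set.seed(602)
  n <- 300
  feats <- tibble::tibble(
    admission_id = sprintf("A%03d", 1:n),
    time_years = runif(n, 0, 4),
    cluster_id = sprintf("P%03d", 1:n)
  )
  y <- rbinom(n, 1, 0.4)
  d <- feats
  d$.y <- y
  fit <- fit_gee_logistic(.y ~ 1, d, id = "cluster_id")
  curve <- predicted_probability_curve(fit, d)
  expect_true(all(diff(curve$time_years) >= 0))
  expect_true(all(curve$predicted > 0 & curve$predicted < 1))
  expect_equal(unique(curve$predicted), mean(y), tolerance = 1e-8)
  # monotone model in time gives a monotone prediction series
  d$.y2 <- rbinom(n, 1, plogis(-1 + 0.8 * d$time_years))
  fit2 <- fit_gee_logistic(.y2 ~ time_years, d, id = "cluster_id")
  curve2 <- predicted_probability_curve(fit2, d)
  expect_true(all(diff(curve2$predicted) * sign(fit2$coefficients[["time_years"]]) >= 0))
})

test_that("trend analysis requires a time span and reports per-year ORs", {
  g <- generate_cohort(small_params(800), seed = 700)
  co <- apply_inclusion(g$cohort)
  f <- compute_admission_features(co)
  flags <- screen_cohort(default_rule_catalog(), co)
  tr <- trend_analysis(flags, f, adjusted = FALSE)
  expect_setequal(tr$trends$outcome, c("PIM", "PPO"))
  expect_true(all(tr$trends$ci_lower <= tr$trends$per_year_or &
                    tr$trends$per_year_or <= tr$trends$ci_upper))
  tr_rule <- trend_analysis(flags, f, rule_subset = "benzo_falls")
  expect_equal(tr_rule$trends$outcome, "benzo_falls")
  f0 <- f
  f0$time_years <- 1
  expect_error(trend_analysis(flags, f0), "zero span")
})

test_that("association analysis returns the eight variables with coherent CIs", {
  g <- generate_cohort(small_params(1200), seed = 701)
  co <- apply_inclusion(g$cohort)
  f <- compute_admission_features(co)
  flags <- screen_cohort(default_rule_catalog(), co)
  tab <- association_analysis(flags, f, "PIM")
  expect_equal(nrow(tab), 8)
  expect_setequal(tab$variable,
                  c("gender", "age_years", "n_medications", "n_diagnoses",
                    "charlson_weighted", "los_days", "n_departments",
                    "n_prescribing_specialties"))
  expect_true(all(tab$crude_ci_lower <= tab$crude_or &
                    tab$crude_or <= tab$crude_ci_upper))
  expect_true(all(tab$adjusted_ci_lower <= tab$adjusted_or &
                    tab$adjusted_or <= tab$adjusted_ci_upper))
  expect_true(all(abs(tab$adjusted_apc) <= 1))
})
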