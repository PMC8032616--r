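test_that("default parameters carry the published cohort targets", {
  p <- default_params_table1()
  expect_equal(p$n_admissions, 16687L)
  expect_equal(p$n_patients, 11289L)
  expect_equal(p$p_female, 0.476)
  expect_equal(unname(p$age_target[c("mean", "sd")]), c(77.2, 5.76))
  expect_equal(unname(p$rule_rates["benzo_falls"]), 0.221)
  expect_equal(unname(p$rule_rates["ppo_laxative_opioid"]), 0.173)
  # solved latent families reproduce their summary targets
  q <- stats::qlnorm(
    stats::plnorm(1, p$los$meanlog, p$los$sdlog) +
      0.5 * (1 - stats::plnorm(1, p$los$meanlog, p$los$sdlog)),
    p$los$meanlog, p$los$sdlog)
  expect_lt(abs(q - 4.1), 0.15)
  expect_equal(qnbinom(0.5, size = p$med_count$size, mu = p$med_count$mu), 16)
})

test_that("generation is deterministic given parameters and seed", {
  p <- small_params(400)
  g1 <- generate_cohort(p, seed = 5)
  g2 <- generate_cohort(p, seed = 5)
  for (tab in names(g1$cohort)) {
    expect_identical(as.data.frame(g1$cohort[[tab]]),
                     as.data.frame(g2$cohort[[tab]]), info = tab)
  }
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_cohort(p, seed = 6)
  expect_false(identical(g1$cohort$admissions, g3$cohort$admissions))
})

test_that("infeasible joint rates are rejected with an explanation", {
  p <- small_params(200)
  p$rule_rates["benzo_falls"] <- 0.9 # exceeds the fall-risk stratum
  expect_error(generate_cohort(p, seed = 1), "infeasible joint rate")
  p2 <- small_params(200)
  p2$p_female <- 1.2
  expect_error(generate_cohort(p2, seed = 1), "proportions")
  p3 <- small_params(200)
  p3$n_patients <- 500L
  expect_error(generate_cohort(p3, seed = 1), "n_patients")
})

test_that("zeroed drug channels produce no medications and no drug-trigger flags", {
  p <- small_params(200)
  p$rule_rates[] <- 0
  p$p_benzo <- p$p_neuroleptic <- p$p_opioid <- p$p_aspirin <- 0
  p$p_laxative_nonopioid <- 0
  p$atc_class_prevalences[] <- 0
  p$med_count <- list(size = 5, mu = 0)
  p$condition_prevalences[] <- 0
  g <- generate_cohort(p, seed = 2)
  expect_equal(nrow(g$cohort$medications), 0)
  flags <- screen_cohort(default_rule_catalog(), g$cohort)
  expect_equal(sum(flags$kind == "PIM"), 0)
})

test_that("generated admissions satisfy the inclusion invariants by construction", {
  g <- generate_cohort(small_params(600), seed = 3)
  co <- g$cohort
  inc <- apply_inclusion(co)
  expect_equal(nrow(inc$admissions), nrow(co$admissions))
  f <- compute_admission_features(inc)
  expect_true(all(f$age_years >= 70))
  expect_true(all(f$los_days >= 1))
  expect_true(all(f$n_departments >= 1))
  expect_true(all(f$n_prescribing_specialties[f$n_medications > 0] >= 1))
  # patient clustering exists and repeat admissions share gender
  expect_lt(dplyr::n_distinct(co$admissions$patient_id), nrow(co$admissions))
  per_pat <- tapply(co$admissions$gender, co$admissions$patient_id,
                    dplyr::n_distinct)
  expect_true(all(per_pat == 1))
})

test_that("engine screening reproduces the constructed ground truth exactly", {
  g <- generate_cohort(small_params(2000), seed = 17)
  flags <- screen_cohort(default_rule_catalog(), g$cohort)
  gt <- g$ground_truth
  for (rule in setdiff(names(gt), "admission_id")) {
    engine <- gt$admission_id %in% flags$admission_id[flags$rule_id == rule]
    expect_identical(engine, gt[[rule]], info = rule)
  }
})

test_that("association cohort recovers null and known effects", {
  # zero gender coefficient: estimated OR near 1
  ac <- generate_association_cohort(
    coefficients = c("(Intercept)" = -0.5, genderfemale = 0),
    seed = 21, n = 6000)
  d <- ac$features
  d$.y <- ac$outcome
  d$gender <- factor(d$gender, levels = c("male", "female"))
  fit <- fit_gee_logistic(.y ~ gender, d, id = "cluster_id")
  expect_gt(fit$ci_upper[["genderfemale"]], 1)
  expect_lt(fit$ci_lower[["genderfemale"]], 1)
  # unknown covariate name is an error
  expect_error(generate_association_cohort(
    coefficients = c("(Intercept)" = 0, nope = 1), seed = 1, n = 50),
    "unknown covariate")
})

test_that("near-degenerate outcomes are handled cleanly", {
  ac <- generate_association_cohort(
    coefficients = c("(Intercept)" = -10), seed = 22, n = 2000, re_sd = 0)
  d <- ac$features
  d$.y <- ac$outcome
  if (sum(d$.y) == 0) {
    expect_error(fit_gee_logistic(.y ~ n_medications, d, id = "cluster_id"),
                 "single class")
  } else {
    fit <- fit_gee_logistic(.y ~ n_medications, d, id = "cluster_id")
    expect_true(is.logical(fit$converged))
  }
})
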