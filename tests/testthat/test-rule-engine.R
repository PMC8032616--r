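test_that("the shipped catalog parses to five PIM and five PPO rules", {
  cat <- default_rule_catalog()
  kinds <- vapply(cat$rules, `[[`, character(1), "kind")
  expect_length(cat$rules, 10)
  expect_equal(sum(kinds == "PIM"), 5)
  expect_equal(sum(kinds == "PPO"), 5)
  expect_false(anyDuplicated(names(cat$rules)) > 0)
})

test_that("catalog parsing enforces the rule invariants", {
  write_catalog <- function(txt) {
    p <- tempfile(fileext = ".yaml")
    writeLines(txt, p)
    p
  }
  expect_error(parse_rule_catalog(write_catalog(c(
    "rules:",
    "  - rule_id: r1", "    kind: PIM", "    drug_triggers: [N05BA]",
    "  - rule_id: r1", "    kind: PIM", "    drug_triggers: [C03C]"
  ))), "duplicated rule_id.*r1")
  expect_error(parse_rule_catalog(write_catalog(c(
    "rules:",
    "  - rule_id: r1", "    kind: PIM", "    drug_triggers: [N05BA]",
    "    required_conditions: [[made_up_concept]]"
  ))), "unknown concept.*made_up_concept")
  expect_error(parse_rule_catalog(write_catalog(c(
    "rules:",
    "  - rule_id: r1", "    kind: PIM", "    drug_triggers: [N05BA]",
    "    not_a_field: 1"
  ))), "unknown field")
  expect_error(parse_rule_catalog(write_catalog(c(
    "rules:", "  - rule_id: r1", "    kind: PPO"
  ))), "needs absent_drugs or required_conditions")
  # empty catalog is valid and screens to nothing
  empty <- parse_rule_catalog(write_catalog("rules: []"))
  expect_length(empty$rules, 0)
  expect_equal(nrow(screen_cohort(empty, tiny_cohort())), 0)
  expect_error(parse_rule_catalog(file.path(tempdir(), "absent.yaml")),
               "not found")
})

test_that("rule evaluation reproduces the worked screening examples", {
  co <- tiny_cohort()
  cat <- default_rule_catalog()
  # benzodiazepine + fall risk triggers the falls PIM
  expect_true(evaluate_rule(cat$rules$benzo_falls, context_of(co, "A1")))
  # opioid without laxative triggers the omission; with overlap it does not
  expect_true(evaluate_rule(cat$rules$ppo_laxative_opioid, context_of(co, "A1")))
  expect_false(evaluate_rule(cat$rules$ppo_laxative_opioid, context_of(co, "A2")))
  # hypertension + loop diuretic, no heart failure
  expect_true(evaluate_rule(cat$rules$loop_diuretic_htn, context_of(co, "A2")))
  # heart failure lacking ACE inhibitor and beta-blocker
  expect_true(evaluate_rule(cat$rules$ppo_ace_hf_cad, context_of(co, "A3")))
  expect_true(evaluate_rule(cat$rules$ppo_betablocker_hf, context_of(co, "A3")))
  # statin omission needs the lab: no LDL measured -> FALSE, not error
  expect_false(evaluate_rule(cat$rules$ppo_statin_vascular, context_of(co, "A3")))
})

test_that("screening an admission is the union of its triggered rules", {
  co <- tiny_cohort()
  cat <- default_rule_catalog()
  # A1 with a neuroleptic added triggers both falls PIMs
  co$medications <- dplyr::bind_rows(
    co$medications, med_row("A1", "N05AH04", "2016-01-12 12:00:00"))
  hits <- screen_admission(cat, context_of(co, "A1"))
  expect_true(all(c("benzo_falls", "neuroleptic_falls") %in% hits$rule_id))
  expect_equal(sum(hits$kind == "PIM"), 2)
  # lithium does not count as a neuroleptic trigger
  co$medications$atc_code[co$medications$atc_code == "N05AH04"] <- "N05AN01"
  hits2 <- screen_admission(cat, context_of(co, "A1"))
  expect_false("neuroleptic_falls" %in% hits2$rule_id)
  # no-match admission yields the empty set
  co2 <- cohort(adm_row("A9", "P9"), empty_meds(), empty_dx(), empty_labs(),
                empty_risk())
  expect_equal(nrow(screen_admission(cat, context_of(co2, "A9"))), 0)
  # singleton catalog is consistent with evaluate_rule
  single <- cat
  single$rules <- cat$rules["benzo_falls"]
  expect_equal(nrow(screen_admission(single, context_of(co, "A1"))),
               as.integer(evaluate_rule(cat$rules$benzo_falls,
                                        context_of(co, "A1"))))
})

test_that("cohort screening equals per-admission evaluation and the naive oracle", {
  g <- generate_cohort(small_params(1000), seed = 314)
  co <- g$cohort
  cat <- default_rule_catalog()
  flags <- screen_cohort(cat, co)
  by_adm <- split(flags$rule_id, flags$admission_id)
  mismatches <- 0L
  for (id in co$admissions$admission_id) {
    ctx <- admission_context(co, id)
    batch <- by_adm[[id]]
    batch <- sort(if (is.null(batch)) character() else batch)
    scalar <- sort(screen_admission(cat, ctx)$rule_id)
    naive <- oracle_screen(ctx)
    if (!identical(batch, scalar) || !identical(batch, naive)) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("screening is deterministic and order-invariant", {
  co <- generate_cohort(small_params(300), seed = 99)$cohort
  cat <- default_rule_catalog()
  f1 <- screen_cohort(cat, co)
  f2 <- screen_cohort(cat, co)
  expect_identical(f1, f2)
  set.seed(1)
  perm <- sample(nrow(co$admissions))
  co_shuf <- cohort(co$admissions[perm, ],
                    co$medications[sample(nrow(co$medications)), ],
                    co$diagnoses, co$labs, co$risk_scores)
  f3 <- screen_cohort(cat, co_shuf)
  key <- function(f) paste(f$admission_id, f$rule_id)
  expect_setequal(key(f3), key(f1))
})

test_that("PIM flags are monotone and PPO flags anti-monotone in exposures", {
  co <- tiny_cohort()
  cat <- default_rule_catalog()
  # adding another trigger administration cannot untrigger a PIM
  co_more <- co
  co_more$medications <- dplyr::bind_rows(
    co$medications, med_row("A1", "N05BA04", "2016-01-15 08:00:00"))
  expect_true(evaluate_rule(cat$rules$benzo_falls, context_of(co_more, "A1")))
  # duplicate trigger administrations do not raise n_pim
  cnt <- flag_counts(screen_cohort(cat, co_more))
  expect_equal(cnt$n_pim[cnt$admission_id == "A1"],
               flag_counts(screen_cohort(cat, co))$n_pim[1])
  # adding the omitted drug overlapping the trigger window kills the PPO
  co_lax <- co
  co_lax$medications <- dplyr::bind_rows(
    co$medications, med_row("A1", "A06AD11", "2016-01-12 12:00:00"))
  expect_false(evaluate_rule(cat$rules$ppo_laxative_opioid,
                             context_of(co_lax, "A1")))
  # a laxative far outside the opioid window does not
  co_far <- co
  co_far$medications <- dplyr::bind_rows(
    co$medications, med_row("A1", "A06AD11", "2016-01-18 08:00:00"))
  expect_true(evaluate_rule(cat$rules$ppo_laxative_opioid,
                            context_of(co_far, "A1")))
})

test_that("age and lab predicates gate rules as specified", {
  co <- tiny_cohort()
  cat <- default_rule_catalog()
  # aspirin without PPI: triggered at age >= 70 only
  co$medications <- dplyr::bind_rows(
    co$medications, med_row("A1", "B01AC06", "2016-01-12 08:00:00"))
  expect_true(evaluate_rule(cat$rules$ppo_ppi_aspirin, context_of(co, "A1")))
  co$admissions$age_at_admission[1] <- 69
  expect_false(evaluate_rule(cat$rules$ppo_ppi_aspirin, context_of(co, "A1")))
  # statin rule fires on the worst (maximum) in-stay LDL
  co2 <- tiny_cohort()
  co2$diagnoses <- dplyr::bind_rows(
    co2$diagnoses, tibble::tibble(admission_id = "A3",
                                  concept = "coronary_artery_disease"))
  co2$labs <- dplyr::bind_rows(
    co2$labs,
    tibble::tibble(admission_id = "A3", analyte = "ldl", value = c(2.0, 3.1),
                   method = "enzymatic",
                   time = ts(c("2017-06-02 08:00:00", "2017-06-03 08:00:00"))))
  expect_true(evaluate_rule(cat$rules$ppo_statin_vascular, context_of(co2, "A3")))
  co2$labs$value[co2$labs$analyte == "ldl"] <- c(2.0, 2.4)
  expect_false(evaluate_rule(cat$rules$ppo_statin_vascular, context_of(co2, "A3")))
})
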