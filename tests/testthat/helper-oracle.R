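# Independent naive re-implementation of the ten shipped criteria as
# literal nested conditionals over one admission's raw event tables.
# Deliberately written without the package's rule primitives (no
# evaluate_rule / exposure_window); serves as the brute-force oracle for
# engine equivalence tests.

oracle_window <- function(meds, prefix, exclude = NULL, grace_h = 24) {
  sel <- rep(FALSE, nrow(meds))
  for (i in seq_len(nrow(meds))) {
    code <- toupper(meds$atc_code[i])
    if (substr(code, 1, nchar(prefix)) == toupper(prefix)) {
      drop <- FALSE
      for (ex in exclude) {
        if (substr(code, 1, nchar(ex)) == toupper(ex)) drop <- TRUE
      }
      if (!drop) sel[i] <- TRUE
    }
  }
  if (!any(sel)) return(NULL)
  tt <- as.numeric(meds$admin_time[sel])
  c(min(tt), max(tt) + grace_h * 3600)
}

oracle_overlap <- function(a, b) {
  !is.null(a) && !is.null(b) && a[1] <= b[2] && b[1] <= a[2]
}

oracle_has_fall <- function(ctx) {
  rs <- ctx$risk_scores
  flag <- any(rs$kind == "fall_risk" & rs$value == 1)
  flag || "falls" %in% ctx$diagnoses$concept
}

oracle_screen <- function(ctx, grace_h = 24) {
  meds <- ctx$medications
  dx <- ctx$diagnoses$concept
  age <- ctx$admission$age_at_admission
  stay <- c(as.numeric(ctx$admission$admit_time),
            as.numeric(ctx$admission$discharge_time))
  hits <- character()

  fall <- oracle_has_fall(ctx)
  if (fall) {
    if (!is.null(oracle_window(meds, "N05BA", grace_h = grace_h)) ||
        !is.null(oracle_window(meds, "N03AE", grace_h = grace_h))) {
      hits <- c(hits, "benzo_falls")
    }
    if (!is.null(oracle_window(meds, "N05A", exclude = "N05AN",
                               grace_h = grace_h))) {
      hits <- c(hits, "neuroleptic_falls")
    }
  }
  if ("hypertension" %in% dx && !("heart_failure" %in% dx)) {
    if (!is.null(oracle_window(meds, "C03C", grace_h = grace_h))) {
      hits <- c(hits, "loop_diuretic_htn")
    }
  }
  vasc <- any(c("coronary_artery_disease", "cerebrovascular_disease",
                "peripheral_arterial_disease") %in% dx)
  if (vasc) {
    wa <- oracle_window(meds, "B01AC", grace_h = grace_h)
    wb <- NULL
    for (p in c("B01AA", "B01AE", "B01AF")) {
      w <- oracle_window(meds, p, grace_h = grace_h)
      if (!is.null(w)) {
        wb <- if (is.null(wb)) w else c(min(wb[1], w[1]), max(wb[2], w[2]))
      }
    }
    if (!is.null(wa) && !is.null(wb) && oracle_overlap(wa, wb)) {
      hits <- c(hits, "antiplatelet_anticoag")
    }
  }
  if (!is.null(oracle_window(meds, "C02A", grace_h = grace_h)) ||
      !is.null(oracle_window(meds, "C02L", grace_h = grace_h))) {
    hits <- c(hits, "central_antihypertensive")
  }

  wop <- oracle_window(meds, "N02A", grace_h = grace_h)
  if (!is.null(wop)) {
    wlax <- oracle_window(meds, "A06A", grace_h = grace_h)
    if (is.null(wlax) || !oracle_overlap(wop, wlax)) {
      hits <- c(hits, "ppo_laxative_opioid")
    }
  }
  wasp1 <- oracle_window(meds, "B01AC06", grace_h = grace_h)
  wasp2 <- oracle_window(meds, "B01AC08", grace_h = grace_h)
  wasp <- if (is.null(wasp1)) wasp2 else if (is.null(wasp2)) wasp1 else
    c(min(wasp1[1], wasp2[1]), max(wasp1[2], wasp2[2]))
  if (!is.null(wasp) && age >= 70) {
    wppi <- oracle_window(meds, "A02BC", grace_h = grace_h)
    if (is.null(wppi) || !oracle_overlap(wasp, wppi)) {
      hits <- c(hits, "ppo_ppi_aspirin")
    }
  }
  if (("heart_failure" %in% dx) || ("coronary_artery_disease" %in% dx)) {
    w1 <- oracle_window(meds, "C09A", grace_h = grace_h)
    w2 <- oracle_window(meds, "C09C", grace_h = grace_h)
    if ((is.null(w1) || !oracle_overlap(w1, stay)) &&
        (is.null(w2) || !oracle_overlap(w2, stay))) {
      hits <- c(hits, "ppo_ace_hf_cad")
    }
  }
  if (vasc) {
    ldl <- ctx$labs$value[ctx$labs$analyte == "ldl"]
    if (length(ldl) > 0 && max(ldl) > 2.5) {
      w <- oracle_window(meds, "C10AA", grace_h = grace_h)
      if (is.null(w) || !oracle_overlap(w, stay)) {
        hits <- c(hits, "ppo_statin_vascular")
      }
    }
  }
  if ("heart_failure" %in% dx) {
    w1 <- oracle_window(meds, "C07AB", grace_h = grace_h)
    w2 <- oracle_window(meds, "C07AG02", grace_h = grace_h)
    if ((is.null(w1) || !oracle_overlap(w1, stay)) &&
        (is.null(w2) || !oracle_overlap(w2, stay))) {
      hits <- c(hits, "ppo_betablocker_hf")
    }
  }
  sort(hits)
}
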