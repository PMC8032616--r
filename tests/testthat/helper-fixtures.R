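# In-code fixture builders shared across test files.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# minimal admission row
adm_row <- function(id = "A1", patient = "P1", gender = "female", age = 80,
                    admit = "2016-01-10 08:00:00",
                    discharge = "2016-01-20 10:00:00",
                    departments = "D01;D02", death = FALSE) {
  tibble::tibble(
    admission_id = id, patient_id = patient, gender = gender,
    age_at_admission = age, admit_time = ts(admit),
    discharge_time = ts(discharge), departments = departments,
    death_flag = death
  )
}

med_row <- function(id, atc, time, specialty = "internal_medicine") {
  tibble::tibble(admission_id = id, atc_code = atc, admin_time = ts(time),
                 prescriber_specialty = specialty)
}

empty_meds <- function() med_row(character(), character(), character())[0, ]
empty_dx <- function() tibble::tibble(admission_id = character(), concept = character())
empty_labs <- function() {
  tibble::tibble(admission_id = character(), analyte = character(),
                 value = numeric(), method = character(),
                 time = ts(character()))
}
empty_risk <- function() {
  tibble::tibble(admission_id = character(), kind = character(),
                 value = numeric(), time = ts(character()))
}

# three-admission cohort with hand-computable screening results:
#  A1: benzodiazepine + positive fall-risk flag, opioid without laxative
#  A2: opioid with overlapping laxative, hypertension + loop diuretic
#  A3: heart failure, no beta-blocker / no ACE inhibitor, no medication
tiny_cohort <- function() {
  adm <- dplyr::bind_rows(
    adm_row("A1", "P1", age = 81),
    adm_row("A2", "P2", gender = "male", age = 75,
            admit = "2016-03-01 09:00:00", discharge = "2016-03-08 12:00:00",
            departments = "D03"),
    adm_row("A3", "P1", age = 82,
            admit = "2017-06-01 10:00:00", discharge = "2017-06-05 10:00:00",
            departments = "D01")
  )
  meds <- dplyr::bind_rows(
    med_row("A1", "N05BA01", "2016-01-11 20:00:00"),
    med_row("A1", "N02AA01", "2016-01-12 08:00:00"),
    med_row("A1", "N02AA01", "2016-01-13 08:00:00"),
    med_row("A2", "N02AA01", "2016-03-02 08:00:00"),
    med_row("A2", "A06AD11", "2016-03-02 09:00:00"),
    med_row("A2", "C03CA01", "2016-03-03 08:00:00", "cardiology")
  )
  dx <- tibble::tibble(
    admission_id = c("A2", "A3", "A3"),
    concept = c("hypertension", "heart_failure", "diabetes")
  )
  labs <- tibble::tibble(
    admission_id = c("A1", "A2", "A3"), analyte = "egfr",
    value = c(80, 45, 62), method = "CKD-EPI",
    time = ts(c("2016-01-10 12:00:00", "2016-03-01 12:00:00",
                "2017-06-01 12:00:00"))
  )
  risk <- tibble::tibble(
    admission_id = c("A1", "A2", "A3"),
    kind = "fall_risk", value = c(1, 0, 0),
    time = ts(c("2016-01-10 09:00:00", "2016-03-01 10:00:00",
                "2017-06-01 11:00:00"))
  )
  cohort(adm, meds, dx, labs, risk)
}

# small synthetic cohort for property tests (scaled-down study parameters)
small_params <- function(n = 1000L) {
  p <- default_params_table1()
  p$n_admissions <- as.integer(n)
  p$n_patients <- as.integer(round(n / (16687 / 11289)))
  p
}

context_of <- function(co, id) admission_context(co, id)

# flag table with a prescribed number of admissions having exactly k flags
# of one kind (k = position in `counts`); rule ids are distinct within kind
strata_flags <- function(counts, kind = "PIM", offset = 0) {
  n_adm <- sum(counts)
  k_of <- rep(seq_along(counts), counts)
  adm <- rep(sprintf("S%07d", offset + seq_len(n_adm)), k_of)
  rid <- unlist(lapply(k_of, seq_len), use.names = FALSE)
  tibble::tibble(
    admission_id = adm,
    rule_id = paste0(tolower(kind), "_r", rid),
    kind = kind
  )
}
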