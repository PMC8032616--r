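#' Parse a declarative PIM/PPO rule catalog
#'
#' Rule catalogs are YAML files with a `rules` list; each rule has:
#' \describe{
#'   \item{rule_id}{unique short identifier.}
#'   \item{kind}{`"PIM"` (inappropriate medication) or `"PPO"`
#'     (prescribing omission).}
#'   \item{category}{free-text clinical category.}
#'   \item{drug_triggers}{ATC prefixes whose exposure can trigger the rule.
#'     An entry may be a plain prefix or a map with `prefix` and `exclude`
#'     (sub-prefixes carved out, e.g. all neuroleptics except lithium).}
#'   \item{required_drugs}{list of ATC-prefix sets; every set must have an
#'     exposure (any prefix within a set suffices), and under
#'     `temporal_mode: overlap` the set windows must pairwise overlap.}
#'   \item{absent_drugs}{ATC prefixes that must have no exposure window
#'     overlapping the trigger window (omission semantics).}
#'   \item{required_conditions}{list of concept groups; each group is a
#'     disjunction (any concept present satisfies it), all groups must be
#'     satisfied. The pseudo-concepts `fall_risk` and `delirium_risk`
#'     evaluate against the risk-score table (fall-risk flag = 1;
#'     DOSS >= 3).}
#'   \item{excluded_conditions}{concepts that must be absent.}
#'   \item{lab_predicate}{optional `analyte` / `comparator` / `threshold`;
#'     evaluated against the in-stay extreme value in the direction of harm
#'     (minimum for `<`-type comparators, maximum for `>`-type).}
#'   \item{age_predicate}{optional `comparator` / `years` on age at
#'     admission.}
#'   \item{temporal_mode}{`"co_occurrence"` (same admission suffices) or
#'     `"overlap"` (exposure windows must overlap).}
#' }
#'
#' @param path path to a YAML rule file; defaults to the shipped catalog
#'   of the ten most prevalent criteria.
#' @param vocabulary concept vocabulary used to check rule condition
#'   references.
#' @return An object of class `ipp_rule_catalog`: list with `rules`
#'   (in file order), `version`, `provenance`.
#' @export
parse_rule_catalog <- function(path = default_catalog_path(),
                               vocabulary = concept_vocabulary()) {
  if (!file.exists(path)) stop("rule catalog file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$rules)) stop("rule catalog has no 'rules' list: ", path)
  known_fields <- c("rule_id", "kind", "category", "description",
                    "drug_triggers", "required_drugs", "absent_drugs",
                    "required_conditions", "excluded_conditions",
                    "lab_predicate", "age_predicate", "temporal_mode")
  known_concepts <- c(vocabulary$concept, "fall_risk", "delirium_risk")
  rules <- lapply(doc$rules, function(r) {
    extra <- setdiff(names(r), known_fields)
    if (length(extra) > 0) {
      stop("unknown field(s) in rule '", r$rule_id %||% "?", "': ",
           paste(extra, collapse = ", "))
    }
    if (is.null(r$rule_id) || is.null(r$kind)) {
      stop("rule missing rule_id or kind")
    }
    if (!r$kind %in% c("PIM", "PPO")) stop("rule '", r$rule_id, "': kind must be PIM or PPO")
    r$temporal_mode <- r$temporal_mode %||% "co_occurrence"
    if (!r$temporal_mode %in% c("co_occurrence", "overlap")) {
      stop("rule '", r$rule_id, "': invalid temporal_mode")
    }
    r$drug_triggers <- lapply(r$drug_triggers, normalize_trigger)
    r$required_drugs <- lapply(r$required_drugs, function(s) unlist(s, use.names = FALSE))
    r$absent_drugs <- unlist(r$absent_drugs, use.names = FALSE)
    r$required_conditions <- lapply(r$required_conditions,
                                    function(g) unlist(g, use.names = FALSE))
    r$excluded_conditions <- unlist(r$excluded_conditions, use.names = FALSE)
    refs <- c(unlist(r$required_conditions), r$excluded_conditions)
    bad <- setdiff(refs, known_concepts)
    if (length(bad) > 0) {
      stop("rule '", r$rule_id, "' references unknown concept(s): ",
           paste(bad, collapse = ", "))
    }
    if (r$kind == "PIM" &&
        length(r$drug_triggers) == 0 && length(r$required_drugs) == 0) {
      stop("PIM rule '", r$rule_id, "' needs drug_triggers or required_drugs")
    }
    if (r$kind == "PPO" &&
        length(r$absent_drugs) == 0 && length(r$required_conditions) == 0) {
      stop("PPO rule '", r$rule_id, "' needs absent_drugs or required_conditions")
    }
    r
  })
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) {
    stop("duplicated rule_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(
    list(rules = setNames(rules, ids),
         version = doc$version %||% "unversioned",
         provenance = doc$provenance %||% ""),
    class = "ipp_rule_catalog"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_trigger <- function(t) {
  if (is.character(t)) list(prefix = t, exclude = character()) else
    list(prefix = t$prefix, exclude = unlist(t$exclude) %||% character())
}

#' Path to the shipped default rule catalog
#' @return File path of `rules_default.yaml`.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "rules_default.yaml", package = "ippscreen")
}

#' Shipped default rule catalog (top-5 PIMs + top-5 PPOs)
#' @return An `ipp_rule_catalog` with ten rules.
#' @export
default_rule_catalog <- function() parse_rule_catalog(default_catalog_path())

#' @export
print.ipp_rule_catalog <- function(x, ...) {
  kinds <- vapply(x$rules, `[[`, character(1), "kind")
  cat(sprintf("<ipp_rule_catalog> version %s: %d rules (%d PIM, %d PPO)\n",
              x$version, length(x$rules), sum(kinds == "PIM"), sum(kinds == "PPO")))
  invisible(x)
}

#' Build the evaluation context for one admission
#'
#' Collects the admission row and its medication, diagnosis, lab and
#' risk-score events from a cohort into the structure consumed by
#' [evaluate_rule()].
#'
#' @param x an [cohort()].
#' @param admission_id the admission to extract.
#' @return List with elements `admission`, `medications`, `diagnoses`,
#'   `labs`, `risk_scores`.
#' @export
admission_context <- function(x, admission_id) {
  stopifnot(inherits(x, "ipp_cohort"))
  id <- admission_id
  adm <- x$admissions[x$admissions$admission_id == id, , drop = FALSE]
  if (nrow(adm) != 1) stop("unknown admission_id: ", id)
  list(
    admission = adm,
    medications = x$medications[x$medications$admission_id == id, , drop = FALSE],
    diagnoses = x$diagnoses[x$diagnoses$admission_id == id, , drop = FALSE],
    labs = x$labs[x$labs$admission_id == id, , drop = FALSE],
    risk_scores = x$risk_scores[x$risk_scores$admission_id == id, , drop = FALSE]
  )
}

trigger_window <- function(ctx, trig, grace_hours) {
  # union window across codes matching prefix minus its exclusions
  med <- ctx$medications
  if (nrow(med) == 0) return(NULL)
  hit <- atc_match(med$atc_code, trig$prefix)
  for (ex in trig$exclude) hit <- hit & !atc_match(med$atc_code, ex)
  if (!any(hit)) return(NULL)
  t <- med$admin_time[hit]
  c(min(t), max(t) + grace_hours * 3600)
}

windows_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

condition_present <- function(ctx, concepts) {
  present <- FALSE
  plain <- setdiff(concepts, c("fall_risk", "delirium_risk"))
  if (length(plain) > 0 && any(ctx$diagnoses$concept %in% plain)) present <- TRUE
  rs <- ctx$risk_scores
  if ("fall_risk" %in% concepts &&
      any(rs$kind == "fall_risk" & rs$value == 1)) present <- TRUE
  if ("delirium_risk" %in% concepts &&
      any(rs$kind == "doss_delirium" & rs$value >= 3)) present <- TRUE
  present
}

compare_op <- function(x, op, threshold) {
  switch(op,
         "<" = x < threshold, "<=" = x <= threshold,
         ">" = x > threshold, ">=" = x >= threshold,
         stop("unknown comparator: ", op))
}

#' Evaluate a single rule on one admission context
#'
#' Deterministic: the rule is true iff the age predicate holds, every
#' required-condition group has at least one member present, no excluded
#' condition is present, the lab predicate holds against the in-stay
#' extreme value in the direction of harm, and the drug logic holds (see
#' [parse_rule_catalog()] for the temporal semantics). Rules referencing
#' an analyte absent from the admission's labs evaluate to `FALSE`.
#'
#' @param rule a rule from an `ipp_rule_catalog`.
#' @param ctx an [admission_context()].
#' @param grace_hours exposure-window persistence allowance (hours).
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_rule <- function(rule, ctx, grace_hours = 24) {
  adm <- ctx$admission
  if (!is.null(rule$age_predicate)) {
    ap <- rule$age_predicate
    if (!isTRUE(compare_op(adm$age_at_admission, ap$comparator, ap$years))) return(FALSE)
  }
  for (grp in rule$required_conditions) {
    if (!condition_present(ctx, grp)) return(FALSE)
  }
  if (length(rule$excluded_conditions) > 0 &&
      condition_present(ctx, rule$excluded_conditions)) return(FALSE)
  if (!is.null(rule$lab_predicate)) {
    lp <- rule$lab_predicate
    v <- ctx$labs$value[ctx$labs$analyte == lp$analyte]
    if (length(v) == 0) return(FALSE)
    extreme <- if (lp$comparator %in% c("<", "<=")) min(v) else max(v)
    if (!isTRUE(compare_op(extreme, lp$comparator, lp$threshold))) return(FALSE)
  }

  stay <- c(adm$admit_time, adm$discharge_time)
  trig_win <- NULL
  if (length(rule$drug_triggers) > 0) {
    wins <- Filter(Negate(is.null),
                   lapply(rule$drug_triggers, trigger_window,
                          ctx = ctx, grace_hours = grace_hours))
    if (length(wins) == 0) return(FALSE)
    trig_win <- c(min(do.call(c, lapply(wins, `[`, 1))),
                  max(do.call(c, lapply(wins, `[`, 2))))
  }
  if (length(rule$required_drugs) > 0) {
    set_wins <- lapply(rule$required_drugs, function(set) {
      wins <- Filter(Negate(is.null), lapply(set, function(p) {
        trigger_window(ctx, list(prefix = p, exclude = character()), grace_hours)
      }))
      if (length(wins) == 0) return(NULL)
      c(min(do.call(c, lapply(wins, `[`, 1))),
        max(do.call(c, lapply(wins, `[`, 2))))
    })
    if (any(vapply(set_wins, is.null, logical(1)))) return(FALSE)
    if (rule$temporal_mode == "overlap" && length(set_wins) > 1) {
      for (i in seq_along(set_wins)[-1]) {
        for (j in seq_len(i - 1)) {
          if (!windows_overlap(set_wins[[i]], set_wins[[j]])) return(FALSE)
        }
      }
    }
    if (is.null(trig_win)) {
      trig_win <- c(min(do.call(c, lapply(set_wins, `[`, 1))),
                    max(do.call(c, lapply(set_wins, `[`, 2))))
    }
  }
  if (length(rule$absent_drugs) > 0) {
    ref <- trig_win %||% stay
    for (p in rule$absent_drugs) {
      w <- trigger_window(ctx, list(prefix = p, exclude = character()), grace_hours)
      if (!is.null(w) && windows_overlap(w, ref)) return(FALSE)
    }
  }
  TRUE
}

#' Screen one admission against a catalog
#'
#' @param catalog an `ipp_rule_catalog`.
#' @param ctx an [admission_context()].
#' @param grace_hours exposure-window persistence allowance (hours).
#' @return Tibble of triggered rules: columns `rule_id`, `kind`
#'   (independent of rule order; each rule at most once).
#' @export
screen_admission <- function(catalog, ctx, grace_hours = 24) {
  hits <- vapply(catalog$rules, evaluate_rule, logical(1),
                 ctx = ctx, grace_hours = grace_hours)
  tibble::tibble(
    rule_id = names(catalog$rules)[hits],
    kind = vapply(catalog$rules[hits], `[[`, character(1), "kind")
  )
}

#' Screen a whole cohort (vectorized)
#'
#' Batch equivalent of mapping [screen_admission()] over every admission;
#' the implementation vectorizes exposure-window and concept lookups across
#' admissions, and agreement with the per-admission path is part of the
#' package's test suite.
#'
#' @param catalog an `ipp_rule_catalog`.
#' @param x an included [cohort()].
#' @param grace_hours exposure-window persistence allowance (hours).
#' @return Flag table: tibble with columns `admission_id`, `rule_id`,
#'   `kind`, one row per triggered (admission, rule) pair, plus a
#'   `counts` attribute (tibble `admission_id`, `n_pim`, `n_ppo` covering
#'   every admission). Retrieve the counts with [flag_counts()].
#' @export
screen_cohort <- function(catalog, x, grace_hours = 24) {
  stopifnot(inherits(x, "ipp_cohort"), inherits(catalog, "ipp_rule_catalog"))
  adm <- x$admissions
  n <- nrow(adm)
  ids <- adm$admission_id
  med <- x$medications
  med_idx <- match(med$admission_id, ids)
  grace <- grace_hours * 3600

  # per-admission exposure windows for every distinct prefix spec
  spec_key <- function(trig) {
    paste0(trig$prefix,
           if (length(trig$exclude) > 0) paste0("!", paste(sort(trig$exclude), collapse = ",")) else "")
  }
  specs <- list()
  for (r in catalog$rules) {
    for (t in r$drug_triggers) specs[[spec_key(t)]] <- t
    for (s in r$required_drugs) for (p in s) {
      specs[[p]] <- list(prefix = p, exclude = character())
    }
    for (p in r$absent_drugs) specs[[p]] <- list(prefix = p, exclude = character())
  }
  win_first <- win_last <- list()
  med_time <- as.numeric(med$admin_time)
  for (k in names(specs)) {
    t <- specs[[k]]
    hit <- atc_match(med$atc_code, t$prefix)
    for (ex in t$exclude) hit <- hit & !atc_match(med$atc_code, ex)
    first <- last <- rep(NA_real_, n)
    if (any(hit)) {
      mn <- tapply(med_time[hit], med_idx[hit], min)
      mx <- tapply(med_time[hit], med_idx[hit], max)
      at <- as.integer(names(mn))
      first[at] <- mn
      last[at] <- mx + grace
    }
    win_first[[k]] <- first
    win_last[[k]] <- last
  }

  # concept / risk-flag presence
  dx <- x$diagnoses
  rs <- x$risk_scores
  fall_ids <- unique(rs$admission_id[rs$kind == "fall_risk" & rs$value == 1])
  doss_ids <- unique(rs$admission_id[rs$kind == "doss_delirium" & rs$value >= 3])
  group_present <- function(concepts) {
    out <- rep(FALSE, n)
    plain <- setdiff(concepts, c("fall_risk", "delirium_risk"))
    if (length(plain) > 0) {
      out <- out | ids %in% dx$admission_id[dx$concept %in% plain]
    }
    if ("fall_risk" %in% concepts) out <- out | ids %in% fall_ids
    if ("delirium_risk" %in% concepts) out <- out | ids %in% doss_ids
    out
  }

  lab <- x$labs
  lab_idx <- match(lab$admission_id, ids)
  lab_extreme <- function(analyte, direction) {
    sel <- lab$analyte == analyte
    out <- rep(NA_real_, n)
    if (any(sel)) {
      agg <- tapply(lab$value[sel], lab_idx[sel], direction)
      out[as.integer(names(agg))] <- agg
    }
    out
  }

  stay_first <- as.numeric(adm$admit_time)
  stay_last <- as.numeric(adm$discharge_time)

  eval_rule_vec <- function(r) {
    ok <- rep(TRUE, n)
    if (!is.null(r$age_predicate)) {
      ok <- ok & compare_op(adm$age_at_admission, r$age_predicate$comparator,
                            r$age_predicate$years)
    }
    for (grp in r$required_conditions) ok <- ok & group_present(grp)
    if (length(r$excluded_conditions) > 0) ok <- ok & !group_present(r$excluded_conditions)
    if (!is.null(r$lab_predicate)) {
      lp <- r$lab_predicate
      dirfun <- if (lp$comparator %in% c("<", "<=")) min else max
      v <- lab_extreme(lp$analyte, dirfun)
      pass <- !is.na(v) & compare_op(v, lp$comparator, lp$threshold)
      ok <- ok & pass
    }
    trig_f <- trig_l <- NULL
    if (length(r$drug_triggers) > 0) {
      ks <- vapply(r$drug_triggers, spec_key, character(1))
      trig_f <- do.call(pmin, c(win_first[ks], list(na.rm = TRUE)))
      trig_l <- do.call(pmax, c(win_last[ks], list(na.rm = TRUE)))
      ok <- ok & !is.na(trig_f)
    }
    if (length(r$required_drugs) > 0) {
      sf <- sl <- list()
      for (i in seq_along(r$required_drugs)) {
        ks <- r$required_drugs[[i]]
        f <- do.call(pmin, c(win_first[ks], list(na.rm = TRUE)))
        l <- do.call(pmax, c(win_last[ks], list(na.rm = TRUE)))
        ok <- ok & !is.na(f)
        sf[[i]] <- f
        sl[[i]] <- l
      }
      if (r$temporal_mode == "overlap" && length(sf) > 1) {
        for (i in seq_along(sf)[-1]) for (j in seq_len(i - 1)) {
          ov <- sf[[i]] <= sl[[j]] & sf[[j]] <= sl[[i]]
          ov[is.na(ov)] <- FALSE
          ok <- ok & ov
        }
      }
      if (is.null(trig_f)) {
        trig_f <- do.call(pmin, c(sf, list(na.rm = TRUE)))
        trig_l <- do.call(pmax, c(sl, list(na.rm = TRUE)))
      }
    }
    if (length(r$absent_drugs) > 0) {
      ref_f <- if (is.null(trig_f)) stay_first else trig_f
      ref_l <- if (is.null(trig_f)) stay_last else trig_l
      for (p in r$absent_drugs) {
        f <- win_first[[p]]
        l <- win_last[[p]]
        ov <- !is.na(f) & !is.na(ref_f) & f <= ref_l & ref_f <= l
        ok <- ok & !ov
      }
    }
    ok
  }

  flag_list <- lapply(catalog$rules, eval_rule_vec)
  rows <- lapply(names(flag_list), function(rid) {
    hit <- flag_list[[rid]]
    tibble::tibble(
      admission_id = ids[hit],
      rule_id = rid,
      kind = catalog$rules[[rid]]$kind
    )
  })
  flags <- dplyr::bind_rows(
    tibble::tibble(admission_id = character(), rule_id = character(),
                   kind = character()),
    rows
  ) |>
    dplyr::arrange(.data$admission_id, .data$rule_id)

  counts <- tibble::tibble(admission_id = ids, n_pim = 0L, n_ppo = 0L)
  if (nrow(flags) > 0) {
    cc <- flags |>
      dplyr::group_by(.data$admission_id) |>
      dplyr::summarise(n_pim = sum(.data$kind == "PIM"),
                       n_ppo = sum(.data$kind == "PPO"), .groups = "drop")
    i <- match(cc$admission_id, counts$admission_id)
    counts$n_pim[i] <- cc$n_pim
    counts$n_ppo[i] <- cc$n_ppo
  }
  attr(flags, "counts") <- counts
  flags
}

#' Per-admission PIM/PPO counts from a flag table
#'
#' @param flags a flag table from [screen_cohort()].
#' @return Tibble `admission_id`, `n_pim`, `n_ppo` (one row per admission
#'   of the screened cohort, zeros included).
#' @export
flag_counts <- function(flags) {
  cc <- attr(flags, "counts")
  if (is.null(cc)) {
    cc <- flags |>
      dplyr::distinct(.data$admission_id, .data$rule_id, .data$kind) |>
      dplyr::group_by(.data$admission_id) |>
      dplyr::summarise(n_pim = sum(.data$kind == "PIM"),
                       n_ppo = sum(.data$kind == "PPO"), .groups = "drop")
  }
  cc
}
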