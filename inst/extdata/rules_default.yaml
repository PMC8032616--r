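# Default PIM/PPO criteria catalog: the five most prevalent PIMs and the
# five most prevalent PPOs in older Dutch inpatients, encoded in the
# declarative rule format documented in ?parse_rule_catalog.
#
# Operationalizations (each criterion names drug classes and clinical
# context only; the concrete ATC prefixes, concept sets and temporal
# semantics below are this catalog's explicit encoding and can be
# overridden by editing the file):
#   - "history or risk of falls" = positive fall-risk screening flag OR a
#     falls diagnosis concept.
#   - condition concepts are admission-level codes without timestamps, so
#     drug-condition rules use co_occurrence; drug-drug rules require
#     overlapping exposure windows.
#   - omission (PPO) semantics: the indicated drug has no exposure window
#     overlapping the trigger window (the triggering drug's window, or the
#     whole stay for condition-triggered rules).
version: "1.0"
provenance: "default top-5 PIM / top-5 PPO catalog shipped with ippscreen"
rules:
  - rule_id: benzo_falls
    kind: PIM
    category: falls
    description: >
      Benzodiazepines (or benzodiazepine-like hypnotic barbiturate
      combinations) in patients with a history or risk of falls.
    drug_triggers: [N05BA, N03AE]
    required_conditions:
      - [fall_risk, falls]
    temporal_mode: co_occurrence

  - rule_id: loop_diuretic_htn
    kind: PIM
    category: cardiovascular
    description: >
      Loop diuretic as first-line treatment for hypertension in the
      absence of heart failure.
    drug_triggers: [C03C]
    required_conditions:
      - [hypertension]
    excluded_conditions: [heart_failure]
    temporal_mode: co_occurrence

  - rule_id: neuroleptic_falls
    kind: PIM
    category: falls
    description: >
      Neuroleptic (antipsychotic) drugs, excluding lithium, in patients
      with a history or risk of falls.
    drug_triggers:
      - prefix: N05A
        exclude: [N05AN]
    required_conditions:
      - [fall_risk, falls]
    temporal_mode: co_occurrence

  - rule_id: antiplatelet_anticoag
    kind: PIM
    category: cardiovascular
    description: >
      Antiplatelet agent combined with a vitamin K antagonist, direct
      thrombin inhibitor or factor Xa inhibitor in patients with stable
      coronary, cerebrovascular or peripheral arterial disease.
    required_drugs:
      - [B01AC]
      - [B01AA, B01AE, B01AF]
    required_conditions:
      - [coronary_artery_disease, cerebrovascular_disease, peripheral_arterial_disease]
    temporal_mode: overlap

  - rule_id: central_antihypertensive
    kind: PIM
    category: cardiovascular
    description: >
      Centrally-acting antihypertensives.
    drug_triggers: [C02A, C02L]
    temporal_mode: co_occurrence

  - rule_id: ppo_laxative_opioid
    kind: PPO
    category: gastrointestinal
    description: >
      Missing laxative in patients receiving opioids.
    drug_triggers: [N02A]
    absent_drugs: [A06A]
    temporal_mode: overlap

  - rule_id: ppo_ppi_aspirin
    kind: PPO
    category: gastrointestinal
    description: >
      Missing proton pump inhibitor with low-dose acetylsalicylic acid or
      carbasalate calcium in patients aged 70 or over.
    drug_triggers: [B01AC06, B01AC08]
    absent_drugs: [A02BC]
    age_predicate:
      comparator: ">="
      years: 70
    temporal_mode: overlap

  - rule_id: ppo_ace_hf_cad
    kind: PPO
    category: cardiovascular
    description: >
      Missing ACE inhibitor (or angiotensin receptor blocker) with
      systolic heart failure and/or documented coronary artery disease.
    required_conditions:
      - [heart_failure, coronary_artery_disease]
    absent_drugs: [C09A, C09C]
    temporal_mode: co_occurrence

  - rule_id: ppo_statin_vascular
    kind: PPO
    category: cardiovascular
    description: >
      Missing statin with documented coronary, cerebral or peripheral
      vascular disease and LDL > 2.5 mmol/l.
    required_conditions:
      - [coronary_artery_disease, cerebrovascular_disease, peripheral_arterial_disease]
    lab_predicate:
      analyte: ldl
      comparator: ">"
      threshold: 2.5
    absent_drugs: [C10AA]
    temporal_mode: co_occurrence

  - rule_id: ppo_betablocker_hf
    kind: PPO
    category: cardiovascular
    description: >
      Missing appropriate beta-blocker with stable systolic heart failure.
    required_conditions:
      - [heart_failure]
    absent_drugs: [C07AB, C07AG02]
    temporal_mode: co_occurrence
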