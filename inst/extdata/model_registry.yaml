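# Base-model registry: one entry per modality-specific model.
# `features_printed` is the feature count reported for the original study
# cohort; `features` is the pool the pipeline selects from in the synthetic
# data dictionary (selector terms: modality:<tag>, items:<scale>, or
# explicit column names). Pools wider than the printed count are narrowed
# by the pipeline's own selection stage.
models:
  - name: somatic_metrics
    label: "Somatic metrics"
    modalities: "Waist-to-hip ratio, blood pressure, temperature"
    features_printed: 9
    pipeline: P1
    features:
      - waist_hip_ratio
      - systolic_bp
      - diastolic_bp
      - body_temperature
      - resting_heart_rate
      - waist_circumference
      - hip_circumference
      - bmi
      - weight
  - name: hrv
    label: "HRV"
    modalities: "Heart rate variability measures"
    features_printed: 26
    pipeline: P4
    features:
      - heart_rate_lying
      - hrv_sdnn
      - hrv_rmssd
      - hrv_lf
      - hrv_hf
      - hrv_baevskii
  - name: lab
    label: "Lab"
    modalities: "Blood test values"
    features_printed: 36
    pipeline: P4
    features:
      - modality:lab
  - name: biographic
    label: "Biographic"
    modalities: "Biographical data + LSNS-6"
    features_printed: 18
    pipeline: P2
    features:
      - age
      - sex_female
      - education
      - financial_difficulties
      - working_hours
      - smoking
      - partnership
      - binge_drinking
      - prior_depressive_episode
      - psychiatric_medication
      - n_depressive_episodes
      - siblings
      - adults_household
      - sport_weekly
      - employment_12m
      - parents_separated
      - attempted_suicide
      - lsns_total
  - name: phq15_somatic
    label: "somatic"
    modalities: "PHQ-15"
    features_printed: 15
    pipeline: P3
    features:
      - items:phq15
  - name: depression_items
    label: "Depression items"
    modalities: "WHO-5 + PHQ-9"
    features_printed: 11
    pipeline: P3
    features:
      - items:who5
      - items:phq9
  - name: all_clinical
    label: "All clinical"
    modalities: "WHO-5 + UCLA + PHQ-9 + WHODAS2.0 + PC-PTSD + PHQ-15"
    features_printed: 19
    pipeline: P3
    features:
      - items:who5
      - items:ucla3
      - items:phq9
      - items:whodas
      - items:pcptsd
      - items:phq15
  - name: all_self_rated
    label: "All self-rated"
    modalities: "All clinical + biographic + LSNS"
    features_printed: 16
    pipeline: P3
    features:
      - items:who5
      - items:ucla3
      - items:phq9
      - items:whodas
      - items:pcptsd
      - items:phq15
      - age
      - sex_female
      - education
      - financial_difficulties
      - working_hours
      - smoking
      - partnership
      - binge_drinking
      - prior_depressive_episode
      - psychiatric_medication
      - n_depressive_episodes
      - siblings
      - adults_household
      - sport_weekly
      - employment_12m
      - parents_separated
      - attempted_suicide
      - lsns_total
  - name: clinical_15
    label: "Clinical 15"
    modalities: "WHO-5 + PHQ-9 + WHODAS2.0"
    features_printed: 15
    pipeline: P1
    # The original 15-item list is not published; this list was frozen
    # from one Boruta pass (top 15 median importances) over
    # the WHO-5 + PHQ-9 + WHODAS-12 item pool on the reference synthetic
    # cohort (generator seed 1, selection seed 201).
    synthetic_derived: true
    features:
      - who5_item_1
      - who5_item_2
      - who5_item_3
      - who5_item_4
      - who5_item_5
      - phq9_item_2
      - phq9_item_3
      - phq9_item_4
      - phq9_item_5
      - phq9_item_7
      - phq9_item_9
      - whodas_item_1
      - whodas_item_2
      - whodas_item_5
      - whodas_item_7
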