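model:
  cohort_start_age: 50.0
  horizon: 35.0
  discount_rate: 0.05
  wtp: 20000.0
  stage_split_early: 0.2
  sex: both
  progression_prob: 0.15
  half_cycle_correction: no
strategies:
  usc:
    name: USC (NRT + counselling)
    quit_rate_12m: 0.06
    relapse_multiplier: 1.0
    cost_items:
    - label: GP visit
      quantity: 1.0
      unit_cost: 21.0
    - label: Patches step 1 (21 mg)
      quantity: 6.0
      unit_cost: 47.950000000000003
    - label: Patches step 2 (14 mg)
      quantity: 2.0
      unit_cost: 27.949999999999999
    - label: Patches step 3 (7 mg)
      quantity: 2.0
      unit_cost: 27.949999999999999
    - label: Telephone counselling
      quantity: 5.0
      unit_cost: 75.739999999999995
    - label: Self-help booklet
      quantity: 1.0
      unit_cost: 2.9
  gt:
    name: USC + genetic test
    quit_rate_12m: 0.11
    relapse_multiplier: 1.0
    cost_items:
    - label: GP visit
      quantity: 1.0
      unit_cost: 21.0
    - label: Patches step 1 (21 mg)
      quantity: 6.0
      unit_cost: 47.950000000000003
    - label: Patches step 2 (14 mg)
      quantity: 2.0
      unit_cost: 27.949999999999999
    - label: Patches step 3 (7 mg)
      quantity: 2.0
      unit_cost: 27.949999999999999
    - label: Telephone counselling
      quantity: 5.0
      unit_cost: 75.739999999999995
    - label: Self-help booklet
      quantity: 1.0
      unit_cost: 2.9
    - label: Clinic visits
      quantity: 2.0
      unit_cost: 21.0
    - label: Genetic test
      quantity: 1.0
      unit_cost: 311.0
    - label: Test booklet
      quantity: 1.0
      unit_cost: 2.9
relapse:
  years_2_6: 0.1
  years_7_plus: 0.04
utilities:
  no_lung_cancer: 1.0
  early_lc: 0.73
  advanced_lc: 0.66
  dead: 0.0
cancer_costs:
  early_first_year: 44274.0
  advanced_first_year: 27057.0
  ongoing_stable: 7115.0
  progressive: 10945.0
  terminal_final_year: 9961.0
epi:
  mortality: mortality.csv
  incidence: incidence.csv
  rr_current_smoker:
    both: 6.609
    male: 7.730799999999999
    female: 5.487200000000001
  rr_ex_smoker: rr_ex_smoker.csv
  lc_survival: lc_survival.csv
  meta:
    mortality:
      anchor_age: 65.0
      anchor_rate: 0.00936
      slope: 0.09
    incidence:
      anchor_age: 65.0
      anchor_rate: 0.0018024
      slope: 0.08
    rr:
      smoker: 6.609
      ex_anchor: 4.75
      ex_anchor_ysq: 3.0
      floor: 1.5
      sex_multiplier:
        male: 1.2
        female: 0.8
    survival:
      s1: 0.36
      s5: 0.12
      p_early: 0.2
      early_hazard_factor: 0.5
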