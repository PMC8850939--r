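parameters:
  p_fn_peg: 0.0116
  p_fn_rhg: 0.0404
  p_inf_fn_peg: 0.0547
  p_inf_fn_rhg: 0.547
  p_death_fn: 0.034
  p_death_inf: 0.034
  cost_gcsf_peg: 3315.739999999999782
  cost_gcsf_rhg: 734.340000000000032
  cost_docetaxel_unit: 1792.740000000000009
  cost_cyclo_unit: 120.75
  cost_fn_inpatient: 25000.0
  cost_inf_given_fn: 50000.0
  cost_hosp_cycle: 14811.100000000000364
  u_chemo: 0.7
  u_fn: 0.33
  u_inf: 0.33
  u_bc_1to5: 0.86
  u_bc_gt5: 0.96
  p_rdi_fn: 0.5
  p_rdi_nofn_lt65: 0.247
  rr_rdi_age65: 1.38
  or_rdi_fn: 1.58
  hr_mort_rdi: 1.73
  discount_chemo: 0.0
  discount_post: 0.05
  n_chemo_cycles: 4.0
  cycle_weeks: 3.0
  weeks_per_year: 52.18
  bsa: 1.6
  dose_docetaxel_mg_m2: 75.0
  dose_cyclo_mg_m2: 600.0
  docetaxel_mg_per_unit: 20.0
  cyclo_mg_per_unit: 200.0
  horizon_years: 35.0
  start_age: 45.0
  wtp: 72371.0
  equalize_infection_risk: no
  rdi_mode: measured
  fn_input_mode: per_cycle
  half_cycle: no
cohort:
  n_peg: 926.0
  n_rhg: 898.0
  los_mean_peg: 10.470000000000001
  los_sd_peg: 7.47
  los_mean_rhg: 8.949999999999999
  los_sd_rhg: 7.88
  cost_mean_peg: 17079.0
  cost_sd_peg: 3084.0
  cost_mean_rhg: 14086.0
  cost_sd_rhg: 335.0
  age_mean_peg: 48.799999999999997
  age_sd_peg: 9.56
  age_mean_rhg: 48.75
  age_sd_rhg: 9.960000000000001
  surgery_rate_peg: 0.529
  surgery_rate_rhg: 0.4
  insurance_categories:
  - 0.6
  - 0.3
  - 0.1
  concomitant_disease_probs:
  - 0.45
  - 0.3
  - 0.17
  - 0.08
  p_fn_course_peg: 0.045598865477607
  p_fn_course_rhg: 0.152068133109734
  conf_age_shift: 5.0
  conf_insurance_tilt: 0.15
run:
  seed: 1.0
  n_psa_draws: 1000.0
  wtp_grid:
  - 0
  - 5000
  - 10000
  - 15000
  - 20000
  - 25000
  - 30000
  - 35000
  - 40000
  - 45000
  - 50000
  - 55000
  - 60000
  - 65000
  - 70000
  - 75000
  - 80000
  - 85000
  - 90000
  - 95000
  - 100000
  - 105000
  - 110000
  - 115000
  - 120000
  - 125000
  - 130000
  - 135000
  - 140000
  - 145000
  - 150000
  - 155000
  - 160000
  - 165000
  - 170000
  - 175000
  - 180000
  - 185000
  - 190000
  - 195000
  - 200000
  caliper: default
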