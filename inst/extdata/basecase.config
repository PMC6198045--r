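# Reference base-case configuration: the published deterministic inputs.
# Loading an empty document gives the same parameter set; this file spells
# every value out for reference and hand editing.
transitions:
  p_bph_stay: 0.345
  p_bph_to_turp: 0.021
  p_bph_to_aur: 0.004
  p_aur_to_turp: 0.8
  p_turp_30day_mortality: 0.0237
  p_turp_to_medical: 0.059
  p_turp_to_repeat: 0.059
  p_repeat_turp_mortality: 0.0
  p_recovery_stay: 0.329
  p_recovery_to_medical: 0.0467
  p_medical_to_second_turp: 0.036
  p_medical_stay: 0.393
  p_medical_to_aur: 0.0
  p_repeat_to_medical: 0.0025
  p_turp_full_recovery: 0.998
efficacy:
  rrr_aur: 0.676
  rrr_turp: 0.706
costs:
  annual_drug_combination: 464.97
  annual_drug_tamsulosin: 55.79
  annual_bph_management: 471.0
  aur_episode: 1312.0
  turp_procedure: 6334.0
  annual_medical_intervention: 371.0
  recovery_followup: 0.0
utilities:
  u_bph: 0.876
  u_aur: 0.25
  u_turp: 0.25
  u_medical: 0.25
  u_recovery: 1.0
  u_death: 0.0
settings:
  discount_rate: 0.03
  horizon_years: 4
  cycles_per_year: 1
  cohort_start_age: 66
  n_microsim_patients: 10000
options:
  row_mode: renormalize
  probability_timescale: annual
  drug_accrual: alive
  half_cycle_correction: no

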