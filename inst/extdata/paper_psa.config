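# Distribution set for probabilistic sensitivity analysis: beta for
# probabilities and efficacies, gamma for costs.  Gamma rates are
# rederived at load time as shape / mean_override (the printed rates are
# inconsistent with the printed means).
psa_distributions:
- target: p_bph_to_turp
  family: beta
  shape_alpha: 0.62
  shape_beta_or_rate: 29.27
- target: p_recovery_stay
  family: beta
  shape_alpha: 2.83
  shape_beta_or_rate: 7.79
- target: p_recovery_to_medical
  family: beta
  shape_alpha: 2.24
  shape_beta_or_rate: 27.97
- target: p_medical_to_second_turp
  family: beta
  shape_alpha: 2.3
  shape_beta_or_rate: 35.16
- target: p_bph_to_aur
  family: beta
  shape_alpha: 0.06
  shape_beta_or_rate: 2.9
- target: rrr_aur
  family: beta
  shape_alpha: 1.77
  shape_beta_or_rate: 0.85
- target: rrr_turp
  family: beta
  shape_alpha: 2.5
  shape_beta_or_rate: 1.04
- target: annual_bph_management
  family: gamma
  shape_alpha: 3.61
  shape_beta_or_rate: 0.01
  mean_override: 471.0
- target: aur_episode
  family: gamma
  shape_alpha: 0.21
  shape_beta_or_rate: 1.57
  mean_override: 1312.0
- target: turp_procedure
  family: gamma
  shape_alpha: 12.59
  shape_beta_or_rate: 0.002
  mean_override: 6334.0
- target: annual_medical_intervention
  family: gamma
  shape_alpha: 2.24
  shape_beta_or_rate: 0.006
  mean_override: 371.0

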