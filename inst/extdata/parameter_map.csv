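published_input,field,role
Remaining in BPH,p_bph_stay,stay weight of the BPH row (renormalized mode); informational in residual mode
BPH patients who experience TURP,p_bph_to_turp,used: BPH to TURP exit
BPH patients who experience AUR,p_bph_to_aur,used: BPH to AUR exit
AUR patients going through TURP,p_aur_to_turp,used: AUR tunnel split (remainder returns to BPH)
TURP patients 30-day mortality,p_turp_30day_mortality,used: surgical mortality charged in the TURP cycle
TURP patients who recover,,remainder convention: survivors not needing repeat surgery or medication recover
TURP patients who require medical intervention,p_turp_to_medical,used: TURP survivor split
TURP patients who require repeated surgical intervention,p_turp_to_repeat,used: TURP survivor split
Patients with repeated TURP died from surgical procedure,p_repeat_turp_mortality,used: repeat-TURP surgical mortality (0)
Patients who remain at recovery state,p_recovery_stay,stay weight of the RECOVERY row (renormalized mode)
Recovered patients who require medical intervention,p_recovery_to_medical,used: RECOVERY to MEDICAL_INTERVENTION exit
Patients on medication who require the second TURP,p_medical_to_second_turp,used: MEDICAL_INTERVENTION to repeat TURP exit (suppressed after a second TURP)
Patients with repeated TURP requiring medication intervention,p_repeat_to_medical,used: repeat-TURP survivor split
Patients with repeated TURP who recover,,remainder convention: repeat-TURP survivors not needing medication recover
Patients remain on medication,p_medical_stay,stay weight of the MEDICAL_INTERVENTION row (renormalized mode)
TURP patients who fully recover,p_turp_full_recovery,stored unused: redundant with the remainder convention of the TURP row
Patients on medication who transition to AUR state,p_medical_to_aur,stored: must be 0 (post-surgical AUR is foreclosed by the chain structure)
All-cause mortality,life_table,used: Gompertz stand-in calibrated to ~5% 4-year cumulative background mortality from age 66
Efficacy against AUR,rrr_aur,used: relative risk reduction on the BPH-to-AUR exit (combination arm)
Efficacy against TURP,rrr_turp,used: relative risk reduction on the BPH-to-TURP exit (combination arm)
Combination drug cost per annum,annual_drug_combination,used: accrues in all alive states (combination arm)
Tamsulosin cost per annum,annual_drug_tamsulosin,used: accrues in all alive states (monotherapy arm)
Managing a BPH patient per annum,annual_bph_management,used: accrues on BPH occupancy
Managing an AUR episode,aur_episode,used: charged per AUR tunnel cycle
TURP procedure,turp_procedure,used: charged per TURP or repeat-TURP cycle
Managing medical intervention per annum,annual_medical_intervention,used: accrues on MEDICAL_INTERVENTION occupancy
BPH utility mild,,informational: severity split is collapsed into the weighted value
BPH utility moderate,,informational: severity split is collapsed into the weighted value
BPH utility severe,,informational: severity split is collapsed into the weighted value
BPH utility weighted,u_bph,used: utility of the BPH state
AUR utility,u_aur,used
TURP utility,u_turp,used: also applied to the repeat-TURP state
Medical intervention utility,u_medical,used
Recovery utility,u_recovery,used
Death utility,u_death,used: fixed at 0
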