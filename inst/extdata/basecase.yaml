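testing:
  frac_tissue: 0.6
  frac_blood: 0.4
  p_insufficient_tissue: 0.05
  p_insufficient_blood: 0.003
  p_fail_tissue: 0.012
  p_fail_blood: 0.005
  p_actionable_tissue: 0.23
  p_actionable_blood: 0.24
splits:
  p_immuno_nontargeted: 0.25
  p_chemo_nontargeted: 0.29
  p_chemoimmuno_nontargeted: 0.36
  p_direct_targeted: 0.73
  p_interim: 0.27
  p_interim_switch: 0.34
money:
  cost_inhouse_test: 600.0
  cost_sendout_test: 300.0
  cost_singlegene_test: 141.0
  cost_machine_acquisition: 200000.0
  reimb_inhouse_test: 580.0
  revenue_hospital_visit: 124.0
  retest_multiplier: 1.0
  visits_per_cycle: 1.0
tat:
  tat_sendout_low: 10.32
  tat_sendout_high: 27.800000000000001
  tat_inhouse: 3.0
clinical:
  pfs_1yr:
    chemo: 0.173
    immuno: 0.279
    chemo_immuno: 0.341
    targeted: 0.4
  os_1yr:
    chemo: 0.494
    immuno: 0.673
    chemo_immuno: 0.692
    targeted: 0.86
  os_1yr_progression: 0.494
  os_1yr_next_line: 0.494
  p_prog_to_nextline_3mo: 0.48
  p_nextline_to_prog_3mo: 0.5
scenario_current:
  horizon_years: 5
  discount_rate_annual: 0.035
  patients_per_year: 500.0
  frac_inhouse: 0.0
  frac_sendout: 1.0
  comparator_mode: sendout_ngs
scenario_proposed:
  horizon_years: 5
  discount_rate_annual: 0.035
  patients_per_year: 500.0
  frac_inhouse: 0.75
  frac_sendout: 0.25
  comparator_mode: sendout_ngs
gaps:
  p_second_opinion_sendout: 0.1
  p_second_opinion_inhouse: 0.02
  interim_tat_scaling: yes
  cycle_days: 30.0
  days_per_year: 365.25
  genes_per_singlegene_panel: 5.0
  reimburse_inhouse_only: yes
uncertainty:
- parameter: testing.frac_tissue
  low: 0.54
  high: 0.66
  dist: beta
  in_psa: yes
- parameter: testing.p_insufficient_tissue
  low: 0.045
  high: 0.055
  dist: beta
  in_psa: yes
- parameter: testing.p_insufficient_blood
  low: 0.0027
  high: 0.0033
  dist: beta
  in_psa: yes
- parameter: testing.p_fail_tissue
  low: 0.0108
  high: 0.0132
  dist: beta
  in_psa: yes
- parameter: testing.p_fail_blood
  low: 0.0045
  high: 0.0055
  dist: beta
  in_psa: yes
- parameter: testing.p_actionable_tissue
  low: 0.207
  high: 0.253
  dist: beta
  in_psa: yes
- parameter: testing.p_actionable_blood
  low: 0.216
  high: 0.264
  dist: beta
  in_psa: yes
- parameter: splits.p_immuno_nontargeted
  low: 0.225
  high: 0.275
  dist: beta
  in_psa: yes
- parameter: splits.p_chemo_nontargeted
  low: 0.261
  high: 0.319
  dist: beta
  in_psa: yes
- parameter: splits.p_chemoimmuno_nontargeted
  low: 0.324
  high: 0.396
  dist: beta
  in_psa: yes
- parameter: splits.p_interim
  low: 0.243
  high: 0.297
  dist: beta
  in_psa: yes
- parameter: splits.p_interim_switch
  low: 0.306
  high: 0.374
  dist: beta
  in_psa: yes
- parameter: money.cost_inhouse_test
  low: 578.0
  high: 908.0
  dist: gamma
  in_psa: yes
- parameter: money.cost_sendout_test
  low: 270.0
  high: 330.0
  dist: gamma
  in_psa: yes
- parameter: money.cost_singlegene_test
  low: 126.900000000000006
  high: 155.099999999999994
  dist: gamma
  in_psa: yes
- parameter: money.cost_machine_acquisition
  low: 180000.0
  high: 220000.0
  dist: gamma
  in_psa: yes
- parameter: money.reimb_inhouse_test
  low: 522.0
  high: 638.0
  dist: gamma
  in_psa: yes
- parameter: money.revenue_hospital_visit
  low: 112.0
  high: 136.0
  dist: gamma
  in_psa: yes
- parameter: tat.sendout_midpoint
  low: 10.32
  high: 27.800000000000001
  dist: uniform
  in_psa: yes
- parameter: tat.tat_inhouse
  low: 2.7
  high: 3.3
  dist: uniform
  in_psa: yes
- parameter: clinical.pfs_1yr.chemo
  low: 0.12
  high: 0.235
  dist: beta
  in_psa: yes
- parameter: clinical.pfs_1yr.immuno
  low: 0.2511
  high: 0.3069
  dist: beta
  in_psa: yes
- parameter: clinical.pfs_1yr.chemo_immuno
  low: 0.288
  high: 0.395
  dist: beta
  in_psa: yes
- parameter: clinical.pfs_1yr.targeted
  low: 0.28
  high: 0.52
  dist: beta
  in_psa: yes
- parameter: clinical.os_1yr.chemo
  low: 0.421
  high: 0.562
  dist: beta
  in_psa: yes
- parameter: clinical.os_1yr.immuno
  low: 0.6057
  high: 0.7403
  dist: beta
  in_psa: yes
- parameter: clinical.os_1yr.chemo_immuno
  low: 0.641
  high: 0.738
  dist: beta
  in_psa: yes
- parameter: clinical.os_1yr.targeted
  low: 0.807
  high: 0.899
  dist: beta
  in_psa: yes
- parameter: clinical.p_prog_to_nextline_3mo
  low: 0.432
  high: 0.528
  dist: beta
  in_psa: yes
- parameter: clinical.p_nextline_to_prog_3mo
  low: 0.45
  high: 0.55
  dist: beta
  in_psa: yes
- parameter: gaps.p_second_opinion_sendout
  low: 0.09
  high: 0.11
  dist: beta
  in_psa: yes
- parameter: gaps.p_second_opinion_inhouse
  low: 0.018
  high: 0.022
  dist: beta
  in_psa: yes
- parameter: scenario_proposed.frac_inhouse
  low: 0.5
  high: 1.0
  dist: uniform
  in_psa: no
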