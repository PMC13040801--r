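# Default ecosoc configuration: 4-compartment ring habitat, 8 antennas,
# 6-day protocol of alternating 12 h light / 12 h dark phases
# (adaptation days 1-2, sociability assessment days 3-5, odor test day 6).
topology:
  n_compartments: 4

phases:
  n_days: 6
  light_s: 43200
  dark_s: 43200
  lights_on_first: true

analysis:
  max_transit_s: 30        # gap (s) separating corridor transits from dropouts
  assessment_phases: [dark3, dark4, dark5]
  odor_test_phase: dark6
  odor_baseline_phase: dark5
  stimulus_compartment: C3
  neutral_compartment: C1
  epsilon_s: 1.0           # additive smoothing (s) in the odor-approach ratio
  lfc_threshold: 1.0       # |log2 fold change| must exceed this (strict)
  fdr_threshold: 0.05      # adjusted p must be below this (strict)

simulation:
  n_mice: 12
  leave_rate_dark: 0.003333333333333333   # 1/300 s^-1
  leave_rate_light: 0.001111111111111111  # 1/900 s^-1
  kappa_stay: 1.0
  kappa_dest: 1.0
  transit_s: 2.0
  p_miss: 0.0
  seed: 1
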