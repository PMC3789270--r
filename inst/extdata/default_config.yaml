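network:
  scale: 0.1
  seed: 1.0
  sizes:
    pc7a: 1000.0
    l3e: 2585.0
    l3i: 729.0
    l5e: 606.0
    l5i: 133.0
    mote: 1000.0
    moti: 250.0
    mdsc: 1000.0
    bg: 1000.0
  p_within:
    l3e_l3e: 0.3584
    l3e_l3i: 0.1008
    l3i_l3e: 0.1552
    l3i_l3i: 0.1371
    l5e_l5e: 0.0758
    l5e_l5i: 0.0566
    l5i_l5e: 0.3765
    l5i_l5i: 0.3158
  p_between: 0.1
  weight_compensation: linear
  normalize_in_degree: yes
  weights:
    pc_l3: 0.006
    pc_l3i: 0.0003
    rec_l3: 0.00025
    l3_ei: 0.0003
    l3_ie: 0.0008
    l3_ii: 0.0003
    lat_ee: 0.00017
    lat_ei: 0.0008
    l5_ee: 0.001
    l5_ei: 0.001
    l5_ie: 0.004
    l5_ii: 0.002
    mdsc_l5: 0.006
    l5_bg: 0.006
    bg_l3: 0.002
    l3_mot: 0.0022
    mot_ei: 0.003
    mot_ie: 0.012
    ext_pc: 0.12
    ext_mdsc: 0.3
condition:
  da: optimal
  ne: optimal
task:
  trial_ms: 6000.0
  fixation_ms: 1000.0
  cue_ms: 500.0
  delay_ms: 2500.0
  response_onset_ms: 4000.0
  cd_rate_hz: 40.0
  cd_ms: 500.0
  bg_rate_hz: 15.0
  cue_rate_hz: 150.0
  cue_direction: 0.0
  n_trials: 50.0
  background_all_phases: yes
modulation:
  modulate_l3_inhibitory: no
analysis:
  delay_start_ms: 1700.0
  delay_end_ms: 4000.0
  decision_window_ms: 500.0
  bin_ms: 10.0
  smooth_bins: 5.0
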