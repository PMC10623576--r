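name: condensate_dry
compounds:
- name: d6-acetone
  mz: 65.086803466879999
  gas_phase_basicity: 782.100000000000023
  role: suppressor
  ppm: .na.real
  channel_fraction: .na.real
  parent: .na.character
- name: d6-acetone_hydrate
  mz: 83.097368066879994
  gas_phase_basicity: 782.100000000000023
  role: channel
  ppm: .na.real
  channel_fraction: 0.5
  parent: d6-acetone
- name: d6-acetone_dimer
  mz: 129.166330466879998
  gas_phase_basicity: 782.100000000000023
  role: channel
  ppm: .na.real
  channel_fraction: 0.15
  parent: d6-acetone
- name: feature_088
  mz: 88.037219040794298
  gas_phase_basicity: 771.944449699949473
  role: constant
  ppm: 9.913004074468326e-05
  channel_fraction: .na.real
  parent: .na.character
- name: feature_097
  mz: 96.886283669853583
  gas_phase_basicity: 762.419473472982645
  role: constant
  ppm: 0.000526498211037
  channel_fraction: .na.real
  parent: .na.character
- name: feature_114
  mz: 113.546829158207402
  gas_phase_basicity: 770.116647789254785
  role: constant
  ppm: 0.0002933351084
  channel_fraction: .na.real
  parent: .na.character
- name: feature_141
  mz: 141.381246569566429
  gas_phase_basicity: 779.716713319066912
  role: constant
  ppm: 0.000297581263738
  channel_fraction: .na.real
  parent: .na.character
- name: feature_141
  mz: 140.566343852318823
  gas_phase_basicity: 758.301231280202046
  role: constant
  ppm: 0.000480919828741
  channel_fraction: .na.real
  parent: .na.character
- name: feature_144
  mz: 144.40804729424417
  gas_phase_basicity: 772.210582746192813
  role: constant
  ppm: 0.000452321437593
  channel_fraction: .na.real
  parent: .na.character
- name: feature_121
  mz: 120.846216776408255
  gas_phase_basicity: 777.714683088706806
  role: constant
  ppm: 0.000403724669814
  channel_fraction: .na.real
  parent: .na.character
- name: feature_118
  mz: 118.21646564360708
  gas_phase_basicity: 752.424988244893029
  role: constant
  ppm: 0.000474979269755
  channel_fraction: .na.real
  parent: .na.character
- name: feature_071
  mz: 71.12826044880785
  gas_phase_basicity: 767.808581813005731
  role: constant
  ppm: 0.0004435677823
  channel_fraction: .na.real
  parent: .na.character
- name: feature_081
  mz: 80.654210459906608
  gas_phase_basicity: 749.39442835864611
  role: constant
  ppm: 0.000311395860568
  channel_fraction: .na.real
  parent: .na.character
- name: feature_123
  mz: 123.022896272595972
  gas_phase_basicity: 754.352723405463621
  role: constant
  ppm: 0.000110952993177
  channel_fraction: .na.real
  parent: .na.character
- name: feature_098
  mz: 97.880608611740172
  gas_phase_basicity: 758.513993239030242
  role: constant
  ppm: 0.000408991898838
  channel_fraction: .na.real
  parent: .na.character
levels:
- 0.0
- 0.011
- 0.034785054261852
- 0.11
- 0.347850542618522
- 1.1
- 3.478505426185218
- 11.0
condition: dry
windows:
- lower: 60.0
  upper: 90.0
- lower: 90.0
  upper: 120.0
- lower: 120.0
  upper: 150.0
program:
  on_duration: 30.0
  off_duration: 30.0
  n_pulses: 3
  washout_time_constant: 3.0
  lead_in: 10.0
params:
  beta: 20.0
  gamma: 2.0
  c50_dry: 0.01
  c50_humid: 15.0
  humid_sensitivity_ratio: 10.0
scan_period: 0.5
resolution: 140000.0
noise:
  baseline_sd: 100.0
  cv: 0.05
response_coefficient: 100000000000.0
seed: 1
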