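name: binary_dry
compounds:
- name: d3-acoh
  mz: 64.047236466879994
  gas_phase_basicity: 752.799999999999955
  role: constant
  ppm: 0.0007
  channel_fraction: .na.real
  parent: .na.character
- name: d6-acetone
  mz: 65.086803466879999
  gas_phase_basicity: 782.100000000000023
  role: suppressor
  ppm: .na.real
  channel_fraction: .na.real
  parent: .na.character
levels:
- 0.0
- 0.011
- 0.034785054261852
- 0.11
- 0.347850542618522
- 1.1
condition: dry
windows:
- lower: 64.0
  upper: 66.0
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
scan_period: 1.0
resolution: 140000.0
noise:
  baseline_sd: 100.0
  cv: 0.05
response_coefficient: 100000000000.0
seed: 1
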