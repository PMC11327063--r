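# Example simulation scenario for the command-line front end:
#   scedr simulate --scenario example_scenario.yaml --out-edf rec.edf
#
# Keys mirror the arguments of sim_scenario(); see ?sim_scenario.
duration_s: 600
hr_baseline: 70          # bpm
rsa_amplitude: 2         # bpm, RSA modulation depth
br_trajectory:           # piecewise-linear breathing rate, bpm (9-27)
  - {time_s: 0, br_bpm: 15}
  - {time_s: 300, br_bpm: 13}
  - {time_s: 600, br_bpm: 16}
interferers:             # transient in-band sinusoids
  - {start_s: 285, stop_s: 315, freq_hz: 0.35, amplitude_bpm: 4}
apnea_windows: []        # e.g. [{start_s: 400, stop_s: 430}]
lf_noise_amp: 1          # bpm, slow sympathetic-like drift
lf_drift_hz: 0.03
noise_sd_bpm: 0.3
sample_rate_hz: 20
seed: 1
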