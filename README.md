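# scedr — spectral-continuity ECG-derived respiration from heart rate

Breathing rate is a vital sign that is rarely monitored because measuring it
directly (nasal-pressure flow meters, respiration belts) is invasive or
impractical. Respiratory sinus arrhythmia (RSA) — the breathing-synchronous
modulation of heart rate — offers a way out: breathing writes a narrow-band
component at the breathing frequency f_BR into the heart-rate signal, and
heart rate is available from any ECG lead or even a wrist PPG sensor.

The catch is that the breathing band (0.15–0.45 Hz, i.e. 9–27 breaths/min)
also hosts transient non-respiratory components that can briefly outpower
the RSA ridge. Classical spectral EDR ("max-power") picks the strongest peak
per time slice and is derailed by every such transient. **scEDR** instead
exploits the one property that distinguishes the RSA component — it is
present *all the time* — and selects the **longest-lasting continuous track**
of spectral peaks in the heart-rate time–frequency plane:

1. heart rate from R–R intervals (HR = 60/RR), gridded at 20 Hz;
2. generalized Morse wavelet transform (γ = 3, β = 90; grid 0.05–0.45 Hz in
   0.02-Hz steps, 50-ms slices);
3. per slice, local power maxima in 0.15–0.45 Hz kept if ≥ 20 % of the
   slice's maximum power over the wider 0.05–0.45 Hz spectrum;
4. peaks of similar frequency (≤ 1 bin jump) linked across slices into
   tracks; the longest track is the breathing component; dropouts (apnea)
   are bridged and rejoined; BR = 60 · f(t);
5. optionally, a breathing waveform is reconstructed by the inverse wavelet
   transform over a ±0.015 Hz window around the extracted frequency.

The package provides the whole validation tool-chain: a synthetic
cardiorespiratory generator with known ground truth (RSA-modulated heart
rate, matched flow signal, stereotyped ECG, interferers, apnea), R-peak
detection, crest-based gold-standard breathing rate from pressure-flow
channels, epoch-wise error tables (error = |BR_EDR − BR_pressure|,
%error = 100 · error / BR_pressure, per 30-s sleep-stage epoch), HRV band
powers and LF/HF, VLF/HF ratios, the HRV/GFP-threshold REM0 sleep-stage
reassignment, minimal EDF I/O, and a command-line front end
(`exec/scedr`, subcommands `simulate`, `preprocess`, `tfa`, `scedr`,
`maxpower`, `evaluate`, `hrv-bands`, `rem0`, `report`).

## Worked example

Ten minutes of synthetic sleep at 15 breaths/min with a 30-s interferer at
0.35 Hz and twice the RSA amplitude (labelled REM here), evaluated against
the simulated flow channel:

```r
library(scedr)

sc <- sim_scenario(duration_s = 600, hr_baseline = 70, rsa_amplitude = 2,
                   br_trajectory = 15,
                   interferers = data.frame(start_s = 285, stop_s = 315,
                                            freq_hz = 0.35, amplitude_bpm = 4),
                   seed = 42)
sim <- simulate_heart_rate(sc)
brp <- br_from_flow(simulate_flow(sim$truth, sc), duration_s = 600)
map <- tfa_heart_rate(sim$hr)
res <- scedr(map, reconstruct = TRUE)
mp  <- maxpower_edr(map)

hy <- hypnogram(rep(c("N2", "REM", "N2"), c(9, 2, 9)))
stage_summary(epoch_errors(res$br, brp, hy))
#>          stage mean_error sd_error mean_pct_error sd_pct_error n_epochs method
#> 1           N2    0.01698  0.01484         0.1133       0.0992       18  scedr
#> 2          REM    0.00605  0.00328         0.0403       0.0218        2  scedr
#> 3 whole record    0.01589  0.01446         0.1060       0.0966       20  scedr
stage_summary(epoch_errors(mp$br, brp, hy))
#>          stage mean_error sd_error mean_pct_error sd_pct_error n_epochs method
#> 1           N2      0.017   0.0148          0.113       0.0992       18 maxpower
#> 2          REM      2.949   0.3291         19.651       2.1886        2 maxpower
#> 3 whole record      0.310   0.9057          2.067       6.0354       20 maxpower
```

During the interferer the max-power baseline jumps to the stronger transient
(mean error 2.95 bpm, ~20 %), while scEDR keeps riding the persistent RSA
track (0.006 bpm). Both methods agree to within the 0.02-Hz frequency bin
elsewhere. The reconstructed breathing signal correlates with the true RSA
component at r = 0.999 on interior slices:

```r
cor(res$reconstructed[1000:11000], sim$truth$rsa_component[1000:11000])
#> [1] 0.9990
```

`whole_record_report()` draws the four-panel overview (2-s moving-average
heart rate; gold-standard vs extracted breathing rate; hypnogram with REM
boundary markers; per-epoch %error against the 5 % reference line).

See `vignettes/scedr-methods.Rmd` for the model, the tunable parameters and
the design choices, including what the synthetic generator does and does not
emulate.

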