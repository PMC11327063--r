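---
title: "Extracting breathing rate from heart rate by spectral continuity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting breathing rate from heart rate by spectral continuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedr)
```

## The physiological signal model

Respiratory sinus arrhythmia (RSA) — heart rate rising on inhalation and
falling on exhalation through vagal modulation of the sinus node — writes the
breathing rhythm into the heart rate as a narrow-band component at the
breathing frequency $f_{BR}$. For breathing rates between 9 and 27 breaths
per minute this component lives in the 0.15–0.45 Hz band of the heart-rate
signal. The band is crowded: parasympathetic modulation, movement artifacts
and measurement noise all visit it. The property that singles out the RSA
component is not its power but its *persistence*: competing components are
short, intermittent events, while breathing modulates every beat of every
minute. scEDR (spectral-continuity ECG-derived respiration) turns that
observation into an algorithm.

The pipeline is:

1. **Heart rate from the ECG.** R peaks are detected (band-pass 5–25 Hz,
   derivative, squaring, 150-ms integration, adaptive threshold, 250-ms
   refractory period); the instantaneous rate $HR = 60/\mathrm{RR}$ of each
   R–R interval is placed at the interval midpoint and interpolated to a
   uniform 20-Hz grid with a monotone piecewise-cubic scheme
   (`hr_from_beats()`). Monotone interpolation cannot overshoot, so the
   gridding adds no spurious spectral content. R–R intervals outside
   0.27–3 s are treated as artifacts and bridged rather than deleted,
   because the wavelet analysis needs an unbroken uniform grid.
2. **Time–frequency map.** A continuous wavelet transform with generalized
   Morse wavelets, $\Psi(\omega) \propto \omega^\beta e^{-\omega^\gamma}$
   for $\omega > 0$, with $\gamma = 3$ and $\beta = 90$
   (`cwt_morse()`). $\gamma = 3$ gives a Gaussian-like envelope; the
   time–bandwidth product $\beta\gamma = 270$ trades time resolution
   (envelope SD $\sigma_t = \sqrt{\beta\gamma}/2\pi f \approx 10$ s at
   0.25 Hz) for the frequency selectivity
   ($\sigma_f = f/\sqrt{\beta\gamma} \approx 0.015$ Hz at 0.25 Hz) needed to
   separate breathing from its neighbours on a 0.02-Hz grid. The map is
   evaluated on an inclusive 0.05–0.45 Hz grid in 0.02-Hz steps with a
   50-ms time slice.
3. **Per-slice peaks.** In every slice the local maxima of power within the
   0.15–0.45 Hz search band are kept if they reach 20 % of the slice's
   maximum power over the wider 0.05–0.45 Hz spectrum
   (`extract_slice_peaks()`). Computing the threshold over the wider band
   deliberately discards breathing-band peaks that are small relative to
   slower autonomic activity.
4. **Continuity linking.** Peaks of adjacent slices whose frequencies differ
   by at most one bin (0.02 Hz) are chained into tracks; a track survives
   dropouts up to 2 s (40 slices) (`build_tracks()`). The tolerance encodes
   that physiological breathing drifts far slower than one bin per 50-ms
   slice.
5. **Selection.** The longest-lasting track is the breathing component; ties
   go to the higher mean power (`select_breathing_track()`). Where the
   winning track drops out (apnea, artifacts), a candidate track starting
   within 60 s whose frequency is closest to the last valid value is
   appended; anything still uncovered holds the last valid frequency and is
   flagged `gap-bridged`. Breathing rate is $60 f(t)$.
6. **Reconstruction.** A breathing-like signal is rebuilt by the band-limited
   inverse transform over bins within ±0.015 Hz of the extracted frequency
   (`inverse_cwt_band()`), i.e. from the RSA ridge only, not the whole HF
   band.

The max-power baseline (`maxpower_edr()`) shares steps 1–3 and then simply
takes the strongest significant peak per slice. Any transient that briefly
outpowers the RSA ridge drags it away, which is exactly the failure mode the
continuity constraint removes; the package's tests reproduce this contrast
quantitatively.

## Numerical choices

**Wavelet normalization.** The frequency-domain filter is peak-normalized to
2 ("bandpass" normalization), so a unit tone yields a unit-amplitude
analytic ridge at every analysis frequency and ridge amplitudes are
comparable across bins.

**Edge handling.** The record is zero-padded (to a fast FFT length covering
the slowest wavelet) and each bin flags slices closer than 1.5 envelope
e-folding times ($\approx 2.1\sigma_t$) to either record edge as inside the
cone of influence. Additionally no peaks at all are extracted in slices
within the search band's worst-case cone of influence (≈ 37 s at 0.15 Hz) of
an edge: inside that buffer the breathing bins are masked, and the relative
threshold would otherwise be set by truncation residue in the remaining
high-frequency bins, spawning fake edge tracks. A consequence is that
records must comfortably exceed ~75 s to be analyzable; the edge buffer is
exposed as an argument for slice-local analysis of interior data.

**Whole-record linking.** Tracks are built in one linear greedy pass over
the whole record rather than in overlapping windows that are stitched
afterwards. The pass keeps only the open track heads in memory, so windowing
would bound nothing while adding a second tie-break surface at every stitch
boundary.

**Greedy vs. globally optimal paths.** The linker is sequential by design:
each open track extends to the nearest-frequency compatible peak of the next
slice, each peak joins at most one track, conflicts resolve by smallest
jump (ties: older track, then lower frequency — all deterministic). The test
suite compares it against an exhaustive longest-path oracle over the linking
DAG (edges into the next compatible slice). In the method's operating
regime — ridge drift far below one bin per slice, interferers at least two
bins away — the greedy result matches the oracle. On deliberately dense
adversarial grids (several peaks on adjacent bins, ridge hopping a full bin
per slice) the sequential linker can be myopic and lose a few slices of
track length to the oracle; this regime is outside the physiological
assumptions, and the suite checks it only for the sanity bound
greedy ≤ oracle.

**PSD scaling for band powers.** Wavelets are constant-Q, so raw wavelet
power grows with frequency for broadband input. `tfa_psd()` divides each
bin's power by its filter energy, making the estimate an unbiased one-sided
PSD for white noise: band integrals (VLF 0.004–0.05, LF 0.05–0.15,
HF 0.15–0.40 Hz) are then directly comparable, and white noise yields
LF/HF equal to the bandwidth ratio 0.4 — a calibration the acceptance tests
verify by Monte Carlo. Band powers are averaged over 90-s windows centered
on each 30-s epoch; VLF periods reach 250 s, so VLF values are
partial-cycle estimates and are labelled as such.

## The REM0 reassignment

Sleep staging by EEG hallmarks leaves a putative stage invisible: epochs
with NREM-like slow EEG but REM-like heart-rate surges. The reassignment
(`reassign_rem0()`) uses two per-epoch variability series — heart rate and
EEG Global Field Power (the across-channel SD at each sample) — thresholded
at a percentile (default 95th) of the pre-sleep eyes-closed-awake epochs:
epochs with HR variability at or below threshold keep the expert label;
above it, high GFP variability ⇒ `REM0`, low ⇒ `REM`. The within-epoch SD is
the reference variability statistic; both the statistic and the percentile
are configurable, since different operationalizations exist in the
literature. Reassignment provably never touches an epoch whose HR
variability is below threshold — a property the tests check on randomized
epoch tables.

## The synthetic generator and what passing tests mean

No public PSG recording ships with this package; every test input comes
from `sim_scenario()`/`simulate_heart_rate()`, which generate the signal
model the method assumes, with known ground truth:

$$HR(t) = HR_0 + A_{RSA}\sin\!\Big(2\pi\!\int_0^t f_{BR}\Big)
  + \textstyle\sum_k I_k(t) + A_{LF}\sin(2\pi f_{LF}t+\theta) + \epsilon(t)$$

* breathing trajectory $f_{BR}(t)$ confined to 9–27 bpm (the extractor's
  representable band) — constants, piecewise-linear ramps, or functions;
* RSA depth 2 bpm by default (a mid-range physiological value; the true
  depth varies across subjects and ages and is a free parameter here);
* transient interferers, by default twice the RSA amplitude for 30 s and at
  least two bins from the breathing frequency — strong enough to capture
  the max-power baseline while continuity holds;
* a slow LF drift (1 bpm at 0.03 Hz) and optional white noise;
* apnea windows where the RSA term and the flow signal vanish;
* a matched flow signal $\sin(2\pi\int f_{BR})$ with exactly one crest per
  breath, and a stereotyped ECG whose beats come from integrate-and-fire on
  $HR(t)$ (so the R–R sequence encodes the RSA exactly) with 80-ms
  raised-cosine QRS spikes.

Everything is deterministic given the scenario seed. What the generator does
*not* emulate: realistic ECG morphology (P/T waves, ectopy), amplitude-
modulated or non-sinusoidal flow shapes, baseline wander, body-movement
artifacts beyond additive transients, and subject-to-subject variability.
Passing tests therefore demonstrate that the algorithm implements its
specification and behaves as designed *under its own signal model*;
accuracy numbers on real polysomnography must come from real recordings and
are intentionally not claimed by the test suite.

Problem sizes used by the tests and the acceptance script are desk-scale by
choice: records of 5–30 minutes at 20 Hz, 21–103 analysis frequencies, 100
Monte-Carlo replicates where distributions are checked. All results scale
to whole-night records; the linking pass is linear in record length.

## Known limitations

* Frequency resolution is the 0.02-Hz bin: a constant true rate between two
  bins reads back up to 0.6 bpm off. The tracking tolerance inherits this.
* Records shorter than about twice the 37-s edge buffer cannot be analyzed,
  and the first/last ~37 s are always bridged rather than tracked.
* During true apnea the method reports the last valid breathing frequency
  flagged `gap-bridged`; it estimates rate, it does not score apnea events.
* The REM0 thresholds require scored eyes-closed-awake epochs before sleep
  onset; without them the reassignment refuses to run.
* Max-power and scEDR share the peak extraction, so a component that is
  both *persistent* and stronger than breathing (e.g. sustained
  oscillatory artifact inside the band) defeats both.
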