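---
title: "cltus: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cltus: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cltus)
```

# Overview

`cltus` simulates and analyzes closed-loop transcranial ultrasound
stimulation (CLTUS) of hippocampal circuits. The package has two online
controllers — theta phase-locked stimulation and responsive anti-seizure
stimulation — plus the supporting pieces: LFP I/O (CSV and EDF), a
linear-phase FIR theta filter with peak/trough prediction, an H/CL seizure
detector, Parseval-exact STFT band-power outcome metrics, seeded synthetic
LFP generators with ground truth, and acoustic dosimetry bookkeeping. Every
loop runs deterministically from a seed, so paired closed-loop versus sham
comparisons are bitwise-fair: the two arms see identical data until the first
stimulus would have acted.

# Theta phase targeting

## Filter design

The theta band-pass is a Hamming-window FIR filter over 4–12 Hz. The kernel
length follows the Hamming transition-width rule
$L = \lceil 3.3 f_s / \Delta f \rceil$ with a 4 Hz transition, rounded up to
odd — 825 taps at 1 kHz — so the group delay $(L-1)/(2f_s) = 0.4125$ s is an
integer number of samples. The designed taps are symmetrized exactly
(`(coef + rev(coef))/2`, a sub-ulp correction) so the filter has exactly
linear phase and extremum times can be corrected by a pure shift.

```{r}
k <- design_bandpass(filter_spec(4, 12, 4), fs = 1000)
k$length
k$group_delay_s
fir_response(k, c(2, 4, 8, 12, 20))
```

Online filtering uses centered ("valid") convolution, which is equivalent to
causal filtering followed by group-delay subtraction: the most recent usable
filtered sample lies `group_delay_s` before the end of the buffer. Buffers
too short for that fall back to circular FFT filtering, exact for
integer-cycle content.

## Cycle estimation and prediction

`estimate_theta_cycles()` locates peaks and troughs of the filtered trace
(strict sign change of the first difference, parabolic sub-sample
refinement), accepts inter-extremum intervals inside the period thresholds
0.08–0.25 s, and requires at least three accepted same-type intervals. The
average accepted interval is the period estimate $A_p$; the mean
absolute difference between adjacent opposite extrema is the peak-to-peak
amplitude used by the amplitude gate.

`predict_phase_time()` computes the wait from the buffer end to the next
target extremum as $A_p - t_c - t_\mathrm{last}$, where $t_c$ is the
processing delay and $t_\mathrm{last}$ the time since the last observed
target extremum. Because the group delay (0.4125 s) exceeds several theta
periods, the newest knowable extremum is cycles in the past, so non-positive
waits are advanced whole cycles ($+A_p$ per skip). When a predicted trigger
falls inside the post-stimulus refractory period (stimulus duration + 1 s),
the controller advances it by at most one further cycle; longer
extrapolation degrades accuracy when the rhythm drifts, so later iterations
re-predict from fresher data instead.

The amplitude gate is either an absolute threshold (`amp_threshold_uv`, the
externally calibrated value an experimenter would set with theta present) or,
by default, `amp_threshold_frac` (0.5) times the median filtered
peak-to-peak amplitude over the first 10 s of the recording.

```{r, eval = FALSE}
ses <- theta_session(theta_model(), duration_s = 60, seed = 1)
run <- run_phase_mode(ses, target = "peak")
err <- phase_error_deg(ses$truth(), run$triggers$time_s, "peak")
mean(abs(err) <= 45)
```

# Seizure detection

Two per-window statistics are computed over 1 s windows hopping 0.5 s: the
population standard deviation of the amplitude,
$H = \sqrt{\tfrac{1}{n}\sum_i (x_i - \bar x)^2}$, and the coastline
(line-length) coefficient, the mean absolute first difference
$CL = \tfrac{1}{n-1}\sum_i |x_i - x_{i+1}|$. The baseline for each is the
median over a seizure-free calibration interval (default first 30 s). A
window is flagged when **both** $H \ge 3 \times H_\mathrm{base}$ and
$CL \ge 2 \times CL_\mathrm{base}$ (inclusive). A flag emits a trigger
carrying the anti-seizure protocol, followed by a lockout of the stimulation
duration plus 5 s; the detected seizure ends after both ratios stay below
threshold for two consecutive windows.

# Spectral outcomes

`stft_power()` is a one-sided short-time Fourier power map using a
1000-point Hamming window with 50% overlap, scaled so that the power column
of each frame sums exactly to the energy of the windowed frame (Parseval;
factor 2 on all bins except DC and Nyquist, divided by $N$). Absolute power
(AP) in a band is the inclusive bin sum; relative power (RP) divides by the
1–200 Hz total, so RP is in $[0, 1]$ and RPs over a partition of 1–200 Hz
sum to 1.

Per-trigger outcomes average AP and RP over a pre-window $[-1, 0]$ s before
stimulation start and a post-window $[0, 3]$ s after stimulation end (MAP /
MRP), giving percent changes dAP and dRP. One subtlety matters: an STFT
frame is supported on a 1 s interval around its center, so a frame centered
just before the trigger already contains post-stimulus samples.
`stim_response_metrics()` therefore only uses pre-window frames whose
support ends before the trigger; without this guard the "pre" mean is
contaminated by the response it is supposed to be the control for. For the
same reason, response analyses should use triggers at least 5 s apart
(`thin_triggers()`), so each trial's $[-1, +3.4]$ s analysis span contains
no other stimulus and the previous trial's exponential response has decayed
to $e^{-4.6/1.5} \approx 4.6\%$.

# Synthetic LFP generators

The theta generator is a frequency-drifting sinusoid (6–10 Hz, sinusoidal
drift with a 60 s period, 100 µV amplitude) over 1/f noise at 10 dB SNR in
the theta band, with an exact unwrapped-phase oracle. A stimulus multiplies
theta amplitude by 1.5 and adds broadband 20–200 Hz noise at 3 times the
background RMS, both decaying exponentially with $\tau = 1.5$ s — so
absolute theta power rises while relative theta power falls, matching the
reported direction.

The TLE generator draws seizure latencies from $N(74, 12^2)$ s and durations
from $N(74, 15^2)$ s, renders seizures as 5 Hz spike-wave discharges
(300 µV spikes, 5× baseline amplitude). A stimulus delivered during a
seizure terminates it 5 s later and delays the next onset by
$0.8 \times 74$ s. Generators are stateful "sessions": samples are a pure
function of (seed, applied trigger set), which is what makes the sham arm an
exact counterfactual.

# Closed-loop experiment

`run_experiment()` runs paired closed-loop and sham arms per seed and
summarizes per-arm mean seizure latency and duration (latency measured from
the previous seizure's offset). The package's synthetic acceptance check is
directional — closed-loop latency longer and duration shorter than sham —
not a reproduction of any in-vivo effect size.

```{r, eval = FALSE}
ex <- run_experiment(seeds = 1:10, duration_s = 600)
experiment_summary(ex)
```

# Dosimetry

Plane-wave intensities and the mechanical index from the protocol
parameters:

```{r}
isppa_from_pressure(0.23) # W/cm^2 at rho = 1000, c = 1500
ispta(1.75, 0.40) # mW/cm^2
mechanical_index(0.23, 0.5)
exposure_summary(protocol_neuromodulation())
exposure_summary(protocol_antiepileptic())
```

Two published figures do not match these definitional products and are
surfaced here rather than asserted: an I_spta of 66.5 mW/cm² has been quoted
for the 5% duty protocol where I_sppa × duty gives 87.5 mW/cm², and an MI of
0.28 where pressure/√frequency gives 0.325 (consistent with a derated
pressure). The package computes the definitional values.

# Limitations

No acoustic field simulation, transcranial attenuation, or thermal index;
single-channel recordings; the synthetic generators are deliberately simple
(sinusoidal theta, spike-wave trains) and support algorithmic validation,
not biological inference.
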