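---
title: "Mapping anesthesia depth states from EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping anesthesia depth states from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `anesmap`, the parameters that
matter and their defaults, the numerical choices made where several
implementations were defensible, what the synthetic-data generator does
and does not emulate, and the known limitations. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R`
themselves compute.

## The signal model

A single-channel cortical EEG during isoflurane anesthesia is treated as a
sum of

1. an **aperiodic background** whose one-sided power spectral density
   follows $a/(c+f^{p})$ — the broadband "1/f" trend of spontaneous
   cortical activity. The offset $c$ (in Hz$^p$) makes the model finite at
   $f=0$, which matters because the fit is carried down to 0.2 Hz where a
   pure power law diverges;
2. **narrow-band rhythms** — θ (~8 Hz, present awake, decaying in
   frequency after induction) and δ (~3 Hz, appearing under anesthesia) —
   modeled in the spectral domain as Gaussians
   $b\exp(-(f-f_0)^2/2\sigma^2)$;
3. **iso-electric suppressions (IES)**: epochs where cortical activity
   collapses and the trace is nearly flat;
4. during recovery after deep anesthesia, a narrow-band ~60 Hz
   **γ-rebound** organized in bursts.

## Suppression detection

"Amplitude" is the pointwise absolute value of the raw (or band-passed)
signal. A suppression is a maximal run with $|S(t)| < T$ lasting at least
`min_dur_s = 1` s; detected suppressions closer than `merge_gap_s = 0.5` s
are then merged.

*Order of the two rules.* The duration filter runs **before** the merge.
The alternative order (merge first, filter after) would let the sub-100 ms
dips that any ongoing oscillation shows at its zero crossings act as
"detections", be bridged by the 0.5 s merge, and flood the recording; with
filter-first, those dips can neither survive nor bridge anything, and a
continuous oscillation above threshold produces no suppression at all.

*Thresholds.* $T_{IES} = r_{IES}\,\mathrm{RMS}_{EEG}$ with
$r_{IES} = 0.7$, and $T_{\theta S} = T_{\delta S} = 0.2\,\mathrm{RMS}_{EEG}$,
where $\mathrm{RMS}_{EEG}$ is the root mean square of the whole unmasked
recording. The relative threshold absorbs inter-individual amplitude
differences; `sweep_ies_threshold()` exposes the duration-vs-threshold
curve whose plateau marks a robust choice. A floor of 0.01 µV keeps the
threshold positive on degenerate all-flat input, in which case the whole
recording is one suppression. An optional baseline-only mode computes the
reference RMS on the pre-induction segment, the variant a real-time
implementation would use. Band suppressions have IES segments removed by
interval difference, so the θS/δS lists never intersect IES.

*Sensitivity limit.* With the pointwise-amplitude definition, a band
suppression is only detectable when the in-band noise floor stays clearly
below $0.2\,\mathrm{RMS}_{EEG}$ for whole seconds. When broadband
background power inside the band approaches that threshold, coverage
drops — the detector is conservative rather than wrong. The bundled
scenarios operate in this regime for θS (their background is deliberately
realistic rather than silent), which is why the package's θS tests use a
dedicated low-background construction.

## Windowed ratios and prominence

Suppression ratios (IESSR, θSR, δSR) are overlap fractions on 20 s
windows with 10 s overlap; band-power ratios $P_\theta, P_\delta$ use
20 s windows without overlap, dividing band power (Butterworth order 1
applied forward–backward, i.e. zero phase) by the < 20 Hz power. A rhythm
is *prominent* at $t$ when its ratio exceeds its threshold
($T_\theta = 0.1$, $T_\delta = 0.15$) on every window in $[t, t+1\,$min$]$;
dampening is the symmetric condition. Per-window prominence *flags* (used
by the state labeling) apply these two rules with hysteresis, so a ratio
oscillating around its threshold cannot flicker states. A persistence
condition is only evaluated where the grid actually covers the horizon;
the tail of a recording shorter than the horizon can neither assert nor
refute it. Windows more than half masked by artifacts are missing and
break persistence runs.

The strong-IES onset $\tau_S$ is the first time after induction with
IESSR > 0.25 on all windows spanning 40 s. Because window centers are
10 s apart, detected event times are quantized; all bundled-scenario
tests budget one grid step per event (30 s for the spectral-frame events,
20 s for prominence events, 10 s for ratio events).

## Spectral decomposition

Per 60 s window (30 s step):

1. **Welch PSD**, 5 s Hann sub-windows, 50% overlap, kept on 0.2–15 Hz
   (0.2 Hz resolution). The sub-window overlap and taper are not dictated
   by the method definition; 50%/Hann is the standard variance-reduction
   choice and preserves the 0.2 Hz grid.
2. **IRASA**: the window is resampled by factors $h$ and $1/h$,
   $h = 1.1, 1.15, \dots, 1.9$; oscillatory peaks move with $h$ while the
   self-affine fractal part is invariant, so the pointwise median over the
   geometric means $\sqrt{PSD_h \cdot PSD_{1/h}}$ estimates the fractal
   component. Resampling is done by Fourier zero-padding/truncation
   (band-limited, no filter-design error), with target lengths nudged to
   7-smooth integers so the transforms stay fast; the realized factor is
   the rational $m/n$, within 0.2% of the nominal $h$.
3. **Aperiodic fit**: nonlinear least squares of $\log PSD_m$ against
   $\log(a/(c+f^p))$ with $a>0$, $c\ge 0$, $p\ge 0$. The amplitude is
   profiled out in closed form; $(c,p)$ are optimized by bounded
   L-BFGS-B from three starting offsets, initialized at the log–log slope.
   Fit failure marks the frame missing.
4. **Oscillatory fit**: the residual (raw PSD minus the aperiodic model,
   negative values clipped to zero — the residual is a power) is fitted on
   1–15 Hz by up to four Gaussians seeded at residual peaks of height at
   least one residual standard deviation, with bounded parameters
   ($f \in [1,15]$, $\sigma \in [0.1,3]$). Components with
   $\sigma \notin [0.2, 2]$ Hz or $b \le \mathrm{std}(\text{residual})$
   are discarded.
5. **Band selection**: at most one component per band; membership is θ
   4–10 Hz and δ 2–4 Hz (half-open at 4 Hz, which belongs to θ), the
   largest area $b\sigma$ wins, ties break toward the band median
   frequency (7.5 / 3 Hz) and then toward the lower center frequency, so
   selection is deterministic.

*A known interaction.* The IRASA median is contaminated on the
"shoulders" where a scaled copy of a spectral peak lands: at such
frequencies the geometric mean is of order
$\sqrt{\text{peak}\times\text{background}}$, i.e. the contamination ratio
grows as the square root of the peak-to-background ratio. For rhythms up
to a few tens of times the local background — the regime of the bundled
scenarios and of typical EEG — the aperiodic fit is essentially unbiased;
for extreme peaks on very steep spectra the fitted exponent is biased
low. The package's exponent-recovery study therefore plants rhythms at a
fixed ~40× local prominence, comfortably above the amplitude-pruning
floor and below the contamination regime.

## Rhythm tracking and the θ decay

Frame-wise detections are linearly interpolated (center frequency and
width) between consecutive frames; a detection whose two neighbors are
both empty is considered not significant and dropped. The envelopes
$f\pm\sigma$ follow the interpolated parameters.

The θ-decay onset is the first frame center $t$ after induction with
$f_\theta(t') < f_\theta(t)$ for **all** tracked frames
$t' \in (t, t+5\,$min$]$. Frames without a θ detection are skipped rather
than treated as violations, and a candidate whose 5 min horizon extends
past the last frame is unverifiable and cannot be the onset. Because the
condition compares against *later* values only, the onset lands on the
last frame of the pre-decay plateau when the decay begins between frame
centers — up to one 30 s step early, which slightly flattens the slope.
The slope is the least-squares slope of the tracked frequency over the
2 min after the onset (three frames minimum), reported in Hz/min.

## γ-rebound

γ power is the mean squared 50–70 Hz band-passed signal on contiguous
0.2 s windows. The threshold is $3\times$ the RMS of the γ-power series
over the pre-induction baseline. Because the rebound is a train of
intermittent bursts rather than a continuous tone, strict pointwise
persistence would never trigger: sub-threshold gaps shorter than 1 s
(configurable) are tolerated inside a run, and a rebound requires a
merged run of at least 2 min after anesthetic cessation. The area
$A_\gamma$ is the trapezoidal integral of the power series from cessation
to the end of the recording.

## Event chain and state chart

The assembled events are checked against
$\tau_{Isostart} < \tau_{\theta decay} < \tau_{\delta app} <
\tau_{\theta disp} < \tau_{\delta disp} < \tau_S < \tau_\gamma$
over the *present* events; because the times live on different grids, an
adjacent pair only counts as violated beyond a one-window (20 s)
tolerance.

State labeling is a pure decision cascade per 20 s window: Awake before
induction; after the return of movement, Movement or γ-rebound+Movement
(movement takes precedence over spectral criteria during emergence — the
transition out of anesthesia is identified by the EMG, not by band
ratios); StrongIES for windows inside a sustained (≥ 40 s) run of
IESSR > 0.25; LightIES for 0 < IESSR ≤ 0.25 with δ active and θ not
(low-ratio windows without δ fall to PreIES); then the four
band-prominence states. ThetaDecay is the θ-only state after induction
and ends when δ becomes prominent. The labeled sequence, collapsed over
repeats, must walk the fixed transition graph exposed by
`state_edges()`.

## The synthetic generator

Scenarios are ordered stages tiling the recording. Each stage contributes
an aperiodic background (spectral shaping of white Gaussian noise in the
frequency domain, so the expected PSD is exactly $a/(c+f^p)$), optional
θ/δ rhythms (sinusoids whose instantaneous frequency follows the stage's
constant or chirping trajectory plus slow Gaussian jitter, giving an
approximately Gaussian spectral line of width σ), an optional γ burst
train (60 Hz, 2 s on / 0.5 s off), and optionally planted IES: ~10 s
cycles whose flat part is jittered with zero-sum noise so the realized
total matches the requested fraction exactly, every segment ≥ 1 s and
every gap > 2 s (unmergeable). Planted flats scale the summed signal to
2% so detectors face realistic near-flat traces rather than exact zeros.
Stages are crossfaded with equal-power ramps over 1 s; ground-truth event
times refer to the nominal boundaries. The EMG is 20–200 Hz noise at
30 µV RMS, scaled to 5% between loss and return of movement.

Default choices worth stating:

- **Amplitudes** (background $a=100, c=1, p=2$; θ amplitude 14 µV, δ
  18 µV) are calibrated for detector testability — they put every
  threshold (0.7·RMS, prominence ratios, γ baseline) in its intended
  operating regime — not for physiological realism; no public reference
  recording exists to calibrate an absolute µV scale against.
- The **θ decay** runs 8 → 6 Hz at −1 Hz/min, inside the 5–10 Hz power
  band throughout: a rhythm decaying below ~5.5 Hz leaves the band-pass
  and would register as a (spurious) early θ dampening — a real
  constraint of the band-ratio definition, not of the generator.
- **Induction at 115 s** sits deliberately off the 30 s frame grid so the
  first frame after induction falls inside the decay.
- The deep scenario is 20 min at 500 Hz; the event-chain tests run ten
  seeded replicates, and the exponent-recovery study uses 10 min signals
  with five seeds per exponent. These sizes give stable medians while
  keeping a full test run in a few minutes.

What the generator does **not** emulate: real bursts (it reuses the
background process at burst amplitude rather than biphasic burst
waveforms), respiration/ECG artifacts in the EMG, electrode drift,
line-noise, state-dependent changes of the aperiodic exponent, and
amplitude nonstationarity within a stage. Passing tests therefore
demonstrate algorithmic correctness against the stated signal model, not
performance on any particular laboratory's recordings.

## Classifier

IES sensitivity is $\Delta_{IES} > 30$ s (strict). Event delays are
normalized by $\tau^* = \log(1 + 100/((\tau-\tau_{Isostart})+0.1))$
(natural log — the base is a convention; the formula is monotone either
way), a bounded, strictly decreasing transform: zero delay maps to
$\log 1001 \approx 6.9$ and long delays to ~0. An absent event is assigned
$\tau^* = 0$, its infinite-delay limit. The model is an l2-penalized
logistic regression with regularization constant $C = 1$ (ridge penalty
$\lambda = 1/(nC)$ on the per-observation likelihood scale, intercept
unpenalized, no standardization), fitted per fold of a stratified group
4-fold split: subjects are assigned greedily, largest first, to the fold
that best balances positive fractions, with seeded tie-breaking — no
subject ever spans folds, and fold positive counts stay within one
recording of the even share. The primary score is the ROC-AUC of pooled
out-of-fold predictions; per-fold AUCs are also reported. Pooling ranks
predictions from different fold models against each other, so it is the
stricter aggregation. If no predictor varies in a training fold the model
is uninformative and scores 0.5 by construction.

## Numerical conventions

Time is seconds from recording start; all intervals are half-open
$[start, end)$; sample $i$ covers $[(i-1)/f_s, i/f_s)$. Window grids
start at half a width and keep only fully contained windows. Artifact
masking combines two rules reported in one mask: exactly-constant runs
≥ 0.5 s (hardware dropout) and hysteresis excursions (any connected
region with $|S| > 0.08$ µV touching 1200 µV). Filtering is Butterworth
order 1 applied forward–backward (effective order 4, zero phase)
throughout; its wide skirts are the reason a pure 3 Hz tone yields a δ
power ratio near 0.8 rather than 1, and why power ratios are only
guaranteed in $[0, 1]$ up to a 5% leakage tolerance.
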