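---
title: "Methods: theta-gamma coupling in a change-detection working-memory task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: theta-gamma coupling in a change-detection working-memory task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgcwm)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the estimator conventions
used at every stage, the numerical choices, and what the test suite does
and does not establish about real recordings.

## The task and its trial clock

The paradigm is a lateralised change-detection task: an arrow cue (200 ms)
directs attention to one hemifield, a blank (300 ms) precedes a bilateral
memory array of 2 or 4 coloured squares (500 ms), a 900 ms retention
interval follows, and a test array stays up until the match/mismatch
response. EEG analysis divides each trial, relative to arrow onset, into
an **attention** window (0–500 ms), an **encoding** window (500–1000 ms)
and a **retention** window (1000–2000 ms). Epochs span −1000 to +2000 ms
around the arrow. Note one convention worth making explicit: task
descriptions in this paradigm often run the trial clock from 1000 ms
*before* the arrow (so the same windows read 1000–1500, 1500–2000 and
2000–3000 ms); `phase_windows()` expresses them relative to arrow onset,
which is where the epoch's time zero sits. Behaviour is summarised by accuracy, mean reaction time
and Cowan's K = load × (hit − false-alarm rate).

## The generative model

No subject-level recordings from this paradigm are publicly deposited, so
the package treats a synthetic generator as a first-class, tested module.
Each channel is

$$x(t) = A_\theta \sin(2\pi f_\theta t)
 + A_\gamma\left[(1-d) + d\,\frac{1+\cos(2\pi f_\theta t)}{2}\right]
 \sin(2\pi f_\gamma t) + \varepsilon(t)$$

the canonical phase-amplitude-coupled test signal: the gamma envelope is
cosine-shaped in theta phase, maximal at the theta peak, and the depth
$d \in [0,1]$ interpolates between no modulation ($d=0$, flat envelope)
and full modulation ($d=1$, envelope touching zero). This form was chosen
because it has a **closed-form phase-bin distribution** — the mass of bin
$[a,b)$ is proportional to $(b-a) + \sin b - \sin a$ — which gives the
modulation-index code an exact, independently computable oracle.

Design choices in the generator, and why:

* **Noise** $\varepsilon$ is half pink (1/f) and half white by variance.
  Real EEG spectra fall off roughly as 1/f, so a flat-noise generator
  would leave the band-power code untested against the dominant feature
  of real spectra.
* **Montage**: standard 10-10 labels, with the 50 electrodes of the eight
  scalp regions (frontal/central/temporal/occipital × left/right) first,
  so named electrode lists resolve directly and reduced montages keep the
  regions used in coupling analyses.
* **Topography**: theta is present on all channels (a global oscillation
  whose frontal phase can be read anywhere), gamma and its coupling only
  on the configured `gamma_channels` (occipital by default). This makes a
  frontal-phase → occipital-amplitude analysis well-posed and gives
  lateralisation tests a ground truth.
* **Trial spacing** is jittered uniformly in 3.5–4.5 s — a declared
  default, not an inferred one; the lower bound is the smallest value for
  which −1000…+2000 ms epochs cannot overlap.
* **Artifacts** are whole 2-s segments scaled by `artifact_gain` (> 5,
  default 10), emulating high-amplitude excursions at segment scale —
  which is exactly the grain at which the rejection rule operates.
* **Behaviour** is binomial (hit rate on match trials, false-alarm rate on
  mismatch trials) with lognormal reaction times — the standard positive,
  right-skewed RT model, and the only distributional commitment needed to
  reproduce a mean RT.

Defaults (1000 Hz, 64 channels, 100 trials per condition, θ = 6 Hz,
γ = 40 Hz, 10 μV theta, 5 μV gamma, 5 μV noise) match the task structure
and a typical 64-channel scalp EEG regime.

## Preprocessing conventions

The stage order is fixed and recorded in the provenance log: segment
rejection → filters → optional ICA → epoching.

* **Segment rejection.** "Intensity" of a 2-s segment is its RMS across
  all channels, and a segment is removed when it **strictly** exceeds 5×
  the mean segment RMS. RMS is the standard intensity proxy; strictness at
  the boundary makes the rule exactly testable (a segment at precisely 5×
  is retained). The rule is idempotent on typical data: after removing
  outlier segments the recomputed mean drops, but a second pass removes
  nothing on the clean record. The scan runs on the *continuous*
  recording; the 3-s epochs are cut afterwards. (These are the two
  segmentations that coexist in the pipeline: a 2-s artifact grid and 3-s
  trial epochs.)
* **Filters.** Zero-phase (forward–backward) Butterworth: 4th-order
  band-pass 0.5–95 Hz and 2nd-order band-stop notches at 50 and 100 Hz.
  Butterworth was chosen because it is maximally
  flat in the pass-band, and the forward–backward application cancels
  phase distortion, which matters because Hilbert phase is consumed
  downstream. Verified contract: ≥ 20 dB attenuation at 50 Hz, ≤ 1 dB in
  the pass-band (10 Hz, 40 Hz).
* **ICA** is delegated to a compact symmetric FastICA (tanh contrast)
  with automatic flagging: blink-like components (frontal-dominated
  topography, mostly < 5 Hz power) and muscle-like components (> 70 % of
  power above 20 Hz) are zeroed before reconstruction. The stage is **off
  by default**: the generator injects no blinks or muscle activity, and
  an unneeded rank-reduction would only distort the ground truth. On
  decomposition failure the recording passes through with a warning.
* **Epoch rejection** at ±100 μV absolute amplitude on any channel is
  applied *after* filtering — the two stages are not intrinsically
  ordered, but filtering first means line noise cannot push a clean epoch
  over threshold.
  Epochs whose window would read outside the recording are dropped and
  counted.

## Spectral estimation

`spectrum_fft()` implements the band-power definition
$\mathrm{Power}_{band} = \sum_{low \le f < high} |F(\omega)|^2$ with these
conventions:

* **2-s analysis length** at any sampling rate, hence a 0.5 Hz grid. The
  phase windows are only 0.5–1 s long, so their samples are Hann-tapered
  over their own length and zero-padded to 2 s. This preserves the stated
  frequency resolution while respecting window boundaries; power is
  normalised by the effective window length so that window duration does
  not change the scale.
* **Hann taper.** No taper is prescribed; Hann limits leakage across the
  narrow 4–8 Hz theta band. The normalisation divides by the window's
  mean-square, so Parseval holds exactly in the form *sum of one-sided
  spectrum = mean-square of the tapered segment / mean-square of the
  taper* — the identity the tests check to 10⁻⁶, along with the
  c² scaling law.
* **Half-open bands** [low, high) make the six bands a partition despite
  their shared edges (4, 8, 12, 30 and 60 Hz each terminate one band and
  start the next).
* Power is reported **absolute** (μV²), not relative.
* Aggregation order: band power per epoch × electrode × window, then mean
  over the region's electrodes and over kept epochs — permutation
  invariant in electrode order.

Zero-padding, Welch averaging and whole-epoch spectra are all defensible
here; zero-padding is the default because it is the only option that
keeps both the window boundaries and the 0.5 Hz grid.

## Coupling estimation

* **Analytic signals** come from zero-phase band-pass plus FFT Hilbert
  transform; a series must contain ≥ 3 cycles of the band's low edge.
  Theta phase uses 4–8 Hz of the *region-averaged* signal (a single
  electrode would also be defensible; averaging is the lower-variance
  choice), and gamma amplitude is computed separately for
  low (30–60 Hz) and high (60–80 Hz) gamma.
* **MI binning**: 18 half-open 20° bins starting at −180°; each amplitude
  sample is assigned by its instantaneous phase; $P_i$ is the mean
  amplitude in bin $i$ divided by the sum over bins (Tort's
  normalisation). Empty bins get $P_i = 0$ and contribute 0 via the
  $0\log 0$ limit. MI is scale-invariant in amplitude and bounded in
  [0, 1].
* **Per-epoch, then average.** MI and PPC are computed within each phase
  window of each epoch and averaged over kept epochs, preserving
  trial-level variance for the statistics stage (the concatenated
  alternative discards it).
* **Filtering is done on the whole epoch** and the phase windows are then
  sliced from the analytic signal, so filter edge effects do not
  accumulate at every window boundary.
* **PPC estimator**: several estimators go by the name phase-phase
  coupling; the package uses the standard n:m phase-locking value
  $|\langle e^{i(n\varphi_\gamma - m\varphi_\theta)}\rangle|$ with a
  configurable ratio defaulting to 1:6 (6 Hz theta against ~36 Hz gamma).
  This choice is deliberately loud in the documentation and the output
  carries the ratio in its metadata; PPC values are not comparable across
  different (n, m).
* **Estimator bias**: MI on pure noise is positive and grows as windows
  shrink (fewer samples per bin → rougher empirical distribution). The
  retention window (1000 ms) therefore has a lower null MI than the
  attention/encoding windows (500 ms) — confirmed by simulation in the
  suite. Comparisons should stay within a window, never across window
  lengths. Windows shorter than 500 ms (two theta cycles at 4 Hz) are
  flagged `low_confidence` rather than refused.

## Behaviour and statistics

Hit and false-alarm rates, accuracy and K are computed over *responded*
trials; omissions leave the denominator (logged via `n_responded`). Mean
RT uses correct trials only — the convention in change-detection work —
with a switch (`rt_correct_only = FALSE`) for all responded trials.
A cell with no mismatch trials fails loudly ("false-alarm rate
undefined") rather than returning a silent NA.

`run_contrast()` applies two-sided tests throughout. The "choose by
distribution" rule is made concrete as: Shapiro-Wilk per group at
α = 0.05; both normal → Student's t, otherwise Mann-Whitney. This is a
documented heuristic, not the only defensible gate. BH-FDR is
applied within analysis families (power contrasts, coupling contrasts,
correlations); family membership is a column of the output, since the
family structure is an analysis choice that changes adjusted p-values.

## Simulation scale and what the tests show

Tests and cohort simulations run at deliberately small problem sizes —
250 Hz sampling (every band edge stays below Nyquist), 6–10 electrode
mini-montages, 2–10 EEG trials per condition, 6–8 s coupling signals,
cohorts of 20 subjects with 6 EEG trials per condition and 100 behaviour
trials per condition — chosen so that repeated cohorts and 20-seed
property checks remain cheap while every code path (filters, rejection,
binning, pairing) is exercised at full fidelity. The full-scale defaults
(1000 Hz, 64 channels, 100 trials) go through the identical code.

The pre/post cohort generator ties a per-subject effect size $r$ to three
observables at once — occipital gamma amplitude $\times(1-r)$, modulation
depth $\times(1-r)$, and 4-item hit rate $+0.3r$ — so the injected
signature is a *negative* paired change in occipital gamma power, a
negative paired change in frontal-theta/occipital-gamma MI, and a
negative Spearman correlation between the per-subject change in gamma
power and the change in K. The acceptance suite verifies that all three
are recovered with the right sign (and the paired contrasts at p < 0.05)
in at least 80 % of 20 meta-seeds.

Passing these tests shows the estimators are correct and the pipeline
recovers known effects of realistic size under pink-noise EEG. It does
**not** show robustness to everything real data contain: no volume
conduction or realistic source topographies, no evoked potentials
overlapping the windows, no eye-blink or cardiac waveforms (only
segment-scale amplitude artifacts), no non-stationary drift, and
stationary sinusoidal rather than burst-like gamma. Conclusions about
real recordings still require the usual inspection of rejection logs and
ICA component decisions.

## Known limitations

* The MI normalises by $\log N$; with $N = 18$ the
  index saturates at 1 only for a single-bin distribution, and typical
  physiological values are small (10⁻³–10⁻¹) — effect sizes, not the
  absolute scale, carry the interpretation.
* The EDF writer emits plain EDF with a sidecar CSV for events rather
  than an EDF+ annotation channel; BrainVision is the lossless round-trip
  format for marker-bearing recordings.
* `remove_artifact_components()` implements its own compact FastICA; it
  is adequate for the rank-20 decompositions used here but is not a
  substitute for inspecting components in an interactive tool on real
  data.
* The rTMS protocol appears only as arithmetic (`rtms_protocol()`) and a
  session label; nothing about stimulation delivery is modelled.
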