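# tgcwm — theta-gamma coupling analysis for visual working-memory EEG

`tgcwm` is an R package for analysing cross-frequency coupling in EEG
recorded during a lateralised change-detection working-memory task, the
paradigm used to probe visuospatial working memory in mild cognitive
impairment and in studies of prefrontal rTMS. It is aimed at
neurophysiologists who need a fully tested, scriptable pipeline from raw
multi-channel EEG (BrainVision or EDF) and trial logs to band power,
theta-gamma coupling, behavioural capacity and group statistics — plus a
synthetic-data generator with known ground truth, so every stage can be
validated without access to patient recordings.

## What it computes

**Band power.** Epochs (−1000 to +2000 ms around the cue arrow) are cut
from filtered, artifact-cleaned recordings; for each trial phase
(attention 0–500 ms, encoding 500–1000 ms, retention 1000–2000 ms after
the arrow), scalp region (8 regions over a 10-10 montage) and canonical
band (δ 0.5–4, θ 4–8, α 8–12, β 12–30, low-γ 30–60, high-γ 60–80 Hz),
power is the FFT band sum

    Power_band = Σ_{low ≤ f < high} |F(ω)|²

on 2-s analysis windows (0.5 Hz resolution).

**Phase-amplitude coupling.** Theta phase φ_θ(t) and gamma amplitude
A_γ(t) come from the Hilbert analytic signal of the band-passed data. The
amplitude is binned by phase into N = 18 bins of 20° and the Tort
modulation index is the normalised Kullback-Leibler divergence of the bin
distribution P from uniform:

    MI = (1 / log N) Σ_i P_i log(P_i / (1/N)),   MI ∈ [0, 1]

**Phase-phase coupling.** The n:m phase-locking value
`|⟨exp(i(n φ_γ − m φ_θ))⟩|` (default 1:6).

**Behaviour.** Accuracy, mean reaction time and Cowan's K
`K = load × (hit rate − false-alarm rate)` per subject, session and load
condition (2 or 4 items).

**Statistics.** Mann-Whitney / t / paired-t / χ² / Spearman contrasts with
a Shapiro-Wilk normality gate, and Benjamini-Hochberg FDR adjustment
within analysis families.

## Worked example

```r
library(tgcwm)

cfg <- synth_config(sampling_rate = 250, n_channels = 50,
                    n_trials_per_condition = 10, modulation_depth = 0.8,
                    noise_sd = 2, artifact_rate = 0, seed = 42)
rec <- generate_recording(cfg)
pp  <- preprocess(rec$recording)
pp$epochs
#> <eeg_epochs> 20 trials (20 kept) x 50 channels x 750 samples @ 250 Hz
#>   kept per condition: 2T=10, 4T=10

power <- band_power_table(pp$epochs)
subset(power, region == "left_occipital" & phase == "retention" &
              condition == "4T" & band %in% c("theta", "low_gamma"))
#>     subject session condition     phase         region      band     power
#> 278     S01     pre        4T retention left_occipital     theta 50.461284
#> 281     S01     pre        4T retention left_occipital low_gamma  5.387371
```

Theta dominates (every channel carries the 6 Hz oscillation at 10 μV) and
the injected 40 Hz gamma appears in the low-gamma band of the occipital
region that carries it. Coupling between left-frontal theta phase and
left-occipital gamma amplitude:

```r
cp <- couple_regions(pp$epochs)
subset(cp, measure == "PAC_MI" & condition == "4T" & gamma_band == "low_gamma")
#>  phase         value
#>  attention 0.03047190
#>  encoding  0.02862378
#>  retention 0.02711408
```

MI is far above its noise floor (compare `modulation_depth = 0`, which
gives ~1e-3 here), and behaviour yields Cowan's K per condition:

```r
summarize_behavior(generate_behavior(cfg))
#>  condition accuracy  mean_rt hit_rate fa_rate   k
#>         2T      0.9 664.3815      0.8     0.0 1.6
#>         4T      0.8 747.1107      0.8     0.2 2.4
```

`run_pipeline()` orchestrates all of this from a JSON/`list` config into
tidy CSVs plus a provenance record, and `simulate_cohort()` +
`cohort_contrasts()` build pre/post cohorts with linked neural and
behavioural effects for power and recovery studies.

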