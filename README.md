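# smtkin — single-molecule tracking kinetics

`smtkin` quantifies how nuclear proteins interact with chromatin from
live-cell single-molecule tracking (SMT) experiments. Given trajectories
of individually labelled molecules (e.g. HaloTag fusions imaged under
HILO illumination), it answers two questions:

1. **What fraction of molecules is chromatin-bound, and how fast do the
   rest diffuse?** — the *fractional study*, from continuous 30-ms
   imaging.
2. **How long do bound molecules stay on chromatin?** — the
   *residence-time study*, from time-lapse imaging (short exposures
   separated by dark time to limit photobleaching).

It is aimed at chromatin biologists and microscopists who already have
tracked localizations (spot detection and linking are upstream, e.g.
u-track) and need the downstream kinetic analysis to be reproducible and
testable. A built-in trajectory simulator generates data with known
ground truth so that every stage of the analysis can be validated by
parameter recovery.

## The model

**Per-track diffusion coefficients.** For a track with consecutive-frame
displacements r_i over frame interval τ,

    Dm  = ⟨r_i²⟩ / (4 τ)        (whole-track mean squared step)
    Df1 = r_f1² / (4 τ)         (first step only)

Short tracks count equally, avoiding bias toward slow molecules that
stay in focus longer.

**Population decomposition.** The histogram of log10 Dm is fitted with a
sum of Gaussians plus offset,

    y(x) = y0 + Σ_i  A_i / (w_i √(π/2)) · exp(−2 (x − x_i)² / w_i²),

where A_i is the area, x_i the center and w_i (= 2σ) the width of
component i. Population fractions are F_i = A_i / ΣA · 100%. The slowest
center can be fixed at log10 D = −1.5 (D = 0.032 µm²/s, the apparent
mobility of nucleosome-incorporated histones); when that fit fails to
support a bound component the pipeline automatically falls back to a
two-component fit. Components are labelled chromatin-bound (CB),
intermediate (ID) and fast diffusion (FD).

**Residence times.** In time-lapse mode, molecules with Dm < 0.10 µm²/s
over ≥ 2 consecutive frames are selected as bound; each dwell time is the
lifetime of its fluorescent spot. The cumulative frequency distribution
(count of molecules with dwell ≥ τ) is corrected for photobleaching by
dividing by a bleach curve B(τ) = y0 + f_b1 e^(−τ/τ_b1) + f_b2 e^(−τ/τ_b2)
fitted to ensemble decay data, then fitted with nested exponential
models

    y(τ) = B1 e^(−τ/τ_tb) + B2 e^(−τ/τ_sb),     τ_tb < τ_sb,

choosing one vs. two components by the extra-sum-of-squares F-test.
The chromatin-bound fraction F1 from the fractional study is split into
transient and stable subfractions by the amplitude ratio:
F1tb = F1·B1/(B1+B2), F1sb = F1·B2/(B1+B2).

## Worked example

Simulate a wild-type Cbx7-like experiment (29% bound, 49% intermediate,
22% fast) and run both studies:

```r
library(smtkin)

rep <- run_fraction_study("cbx7_wt", seed = 11)
rep$fit
#> <diffusion_fit> 3 components
#>   center width  area d_um2s fraction fraction_sd
#> 1  -1.50 0.402 0.285 0.0316     31.4        1.48
#> 2  -0.31 0.418 0.463 0.4893     51.0        1.96
#> 3   0.38 0.333 0.160 2.3977     17.6        1.76

res <- run_residence_study("cbx7_dwell_wt",
                           f1 = rep$fractions$fraction[1], seed = 11)
res$fit
#> <dwell_fit> two_exp (F = 4.57e+03, p = 1.51e-81)
#>   tau_tb = 0.764 s (B1 = 2.51e+03), tau_sb = 6.96 s (B2 = 551), y0 = 1e-12
res$subfractions
#>      F1tb      F1sb
#> 25.747268  5.655719
```

Reading the output: the fractional fit recovers the three generative
populations — 31.4% of molecules chromatin-bound at an apparent
0.032 µm²/s, 51% diffusing at ~0.49 µm²/s and 17.6% at ~2.4 µm²/s
(truth: 29/49/22). The residence-time study selects the bound
molecules, corrects their dwell distribution for photobleaching and
finds two binding classes: transient (τ_tb ≈ 0.76 s) and stable
(τ_sb ≈ 7.0 s; truth 0.79 s and 7.3 s). Of the 31.4% bound fraction,
5.7 percentage points are stably bound. `make_report()` writes these
results as JSON/CSV plus figures.

Real track tables are read with `read_tracks()` (CSV with
`track_id,frame,x_um,y_um` columns and timing metadata in header
comments); `run_fraction_study()` and `run_residence_study()` accept a
`track_set` anywhere a preset name is shown above.

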