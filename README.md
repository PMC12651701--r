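# eegnetkit

Low- and high-order functional brain-network analysis for 16-channel
resting-state EEG, with dynamic integration/segregation state entropy and
paired pre/post statistics.

## The problem

Interventions that aim to modulate cognition (neurofeedback training,
stimulation protocols, rehabilitation programs) are often evaluated with
resting-state EEG recorded before and after treatment on the same
subjects. The question is whether the *organization* of band-specific
functional networks changed — not just spectral power. `eegnetkit`
implements that analysis end to end for recordings on the international
10–20 montage (FP1, FP2, F3, F4, F7, T3, T5, F8, T4, T6, C3, C4, P3, P4,
O1, O2):

1. **Conditioning** — downsample (1000 → 128 Hz), 50 Hz notch, and
   decomposition into delta (1–4 Hz), theta (4–8), alpha (8–13) and beta
   (13–30) bands by a 5-level Daubechies-4 wavelet transform (or exact-edge
   zero-phase band-passes via `band_mode = "fir"`).
2. **Low-order connectivity (LOFC)** — per band, the amplitude envelope of
   each channel's analytic (Hilbert) signal is computed and the network
   weight is `w_ij = |corr(env_i, env_j)|`.
3. **High-order connectivity (HOFC)** — the columns of the
   Fisher-z-transformed LOFC are treated as connectivity *profiles*; for
   each node pair the profiles (rows i, j removed, aligned by node) are
   correlated: networks of similar connection patterns.
4. **Graph metrics** — with edge lengths `1/w`: nodal efficiency
   `NE_i = (N−1)^{-1} Σ_{j≠i} 1/d_ij`, global efficiency `GE = mean(NE)`,
   Zhang–Horvath weighted clustering `NCC_i`, average clustering
   `Cave = mean(NCC)`, plus frontal/temporal/parietal/occipital lobe
   aggregates.
5. **Dynamics** — non-overlapping windows (1/f_min, 1, 2, 4, 6, 8, 10 s per
   band) give per-window networks; each window is classified integrated (1)
   or segregated (0) by a per-recording GE-median split, and the normalized
   entropy of consecutive state-pair patterns (00/01/10/11) is
   `NSE = −(log 4)^{-1} Σ p_i log p_i ∈ [0, 1]`.
6. **Statistics** — paired t-tests across subjects for every metric, star
   coding (`*` p<0.05, `**` p<0.01, `***` p<0.001), optional
   Benjamini–Hochberg adjustment, and cohort bookkeeping such as the
   proportion of subjects improving on a cognitive score.

Because suitable public recordings with known ground truth do not exist,
the package ships a seeded synthetic-cohort generator that plants
band-specific envelope coupling (shared + community + independent sources
as variance fractions), integrated/segregated regime dynamics, and a pink
1/f background — every estimator is validated against this ground truth.

## Worked example

```r
library(eegnetkit)

spec <- cohort_spec(n_subjects = 4, duration_s = 60,
                    sampling_rate = 128, seed = 11)
cfg <- pipeline_config(cohort_spec = spec, line_freq = NULL,
                       export_heatmaps = FALSE, seed = 11,
                       out_dir = "demo_out")
res <- run_pipeline(cfg)

subset(res$stats, metric == "mean_connectivity" & order == "low",
       c(band, n, mean_pre, mean_post, t, p, stars))
```

```
     band n  mean_pre  mean_post          t            p stars
21  alpha 4 0.2092623 0.13659250  -9.411143 0.0025419508    **
57   beta 4 0.1621951 0.08273078 -20.980768 0.0002368461   ***
92  delta 4 0.1924758 0.33645166  12.296631 0.0011584250    **
127 theta 4 0.2398547 0.14962030  -4.455063 0.0210501006     *
```

Even at 4 subjects the planted contrast is visible: mean delta-band
low-order connectivity rises from 0.19 to 0.34 after the simulated
intervention while theta, alpha and beta fall — the sign pattern the
generator plants by raising delta coupling and lowering the rest.
`demo_out/` also contains `metrics.csv` (efficiency/clustering at global,
node and lobe scope), `dynamics.csv` (state-pattern probabilities and NSE
per window length), per-matrix CSVs, and `manifest.json` with the config
hash. A thin CLI over the same functions lives in
`inst/scripts/eegnetkit.R` (`simulate` and `run` subcommands).

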