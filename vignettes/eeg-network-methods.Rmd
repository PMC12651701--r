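---
title: "Low- and high-order EEG network analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low- and high-order EEG network analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegnetkit)
```

## The analysis in one paragraph

`eegnetkit` turns multichannel resting-state EEG on a 16-channel 10-20
montage into weighted functional brain networks and summarizes how their
organization differs between two conditions recorded on the same subjects
(labelled `pre` and `post` throughout). Band-limited signals in the four
canonical bands — delta (1–4 Hz), theta (4–8 Hz), alpha (8–13 Hz), beta
(13–30 Hz) — are reduced to amplitude envelopes; the *low-order* network
(LOFC) is the absolute Pearson correlation between every pair of channel
envelopes, and the *high-order* network (HOFC) correlates whole
connectivity profiles (columns of the Fisher-z-transformed LOFC),
capturing similarity of connection *patterns* rather than of signals.
Weighted graph metrics (nodal/global efficiency, nodal/average
clustering) describe each network; non-overlapping windowed networks
yield a binary integrated/segregated state per window whose
transition-pattern entropy quantifies dynamic reorganization; paired
t-tests compare conditions across subjects.

## Signal conditioning

Recordings are downsampled (default 1000 Hz to 128 Hz) with a zero-phase
order-8 Butterworth anti-alias low-pass cut at 0.9x the target Nyquist
followed by cubic-spline resampling, then notch-filtered (default 50 Hz,
zero-phase order-2 band-stop with a 4 Hz stop band). Artifact handling
(ICA component rejection, visual segment exclusion) is deliberately out
of scope: those steps are operator-guided and upstream of this package,
which accepts pre-cleaned data.

Band decomposition is a five-level periodized Daubechies-4 discrete
wavelet transform at 128 Hz, with detail shells mapped to bands: D2
(16–32 Hz) to beta, D3 (8–16 Hz) to alpha, D4 (4–8 Hz) to theta, D5 plus
the final approximation (0–4 Hz) to delta; D1 (32–64 Hz) is discarded.
Two consequences are worth knowing. First, dyadic shell edges do not
coincide with the nominal alpha/beta edges (8–16 vs 8–13, 16–32 vs
13–30); `band_mode = "fir"` substitutes a zero-phase order-4 Butterworth
band-pass at the exact nominal edges when shell mismatch matters — we use
it ourselves for cohort-level validation, where band-specific planted
structure is being recovered. Second, a periodized orthonormal DWT is
only defined up to the phase convention of its downsampling lattice;
ours reconstructs the input exactly (the four bands plus D1 sum to the
input to machine precision, enforced by test), localizes tones correctly,
and differs from other libraries' equally valid conventions. The
decomposition depth and shell-to-band map are documented choices; the
method description we implement fixes neither.

The delta reconstruction retains 0–1 Hz drift; an explicit high-pass is
not applied by default because the source procedure specifies none, and
the synthetic data contain only a weak 1/f floor at those frequencies.

## Connectivity

Envelopes are magnitudes of the FFT-based analytic signal computed on the
full-length band signal; windows later slice this envelope rather than
re-enveloping short segments, so sub-second windows (needed for the
shortest window lengths) remain well defined. Correlations use a
two-pass centred cross-product; zero-variance channels are hard errors,
never silently dropped.

For the HOFC the procedure "remove self-connections from each column,
then correlate columns" leaves the row alignment for a node pair (i, j)
underdetermined; we adopt the standard profile-similarity convention of
deleting rows i and j from both columns, aligning the remaining N − 2
entries by node identity. The absolute value of the profile correlation
is stored, mirroring the low-order definition; signed variants would
change nothing qualitative in the synthetic validation since planted
profile correlations are positive.

`fisher_z()` clips |r| at 1 − 1e−7 before `arctanh`, so duplicated
profiles map to a finite z (about 8.4) instead of infinity.

## Graph metrics

Edge lengths are reciprocal weights (1/w, no edge at w = 0) — the
dominant convention for weighted efficiency; matrices are fully weighted,
with no proportional thresholding, since the procedure we follow
mentions none. Nodal efficiency is the mean inverse shortest-path length
from a node (1/∞ = 0), global efficiency its network mean. The printed
nodal-clustering formula in our source material is typographically
corrupted (duplicated summation indices); we implement the Zhang–Horvath
weighted clustering coefficient

$$\mathrm{NCC}_i = \frac{\sum_{j \ne k;\, j,k \ne i} w_{ij} w_{jk} w_{ki}}
{\big(\sum_{j \ne i} w_{ij}\big)^2 - \sum_{j \ne i} w_{ij}^2},$$

which is bounded in [0, 1] for weights in [0, 1], with the Onnela
geometric-mean variant available via `clustering = "onnela"`; every
output records which variant produced it. Shortest paths are delegated
to igraph (Dijkstra); tests verify them against a brute-force
Floyd–Warshall oracle, and nodal metrics against triple-loop oracles, to
1e−12 over exhaustive small sweeps.

Nodal metrics aggregate over four lobes — frontal (FP1, FP2, F3, F4),
temporal (F7, T3, T5, F8, T4, T6; left and right pooled), parietal (C3,
C4, P3, P4), occipital (O1, O2).

## Dynamics and state entropy

Seven non-overlapping window lengths per band: 1/f_min plus 1, 2, 4, 6,
8, 10 s, where 1/f_min is read as the reciprocal of the band's *lower*
edge (delta 1 s, theta 0.25 s, alpha 0.125 s, beta 1/13 s). The
alternative reading — reciprocal of the centre frequency — is available
(`fmin_window(band, rule = "center")`); the source text supports either,
and for delta the lower-edge reading duplicates the 1 s window, which is
simply reported twice.

The integrated/segregated criterion is unspecified in our source
material, so results that depend on it are classifier-relative. We use a
parameter-free per-recording median split: a window is integrated (1)
iff its global efficiency strictly exceeds the median GE across that
recording's windows at the same band, order and window length; ties are
segregated, and an all-tied sequence is all-segregated with a warning.
This rule is scale-invariant, reproducible, and recovers planted
regimes essentially perfectly when window boundaries tile regime epochs
(a validation, not a guarantee for real data, where regime contrast and
alignment are unknown).

Transition patterns are consecutive state pairs sliding by one window
(n − 1 overlapping pairs — the maximal sample, since disjoint pairing
halves the count for no benefit), and the normalized state entropy is

$$\mathrm{NSE} = -\frac{1}{\log M} \sum_{i=1}^{M} p_i \log p_i, \qquad M = 4,$$

with 0·log 0 = 0; the log base cancels. NSE is computed per
subject/condition/band/order/window length and only then compared across
subjects — pooling states across subjects before the entropy would
conflate between-subject heterogeneity with within-subject dynamics.

## Statistics

Two-sided paired t-tests throughout (the sidedness is a conservative
default; directional hypotheses would halve the p-values). Star coding:
`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, strict inequalities.
No multiple-testing correction is applied by default, matching the
reporting convention of the study design this mirrors; Benjamini–
Hochberg is available (`adjust = "bh"`) and recorded in the output.
Zero-variance difference vectors are reported as degenerate (t = 0,
p = 1, flagged) rather than erroring or claiming significance. A
matched-null simulation (n = 28, 5000 replicates) verifying the 5%
type-I error is part of the acceptance suite.

## The synthetic cohort generator

No recordings ship with the package (the motivating study's data are not
deposited), so a seeded generator provides ground truth. Per band, each
channel mixes three unit-variance band-limited Gaussian sources —
shared (global), community (anterior vs posterior split by default), and
independent — as variance fractions:

$$x_i = \sqrt{g}\, s + \sqrt{w}\, c_{k(i)} + \sqrt{1 - g - w}\, e_i ,$$

so the inter-channel signal correlation equals the summed shared
fractions and envelope correlation rises monotonically with them
(property-tested). Sources are white noise shaped by the squared
magnitude response of an order-4 Butterworth band-pass — exactly the
response of zero-phase (forward–reverse) filtering, applied spectrally.
A pink (1/f) broadband floor (`noise_sd`, default 5 µV against a 10 µV
per-band source amplitude) exercises the conditioning path. The
independent-plus-pink background of a channel is drawn as a single
Gaussian process with the summed power spectrum, which is
distributionally identical to summing independent draws.

Regime dynamics alternate integrated epochs (global source at full
coupling, community attenuated to 20%) with segregated epochs (the
reverse), dwell times jittered ±20% around `state_epoch_s` (default
10 s); jitter 0 gives exact epoch tiling for recovery tests. The default
condition preset plants the contrast the pipeline is expected to
recover: global coupling rises in delta (0.55 to 0.70) and falls in
theta/alpha (0.50 to 0.38) and beta (0.42 to 0.30) after the
intervention. These magnitudes were chosen once to put mean connectivity
in the range reported for real envelope-correlation EEG networks
(roughly 0.2–0.5) with clearly signed but not trivial contrasts; they
are modelling choices, not fits to any dataset, and the validation
targets *signs*, never magnitudes.

What the generator does not emulate: volume conduction and field spread,
ocular/muscle artifacts, non-Gaussian and non-stationary background
beyond the regime switching, per-subject variability in coupling
topography, and any realistic head geometry. Passing tests therefore
demonstrate that the estimators recover planted statistical structure,
not that they are robust to everything real EEG contains.

## Numerical and engineering choices

* Identical `cohort_spec` (including seed) gives bit-identical
  recordings; per-recording seeds are derived deterministically from the
  cohort seed.
* The DWT pads to a multiple of 32 samples by periodic extension and
  truncates after reconstruction, preserving exactness.
* Windows discard the trailing partial window; fewer than two complete
  windows is an error (no transitions exist).
* Provenance: each pipeline run writes a `manifest.json` containing the
  full configuration and its MD5 hash next to the result CSVs, rather
  than embedding headers inside each CSV, keeping every table readable
  by any CSV parser.
* Heatmap exports clip at the fixed 0–0.6 colour scale and report the
  number of clipped cells.
* EDF export quantizes to 16 bits with integer physical limits; CSV (+
  JSON sidecar) is the lossless interchange format.

## Problem sizes used in validation

The acceptance suite validates at the study's own scale where that scale
is defined by the design — 28 subjects, 300 s recordings, 16 channels,
20 seeded cohorts for contrast recovery — and synthesizes at 128 Hz, the
rate at which all analysis happens; unit tests use 60–120 s recordings.
The paired-t null simulation uses 5000 replicates at n = 28; the graph
oracle sweep draws 1000 random weighted graphs with up to 6 nodes on a
0.25 weight grid.

## Known limitations

* The integrated/segregated classifier is this package's choice;
  criterion-level agreement with analyses that used a different
  (unpublished) rule cannot be expected.
* Wavelet shells only approximate nominal alpha/beta edges; use
  `band_mode = "fir"` when exact edges matter.
* The HOFC sign convention (absolute value) discards anticorrelated
  profile structure.
* EDF support covers the plain-EDF subset the package itself writes
  (uniform rate, one-second records), not EDF+ annotations.
* With 16 electrodes, "lobe" aggregates rest on 2–6 channels each;
  occipital means in particular average only O1 and O2.
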