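---
title: "Methods: GED source separation and inference for multichannel LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GED source separation and inference for multichannel LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and what GED assumes

`lfpged` analyzes multichannel local field potentials (LFP) recorded on a
linear probe (by default 16 equidistant contacts sampled at 1 kHz) during a
trial-structured task with three sensory modalities. The generative
assumption is linear instantaneous mixing: a small number of band-limited
neural sources project simultaneously onto many contacts, so the recorded
signal is `X = M A(t) + noise`, where the columns of `M` are spatial mixing
vectors. Nothing in the decomposition enforces spatial smoothness or
anatomical structure; any spatial organization in the results comes from the
data.

For each trial, two windows are cut: a baseline window over [-1.5, -1.0) s
relative to fixation-cue onset and a stimulus window over [0, +1.0) s
relative to stimulus onset (500 and 1000 samples at 1 kHz, half-open).
Per-trial covariance matrices from the two windows are averaged into a
stimulus matrix `S` and a reference matrix `R`, and the generalized
eigendecomposition `R W Λ = S W` finds spatial filters `w` maximizing the
Rayleigh quotient `(w'Sw)/(w'Rw)` — the multivariate stimulus-to-baseline
variance ratio. When stimulus and baseline co-activity are alike, the
eigenvalues sit at 1; stimulus-locked network changes push eigenvalues above
1. Components are interpreted through their forward-model maps `S w` (one
value per contact) and their time series `w'X`.

### Covariance centering

Each trial's two windows are centered on the *trial-wide* mean LFP (the
per-contact average from baseline start to stimulus end), not on each
window's own mean. This matters: centering a window on its own mean acts as
a high-pass at roughly 1/length, which differs between the 0.5 s and 1.0 s
windows. With 1/f signals that asymmetry makes `E[S] > E[R]` under
stationarity and inflates the eigenvalue permutation test's false-positive
rate by an order of magnitude; with trial-wide centering the test is
calibrated (the type-I rate on simulated null sessions is asserted against
its binomial band in `test-acceptance.R` and recomputed at full size by
`scripts/acceptance.R`). Covariances are
normalized by `n_samples - 1` so the unequal window lengths do not scale
`S` against `R`.

## Inference

**Eigenvalue significance.** The trial labels (which window counts as
stimulus vs baseline) are swapped independently per trial with probability
1/2; covariances are re-averaged and the GED re-solved 500 times. The
observed k-th eigenvalue is compared with the 99th percentile of the 500
permuted k-th eigenvalues (rank-matched null). Whether the original
procedure pooled eigenvalue ranks or not is not documented; a max-statistic
mode (`mode = "max"`, comparing all observed eigenvalues to the null of the
permuted largest) is available behind a flag. One property of the published procedure deserves explicit mention: the two
windows have different lengths, so the per-trial covariance estimates
entering `S` and `R` have different sampling variability and skew. Swapping
a trial's two matrices is therefore not an exact exchange for the
maximum-eigenvalue statistic, and the rank-1 test runs conservative (below
the nominal 1% on simulated null sessions; with equal-length windows the
same pipeline is exact at 1%). The calibration tests assert the binomial
band at their simulation size, and the full-size rate is recomputed by
`scripts/acceptance.R`. We report this behaviour rather than "fix" it — the
windows are part of the procedure.

**Responsiveness screen.** Per contact, pooled baseline samples vs pooled
stimulus samples across trials are compared with a Wilcoxon rank-sum test
(normal approximation with tie correction), Bonferroni-corrected within
session: alpha = 0.01/16 = 0.000625 for a 16-contact probe. Timepoints are
treated as exchangeable samples, as in the original screen; with
autocorrelated LFP this is a descriptive screen, not a calibrated test, and
the package's calibration claims are made only for the permutation tests.

**Anatomy vs statistics.** Component maps are segmented by exact penalized
change-in-mean segmentation (dynamic programming over all segmentations;
a changepoint must reduce the residual sum of squares by at least the
penalty, default 0.05). A fixed additive penalty is only meaningful relative
to the scale of the map values, which the source procedure leaves in raw
covariance units; in the pipeline each map is therefore normalized to unit
variance before segmentation, which makes the 0.05 penalty a scale-free
overfitting guard (steps below roughly 0.2 SD are rejected). The core
function applies the penalty to whatever values it is given. Note one
consequence of the matching rules worth knowing when simulating: a map with
a single active block segments into two pieces, and the flat remainder spans
several nuclei of which only the best-represented is credited, so
single-block components score near chance by construction; positive controls
plant sources whose projection steps at every boundary. Matching
between statistical segments and nucleus labels follows three rules: a
nucleus wholly inside one segment matches entirely; a segment containing
several nuclei credits only its best-represented nucleus; a nucleus split
across segments credits only its largest group. Contacts within 200 µm of a
nucleus boundary (a precomputed annotation flag — the package does no
geometry) and contacts outside the structure are excluded from both
numerator and denominator. Ties (equally represented nuclei, equally sized
groups) resolve toward the lower contact index, deterministically.

The chance level comes from cut-and-shift permutations: the in-structure
subvector of the map is circularly shifted by a uniform draw from
1..(len-1) — the identity shift is excluded, and shifting is confined to
in-structure slots because shifting values into excluded positions would be
undefined. Changepoints and matching are recomputed per shift (1000 times).
Across sessions, observed matching counts are paired with their own null
means and tested per component rank with paired t-tests, Bonferroni
alpha = 0.05/5.

**Time-frequency cluster statistics.** Component time series are convolved
with 80 complex Morlet wavelets log-spaced from 1 to 100 Hz. The cycle
parameter is not documented in the source procedure; we use 3 cycles at 1 Hz
rising log-linearly to 10 at 100 Hz, the standard variable-resolution
choice. The stimulus-window TF power (time-resolved) minus the baseline
power (averaged over the 0.5 s window per frequency, since the windows have
unequal lengths) forms the difference map. A null ensemble of 1000 maps is
built by swapping window roles per trial and jittering both window starts
uniformly within ±500 ms (out-of-bounds draws are redrawn); the observed map
is z-scored cell-wise by the ensemble mean and SD and each ensemble map is
z-scored by the same parameters. Clusters form at |z| > 2.33 with
4-connectivity, positive and negative clusters kept separate (the two-sided
threshold is our resolution of a one-sided phrasing in the source, which
nonetheless reports power decreases); a cluster is significant when its
absolute mass exceeds the 99th percentile of per-ensemble maximum absolute
masses.

For the statistics the TF power is time-binned (default 10 ms). Binned power
is the squared magnitude of the analytic wavelet signal sampled once per
bin, computed by folding the product spectrum and taking a short inverse
FFT; because the wavelet output is analytic, decimation aliases only the
carrier, not the magnitude, so the binned values are exact point samples of
full-resolution power (asserted in the tests).

**Spectral profiles.** Per-component spectra are the time-averaged Morlet
power on the same grid, normalized to unit total power — re-using the single
spectral pathway rather than introducing a second estimator. PCA runs across
the components of each rank group with frequencies as variables; the
explained-variance convention for a zero-variance group (identical spectra)
is `(1, 0, ...)`.

## The synthetic world

The generator emulates what the analysis assumes, with every paper-stated
parameter at its published value: 16 contacts, 1 kHz, 1 s stimuli, 3-4 s
inter-trial intervals, 0.2 s fixation-to-stimulus delay, three modalities ×
eight stimuli × 12-20 repetitions. Where the source is silent the defaults
were chosen once as plausible for primate amygdala LFP and are all
configurable:

| parameter | default | why |
|---|---|---|
| source center frequencies | 4, 7, 38, 70 Hz | the rhythms reported for this structure |
| source amplitude | 1 (arb. units) | sets SNR = 1 against the noise floor |
| per-contact 1/f noise SD | 1, exponent 1.0 | typical field-potential background |
| shared noise SD | 0.5 | common-mode component; removed by the reference |
| amplitude envelope | 1 + 0.5·(0.2 s-smoothed noise), floor 0.1 | slow waxing/waning of rhythms |
| modality gains | visual 2.0 > tactile 1.5 > auditory 1.2 | the reported selectivity ordering |
| mixing vectors | unit blocks on contiguous nucleus contacts | gives the concordance test a ground truth |
| annotations | 2 contacts outside; boundary flags flanking one internal boundary | emulates a probe crossing the structure |

Sources are amplitude-modulated sinusoids (random phase, smooth positive
envelope), not filtered noise, so spectral-peak tests have exact targets.
During each stimulus window the matching modality's gain multiplies the
source amplitude, so the stimulus/baseline variance ratio of a clean source
projection is the squared gain.

What the generator does *not* emulate: volume-conduction geometry,
biophysical forward models, spiking, artifacts, non-stationary noise floors,
or cross-frequency structure. A green end-to-end test therefore establishes
that the statistics are calibrated and that planted linear-mixing structure
is recovered — not that the method is robust to everything real recordings
contain.

## Numerical choices

- **Shrinkage.** `R <- (1-γ)R + γ·mean(diag(R))·I`. The pipeline default is
  γ = 1e-6 because common-average-referenced covariances are rank-deficient
  by one. The core solver's own default is γ = 0 so that the `S = R ⇒ λ ≡ 1`
  identity holds to 1e-8; with γ = 1e-6 the identity would be violated at
  ~1e-6, which is exactly the tolerance the identity is tested at.
- **Solver.** Cholesky whitening of `R` then a symmetric eigendecomposition;
  validated against an independent nonsymmetric eigensolver route on random
  SPD pairs at 1e-8.
- **Sign/scale convention.** Eigenvectors have unit norm with the
  largest-magnitude element positive; GED is sign/scale-invariant and
  downstream correlations need determinism.
- **Degenerate inputs.** Permutation-invariant data must not become
  significant through solver rounding, so the significance comparison adds a
  1e-9 relative epsilon to the strict inequality. Constant TF cells (shuffle
  SD 0) report z = 0. A singular `R` with γ = 0 raises an error that points
  at the shrinkage parameter.
- **Seeds.** Every permutation routine takes an explicit seed; the pipeline
  derives per-stage seeds from one master seed, and all compiled code draws
  through R's RNG, so whole-session reports are reproducible bit-for-bit.

## Limitations

Rank pairing across analyses (all-trials vs modality-specific, rank groups
for PCA and concordance) uses eigenvalue order only; no map-matching is
attempted. The screen's sample pooling ignores autocorrelation. The
cut-and-shift null preserves local ordering and the value multiset but not
longer-range spatial autocorrelation of maps. Cross-structure connectivity,
phase metrics, and real-data ingestion beyond the documented session format
are out of scope.
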