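# lfpged

Source separation and statistical inference for multichannel local field
potentials (LFP) recorded on linear electrode arrays, built for the question:
*do stimulus-locked mesoscale subnetworks exist across the contacts, and do
their spatial footprints respect anatomical boundaries?*

The package is aimed at electrophysiologists working with trial-structured
multichannel recordings (e.g., a 16-contact probe through the primate
amygdala during visual/tactile/auditory stimulation) and at methodologists
who want a fully synthetic, ground-truth-verified test bed for this family
of analyses.

## The method

For each trial, covariance matrices are formed from a baseline window
([-1.5, -1.0) s before fixation-cue onset) and a stimulus window
([0, +1.0) s after stimulus onset), centred on the trial-wide mean, and
averaged into a stimulus matrix **S** and a reference matrix **R**. A
generalized eigendecomposition (GED)

&nbsp;&nbsp;&nbsp;&nbsp;**R W Λ = S W**,&nbsp;&nbsp; w_max = argmax_w (wᵀSw)/(wᵀRw)

yields spatial filters maximizing the stimulus/baseline variance ratio.
Eigenvalues near 1 mean "no change"; significant components are found by
shuffling each trial's window labels 500 times and comparing each observed
eigenvalue to the 99th percentile of its rank-matched permutation null.
Components are interpreted via forward-model maps **S**w (per-contact
contributions) and time series wᵀ**X**.

Downstream analyses mirror the full pipeline of the study this reimplements:

- per-contact responsiveness screen (Wilcoxon rank-sum, Bonferroni
  α = 0.01/16 = 0.000625);
- penalized change-in-mean segmentation of component maps (exact dynamic
  programming, penalty 0.05) and concordance with nucleus annotations under
  a 1000-draw cut-and-shift permutation null, with rank-wise paired t-tests
  (Bonferroni α = 0.05/5);
- Morlet time-frequency decomposition (80 log-spaced wavelets, 1–100 Hz),
  1000-shuffle z-scoring with ±500 ms window jitter, and cluster-mass
  significance (|z| > 2.33 forming threshold, 99th percentile of maximum
  cluster masses);
- modality-specific GED reruns, map correlations, component-count
  comparisons, and spectral-profile PCA per component rank group;
- a synthetic-session generator with known mixing vectors, per-modality
  gains, 1/f noise, and anatomical annotations, so every statistic above is
  testable against ground truth with no recorded data.

## Worked example

```r
library(lfpged)

# a session with one planted subnetwork: a 4 Hz source on the "lateral"
# contact block, amplitude tripled during every stimulus
cfg <- sim_config(n_trials_per_modality = 20, seed = 7)
gt  <- default_ground_truth(cfg, n_sources = 1, gains = matrix(3, 1, 3))
sim <- generate_session(cfg, gt)

ref  <- common_average_reference(sim$session)
ged  <- run_ged_on_subset(ref, n_perm = 500, seed = 11)
ged
#> <ged_result> 16 components, top eigenvalues: 7.09, 1.275, 1.224, 1.191, 1.165
#>   significant components: 1 (ranks 1)

cor(ged$maps[, 1], gt$mixing_vectors[, 1])
#> [1] 0.9999003
```

The rank-1 eigenvalue (7.1) towers over the permutation threshold while the
remaining eigenvalues sit near 1, exactly one component is declared
significant, and its forward-model map reproduces the planted mixing vector
to r = 0.9999. A null session (all gains 1) run through the same chain
yields no significant components.

For the anatomy question, plant a source whose projection steps at every
nucleus boundary (levels 3/2/1/0 across lateral, basal, accessory basal,
central) and compare the changepoint grouping of its unit-variance rank-1
map with the annotations:

```r
cc <- component_concordance(m, session$annotations, n_perm = 1000, seed = 13)
c(observed = cc$match$n_matching, evaluated = cc$match$n_evaluated,
  null_mean = cc$null_mean)
#>  observed evaluated null_mean
#>    12.000    12.000     8.896
```

All 12 evaluated contacts are grouped in agreement with the anatomy, against
a cut-and-shift chance level of about 8.9.

## Command line

A subcommand front end is installed under `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lfpged.R", package="lfpged"))')" \
  simulate --seed 1 --out session_dir
# ... run | modality | concordance | tf | spectra | aggregate
```

Sessions live in a documented plain format: little-endian float64 LFP
(`lfp.f64`), a JSON sidecar (shape, rate, contact annotations), and a CSV
event table.

## Method documentation

`vignettes/lfp-ged-methods.Rmd` describes the model and its assumptions, the
permutation schemes, every tunable threshold with its default and origin,
what the synthetic world does and does not emulate, and the package's
resolutions of points the source procedure leaves unspecified.
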