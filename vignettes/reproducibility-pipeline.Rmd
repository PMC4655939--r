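---
title: "Probing the reproducibility of dual-regression rfMRI group analyses on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing the reproducibility of dual-regression rfMRI group analyses on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcrepro)
```

## The problem

Resting-state fMRI group studies of functional connectivity typically
estimate a subject's expression of a resting-state network (RSN) by dual
regression against a set of group-level independent components, and then
compare parameter estimates (P.E.) between groups, either within anatomical
ROIs or voxel-wise with permutation inference. Two analysis choices are
known to move the results substantially: how individual data are cleaned of
structured artefacts, and which component set (the *template*) is used as
the spatial regressors. `rsfcrepro` implements this full pipeline together
with a synthetic-data generator that plants a known, localized
basal-ganglia-like connectivity deficit in one of two groups, so that every
stage — cleaning, template construction, dual regression, ROI and
voxel-wise inference, and the reproducibility metrics used to compare
pipeline variants — can be tested against ground truth without any data
download.

## The generative model

A cohort consists of `n_controls + n_patients` 4D images on a common grid
with an ellipsoidal brain mask. Each subject's data is a linear mixture

$$y_v(t) = b + \sum_c \alpha_{c}\, m_c(v)\, a_c(t) + \varepsilon_v(t),$$

where $m_c$ are shared spatial maps (signal networks and artefact
components), $a_c$ are unit-variance subject-specific time courses,
$\alpha_c$ are subject component amplitudes, $b$ is a flat baseline, and
$\varepsilon$ is Gaussian noise (white by default; a smoothed-noise switch
is provided because the spatial autocorrelation of scanner noise is
unknown and configurable here). Because time courses are unit variance and
the amplitude multiplies the map, the stage-2 dual-regression P.E. is
directly interpretable as amplitude, which is what the ROI group
comparison measures.

The first network is the target: two bilateral clusters of three Gaussian
blobs each, whose cores define six disjoint ROIs (caudate, putamen,
pallidum analogues, left and right). Patients have the target network's
amplitude scaled by `1 - effect_size` inside the deficit mask — the
bilateral putamen cores — mirroring the bilateral-putamen topography of
the clinical finding the pipeline is designed to probe. Artefact
components emulate the noise classes ICA-based cleaning targets:
low-frequency drift (with a spatially sparse map concentrated at one end
of the readout axis), scattered signal spikes, a motion-coupled component
living on the brain edge whose time course correlates with the subject's
rigid-body traces, and a vessel-like inferior slab. Motion traces are
smooth random walks scaled to a target mean relative displacement; ages
and motion severity are drawn from the same distribution for both groups
so the cohorts are matched.

### Defaults and why

| parameter | default | unit | rationale |
|---|---|---|---|
| `grid_shape` | 20 x 20 x 12 | voxels | desk-scale grid that still separates 6 ROIs and 5 networks |
| `n_timepoints`, `tr` | 180, 2 | volumes, s | six minutes of data at TR 2 s, the acquisition scale of the study emulated |
| `n_controls`, `n_patients` | 19, 19 | subjects | the matched subsample size used for the cleaning comparisons |
| `n_networks`, `n_artefacts` | 5, 4 | — | a handful of RSNs plus the four artefact classes above |
| `effect_size` | 0.4 | fraction | a strong, unambiguous deficit, the regime the reproducibility questions presuppose |
| `noise_sd` | 1 | a.u. | voxel SNR of about 4:1 at network cores (amplitudes average 4) |
| `amp_mean`, `amp_sd` | 4, 0.5 | a.u. | between-subject amplitude CV of 12.5%; see the note below |
| `motion_severity_mean/sd` | 0.13, 0.05 | mm | mean relative displacement at the level reported for both clinical groups |
| `age_mean`, `age_sd` | 63, 9 | years | an elderly cohort; ages are only exercised as a covariate |
| `baseline` | 100 | a.u. | gives temporal SNR its conventional mean/SD meaning |

A note on `amp_sd` and ROI size: at desk scale, the smoothing kernel's
halo spreads each network's signature over a large fraction of the small
grid, so between-group *sampling* fluctuations of network amplitude
produce spatially extended t-elevations that compete with the planted
deficit in threshold-free cluster enhancement (TFCE) inference — an
artefact of the reduced geometry, not of the method. The amplitude CV
(12.5%) and ROI core radius (1.5 voxels, 19 voxels per ROI) are set so
that the planted deficit is the dominant group effect, which is the regime
the emulated study reports (a deficit "substantial in both magnitude and
extent"). These are properties of the synthetic study conditions, fixed
here once; they are not exposed tuning knobs of the analysis code.

## Cleaning variants

`clean_image()` applies spatial smoothing (separable Gaussian, sigma =
FWHM/2.3548 per axis, mask-renormalized so constants are preserved),
high-pass filtering, and then one of four nuisance-regression modes:

* `uncleaned` — smoothing and high-pass only;
* `motion24` — additionally regresses the 24-parameter motion design
  (6 rigid-body series, backward differences, and the squares of those
  12);
* `ica_soft` / `ica_aggressive` — `motion24` plus regression of
  artefact-labelled ICA component time courses. The *soft* variant fits
  signal and noise time courses jointly and removes only the noise part of
  the fit (the variance uniquely attributable to artefacts); the
  *aggressive* variant removes the full projection onto the noise design.
  Soft and aggressive coincide exactly when signal and noise time courses
  are orthogonal, and soft never removes more variance than aggressive.

Component signal/noise labels come from the generator's ground truth,
optionally passed through `corrupt_labels()`, which emulates an automated
component classifier by an operating point: each signal label survives
with probability TPR, each noise label with probability TNR. The defaults
(0.982, 0.658) and the alternative (0.969, 0.720) are the two
study-specific classifier operating points reported for the emulated
study; the classifier itself (feature extraction, training) is out of
scope. All regressions demean regressors and data and preserve the
per-voxel temporal mean, so temporal SNR (`tsnr_median()`: voxelwise
mean/SD over time, median over a once-eroded mask, zero-SD voxels excluded
with a count) remains well defined after cleaning.

**High-pass filter.** The filter projects each voxel's series onto the
complement of the span of sine/cosine pairs with period at or above the
cutoff (plus the mean). A cosine-only (DCT) drift basis was considered and
rejected: it cannot remove a sine-phase slow oscillation at the window
boundary (a 300 s probe keeps 5–12% of its amplitude for any window
length), whereas the full pair basis removes resolved sub-cutoff probes
essentially completely while passing a 50 s probe with gain above 0.99.
The cutoff default of 150 s matches the preprocessing the pipeline
emulates.

## Templates and dual regression

`concat_normalize()` demeans (and by default variance-normalizes) each
subject's voxel series and concatenates subjects along time;
`group_ica()` reduces the concatenated matrix to `d` dimensions by SVD and
estimates spatially independent maps with FastICA (non-Gaussianity of the
*maps* is maximized, the group-ICA convention for spatial ICA). Maps are
scaled to unit variance and signed to non-negative skewness so networks
are positive-bodied and runs are deterministic given a seed;
non-convergence triggers up to five seeded random restarts. For synthetic
runs `d` defaults to the true component count plus two — the fixed d = 50
used on real data has no desk-scale analogue, and a small surplus over the
true count keeps every source identifiable.

`assemble_template()` builds the two template flavours compared by the
pipeline: `all` (every component, order preserved) and
`network_plus_noise` (the target network first, then all noise-labelled
components). `match_target()` locates the target component as the largest
absolute spatial correlation with a reference map, erroring on genuine
ties (near-zero ties are reported as a non-match instead, since a
reference orthogonal to every component is the caller's rejection case,
not an ambiguity). `build_template()` additionally orients the matched
component to correlate positively with its reference: ICA sign is
arbitrary, and an anti-correlated target map would silently flip every
downstream group contrast.

Dual regression is two ordinary least-squares stages: stage 1 regresses
each time point's volume on all (demeaned) template maps simultaneously,
stage 2 regresses each voxel's series on all stage-1 time courses. Stage-1
time courses are variance-normalized before stage 2 by default, so the
stage-2 P.E. carries amplitude; the flag is exposed because the
convention is not universal. Component identity is positional from the
template — no per-subject reordering. One caveat worth knowing when
interpreting subset templates (`network_plus_noise`): when strong
networks are left out of the spatial regression, the estimated target
time course absorbs shared variance and its normalization couples every
subject's P.E. scale to the subject's overall network expression. On
synthetic cohorts with a strong planted deficit this shows up as a
spatially extended group effect surrounding the deficit; the all-component
template does not exhibit it. This mirrors the general advice that the
subset choice redistributes variance across regressors and is part of
what the comparison grid quantifies.

## Inference

ROI inference extracts the mean target-component P.E. within each atlas
ROI (`roi_mean_pe()`) and compares groups with the classical
pooled-variance two-sample t-test, Bonferroni-corrected across the six
structures (flag p < alpha/m). `t_from_summary()` reproduces a published
t-value from printed mean ± SD cells; it also exposes the Welch variant,
but only the equal-n pooled form is certified against the published
worked examples, because the published full-cohort table is internally
inconsistent between the two formulas and the equal-n table is not. ROI
tests take no covariates by default (whether the original ROI analysis
covaried for age is unstated).

Voxel-wise inference (`permutation_glm()`) tests a one-sided group
contrast on subject maps with age as a global covariate and grey matter as
a voxel-wise covariate (the subject's GM value at the voxel, demeaned), on
an analysis mask defaulting to mean GM > 0.3. Nuisance handling follows
the Freedman–Lane scheme: maps and the group regressor are residualized
against the nuisance design per voxel, residual rows are permuted, and the
full model is refitted; the permutation set is the distinct group-label
arrangements (sampled, or enumerated exhaustively with a warning when
`n_perm` reaches their number). Family-wise error is controlled by the
permutation distribution of the maximum TFCE score over the mask, with
`p = (1 + \#\{null \ge obs\})/(n_{perm}+1)` for sampled permutations.
TFCE uses E = 0.5, H = 2, 100 threshold steps, 26-connectivity — the
common reference defaults, all configurable. Both contrast directions are
run separately, as in the emulated analyses. One numerical detail: the top
integration threshold is set to the map maximum exactly rather than
`n_steps * (max/n_steps)`, which can round past the maximum and drop the
peak voxel's final contribution — a one-ulp difference with a visible
effect on the score.

## Reproducibility metrics and experiments

`spatial_correlation()` (Pearson over a mask) and `dice()`
(2|A∩B|/(|A|+|B|), defined as 0 with a warning when both masks are empty)
quantify similarity of t-maps and overlap of significant clusters.
`compare_variants()` runs a labelled grid of (cleaning × template)
variants on one cohort and classifies template pairs into the four
comparison classes: A — same `network_plus_noise` subset, different
cohort; B — same cohort, different subset; C — both all-components,
different cohort; D — both different. t-map correlations are computed over
the analysis mask (the published support is unstated); a variant with an
empty significant mask scores Dice 0 against any other and the pair is
flagged. `split_half()` repeatedly splits the cohort into disjoint,
group-stratified halves (disjointness chosen for independence; the
supplementary description does not fix it), runs the pipeline on each
half, and reports between-half Dice and t-map correlation — both metrics,
since the supplementary "reproducibility" measure is not precisely
defined. A degenerate test hook can force both halves identical, in which
case reproducibility must be exact.

## What the tests do and do not show

The test suite verifies the algebraic contracts of every operation against
independent oracles (explicit pseudoinverse fits, brute-force per-threshold
connected-component TFCE, exhaustive permutation enumeration, textbook
t-tests), the published worked examples from the ROI table, and the
qualitative simulation properties: the tSNR ordering uncleaned <
motion24 < ica_soft across subjects, FWE calibration under
effect-free cohorts (200 replicates at a 12 x 12 x 8 grid, 500
permutations), localized detection of the planted deficit with an empty
opposite contrast, the comparison-class ordering (class A similarity at or
above class D), and the template-composition property (an out-of-sample
control template detects the deficit at least as well as a mixed
all-component template, at the default grid with standard smoothing where
detection is not at ceiling). Problem sizes in the suite — grids from
10 x 10 x 8 to the default 20 x 20 x 12, 30–180 volumes, 100–500
permutations — were chosen as the smallest instances at which each
property is identifiable.

Passing these tests shows the pipeline's machinery is correct and that the
published qualitative orderings emerge under the stated generative model.
It does not show that the generator reproduces real rfMRI data:
haemodynamics, slice timing, k-space artefacts, registration misalignment
and physiological noise spectra are all absent by design, noise is white
by default, and the real-data voxel-wise maps, classifier accuracies and
full-cohort ROI table are not reproducible from synthetic cohorts at desk
scale.

## Known limitations

* Subset (`network_plus_noise`) templates couple P.E. scale to overall
  network expression (see above), so their significant clusters are
  spatially liberal on strong-effect synthetic cohorts; conclusions about
  *localization* should use all-component templates or ROI analyses.
* The FastICA separation floor for the brain-edge motion artefact map is
  about |r| = 0.92 against truth on default cohorts — its support overlaps
  every other component's edge, which caps achievable independence.
* Exhaustive permutation enumeration is by group-label arrangement; with
  continuous covariates the Freedman–Lane statistic is itself
  permutation-dependent, so "exhaustive" means exhaustive over the
  representative arrangement set, the convention of the reference
  implementations.
* `sim_config()` seeds the global RNG; cohort generation is byte-identical
  per seed but not independent of R's RNG kind (fixed to the session
  default Mersenne–Twister).
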