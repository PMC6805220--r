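---
title: "Models and methods behind dediffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dediffr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dediffr` implements a complete analysis chain for event-related fMRI
studies of associative recognition memory in which (i) encoding-phase
multivoxel patterns are compared across trials whose stimuli vary
systematically in relatedness, (ii) retrieval-phase regional activation is
contrasted between trial types that differ in retrieval-control demand
(hits to intact pairs versus correct rejections, CRs, of recombined
pairs), and (iii) hippocampal–cortical coupling is estimated per trial
type by beta-series correlation. Because no scan data are distributed with
such studies, the package ships a synthetic-data generator that plants the
representational, activation and connectivity structure the analysis is
meant to detect, so every stage is testable end-to-end.

# Experimental design

The stimulus set is a fixed 2 × 2 × 2 hierarchy: two categories (object,
scene), two subcategories per category (living/inanimate; indoor/outdoor)
and two picture exemplars per subcategory. Pairs of trials are scored at
four relatedness levels — same exemplar (SE), same subcategory (SS), same
category (SC), different category (DC). 192 trial-unique adjectives are
paired with pictures and split into three 64-item study lists, each
balanced at 8 pairs per picture; half of each list is tested intact, half
recombined, counterbalanced over two versions so each pair appears once in
each status across versions.

Two design questions are not fixed by the construction rules and were
decided here:

* **Recombination scheme.** Recombined pairs must re-pair a studied
  adjective with a different picture studied in the same list. We apply a
  random derangement of the eight picture identities to the recombined
  subset, which simultaneously guarantees "different picture" for every
  adjective and preserves the 8-per-picture balance of the test list. We
  do not constrain the derangement to stay within or cross categories —
  the construction rules do not say, and the derangement treats both
  cases symmetrically.
* **Sequencing.** Trial orders are drawn by rejection sampling (full
  reshuffle on any violation, default cap 10,000 attempts), which is
  uniform over the valid orders. Constraints: at most 4 consecutive
  same-category pictures, at most 2 consecutive presentations of a
  picture, and (test phase only) at most 4 consecutive same-status
  trials.

Adjectives are synthetic tokens (`adj_0001`, …): the actual word list is
not part of the published materials, and nothing downstream depends on
word identity.

# The generative model

`simulate_run()` builds each run as

$$Y(v, t) = B + \sum_{\text{trials } i} s_i(t)\, a_i(v) + d(v, t) + \varepsilon(v, t),$$

with baseline $B = 100$, $s_i$ the canonical HRF-convolved delta regressor
of trial $i$, $d$ a slow cosine drift and $\varepsilon$ AR(1) noise. The
amplitude map $a_i(v)$ carries all planted structure:

* **Representational geometry (VTC, study phase).** Each trial's pattern
  is $w_b P_b + w_c P_{cat} + w_s P_{sub} + w_e P_{ex} + w_t \epsilon_i$
  over VTC voxels, with component maps drawn once per subject (standard
  normal, standardised). With unit-variance independent maps the expected
  trial-pair correlation is the share of common variance, e.g.
  $E[r_{SE}] = (w_b^2+w_c^2+w_s^2+w_e^2) / (w_b^2+w_c^2+w_s^2+w_e^2+w_t^2)$,
  dropping unshared terms for SS/SC/DC (`expected_similarity()`, the
  closed-form oracle used by the tests).
* **Condition activation.** Region amplitude by (region, phase, outcome):
  hippocampus and angular gyrus respond more to hits than CRs in both
  groups; DLPFC responds more to CRs than hits in the young preset only;
  VLPFC carries only a small, non-significant trend, matching the pattern
  of reported results.
* **Trial-wise coupling.** A latent scalar $\xi_i$ (SD 0.5) is added to
  the hippocampal seed amplitude and, scaled by
  $\kappa(\text{target}, \text{outcome})$, to each cortical target. The
  young preset sets $\kappa_{\text{VLPFC}}(CR) = 1.0$ versus
  $\kappa_{\text{VLPFC}}(hit) = 0.4$ and flat 0.7 elsewhere; the old
  preset is flat per trial type with a higher overall level (0.9),
  mirroring the reported old-greater-overall-coupling pattern.

## Preset parameter choices

The presets are the package's statement of the world the analyses are
meant to recover; they were fixed once, from the quantities the modelled experiment
reports, and are not tuned against test outcomes.

* **Pattern weights.** Young: $w = (0.30, 0.60, 0.40, 0.30, 1)$, giving
  expected level correlations ≈ .41/.36/.27/.05 — a graded profile with
  the exemplar step smallest, matching the ordering of the reported
  difference-score statistics. Old: $(0.45, 0.49, 0.17, 0.07, 1)$ —
  lower exemplar/subcategory weights and a higher shared baseline, i.e.
  dedifferentiation expressed as both reduced similarity of related
  events (≈ .32/.32/.30) and inflated similarity of distinct events
  (DC ≈ .14).
* **Between-subject heterogeneity.** Log-normal jitter (SD 0.25) on
  pattern weights and coupling, Gaussian jitter (SD 0.25) on region
  amplitudes, and per-trial amplitude jitter (SD 0.3). Without such
  heterogeneity group comparisons become arbitrarily significant because
  each subject's level means average thousands of trial pairs.
* **Behavioural rates.** Per-subject hit/CR probabilities are drawn
  around the group means implied by the reference trial-count table
  (85.05/96 and 89.60/96 young; 71.90/96 and 72.0/96 old) with
  between-subject SDs chosen so simulated count SDs match the reference
  ones after removing binomial variance: e.g. young hits,
  $\sqrt{7.3^2 - 96 p(1-p)}/96 = 0.068$. No-response trials are off by
  default (rates of 1–2.5% would remove ~2 trials per subject and
  nothing downstream depends on them); a `p_none` parameter exists.
* **Noise.** AR(1) with marginal SD 1 and $\rho = 0.12$, plus a 300 s
  cosine drift (amplitude 2, per-voxel scale jitter) chosen to lie below
  the 128 s high-pass cutoff so the drift basis provably removes it.
* **Seed subregion.** A small `HIPP_PEAK` sphere inside the hippocampus
  carries the strongest hit > CR amplitude (2.6 vs 1.2 elsewhere in
  HIPP), making the participant-specific peak localisable in ≥ 95% of
  simulated subjects at default SNR — the property the seed-construction
  stage is designed to have.

What a green recovery test establishes: that the pipeline detects the
planted effects at the stated power in a world with independent Gaussian
voxel noise, AR(1) temporal structure, exact grid alignment, no motion,
and no physiological or vascular artefacts. It does not establish
performance under realistic spatial noise correlations, registration
error, or susceptibility dropout — none of which the generator emulates.

# GLM estimation

The canonical HRF is the double-gamma difference (peak 6 s, undershoot
16 s, dispersions 1, ratio 1/6, 32 s support), normalised by its
*continuous* peak so that coarse samplings are exact subsamples of fine
ones. Event regressors are delta functions convolved on a 0.1 s grid and
sampled at volume onsets $0, T_R, 2T_R, \dots$ (one of two defensible
sampling conventions; chosen to make a trial at $t = 0$ reproduce the
sampled kernel exactly). Drift is modelled by the discrete-cosine set with
$K = \lfloor 2 n T_R / \text{cutoff} \rfloor$ components (6 for 205
volumes at TR 2 s and a 128 s cutoff).

Estimation is voxelwise OLS; `whitening = "ar1"` estimates a single pooled
lag-1 residual autocorrelation, prewhitens both sides per session and
refits — a deliberate simplification of full restricted maximum
likelihood, adequate here because the generator's AR coefficient is small
and shared across voxels. Single-trial betas use the least-squares-all
scheme: one joint model with 192 trial regressors plus per-session drift
and mean columns (motion columns are accepted but dropped when constant,
as in synthetic data). Percent signal change scales a condition beta by
100 × (unit-event peak on the microtime grid) / voxel session mean —
the convention is not dictated by the analysis description, so it is
fixed and documented here; with delta events the peak factor is 1 by
construction.

# ROIs

Sphere masks take every voxel whose *centre* lies within the radius of
the centre of the voxel containing the requested coordinate; this is the
convention that yields the quoted 19 voxels for a 5 mm sphere on a 3 mm
grid, and makes counts translation-invariant. Cortical ROI defaults are
the conventional retrieval-network peak coordinates (DLPFC −47, 17, 24; VLPFC −45, 35, −4;
ANG −45, −69, −6; 10 mm radius) — the ANG z-coordinate is anatomically
surprising but is taken verbatim and left configurable. The
localizer-defined VTC mask uses a voxelwise paired contrast across
subjects, two one-sided tests per voxel with Bonferroni control over the
in-mask voxels (random-field-theory FWE is out of scope); a sign-flip
max-statistic permutation option is provided. The participant-specific
hippocampal seed is a 5 mm sphere at the in-mask peak of the subject's
hit > CR contrast, ties broken at the smallest voxel index with a
warning, and the sphere deliberately not clipped to the search mask.

# RSA and connectivity conventions

Pattern similarity uses unsmoothed single-trial betas, Pearson
correlation over VTC voxels, Fisher z before averaging (values at
|r| ≥ 1 are clipped to ±(1 − 10⁻⁷) with a warning), unordered
*across-run* pairs only, diagonal excluded, missing entries dropped with
counts reported. Difference scores are SE−SS (exemplar), SS−SC
(subcategory), SC−DC (category). The one-sample tests on difference
scores report two-sided p-values with the sign of the effect; the
source analysis phrased them directionally, and the two-sided choice is
conservative by a factor of two.

Beta-series connectivity averages the betas over ROI voxels first and
correlates the mean series (not the mean of voxelwise correlations — the
two differ, and a test documents the distinction), separately within hit
and CR trials, from smoothed data, with a configurable minimum trial
count (default 10). Averaging and testing are on the Fisher-z scale;
r is reported alongside. Raw betas are correlated without per-session
standardisation, since session means are nuisance-regressed in the trial
GLM.

# Group statistics

`mixed_anova()` implements the classical balanced split-plot partition:
Group against subjects-within-groups; Level and Group × Level against the
Level × subjects-within-groups residual. It is verified against
`stats::aov` with an `Error(subject/level)` stratum. The identity
"two-level within-F equals the squared paired t" holds exactly in the
one-group reduction and is tested there; with a Group factor the error
stratum excludes the interaction SS, so the two differ slightly by
construction. The 4-level ANOVA reports uncorrected degrees of freedom
(a 2 × 4 design at n = 40 gives (3, 114) for the within effects; the (3, 151) degrees of freedom sometimes quoted for this design are not
consistent with any standard partition and are not reproduced). Sphericity correction is out of scope for
two-level factors and deliberately omitted for the four-level analysis.

Behavioural scoring uses all presented trials of a status (96) as the
proportion denominator, so no-responses count against accuracy; a
`denominator = "responded"` switch exists because the modelled analysis does not state its
treatment of no-responses. Group comparisons default to the pooled-variance t
(df = 38 at n = 20/group, matching the reference degrees of freedom);
Welch is available.

# Numerical and runtime choices in the test suite

The acceptance suite runs the full pipeline at the full temporal design
(6 runs × 64 trials, 205 usable volumes, TR 2 s) on a reduced 12 × 12 × 8
voxel grid with smoothing disabled. With smoothing off and independent
voxel noise, voxels outside the union of analysis masks cannot influence
any result, so the generator's mask-restricted fast path is an exact
shortcut, not an approximation. Power is estimated over 50 replicate
cohorts at n = 20/group; the type-I calibration runs 50 null-preset
replicates at n = 8/group, since the size of the tests does not depend on
n. Rates are compared with α = 0.05 within three binomial standard
errors.

# Known limitations

* The NIfTI-1 reader/writer is minimal by design: single-file
  little-endian images, a small datatype set, sform-only orientation.
* AR(1) whitening pools one coefficient over voxels and sessions; SPM's
  REML estimates richer covariance structure.
* Whole-brain FWE control is Bonferroni or sign-flip permutation;
  random-field theory and cluster inference are out of scope.
* The generator does not simulate motion (motion regressors are zeros
  and hence dropped), physiological noise, or spatial noise correlation.
* MRI preprocessing (realignment, slice timing, normalisation) is out of
  scope; real data must arrive on a common grid.
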