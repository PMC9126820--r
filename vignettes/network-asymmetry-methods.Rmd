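---
title: "Methods: intra-individual hemispheric covariance network asymmetry"
author: "hemisnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-individual hemispheric covariance network asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Structural covariance networks describe how regional brain morphology
covaries across a cortex. In the usual group-level construction an edge is a
cross-subject correlation of regional measures, which yields one network per
group and no subject-level statistic. `hemisnet` implements the
*intra-individual* construction instead: for each subject, regional cortical
thickness values (34 Desikan–Killiany regions per hemisphere, in mm) are
standardized against control statistics and the similarity of every pair of
regions *within that subject* forms the edge weight. This yields two 34-node
networks per subject — one per hemisphere — so hemispheric asymmetry of
network topology becomes an individual-level quantity that can be compared
between diagnostic groups with ordinary mixed models.

The target application is multi-site case–control cohorts (for example
autism-spectrum-disorder consortium data pooled over tens of scanners),
where dataset heterogeneity makes a random-intercept model and
within-dataset standardization essential.

# Pipeline

1. **Control reference.** Per dataset and region, the mean and sample SD
   (denominator `n − 1`) of the controls only. Controls must number at
   least two per dataset; a zero SD is an error rather than a silent
   division. Referencing is within-dataset because scanners differ between
   datasets; a pooled reference is available behind a flag.
2. **Standardization.** `z = (t − mean) / sd` with each subject scored
   against its own dataset's reference. Controls of a dataset thus have
   per-region mean 0 and SD 1; cases need not.
3. **Weighted networks.** For each subject and hemisphere, the edge weight
   between regions *i* and *j* is the Gaussian similarity kernel
   `w_ij = exp(−(z_i − z_j)² / 2)`, giving a symmetric 34 × 34 matrix with
   561 distinct pairs, zero diagonal, weights in (0, 1].
4. **Binarization.** The strongest `floor(S × 561)` edges are set to 1
   (224 at the default sparsity `S = 0.4`), the rest to 0, so every
   subject's network has an identical edge count and topological metrics
   are comparable across subjects.
5. **Metrics.** Node level: degree centrality, clustering coefficient,
   nodal global efficiency, nodal local efficiency. Hemisphere level: the
   normalized clustering coefficient γ, normalized characteristic path
   length λ and small-world index σ = γ/λ, normalized against
   degree-preserving rewired null networks.
6. **Asymmetry and inference.** For every metric, `HD = Left − Right`
   (positive = leftward asymmetry). Case–control differences are tested
   with `HD ~ diagnosis + age + sex + (1 | dataset)`, Cohen's *d* derived
   from the diagnosis *t*, empirical two-tailed p-values from label-swap
   permutations, Bonferroni correction over the 3 hemisphere-level HDs and
   per-metric Benjamini–Hochberg FDR over the 34 node-level HDs (threshold
   0.05/4 for the four node metrics). Significant HDs get unilateral
   (left-only/right-only) follow-up models and, for degree centrality,
   a descriptive edge-level analysis of the 33 unthresholded seed edges
   (BH at 0.05 per seed). Follow-up tiers are reported uncorrected, as
   descriptive analyses.

## Why a difference rather than a laterality index

`HD = Left − Right` is used instead of the normalized index
`(L − R)/(L + R)` because several metrics (degree, clustering, local
efficiency) can legitimately be zero in one hemisphere, which makes the
normalized index unstable or undefined.

# The kernel choice and what depends on it

The binarization step only consumes the *ranking* of edge weights, and any
strictly decreasing function of `|z_i − z_j|` produces the same ranking.
All binary-topology results — every metric, every HD test — are therefore
bit-identical across such kernel choices; the test suite asserts this
directly. The Gaussian kernel matters only for the *unthresholded*
edge-level analysis, where weights are used as-is. For that tier the
package documents that signs, ranks and inference calibration are
kernel-robust while raw magnitudes are kernel-specific.

# Mixed-model estimation and permutation inference

The model has a single random intercept (dataset). Writing λ for the ratio
of between-dataset to residual variance, the covariance `V = I + λZZ'` is
block diagonal, so for fixed λ every generalized-least-squares quantity
reduces to group-sum corrections of the ordinary crossproducts. The REML
criterion is profiled and minimized over `log λ` (coarse grid plus
golden-section refinement) in compiled code. This makes a full refit cheap
enough to be repeated for every permutation — the package refits the model
`n_permutations` times per test rather than permuting residuals — and the
test suite verifies that estimates, standard errors and *t* statistics
agree with `lme4::lmer(..., REML = TRUE)` to ~1e−6.

Permutations swap diagnosis labels *within dataset* by default, preserving
each dataset's case/control count; this respects exchangeability under the
random-intercept model. Global swapping is available behind a flag. The
empirical p uses add-one smoothing,
`p = (1 + #{|t_perm| ≥ |t_obs|}) / (1 + n_perm)`, so p is never zero and is
floored at `1/(n_perm + 1)`. Because the same estimator is used for the
observed and permuted fits, the test is valid regardless of estimator
details.

## Two permutation schemes

The default scheme swaps labels and refits the model on the *fixed* metric
outcomes. That is exact only if the metric outcomes themselves are
exchangeable between cases and controls under the null — and the
construction quietly breaks this in small samples, because controls define
the standardization reference: within each dataset the controls'
z-scores average to exactly zero per region (they are scored against
themselves), while cases are scored against an external reference. Case
and control metric distributions therefore differ slightly even when no
group effect exists, case HDs are a little more variable than control
HDs, and relabeling at the model stage — which never recomputes the
reference — inherits that asymmetry as anticonservatism. The distortion
scales like `1/n_controls` per dataset: irrelevant for consortium-sized
datasets with dozens of controls, but material when a dataset contributes
only a handful.

[run_pipeline_permutation()] therefore implements the exact alternative
for node-level metrics: every permutation re-runs the complete
construction — pseudo-controls define the reference, all subjects are
re-standardized, networks rebuilt and re-thresholded, metrics recomputed
— before the model is refit. Because the raw thickness data are
exchangeable under the null, this scheme is exact at any control count;
its calibration at 6 controls per dataset is verified in the test suite.
Degree centrality has a compiled fast path (the rank thresholding reduces
to a selection problem on |z_i − z_j|); the other node metrics re-run the
R construction per permutation and suit smaller `n_permutations`. The
model-stage swap remains the default because it is the appropriate,
inexpensive choice at the multi-site scale the pipeline targets; the
pipeline scheme is recommended whenever per-dataset control counts are
small.

Cohen's *d* is converted from the diagnosis *t* as
`d = t(n1 + n2) / (sqrt(n1 n2) sqrt(df))` with `df` the residual degrees of
freedom of the fixed-effects design (`n − p`). This two-group conversion is
implemented in one isolated function so an alternative convention can be
swapped in without touching the inference chain.

# Null networks

γ and λ normalize against Maslov–Sneppen degree-preserving double-edge-swap
randomizations (igraph's `keeping_degseq`), with an attempt budget of
`rewire_factor × edge count` swaps (default 10×) and `n_null_networks`
nulls (default 100), both configurable. The budget counts *attempted*
swaps; at the densities involved (224 of 561 edges) the acceptance rate is
high and doubling the budget does not change the normalization materially.
Rigid graphs that admit no legal swap are returned unchanged and flagged.
Null seeds derive from the subject index only — not the hemisphere — so
relabeling hemispheres permutes results exactly rather than approximately.

# Degenerate inputs and numerical conventions

* Disconnected binary networks: path lengths average over reachable pairs
  only, efficiencies count unreachable pairs as contributing 0, and the
  network is flagged. At `S = 0.4` (mean degree ≈ 13) disconnection is
  rare.
* Clustering and local efficiency are defined as 0 for nodes of degree
  < 2; an edgeless graph is an error (path length undefined).
* Sparsity ties are broken by stable sort on (weight descending, then
  upper-triangle pair index), so binarization is deterministic on every
  platform; ties have measure zero for continuous data. The rank
  thresholding also makes edge sets *nested* across the sparsity sweep.
* Perfect (noise-free) fits clamp the residual variance away from zero so
  the REML criterion stays finite; coefficients are still recovered
  exactly.
* Subjects with missing age, sex or outcome are excluded from a fit with a
  reported count; within-case variables non-missing for fewer than 20
  cases produce a flagged skip record, not an error.

# The synthetic cohort generator

No public cohort ships with the package, so `sim_config()` /
`generate_cohort()` define the study conditions every test runs under.
Thickness for subject *k*, region *r*, hemisphere *h* is

```
t = mu_r + delta_dataset + beta_age (age_k − age_ref) + beta_sex male_k
    + g_k + eps_krh
```

with regional means `mu_r ~ U(1.8, 3.2)` mm shared by both hemispheres,
dataset offsets (SD 0.10 mm) standing in for scanner effects, a bilateral
age slope of −0.01 mm/yr referenced at 15 years and a sex effect of
0.02 mm (age and sex effects are bilateral, hence nearly invisible to HD
statistics), a shared per-subject factor `g_k` (SD 0.10 mm) that creates
the positive inter-regional covariance structural covariance presupposes,
and independent region noise (SD 0.15 mm). Ages are uniform on 6–30 years
and 80% of subjects are male, matching the strongly male cohorts typical
of this field. Defaults use 5 datasets of 6 + 6 subjects — dataset count is
a free parameter and desk-scale tests do not need the full consortium's
43 sites.

Group effects are injected by *coupling*: for a chosen (region,
hemisphere, group), the region's deviation from its population mean is
replaced by `(1 − α) · own + α · hemisphere-mean deviation`. Pulling a
region toward its hemisphere's profile shrinks its idiosyncratic
component, which shrinks `|z_i − z_j|` to every other region, raises its
similarity rank, and therefore raises its degree after thresholding — so
the injected effect must survive the entire pipeline (standardization →
kernel → sparsity → metrics → mixed model) to be detected. The coupling
acts on deviations rather than raw thickness so that the coupled region's
*mean level* is preserved; coupling raw values would shift the region by
α·(hemisphere mean − regional mean), a level artifact that would dominate
and even invert the intended rank effect.

The canned `make_fixture()` conditions are: `tiny` (2 datasets × 6
subjects, smoke tests), `null` (5 × 12, α ≡ 0 — used for type-I
calibration), `effect` (5 × 80, right-fusiform coupling α = 0.6 in cases —
used for sign and significance recovery; cases' right fusiform degree
rises, so its degree HD shifts negative, i.e. reduced leftward asymmetry).

What the generator does *not* emulate: realistic anatomical covariance
structure beyond a single shared factor, region-specific age
trajectories, site-by-region interactions, motion or segmentation
artifacts, and diagnosis differences in mean thickness. Passing tests
demonstrate that the pipeline recovers what it is designed to recover
under its own assumptions — not that real cohorts satisfy those
assumptions.

# Sensitivity analyses

* **Sparsity sweep.** Weighted networks are built once and re-thresholded
  at each S in 0.25–0.50 (step 0.01; outside this range such networks
  lose connectedness or small-world organization). Each
  subject/hemisphere/metric curve is integrated by the trapezoidal rule,
  and the mixed-model analysis is run on the HDs of the AUCs. HD-of-AUC
  equals AUC-of-HD because both operations are linear; the suite asserts
  the identity.
* **Model variants.** The main models are refit with a centred quadratic
  age term `(age − mean age)²`, and with the subject's mean thickness over
  all 68 regions as an extra fixed effect. Adding a constant to every
  region of every subject leaves all HD conclusions unchanged (z-scores
  and hence networks are shift-invariant), which the suite also asserts.

# Problem sizes used by the shipped tests

The packaged tests and the acceptance script run at desk scale, chosen as
reasonable Monte-Carlo compromises: type-I calibration uses 200 replicate
null cohorts (60 subjects each) at 500 full-pipeline permutations with a
single pre-specified node test (fusiform degree HD); effect recovery uses
20 replicate effect cohorts (400 subjects) at 3,000 full-pipeline
permutations — 3,000
rather than the 10,000 production default because a BH-corrected discovery
at 0.05/4 over 34 nodes needs the add-one floor `34/(n_perm + 1)` below
0.0125, i.e. `n_perm ≥ 2,720`. Production analyses should keep the 10,000
default.

# Known limitations

* Inter-hemispheric edges are out of scope by design; the two hemispheric
  networks are built and compared separately.
* Only binary-graph metrics are provided; weighted variants (and
  modularity-type metrics, which involve arbitrary resolution choices)
  are not.
* The hemisphere-level γ/λ/σ depend on null-network sampling noise;
  `n_null_networks` trades precision for runtime.
* The REML engine covers exactly the single-random-intercept designs the
  analysis uses; it is not a general mixed-model solver.
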