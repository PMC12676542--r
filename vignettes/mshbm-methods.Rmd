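---
title: "Individual-specific cortical networks and language laterality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific cortical networks and language laterality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshbm)
```

## The problem

Resting-state cortical networks vary substantially across individuals, and
in drug-resistant epilepsy the language system in particular can reorganize
(inferior frontal regions coupling to default-mode territory). Group-average
parcellations blur these differences. This package implements a pipeline
that (1) derives group-average networks by clustering functional
connectivity profiles on the unit hypersphere, (2) refines them into
individual-specific parcellations with a multi-session hierarchical
Bayesian model (MS-HBM), (3) quantifies parcellation quality with
leave-one-run-out connectional homogeneity and stimulation-evoked
inhomogeneity, and (4) summarizes language-network topography as a
hemispheric laterality index used to predict language dominance. A
synthetic-cohort generator with known ground truth makes every stage
testable without patient data.

## Connectivity profiles

For each cortical vertex we compute Pearson correlations between its time
course and a set of R ROI time courses, keep the largest
`ceiling(top_fraction * R)` as 1 (default `top_fraction = 0.10`), zero the
rest, and L2-normalize the row. At full scale (1175 ROIs) the top decile
keeps 118 entries; at the package's synthetic scale (R = 50) it keeps 5.
Using the ceiling guarantees at least one retained entry for any R. Ties at
the cutoff are broken by larger correlation, then lower ROI index; both
choices are configurable in spirit but fixed here so that profiles are
reproducible. Correlations are not Fisher-transformed before ranking —
ranking is invariant to any monotone transform, so the binarized profile
would be identical. Binarized, unit-normalized profiles live on the
hypersphere, which motivates von Mises-Fisher (vMF) machinery throughout.

Runs acquired under intermittent electrical stimulation are first censored
to rest-only frames: stimulation blocks are dropped entirely and the first
`discard_frames` (default 4) frames of each rest block are discarded to let
the hemodynamic response of the preceding block wash out.

## Group networks: vMF mixture clustering

Pooled profiles from all training subjects and sessions are clustered with
a K-component mixture of von Mises-Fisher distributions (default K = 15 at
full scale; the synthetic experiments use K = 5). EM runs in the log
domain; mean directions are responsibility-weighted resultants, and each
concentration is estimated from the mean resultant length r̄ by the
closed-form approximation κ ≈ r̄(d − r̄²)/(1 − r̄²), then refined by a 1-D
likelihood maximization. The refinement matters: the closed form is an
approximate inverse of the Bessel ratio A_d(κ), and using it directly can
produce tiny log-likelihood decreases; with the refinement the EM objective
is monotone to numerical tolerance, which the tests assert on every run.
Concentrations are per-cluster by default (a shared-κ mode exists), clipped
at 1e5 to keep exponentials finite when clusters become near-degenerate.
The best of `n_init` (default 10; 3 in the heavier pipeline stages) seeded
restarts is kept. An emptied cluster is re-seeded from the worst-fit row.
Group labels are assigned per vertex by the summed responsibility across
that vertex's pooled rows — the pooling rule is our choice, as is most of
the label-assignment detail at this stage; no spatial constraint is applied
until the hierarchical model.

## The multi-session hierarchical Bayesian model

The generative hierarchy has three vMF levels plus a spatial label prior:

- group mean directions μ_k;
- subject means μ_k^s ~ vMF(μ_k, ε_k) — inter-subject functional
  connectivity variability;
- session means μ_k^{s,t} ~ vMF(μ_k^s, σ_k) — intra-subject (inter-session)
  variability;
- observations x_v^{s,t} ~ vMF(μ_{l_v}^{s,t}, κ) with a single shared
  observation concentration;
- label field P(l) ∝ exp(Σ_v log θ_v(l_v) + c Σ_{(u,v)∈E} 1[l_u = l_v]),
  where θ is the inter-subject spatial variability prior (per-vertex
  distribution over networks) and c ≥ 0 the smoothness weight.

We fit by blocked coordinate ascent with point estimates: iterated
conditional modes (ICM) for the labels, closed-form normalized resultants
for the three levels of means (each MAP direction is the normalized sum of
the likelihood resultant and the prior direction scaled by its
concentration), concentration updates by the refined r̄ inversion, and θ as
Dirichlet-smoothed empirical label frequencies (pseudocount α = 1). A full
variational treatment of the same hierarchy is possible and the module API
leaves room for one; point-estimate EM/ICM keeps the implementation
tractable and testable while preserving the generative structure.

The tracked objective is the complete-data pseudo-log-joint: the MRF
partition function is omitted (it is constant in everything we update
except θ when c > 0, the standard pseudo-likelihood convention). Every
update weakly increases this quantity, so the trace is monotone, which is
asserted in the tests. Sharing κ across networks has a useful side effect:
the vMF normalizer cancels in the ICM label energies, so label updates
reduce to comparing κ·Σ_t x_v·μ_k^{s,t} + log θ_v(k) + c·(same-label
neighbor count). ICM sweeps run in fixed ascending vertex order (at most
10 per outer iteration by default, 50 overall cap in inference); energy
ties are broken by larger θ, then lower label index. All of these
determinism choices exist so that a cohort, a training run, and a report
are bit-reproducible from a root seed.

Inference for a new subject freezes the group-level parameters and
alternates session/subject mean updates with ICM sweeps until labels stop
changing. One session suffices (the hierarchy shrinks the subject means
toward μ_k in proportion to ε, σ); more sessions sharpen the estimate, and
a test checks that recovery quality never degrades with added sessions.

Two collapse limits anchor correctness: with ε, σ → ∞, c = 0 and uniform θ,
inference must equal independent per-vertex maximum-likelihood labeling
(checked exactly against a brute-force argmax oracle), and increasing c
must never increase the number of connected label components.

## Evaluation metrics

Resting-state homogeneity of a parcellation on a run is the mean
correlation of each member vertex with its network's mean time course,
averaged over networks with vertex-count weights ("accounting for network
size"). Weighting is done over the whole cortex rather than per hemisphere
— the natural reading, though a per-hemisphere variant would differ only
through hemispheric size imbalance; an equal-weight mode is retained for
sensitivity checks. A singleton network's homogeneity is defined as 1
(its vertex is its own mean); its z-score standard deviation is defined as
0. Task inhomogeneity is the size-weighted mean of the within-network
sample standard deviation (denominator n − 1) of stimulation z-scores;
lower is better.

The stimulation GLM is ordinary least squares of each vertex on an
intercept plus the stimulation boxcar convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, 1:6 ratio), with z the
t-statistic of the stimulation regressor. No autoregressive prewhitening or
nuisance regression is modeled — the synthetic noise is white by
construction, and a calibration test confirms the null rejection rate at
|z| > 1.96 matches the t reference.

Leave-one-run-out evaluation estimates labels from n − 1 runs and scores
the held-out run, averaging over folds; a probe test verifies the held-out
run can never influence its fold's labels. Approaches are compared with
two-tailed paired t-tests (dof = subjects − 1) over all C(A, 2) pairs,
Benjamini-Hochberg corrected, significant at q < 0.05. A pair with a
zero-variance difference vector has no defined t and is reported as NA
rather than 0 or 1.

## Laterality

LI = (LH − RH)/(LH + RH) over vertices assigned to the two designated
language networks (Language A and Language/Default B pooled), computed from
integer counts so it is exact. An LI with zero language vertices is flagged
undefined and excluded downstream, never coerced to 0. Dominance groups are
compared by one-way fixed-effects ANOVA; predictive power is one-vs-rest
ROC/AUC via the Mann-Whitney concordance with half credit for ties. Scores
are oriented +1 (higher LI ⇒ positive) for the left-dominance contrast and
−1 for right dominance; bilateral-vs-rest uses raw LI by default, which is
a documented limitation — the bilateral group sits between the other two,
so raw LI cannot separate it well (an |LI − median| auxiliary score is
noted as an alternative). Inter-subject topographic similarity uses the
per-network Dice coefficient over all subject pairs.

## The synthetic cohort generator

The generator is first-class, tested code; it plants a known truth so every
downstream claim is checkable.

- **Geometry.** Two hemispheres of `n_per_hemisphere` vertices (default
  100 in the pipeline; 300 in the recovery experiments) as rings or grids,
  never connected across the midline — a desk-scale stand-in for the
  81,924-vertex cortical surface. All algorithms are graph-generic.
- **Group truth.** K contiguous patches per hemisphere grown by seeded
  multi-source BFS. Each ROI (default R = 50, versus 1175 at full scale)
  is assigned a parent network round-robin; the true network directions
  are unit-normalized ROI-set indicators with a small nonnegative jitter,
  so they are near-orthogonal and generated profiles point at them. A
  minimum pairwise angle is enforced with bounded retries.
- **Individual deviations.** Boundary vertices flip to a neighboring
  network with probability `deviation_rate` (default 0.1), preserving
  contiguity.
- **Planted laterality.** Each subject's target LI is drawn from a normal
  with the dominance group's reported moments — left 0.165 ± 0.106,
  bilateral 0.056 ± 0.074, right 0.023 ± 0.055 — truncated to [−1, 1];
  these moments are the study's published group statistics, used here as
  generator defaults because no generative recipe exists at the subject
  level. Vertices are then transferred between the language networks and a
  single designated donor network per hemisphere until the achieved LI is
  as close as moves allow to the target (flagging the subject if the
  supply of border vertices runs out before ±0.02). Transfers continue
  while they strictly reduce the distance to the target; stopping at the
  first entry into the tolerance band would bias achieved LIs low by up to
  the tolerance. Restricting transfers to one donor keeps the asymmetry
  confined to the language system, which the specificity control (AUC ≈
  0.5 when asymmetry is planted elsewhere) depends on. Per-group counts
  are not published for the 43 dominance-labeled participants, so the
  generator defaults to 15/14/14.
- **Signals.** Each network carries an i.i.d. standard-normal latent
  signal per run; vertices and ROIs observe their network's signal scaled
  by √snr (default snr = 4) plus unit white noise. Stimulation runs add an
  HRF-convolved boxcar of amplitude `effect` to stimulated-network
  vertices, using the same HRF as the analysis GLM.

What the generator does **not** emulate: hemodynamic autocorrelation,
physiological noise, spatial noise correlations, magnitude-dependent
signal scaling, volumetric geometry, lesions, or scanner/site effects
beyond seed differences. Passing tests therefore demonstrate algorithmic
correctness and internal consistency — recovery of planted structure under
idealized noise — not clinical performance on real fMRI.

## Numerical choices

- vMF radial sampling uses a Wood-style beta-envelope rejection sampler;
  tangential directions are isotropic Gaussian projected orthogonally to
  the mean. κ = 0 falls back to uniform sphere sampling.
- Bessel-dependent quantities (A_d(κ), log C_d(κ)) use exponentially
  scaled `besselI`, with large-argument asymptotics past its range.
- Concentrations are clipped at 1e5; r̄ is clamped below 1 before
  inversion.
- EM convergence: |Δ log-lik| < 1e-5·|log-lik|; MS-HBM outer loop 1e-6
  relative, default 30 iterations (10 in the pipeline stages).
- Seeds: every stochastic stage derives a 32-bit child seed from the root
  seed and a stage tag via a string hash, so stages are independently
  reproducible and reordering one does not perturb another.

## Problem sizes

The packaged experiments use V = 600 (300 per hemisphere), K = 5, R = 50,
20 training subjects × 2 sessions, T = 200 frames at snr = 4 for the
recovery studies; the pipeline demonstration and smoke configuration use
V = 80–200, K = 4–5, T = 60–150 with 4–8 training and 6–9 test subjects.
These sizes were chosen so a full run completes on a laptop-class single
core in seconds to a couple of minutes while leaving all algorithmic
structure intact; everything scales to larger graphs by configuration.

## Known limitations

- Point-estimate EM/ICM can stop in local optima; restarts mitigate this
  at the group stage, and the hierarchical stage starts from the group
  solution.
- The bilateral-dominance AUC from raw LI is near chance by construction
  (see above); the study's published bilateral AUC presumably reflects
  additional signal not captured by a single scalar LI.
- At the planted group moments the sample-mean ordering left > bilateral >
  right across dominance groups holds in roughly 90% of simulated cohorts,
  not more — the bilateral–right mean gap (0.033) is only ~1.3 standard
  errors at n = 14 per group, an intrinsic property of those effect sizes
  rather than of the estimator.
- The MRF smoothness weight c is treated as a tuned hyperparameter
  (default 5; tests sweep {0, 1, 5}); no published value exists.
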