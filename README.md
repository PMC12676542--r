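# mshbm

Individual-specific resting-state cortical network parcellation and
language lateralization, built around a multi-session hierarchical
Bayesian model (MS-HBM).

## What it does, and for whom

Group-average cortical network atlases blur the substantial
individual-to-individual variation in network topography — variation that
matters clinically in drug-resistant epilepsy, where language networks can
reorganize and where lateralizing language is a key step in surgical
planning. This package is for researchers who want to:

1. derive group-average networks from resting-state functional
   connectivity,
2. estimate **individual-specific** parcellations from as little as one
   short run of data per subject,
3. validate parcellations with leave-one-run-out connectional homogeneity
   and stimulation-evoked inhomogeneity, and
4. predict task-based language dominance from a resting-state laterality
   index over the individual's language networks.

A fully seeded synthetic-cohort generator plants known group/individual
parcellations, network-structured time series, stimulation runs and
dominance labels, so the entire pipeline is testable end to end without
access to patient data.

## The model

Each vertex's functional connectivity profile — correlations with R ROIs,
binarized to the top 10% and L2-normalized — is a point on the unit
hypersphere. Group networks come from a K-component von Mises-Fisher (vMF)
mixture fitted by EM:

    p(x) = Σ_k w_k C_d(κ_k) exp(κ_k μ_k·x)

Individual parcellations come from a three-level vMF hierarchy with a
Markov random field label prior:

    μ_k^s     ~ vMF(μ_k,     ε_k)        inter-subject variability
    μ_k^{s,t} ~ vMF(μ_k^s,   σ_k)        intra-subject (session) variability
    x_v^{s,t} ~ vMF(μ_{l_v}^{s,t}, κ)    observations
    P(l) ∝ exp( Σ_v log θ_v(l_v) + c Σ_{(u,v)∈E} 1[l_u = l_v] )

fitted by blocked EM with ICM label sweeps. Language lateralization is

    LI = (LH − RH) / (LH + RH)

over vertices assigned to the two language networks (Language A +
Language/Default B), compared across dominance groups by one-way ANOVA and
one-vs-rest ROC/AUC. See `vignettes/mshbm-methods.Rmd` for assumptions,
parameter meanings, and numerical choices.

## Worked example

Simulate a 10-subject cohort (8 for training, 2 held out with planted
left/right language dominance), train the model, and analyze subject 9:

```r
library(mshbm)

graph <- build_cortical_graph(100, "grid")        # 200 vertices, 2 hemispheres
truth <- sample_group_truth(graph, K = 5, R = 50, seed = 1)
truth <- sample_subject_labels(truth, c(rep("none", 8), "left", "right"),
                               deviation_rate = 0.1, seed = 2)

profiles <- lapply(1:8, function(s) lapply(1:2, function(t)
  compute_profile(simulate_run(truth, s, t, T_frames = 150, snr = 4,
                               seed = 100 + 10 * s + t))))
rows <- do.call(rbind, lapply(profiles, function(ps)
  do.call(rbind, lapply(ps, function(p) as.matrix(p$matrix)))))
gfit <- fit_vmf_mixture(rows, K = 5, vertex_id = rep(1:200, 16),
                        n_init = 3, seed = 3)
model <- train_mshbm(profiles, graph,
                     init = list(mu = gfit$params$mu, labels = gfit$labels),
                     c_smooth = 5)
model
#> mshbm_params: K=5, R=50, V=200, kappa=99.5, c=5.0, 7 iterations (converged)

prof9 <- lapply(1:2, function(t)
  compute_profile(simulate_run(truth, 9, t, T_frames = 150, snr = 4,
                               seed = 190 + t)))
indiv <- infer_individual(model, prof9, graph)
indiv
#> individual_parcellation: subject 9, 200 labeled vertices, 2 iterations (converged)
```

The fitted label space is an arbitrary permutation of the planted one;
`match_networks` aligns them. The individual parcellation recovers the
subject's true labels better than the group atlas (Dice 1.00 vs 0.86) and
is more homogeneous on an unseen run (0.903 vs 0.801):

```r
perm <- match_networks(gfit$labels, truth$group_labels, 5)
aligned <- ifelse(indiv$labels > 0, perm[pmax(indiv$labels, 1)], 0L)
dice_coefficient(truth$subjects[[9]]$labels, aligned, 5)$overall
#> [1] 1
dice_coefficient(truth$subjects[[9]]$labels, perm[gfit$labels], 5)$overall
#> [1] 0.86

run9 <- simulate_run(truth, 9, 3, T_frames = 150, snr = 4, seed = 193)
resting_homogeneity(indiv$labels, run9, K = 5)$value
#> [1] 0.9030426
resting_homogeneity(gfit$labels, run9, K = 5)$value
#> [1] 0.8011957
```

Subject 9 was planted left-dominant; the laterality index computed from
the *inferred* parcellation reproduces the planted value exactly (55
left-hemisphere vs 35 right-hemisphere language vertices):

```r
rec <- compute_li(aligned, truth$language_ids, graph$hemisphere,
                  subject_id = 9, dominance = "left")
c(rec$lh_count, rec$rh_count, rec$li)
#> [1] 55.0000000 35.0000000  0.2222222
truth$subjects[[9]]$achieved_li
#> [1] 0.2222222
```

`run_pipeline(experiment_config(...))` chains all stages — simulation,
profiles, three group fits, three MS-HBM models, six-approach
homogeneity/inhomogeneity comparisons with BH-corrected paired t-tests,
the inter-subject Dice matrix, and the LI/ANOVA/ROC analysis — writing
every artifact plus a `summary.json`. A thin CLI wrapper lives in
`inst/scripts/run_pipeline.R`.

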