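#' Default experiment configuration
#'
#' Bundles every knob of the synthetic end-to-end experiment: cohort
#' geometry, generator settings, model hyperparameters, and evaluation
#' design. Three training "sites" emulate group atlases and models trained
#' on different cohorts (two healthy-like off-site cohorts and the target
#' cohort), giving the six compared approaches: each site's group-average
#' parcellation and each site's individually-inferred parcellations.
#'
#' @param n_per_hemisphere Vertices per hemisphere (default 100).
#' @param topology Graph topology, `"grid"` or `"ring"`.
#' @param K Networks (default 5 at synthetic scale).
#' @param R ROIs (default 50).
#' @param n_train Training subjects per site (default 8).
#' @param n_test Test subjects (default 9, three per dominance group).
#' @param n_sessions_train,n_runs_test Sessions per training subject /
#'   runs per test subject (defaults 2).
#' @param T_frames Frames per run (default 150).
#' @param snr Signal-to-noise variance ratio (default 4).
#' @param deviation_rate Individual boundary deviation rate (default 0.1).
#' @param c_smooth MRF smoothness weight (default 5).
#' @param stim_effect Evoked amplitude in stimulation runs (default 1.5).
#' @param seed Root seed; every stage derives its own stream from it.
#' @param out_dir Output directory for artifacts.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_per_hemisphere = 100L, topology = "grid",
                              K = 5L, R = 50L, n_train = 8L, n_test = 9L,
                              n_sessions_train = 2L, n_runs_test = 2L,
                              T_frames = 150L, snr = 4,
                              deviation_rate = 0.1, c_smooth = 5,
                              stim_effect = 1.5, seed = 1L,
                              out_dir = tempfile("mshbm-experiment-")) {
  cfg <- list(
    n_per_hemisphere = as.integer(n_per_hemisphere), topology = topology,
    K = as.integer(K), R = as.integer(R), n_train = as.integer(n_train),
    n_test = as.integer(n_test),
    n_sessions_train = as.integer(n_sessions_train),
    n_runs_test = as.integer(n_runs_test),
    T_frames = as.integer(T_frames), snr = snr,
    deviation_rate = deviation_rate, c_smooth = c_smooth,
    stim_effect = stim_effect, seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' Run the full synthetic experiment
#'
#' Executes every stage in order — simulate cohorts, compute profiles, fit
#' the group von Mises-Fisher mixtures for three sites, train the three
#' MS-HBM models, infer individual parcellations, evaluate leave-one-run-out
#' homogeneity and stimulation inhomogeneity across the six approaches with
#' pairwise paired t-tests (BH-corrected), compute the inter-subject Dice
#' matrix, and run the laterality/ANOVA/ROC analysis — writing every
#' intermediate artifact under `config$out_dir`. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, the report list (also serialized to
#'   `summary.json`); key entries: `homogeneity` (subjects x 6 matrix +
#'   `pairwise_stats`), `inhomogeneity` (likewise), `dice`
#'   (per-network means), `laterality` (records, ANOVA, AUCs).
#' @export
run_pipeline <- function(config = experiment_config(), verbose = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed (artifacts in %s): %s",
            name, cfg$out_dir, conditionMessage(e)))
  }
  approaches <- c("siteA_group", "siteA_mshbm", "siteB_group", "siteB_mshbm",
                  "target_group", "target_mshbm")

  say("stage simulate: building graph and cohorts")
  graph <- stage("simulate", build_cortical_graph(cfg$n_per_hemisphere, cfg$topology))
  write_graph(graph, file.path(cfg$out_dir, "graph.txt"))
  truth <- stage("simulate",
                 sample_group_truth(graph, cfg$K, cfg$R,
                                    seed = derive_seed(cfg$seed, "truth")))
  write_parcellation(truth$group_labels, cfg$K,
                     file.path(cfg$out_dir, "group_truth.parc"))

  # three sites: two off-site cohorts plus the target cohort; the target
  # site's training subjects and the test subjects come from the same
  # generator settings
  site_seeds <- vapply(c("siteA", "siteB", "target"),
                       function(s) derive_seed(cfg$seed, "site", s), integer(1))
  dom_cycle <- rep(c("left", "bilateral", "right"), length.out = cfg$n_test)
  site_truths <- list(
    siteA = sample_subject_labels(truth, rep("none", cfg$n_train),
                                  cfg$deviation_rate, seed = site_seeds[1L]),
    siteB = sample_subject_labels(truth, rep("none", cfg$n_train),
                                  cfg$deviation_rate, seed = site_seeds[2L]),
    target = sample_subject_labels(truth,
                                   c(rep("none", cfg$n_train), dom_cycle),
                                   cfg$deviation_rate, seed = site_seeds[3L])
  )

  sim_profiles <- function(tr, sids, n_sessions, tag) {
    lapply(sids, function(s) lapply(seq_len(n_sessions), function(t) {
      run <- simulate_run(tr, s, t, cfg$T_frames, cfg$snr,
                          seed = derive_seed(cfg$seed, paste0("run-", tag), s * 1000L + t))
      compute_profile(run, graph$cortex_mask)
    }))
  }

  say("stage profile: computing connectivity profiles")
  train_profiles <- stage("profile", lapply(names(site_truths), function(nm) {
    sim_profiles(site_truths[[nm]], seq_len(cfg$n_train),
                 cfg$n_sessions_train, nm)
  }))
  names(train_profiles) <- names(site_truths)
  test_ids <- cfg$n_train + seq_len(cfg$n_test)
  test_runs <- stage("profile", lapply(test_ids, function(s) {
    lapply(seq_len(cfg$n_runs_test), function(t)
      simulate_run(site_truths$target, s, t, cfg$T_frames, cfg$snr,
                   seed = derive_seed(cfg$seed, "run-test", s * 1000L + t)))
  }))

  say("stage group-fit: von Mises-Fisher mixtures per site")
  group_fits <- stage("group-fit", lapply(names(train_profiles), function(nm) {
    prof <- train_profiles[[nm]]
    rows <- do.call(rbind, lapply(prof, function(ps)
      do.call(rbind, lapply(ps, profile_rows))))
    vid <- rep(seq_len(graph$n_vertices),
               times = cfg$n_train * cfg$n_sessions_train)
    fit <- fit_vmf_mixture(rows, cfg$K, vertex_id = vid, n_init = 3L,
                           seed = derive_seed(cfg$seed, "groupfit", nm))
    write_parcellation(fit$labels, cfg$K,
                       file.path(cfg$out_dir, sprintf("group_%s.parc", nm)))
    fit
  }))
  names(group_fits) <- names(train_profiles)

  say("stage train: MS-HBM per site")
  models <- stage("train", lapply(names(group_fits), function(nm) {
    m <- train_mshbm(train_profiles[[nm]], graph,
                     init = list(mu = group_fits[[nm]]$params$mu,
                                 labels = group_fits[[nm]]$labels),
                     c_smooth = cfg$c_smooth, max_iter = 10L)
    write_model(m, file.path(cfg$out_dir, sprintf("model_%s.json", nm)),
                trained_on = nm)
    m
  }))
  names(models) <- names(group_fits)

  say("stage evaluate: leave-one-run-out homogeneity, six approaches")
  label_source <- function(model) function(runs) {
    prof <- lapply(runs, compute_profile, mask = graph$cortex_mask)
    infer_individual(model, prof, graph)$labels
  }
  fixed_source <- function(labels) function(runs) labels
  sources <- list(
    fixed_source(group_fits$siteA$labels), label_source(models$siteA),
    fixed_source(group_fits$siteB$labels), label_source(models$siteB),
    fixed_source(group_fits$target$labels), label_source(models$target)
  )
  names(sources) <- approaches
  homog <- stage("evaluate", vapply(sources, function(src) {
    vapply(test_runs, function(runs)
      loro_evaluate(runs, src, function(l, r)
        resting_homogeneity(l, r, K = cfg$K))$value, numeric(1))
  }, numeric(length(test_runs))))
  homog_stats <- compare_approaches(homog)

  say("stage evaluate: stimulation inhomogeneity, six approaches")
  design <- alternating_design(n_cycles = 3L)
  stim_nets <- truth$language_ids[1L]
  stim <- stage("evaluate", lapply(seq_along(test_ids), function(i) {
    sr <- simulate_stim_run(site_truths$target, test_ids[i], design,
                            stim_networks = stim_nets,
                            effect = cfg$stim_effect,
                            seed = derive_seed(cfg$seed, "stim", test_ids[i]))
    write_design(sr$design, file.path(cfg$out_dir,
                                      sprintf("design_s%02d.csv", test_ids[i])))
    stim_glm(sr$run, sr$design)
  }))
  indiv_labels <- lapply(models, function(m) {
    lapply(seq_along(test_ids), function(i) {
      prof <- lapply(test_runs[[i]], compute_profile, mask = graph$cortex_mask)
      infer_individual(m, prof, graph)$labels
    })
  })
  inhomog <- vapply(seq_along(sources), function(a) {
    vapply(seq_along(test_ids), function(i) {
      labels <- if (a %% 2L == 1L) {
        list(group_fits$siteA$labels, NULL, group_fits$siteB$labels, NULL,
             group_fits$target$labels)[[a]]
      } else {
        indiv_labels[[c(1L, 1L, 2L, 2L, 3L, 3L)[a]]][[i]]
      }
      task_inhomogeneity(labels, stim[[i]], K = cfg$K)$value
    }, numeric(1))
  }, numeric(length(test_ids)))
  colnames(inhomog) <- approaches
  inhomog_stats <- compare_approaches(inhomog)

  say("stage laterality: LI, ANOVA, ROC from target-model parcellations")
  lat <- stage("laterality", {
    records <- lapply(seq_along(test_ids), function(i) {
      sub <- site_truths$target$subjects[[test_ids[i]]]
      compute_li(indiv_labels$target[[i]], truth$language_ids,
                 graph$hemisphere, subject_id = test_ids[i],
                 dominance = sub$dominance)
    })
    rec_df <- records_to_df(records)
    write.csv(rec_df, file.path(cfg$out_dir, "laterality_records.csv"),
              row.names = FALSE)
    an <- tryCatch(anova_li(rec_df), error = function(e) NULL)
    aucs <- vapply(c("left", "bilateral", "right"), function(g) {
      tryCatch(roc_auc(rec_df, g)$auc, error = function(e) NA_real_)
    }, numeric(1))
    list(records = rec_df, anova = an, auc = aucs)
  })

  say("stage dice: inter-subject topographic similarity")
  dice <- stage("dice", inter_subject_dice(indiv_labels$target, cfg$K))

  report <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    approaches = approaches,
    homogeneity = list(values = round(homog, 10),
                       mean = colMeans(homog),
                       q = homog_stats$q, significant = homog_stats$significant,
                       n_pairs = homog_stats$n_pairs),
    inhomogeneity = list(values = round(inhomog, 10),
                         mean = colMeans(inhomog),
                         q = inhomog_stats$q,
                         significant = inhomog_stats$significant,
                         n_pairs = inhomog_stats$n_pairs),
    dice = list(network_mean = round(dice$network_mean, 10)),
    laterality = list(
      records = lat$records,
      group_means = if (!is.null(lat$anova)) lat$anova$group_means,
      anova_F = if (!is.null(lat$anova)) lat$anova$F,
      anova_p = if (!is.null(lat$anova)) lat$anova$p,
      auc = lat$auc
    )
  )
  ev <- data.frame(
    subject = rep(paste0("s", test_ids), times = 2L * length(approaches)),
    approach = rep(rep(approaches, each = length(test_ids)), times = 2L),
    metric = rep(c("homogeneity", "inhomogeneity"),
                 each = length(test_ids) * length(approaches)),
    value = c(as.vector(homog), as.vector(inhomog))
  )
  write.csv(ev, file.path(cfg$out_dir, "evaluation.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
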