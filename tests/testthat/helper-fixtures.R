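# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 100-vertex grid graph with a 5-network planted truth and 10 deviation-free
# training subjects plus runs/profiles; the workhorse for module tests.
small_cohort <- function() fixture("small_cohort", function() {
  g <- build_cortical_graph(50, "grid")
  truth <- sample_group_truth(g, K = 5, R = 50, seed = 3)
  truth <- sample_subject_labels(truth, rep("none", 10), deviation_rate = 0.1,
                                 seed = 2)
  profiles <- lapply(1:10, function(s) lapply(1:2, function(t) {
    compute_profile(simulate_run(truth, s, t, T_frames = 150, snr = 4,
                                 seed = 1000L + s * 10L + t))
  }))
  list(graph = g, truth = truth, profiles = profiles)
})

# Group vMF fit and trained MS-HBM on the small cohort.
small_model <- function() fixture("small_model", function() {
  co <- small_cohort()
  rows <- do.call(rbind, lapply(co$profiles, function(ps)
    do.call(rbind, lapply(ps, mshbm:::profile_rows))))
  vid <- rep(seq_len(co$graph$n_vertices), 20)
  gf <- fit_vmf_mixture(rows, 5, vertex_id = vid, n_init = 3, seed = 4)
  model <- train_mshbm(co$profiles, co$graph,
                       init = list(mu = gf$params$mu, labels = gf$labels),
                       c_smooth = 5, max_iter = 10)
  # permutation mapping fitted label space onto the planted one
  perm <- match_networks(gf$labels, co$truth$group_labels, 5)
  list(group_fit = gf, model = model, perm = perm,
       to_truth = function(lab) ifelse(lab > 0, perm[pmax(lab, 1L)], 0L))
})

# An mshbm_params object with explicit values (no training); used for
# collapse-limit and inference oracle tests.
manual_params <- function(mu, epsilon, sigma, kappa, theta, c_smooth, V) {
  structure(
    list(mu = mu, epsilon = epsilon, sigma = sigma, kappa = kappa,
         theta = theta, c_smooth = c_smooth, K = nrow(mu), R = ncol(mu),
         V = V, theta_alpha = 1, objective_trace = numeric(0),
         subject_labels = NULL, converged = TRUE, mask = rep(TRUE, V)),
    class = "mshbm_params"
  )
}

# Hand-rolled run container for constructed time series.
manual_run <- function(vertex_ts, roi_ts = NULL, tr = 2) {
  if (is.null(roi_ts)) roi_ts <- vertex_ts[, 1:2, drop = FALSE]
  structure(list(subject_id = "manual", session_id = 1L,
                 vertex_ts = vertex_ts, roi_ts = roi_ts, tr_seconds = tr),
            class = "run_time_series")
}

unit_vec <- function(x) x / sqrt(sum(x^2))
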