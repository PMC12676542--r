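test_that("training requires at least two sessions per subject", {
  co <- small_cohort()
  bad <- co$profiles
  bad[[3]] <- bad[[3]][1]
  sm <- small_model()
  expect_error(
    train_mshbm(bad, co$graph, init = list(mu = sm$group_fit$params$mu,
                                           labels = sm$group_fit$labels)),
    ">= 2 sessions")
})

test_that("training objective is monotone non-decreasing", {
  tr <- small_model()$model$objective_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
})

test_that("individual inference beats the group atlas in Dice to subject truth", {
  co <- small_cohort(); sm <- small_model()
  held <- sample_subject_labels(co$truth, rep("none", 8),
                                deviation_rate = 0.1, seed = 77)
  wins <- 0
  for (s in 1:8) {
    prof <- lapply(1:2, function(t)
      compute_profile(simulate_run(held, s, t, 150, 4, seed = 500 + s * 10 + t)))
    ind <- infer_individual(sm$model, prof, co$graph)
    st <- held$subjects[[s]]$labels
    d_ind <- dice_coefficient(st, sm$to_truth(ind$labels), 5)$overall
    d_grp <- dice_coefficient(st, sm$to_truth(sm$group_fit$labels), 5)$overall
    wins <- wins + (d_ind > d_grp)
  }
  expect_gte(wins, 7)
})

test_that("inference collapses to per-vertex maximum likelihood in the flat limit", {
  g <- build_cortical_graph(30, "ring")
  truth <- sample_group_truth(g, K = 3, R = 12, seed = 5)
  truth <- sample_subject_labels(truth, "none", 0.1, seed = 2)
  prof <- list(compute_profile(simulate_run(truth, 1, 1, 100, 4, seed = 6)))
  params <- manual_params(truth$mu_true, rep(1e6, 3), rep(1e6, 3), 50,
                          matrix(1 / 3, g$n_vertices, 3), c_smooth = 0,
                          V = g$n_vertices)
  ind <- infer_individual(params, prof, g)
  oracle <- max.col(mshbm:::profile_rows(prof[[1]]) %*% t(truth$mu_true))
  expect_identical(ind$labels, oracle)
})

test_that("stronger smoothing never fragments the label field", {
  co <- small_cohort(); sm <- small_model()
  prof <- lapply(1:2, function(t)
    compute_profile(simulate_run(co$truth, 4, t, 150, 4, seed = 700 + t)))
  n_comp <- vapply(c(0, 1, 5), function(cs) {
    p <- sm$model
    p$c_smooth <- cs
    mshbm:::label_components(co$graph,
                             infer_individual(p, prof, co$graph)$labels)
  }, numeric(1))
  expect_true(all(diff(n_comp) <= 0))
})

test_that("more sessions never hurt recovery of the subject truth", {
  co <- small_cohort(); sm <- small_model()
  held <- sample_subject_labels(co$truth, rep("none", 6), 0.1, seed = 31)
  dice_at <- function(n_ses) {
    vapply(1:6, function(s) {
      prof <- lapply(seq_len(n_ses), function(t)
        compute_profile(simulate_run(held, s, t, 150, 4,
                                     seed = 900 + s * 10 + t)))
      ind <- infer_individual(sm$model, prof, co$graph)
      dice_coefficient(held$subjects[[s]]$labels, sm$to_truth(ind$labels),
                       5)$overall
    }, numeric(1))
  }
  d1 <- dice_at(1); d2 <- dice_at(2); d4 <- dice_at(4)
  expect_gte(mean(d2), mean(d1) - 1e-9)
  expect_gte(mean(d4), mean(d2) - 1e-9)
})

test_that("network matching recovers planted permutations", {
  a <- rep(1:4, times = c(5, 7, 3, 6))
  expect_equal(match_networks(a, a, 4), 1:4)
  perms <- list(c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1), c(2, 3, 4, 1))
  for (p in perms) expect_equal(match_networks(a, p[a], 4), p)
  # exhaustive optimality check on noisy overlaps, K = 4
  set.seed(8)
  b <- sample(1:4, length(a), replace = TRUE)
  got <- match_networks(a, b, 4)
  total <- function(p) sum(vapply(1:4, function(k) sum(a == k & b == p[k]),
                                  numeric(1)))
  all_perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  all_perms <- all_perms[apply(all_perms, 1, function(r)
    length(unique(r)) == 4), ]
  expect_equal(total(got), max(apply(all_perms, 1, total)))
  # disjoint supports still produce a valid permutation
  expect_setequal(match_networks(c(1, 1, 2, 0), c(0, 0, 0, 3), 3), 1:3)
  expect_error(match_networks(1:3, 1:4, 3), "share the vertex set")
})

test_that("model round-trips through the JSON container", {
  sm <- small_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(sm$model, path, trained_on = "small-cohort")
  back <- read_model(path)
  expect_equal(back$mu, sm$model$mu, tolerance = 1e-12)
  expect_equal(back$theta, sm$model$theta, tolerance = 1e-12)
  expect_equal(back$kappa, sm$model$kappa, tolerance = 1e-12)
  expect_equal(back$epsilon, sm$model$epsilon, tolerance = 1e-12)
})
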