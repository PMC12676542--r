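test_that("group truth covers all networks with contiguous per-hemisphere patches", {
  co <- small_cohort()
  g <- co$graph; truth <- co$truth
  expect_true(all(seq_len(5) %in% truth$group_labels))
  # each network's patch is connected within each hemisphere (BFS check)
  ig <- mshbm:::as_igraph(g)
  for (k in 1:5) for (h in c("L", "R")) {
    vs <- which(truth$group_labels == k & g$hemisphere == h)
    expect_gt(length(vs), 0)
    sub <- igraph::induced_subgraph(ig, vs)
    expect_equal(igraph::components(sub)$no, 1L)
  }
  # planted directions respect the minimum pairwise angle
  gram <- truth$mu_true %*% t(truth$mu_true)
  diag(gram) <- -1
  expect_lte(max(gram), cos(truth$generator_params$min_angle))
})

test_that("infeasible direction sampling fails after bounded retries", {
  g <- build_cortical_graph(10, "ring")
  expect_error(sample_group_truth(g, K = 3, R = 6, min_angle = 3.1),
               "could not sample")
})

test_that("zero deviation and no asymmetry reproduce the group labels", {
  co <- small_cohort()
  t0 <- sample_subject_labels(co$truth, "none", deviation_rate = 0, seed = 1)
  expect_identical(t0$subjects[[1]]$labels, co$truth$group_labels)
})

test_that("Dice to the group atlas decreases as the deviation rate grows", {
  co <- small_cohort()
  rates <- c(0, 0.05, 0.1, 0.2)
  mean_dice <- vapply(seq_along(rates), function(i) {
    tt <- sample_subject_labels(co$truth, rep("none", 50), rates[i],
                                seed = 100 + i)
    mean(vapply(tt$subjects, function(s)
      dice_coefficient(s$labels, co$truth$group_labels, 5)$overall,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
})

test_that("planted laterality hits its targets and matches the group moments", {
  co <- small_cohort()
  tt <- sample_subject_labels(co$truth, rep("left", 60),
                              deviation_rate = 0.05, seed = 9)
  ach <- vapply(tt$subjects, `[[`, numeric(1), "achieved_li")
  tgt <- vapply(tt$subjects, `[[`, numeric(1), "target_li")
  flg <- vapply(tt$subjects, `[[`, logical(1), "flagged")
  expect_true(all(abs(ach[!flg] - tgt[!flg]) <= 0.02))
  # LI recomputed from the labels equals the generator's stored value
  for (s in tt$subjects[1:5]) {
    rec <- compute_li(s$labels, co$truth$language_ids, co$graph$hemisphere)
    expect_equal(rec$li, s$achieved_li)
  }
  expect_lt(abs(mean(ach[!flg]) - 0.165), 0.03)
})

test_that("simulated runs carry network signal and are seed-deterministic", {
  co <- small_cohort()
  r1 <- simulate_run(co$truth, 1, 1, T_frames = 100, snr = 1e6, seed = 4)
  lab <- co$truth$subjects[[1]]$labels
  # noise-free limit: vertex correlates with an own-network ROI
  roi_of <- match(lab[1], co$truth$roi_parent)
  expect_gt(cor(r1$vertex_ts[, 1], r1$roi_ts[, roi_of]), 0.99)
  r2 <- simulate_run(co$truth, 1, 1, T_frames = 100, snr = 1e6, seed = 4)
  expect_identical(r1$vertex_ts, r2$vertex_ts)
  expect_identical(r1$roi_ts, r2$roi_ts)
  expect_error(simulate_run(co$truth, 1, 1, snr = 0), "snr")
  expect_error(simulate_run(co$truth, 1, 1, T_frames = 10), "T_frames")
})

test_that("top-10% profile entries land on own-network ROIs at study snr", {
  co <- small_cohort()
  run <- simulate_run(co$truth, 2, 1, T_frames = 200, snr = 4, seed = 8)
  prof <- compute_profile(run)
  lab <- co$truth$subjects[[2]]$labels
  own <- vapply(seq_len(co$graph$n_vertices), function(v) {
    kept <- which(prof$matrix[v, ] > 0)
    all(co$truth$roi_parent[kept] == lab[v])
  }, logical(1))
  expect_gte(mean(own), 0.95)
  # generator self-consistency: nearest true direction recovers the labels
  pred <- max.col(as.matrix(prof$matrix) %*% t(co$truth$mu_true))
  expect_gte(mean(pred == lab), 0.90)
})

test_that("stimulation runs reduce to rest runs at zero effect", {
  co <- small_cohort()
  d <- alternating_design(n_cycles = 2)
  sr <- simulate_stim_run(co$truth, 1, d, stim_networks = 2, effect = 0,
                          seed = 6)
  base <- simulate_run(co$truth, 1, 1, T_frames = d$total_frames, snr = 4,
                       seed = 6)
  expect_identical(sr$run$vertex_ts, base$vertex_ts)
  expect_warning(simulate_stim_run(co$truth, 1, d, stim_networks = integer(0),
                                   effect = 1, seed = 6), "empty")
  # stimulated vertices dominate the evoked z-map
  sr2 <- simulate_stim_run(co$truth, 1, d, stim_networks = 2, effect = 3,
                           seed = 6)
  z <- stim_glm(sr2$run, d)
  lab <- co$truth$subjects[[1]]$labels
  expect_gt(mean(z$z[lab == 2]), mean(z$z[lab != 2]) + 5)
})

test_that("deviation rate outside [0, 0.5) is rejected", {
  co <- small_cohort()
  expect_error(sample_subject_labels(co$truth, "none", deviation_rate = 0.5),
               "deviation_rate")
})
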