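test_that("homogeneity is 1 for identical member time courses and size-weights correctly", {
  t_ <- rnorm(30)
  y <- cbind(t_, t_, t_, rnorm(30), rnorm(30))
  res <- resting_homogeneity(c(1, 1, 1, 2, 2), manual_run(y), K = 2)
  expect_equal(res$per_network[1], 1)
  w <- res$network_sizes / sum(res$network_sizes)
  expect_equal(res$value, sum(w * res$per_network))
})

test_that("homogeneity equals the naive double-loop oracle", {
  set.seed(12)
  labels <- sample(1:3, 24, replace = TRUE)
  y <- matrix(rnorm(40 * 24), 40, 24)
  res <- resting_homogeneity(labels, manual_run(y), K = 3)
  oracle_per <- vapply(1:3, function(k) {
    memb <- which(labels == k)
    m <- rowMeans(y[, memb, drop = FALSE])
    mean(vapply(memb, function(v) cor(y[, v], m), numeric(1)))
  }, numeric(1))
  sizes <- tabulate(labels, 3)
  expect_equal(res$per_network, oracle_per, tolerance = 1e-12)
  expect_equal(res$value, sum(oracle_per * sizes / sum(sizes)),
               tolerance = 1e-12)
})

test_that("GLM z-maps behave at the exact-fit and pure-noise extremes", {
  d <- stim_design(c(15, 15, 15, 15), c("rest", "stim", "rest", "stim"))
  reg <- mshbm:::stim_regressor(d, 2)
  run <- manual_run(cbind(2 * reg + 1, matrix(rnorm(60 * 500), 60, 500)))
  z <- stim_glm(run, d)
  expect_true(is.infinite(z$z[1]) && z$z[1] > 0)   # zero-residual fit
  noise_z <- z$z[-1]
  expect_lt(abs(mean(noise_z)), 3 * sd(noise_z) / sqrt(500))
  # t-distributed scores: SD near 1, calibrated tail
  expect_lt(abs(sd(noise_z) - sqrt(z$dof / (z$dof - 2))), 0.1)
  frac <- mean(abs(noise_z) > 1.96)
  p_th <- 2 * pt(1.96, z$dof, lower.tail = FALSE)
  expect_lt(abs(frac - p_th), 3 * sqrt(p_th * (1 - p_th) / 500) + 1e-12)
})

test_that("inhomogeneity matches hand values and the naive oracle", {
  z <- c(0, 2, 1, 1, 1)
  labels <- c(1, 1, 2, 2, 2)
  res <- task_inhomogeneity(labels, z, K = 2)
  expect_equal(res$per_network, c(sqrt(2), 0))
  expect_equal(res$value, 2 / 5 * sqrt(2))
  set.seed(13)
  zz <- rnorm(30); ll <- sample(1:4, 30, replace = TRUE)
  res2 <- task_inhomogeneity(ll, zz, K = 4)
  oracle <- vapply(1:4, function(k) sd(zz[ll == k]), numeric(1))
  expect_equal(res2$per_network, oracle)
  expect_warning(task_inhomogeneity(c(1, 2, 2), c(0, 1, 2), K = 2),
                 "single vertex")
})

test_that("leave-one-run-out decouples folds and never sees the held-out run", {
  co <- small_cohort()
  runs <- lapply(1:3, function(t) simulate_run(co$truth, 1, t, 60, 4,
                                               seed = 40 + t))
  fixed <- function(rs) co$truth$group_labels
  metric <- function(l, r) resting_homogeneity(l, r, K = 5)
  res <- loro_evaluate(runs, fixed, metric)
  expect_equal(res$n_folds, 3)
  plain <- vapply(runs, function(r) metric(co$truth$group_labels, r)$value,
                  numeric(1))
  expect_equal(res$value, mean(plain))
  # leakage probe: record what each fold's source receives
  seen <- list()
  probe <- function(rs) {
    seen[[length(seen) + 1]] <<- vapply(rs, function(r) r$session_id, numeric(1))
    co$truth$group_labels
  }
  loro_evaluate(runs, probe, metric)
  for (i in 1:3) expect_false(i %in% seen[[i]])
  expect_error(loro_evaluate(runs[1], fixed, metric), "needs >= 2 runs")
})

test_that("pairwise comparisons produce C(A,2) BH-corrected paired tests", {
  set.seed(14)
  vals <- matrix(rnorm(8 * 6), 8, 6)
  st <- compare_approaches(vals)
  expect_equal(st$n_pairs, 15)
  expect_equal(st$dof, 7)
  tt <- t.test(vals[, 1], vals[, 2], paired = TRUE)
  expect_equal(st$t[1, 2], unname(tt$statistic))
  expect_equal(st$p[1, 2], tt$p.value)
  expect_equal(st$p, t(st$p))
  # constant-shift column: degenerate difference flagged as NA
  vals2 <- cbind(vals[, 1], vals[, 1] + 1, vals[, 2])
  st2 <- compare_approaches(vals2)
  expect_true(is.na(st2$p[1, 2]))
  expect_false(is.na(st2$p[1, 3]))
})

test_that("the comparison pipeline controls the false discovery rate", {
  set.seed(15)
  any_hit <- vapply(1:500, function(i) {
    vals <- matrix(rnorm(6 * 6), 6, 6)
    any(compare_approaches(vals)$significant, na.rm = TRUE)
  }, logical(1))
  rate <- mean(any_hit)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 0.01)
})

test_that("BH step-up matches the by-hand oracle", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05)
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, FALSE))
  # hand step-up: 0.01 <= 1/4*.05, 0.02 <= 2/4*.05, 0.03 <= 3/4*.05, 0.5 > .05
  expect_equal(res$q, c(0.04, 0.04, 0.04, 0.5))
  all1 <- bh_fdr(rep(1, 5))
  expect_false(any(all1$rejected))
  expect_equal(all1$q, rep(1, 5))
  single <- bh_fdr(0.04)
  expect_true(single$rejected)
  expect_length(bh_fdr(numeric(0))$q, 0)
})

test_that("DVARS matches closed-form cases", {
  expect_equal(dvars(manual_run(matrix(5, 30, 4))), 0)
  alt <- matrix(rep(c(1, -1), 20), 40, 6)
  expect_equal(dvars(manual_run(alt)), 2)
  set.seed(16)
  big <- manual_run(matrix(rnorm(500 * 100), 500, 100))
  expect_lt(abs(dvars(big) - sqrt(2)), 0.02)
})

test_that("true labels are more homogeneous and less task-inhomogeneous than permuted", {
  co <- small_cohort()
  set.seed(17)
  d <- alternating_design(n_cycles = 2)
  for (s in 1:6) {
    lab <- co$truth$subjects[[s]]$labels
    run <- simulate_run(co$truth, s, 1, 100, 4, seed = 60 + s)
    perm_lab <- sample(lab)
    expect_gt(resting_homogeneity(lab, run, K = 5)$value,
              resting_homogeneity(perm_lab, run, K = 5)$value)
    sr <- simulate_stim_run(co$truth, s, d, stim_networks = 2, effect = 2,
                            seed = 80 + s)
    z <- stim_glm(sr$run, d)
    expect_lt(task_inhomogeneity(lab, z, K = 5)$value,
              task_inhomogeneity(perm_lab, z, K = 5)$value)
  }
})
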