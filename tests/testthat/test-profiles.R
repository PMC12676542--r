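test_that("kept sets equal the full-sort oracle and rows are unit-norm", {
  set.seed(3)
  run <- manual_run(matrix(rnorm(60 * 15), 60, 15),
                    matrix(rnorm(60 * 20), 60, 20))
  prof <- compute_profile(run, top_fraction = 0.1)
  expect_equal(prof$n_kept, 2L)  # ceiling(0.1 * 20)
  C <- cor(run$vertex_ts, run$roi_ts)
  for (v in 1:15) {
    kept <- which(prof$matrix[v, ] > 0)
    oracle <- order(-C[v, ], seq_len(20))[1:2]   # full sort, stated tie-break
    expect_setequal(kept, oracle)
    expect_equal(as.numeric(prof$matrix[v, kept]), rep(1 / sqrt(2), 2))
  }
  expect_equal(Matrix::rowSums(prof$matrix^2), rep(1, 15), tolerance = 1e-10)
})

test_that("a dominant correlation is the single kept entry at top 10% of 10 ROIs", {
  set.seed(4)
  t_ <- seq_len(100)
  base <- rnorm(100)
  roi <- cbind(base + rnorm(100, sd = 0.2), base + rnorm(100, sd = 0.6),
               matrix(rnorm(100 * 8), 100, 8))
  run <- manual_run(matrix(base, 100, 1), roi)
  prof <- compute_profile(run, top_fraction = 0.1)
  expect_equal(prof$n_kept, 1L)
  expect_equal(which(prof$matrix[1, ] > 0), 1L)
  expect_equal(prof$matrix[1, 1], 1.0)
})

test_that("profiles are invariant to affine rescaling of the series", {
  set.seed(5)
  run <- manual_run(matrix(rnorm(50 * 8), 50, 8), matrix(rnorm(50 * 12), 50, 12))
  p1 <- compute_profile(run)
  run2 <- run
  run2$vertex_ts <- sweep(run$vertex_ts * 3.7, 2, rnorm(8), `+`)
  run2$roi_ts <- run$roi_ts * 0.01 + 5
  p2 <- compute_profile(run2)
  expect_equal(p1$matrix, p2$matrix)
})

test_that("degenerate series are handled as specified", {
  set.seed(6)
  y <- matrix(rnorm(40 * 4), 40, 4); y[, 2] <- 1
  run <- manual_run(y, matrix(rnorm(40 * 6), 40, 6))
  expect_warning(p <- compute_profile(run), "zero-variance vertices")
  expect_equal(sum(p$matrix[2, ]), 0)
  run_bad <- manual_run(matrix(rnorm(40 * 4), 40, 4),
                        cbind(matrix(rnorm(40 * 5), 40, 5), 2))
  expect_error(compute_profile(run_bad), "zero-variance ROI")
})

test_that("censoring keeps rest frames minus the per-block discard", {
  y <- matrix(seq_len(90 * 2), 90, 2)
  run <- manual_run(y, y)
  d <- stim_design(c(30, 30, 30), c("rest", "stim", "rest"), discard_frames = 4)
  out <- censor_stim_blocks(run, d)
  expect_equal(nrow(out$vertex_ts), 52)  # (30 - 4) * 2
  expect_equal(out$vertex_ts[, 1], c(5:30, 65:90))  # order preserved
  # identity case: one all-rest block, discard 0
  d0 <- stim_design(90, "rest", discard_frames = 0)
  expect_equal(censor_stim_blocks(run, d0)$vertex_ts, run$vertex_ts)
  # degenerate: everything stimulated
  d1 <- stim_design(90, "stim", discard_frames = 4)
  expect_error(censor_stim_blocks(run, d1), "no rest frames")
  # rest block shorter than the discard is named
  d2 <- stim_design(c(3, 87), c("rest", "stim"), discard_frames = 4)
  expect_error(censor_stim_blocks(run, d2), "rest block 1")
})

test_that("designs must alternate and fit the run", {
  expect_error(stim_design(c(10, 10), c("rest", "rest")), "alternate")
  run <- manual_run(matrix(rnorm(40), 20, 2))
  expect_error(censor_stim_blocks(run, stim_design(30, "rest")), "covers 30")
})
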