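test_that("LI is the exact hemispheric vertex-count ratio", {
  hemi <- factor(rep(c("L", "R"), each = 200), levels = c("L", "R"))
  lab <- integer(400)
  lab[1:100] <- 4; lab[201:300] <- 5      # 100 L vs 100 R language vertices
  rec <- compute_li(lab, c(4, 5), hemi)
  expect_equal(rec$li, 0)
  lab2 <- integer(400)
  lab2[1:150] <- 4; lab2[201:250] <- 5    # 150 vs 50
  rec2 <- compute_li(lab2, c(4, 5), hemi)
  expect_equal(rec2$li, 0.5)
  expect_equal(rec2$lh_count, 150); expect_equal(rec2$rh_count, 50)
  # undefined LI is flagged, not zero
  expect_warning(rec3 <- compute_li(integer(400), c(4, 5), hemi), "undefined")
  expect_true(is.na(rec3$li)); expect_false(rec3$defined)
})

test_that("LI is antisymmetric under hemisphere swap", {
  co <- small_cohort()
  hemi <- co$graph$hemisphere
  swapped <- factor(ifelse(hemi == "L", "R", "L"), levels = c("L", "R"))
  for (s in 1:5) {
    lab <- co$truth$subjects[[s]]$labels
    a <- compute_li(lab, co$truth$language_ids, hemi)
    b <- compute_li(lab, co$truth$language_ids, swapped)
    expect_identical(b$li, -a$li)
  }
})

test_that("one-way ANOVA reduces to known special cases", {
  df0 <- data.frame(li = rep(c(1, 2, 3), 3),
                    dominance = rep(c("left", "bilateral", "right"), each = 3))
  res0 <- anova_li(df0)
  expect_equal(res0$F, 0)
  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(18)
  df2 <- data.frame(li = rnorm(20), dominance = rep(c("left", "right"), 10))
  res2 <- anova_li(df2)
  tt <- t.test(li ~ dominance, data = df2, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  expect_error(anova_li(data.frame(li = 1:3, dominance = c("a", "a", "b"))),
               ">= 2 groups")
})

test_that("AUC is the Mann-Whitney concordance with tie credit", {
  df <- data.frame(li = c(0.9, 0.8, 0.7, 0.85),
                   dominance = c("left", "left", "right", "right"))
  expect_equal(roc_auc(df, "left")$auc, 0.75)   # 3 concordant of 4 pairs
  sep <- data.frame(li = c(1, 2, -1, -2),
                    dominance = c("left", "left", "right", "right"))
  expect_equal(roc_auc(sep, "left")$auc, 1.0)
  ties <- data.frame(li = rep(0.3, 6),
                     dominance = rep(c("left", "right"), 3))
  expect_equal(roc_auc(ties, "left")$auc, 0.5)
  expect_error(roc_auc(df[df$dominance == "left", ], "left"), "non-empty")
  # right-dominance orientation flips the score sign
  expect_equal(roc_auc(df, "right")$auc, 1 - roc_auc(df, "right", orientation = 1)$auc)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  df <- data.frame(li = rnorm(40),
                   dominance = sample(c("left", "other"), 40, replace = TRUE))
  ours <- roc_auc(df, "left", orientation = 1)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = df$dominance == "left", predictor = df$li,
    direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("inter-subject Dice matches hand cases and drops empty pairs", {
  a <- c(rep(1, 10), rep(2, 10))
  b <- c(rep(1, 5), rep(2, 15))
  d <- inter_subject_dice(list(a, a, b), K = 2)
  expect_equal(d$per_network[, 1], c(1, 1))          # identical pair
  expect_equal(d$per_network[1, 2], 2 * 5 / (10 + 5))
  disj <- inter_subject_dice(list(c(1, 1, 0, 0), c(0, 0, 1, 1)), K = 1)
  expect_equal(disj$per_network[1, 1], 0)
  both_empty <- inter_subject_dice(list(c(1, 0), c(1, 0)), K = 2)
  expect_true(is.na(both_empty$per_network[2, 1]))
})

test_that("networks with higher planted deviation show lower inter-subject Dice", {
  co <- small_cohort()
  dice_at <- function(rate, seed) {
    tt <- sample_subject_labels(co$truth, rep("none", 12), rate, seed = seed)
    d <- inter_subject_dice(lapply(tt$subjects, `[[`, "labels"), K = 5)
    mean(d$network_mean)
  }
  d <- vapply(c(0.02, 0.1, 0.25), dice_at, numeric(1), seed = 23)
  expect_true(all(diff(d) < 0))
})
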