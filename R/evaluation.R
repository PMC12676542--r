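#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking near 6 s minus a
#' one-sixth-weight undershoot peaking near 16 s, sampled at the TR and
#' normalized to unit peak.
#'
#' @param t Time points in seconds.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(dgamma(seq(0, 32, by = 0.01), shape = 6, rate = 1) -
            dgamma(seq(0, 32, by = 0.01), shape = 16, rate = 1) / 6)
}

# Stimulation boxcar convolved with the canonical HRF, length = total frames.
stim_regressor <- function(design, tr_seconds) {
  Tn <- design$total_frames
  box <- numeric(Tn)
  for (b in seq_along(design$block_kinds)) {
    if (design$block_kinds[b] == "stim") {
      on <- design$block_onsets[b]
      box[on:(on + design$block_durations[b] - 1L)] <- 1
    }
  }
  h <- canonical_hrf(seq(0, 32, by = tr_seconds))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(Tn)]
  conv
}

#' Size-weighted resting-state connectional homogeneity
#'
#' For each network, the mean Pearson correlation between every member
#' vertex's time course and the network's mean time course; the overall
#' value averages the per-network homogeneities weighted by network size
#' (vertex count). High homogeneity indicates that the parcellation groups
#' functionally coherent cortex.
#'
#' @param labels Per-vertex integer labels in 0..K (0 = masked/excluded).
#' @param run A `run_time_series` (>= 3 frames).
#' @param K Number of networks; defaults to `max(labels)`.
#' @param size_weighted If `FALSE`, networks are weighted equally
#'   (sensitivity-check mode).
#' @return An `evaluation_result`: `value`, `per_network` (length K, `NA`
#'   for empty networks), `network_sizes`, `metric = "homogeneity"`.
#' @export
resting_homogeneity <- function(labels, run, K = max(labels),
                                size_weighted = TRUE) {
  stopifnot(inherits(run, "run_time_series"))
  Y <- run$vertex_ts
  if (nrow(Y) < 3L) stopf("need >= 3 frames")
  if (length(labels) != ncol(Y)) stopf("labels must cover the run's vertices")
  per <- rep(NA_real_, K)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    memb <- which(labels == k)
    sizes[k] <- length(memb)
    if (length(memb) == 0L) next
    if (length(memb) == 1L) { per[k] <- 1; next }  # vertex vs itself
    m <- rowMeans(Y[, memb, drop = FALSE])
    per[k] <- mean(suppressWarnings(cor(Y[, memb, drop = FALSE], m)), na.rm = TRUE)
  }
  weighted_result(per, sizes, "homogeneity", size_weighted)
}

#' Per-vertex GLM z-map of stimulation-evoked activity
#'
#' Ordinary least squares of each vertex time course on an intercept plus
#' the stimulation boxcar convolved with the canonical double-gamma HRF;
#' the map is the t-statistic (beta / SE) of the stimulation regressor,
#' reported unthresholded.
#'
#' @param run A `run_time_series`.
#' @param design A `stim_design` covering the run.
#' @return An `activation_zmap`: `z` per vertex, `dof`, `subject_id`.
#' @export
stim_glm <- function(run, design) {
  stopifnot(inherits(run, "run_time_series"), inherits(design, "stim_design"))
  Y <- run$vertex_ts
  Tn <- nrow(Y)
  if (design$total_frames > Tn) stopf("run shorter than design")
  reg <- stim_regressor(design, run$tr_seconds)[seq_len(Tn)]
  if (sd(reg) == 0) stopf("collinear design: stimulation regressor is constant")
  X <- cbind(1, reg)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)                  # 2 x V
  res <- Y - X %*% B
  dof <- Tn - 2L
  s2 <- colSums(res^2) / dof
  # residuals at roundoff level relative to the fit are a perfect fit
  perfect <- s2 <= 1e-20 * colSums((X %*% B)^2)
  se <- sqrt(pmax(s2 * XtXi[2L, 2L], 0))
  z <- ifelse(se > 0 & !perfect, B[2L, ] / se, sign(B[2L, ]) * Inf)
  structure(list(z = as.numeric(z), dof = dof, subject_id = run$subject_id),
            class = "activation_zmap")
}

#' Size-weighted stimulation-evoked task inhomogeneity
#'
#' The sample standard deviation (denominator n-1) of activation z-scores
#' within each network, averaged across networks with vertex-count weights.
#' A parcellation whose boundaries respect evoked activity keeps z-scores
#' homogeneous within networks, giving a lower value. Singleton networks
#' contribute SD 0.
#'
#' @param labels Per-vertex integer labels in 0..K.
#' @param zmap An `activation_zmap` (or numeric z vector).
#' @inheritParams resting_homogeneity
#' @return An `evaluation_result` with `metric = "inhomogeneity"`.
#' @export
task_inhomogeneity <- function(labels, zmap, K = max(labels),
                               size_weighted = TRUE) {
  z <- if (inherits(zmap, "activation_zmap")) zmap$z else as.numeric(zmap)
  if (length(labels) != length(z)) stopf("labels and z-map differ in length")
  if (any(!is.finite(z[labels > 0L]))) stopf("z must be finite on labeled vertices")
  per <- rep(NA_real_, K)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    memb <- which(labels == k)
    sizes[k] <- length(memb)
    if (length(memb) == 0L) next
    if (length(memb) == 1L) {
      warnf("network %d has a single vertex; SD taken as 0", k)
      per[k] <- 0
    } else per[k] <- sd(z[memb])
  }
  weighted_result(per, sizes, "inhomogeneity", size_weighted)
}

weighted_result <- function(per, sizes, metric, size_weighted) {
  present <- which(sizes > 0L)
  if (length(present) < length(per))
    warnf("%d empty network(s) excluded from weighting", sum(sizes == 0L))
  w <- if (size_weighted) sizes[present] / sum(sizes[present])
       else rep(1 / length(present), length(present))
  structure(
    list(value = sum(w * per[present]), per_network = per,
         network_sizes = sizes, metric = metric,
         size_weighted = size_weighted),
    class = "evaluation_result"
  )
}

#' Leave-one-run-out evaluation of a parcellation source
#'
#' For a subject with n runs, each run is held out in turn: labels are
#' estimated from the remaining n-1 runs by `parcellation_source` and the
#' metric is computed on the held-out run alone; the per-subject value is
#' the mean over folds. This keeps the data that defines the parcellation
#' independent of the data that scores it.
#'
#' @param runs List of >= 2 `run_time_series` for one subject.
#' @param parcellation_source Function taking a list of runs and returning
#'   per-vertex labels. Pass a constant function for fixed atlases.
#' @param metric Function `(labels, run) -> evaluation_result` (e.g.
#'   [resting_homogeneity()]).
#' @return List with `value` (mean over folds), `per_fold`, `n_folds`.
#' @export
loro_evaluate <- function(runs, parcellation_source, metric) {
  n <- length(runs)
  if (n < 2L) stopf("subject excluded: needs >= 2 runs, has %d", n)
  per_fold <- numeric(n)
  for (i in seq_len(n)) {
    labels <- parcellation_source(runs[-i])
    per_fold[i] <- metric(labels, runs[[i]])$value
  }
  list(value = mean(per_fold), per_fold = per_fold, n_folds = n)
}

#' Pairwise paired t-tests across parcellation approaches
#'
#' Runs a two-tailed paired t-test (dof = n_subjects - 1) for every pair of
#' approaches and corrects the p-values across the pair set with the
#' Benjamini-Hochberg procedure; significance is q < `q_level`. Pairs with
#' a zero-variance difference vector have no defined t-statistic and are
#' reported as `NA`.
#'
#' @param values Numeric matrix, subjects x approaches, no missing cells.
#' @param q_level FDR level (default 0.05).
#' @return A `pairwise_stats`: `t`, `p`, `q`, `significant`, `direction`
#'   (sign of mean row-minus-column difference) matrices and `dof`.
#' @export
compare_approaches <- function(values, q_level = 0.05) {
  values <- as.matrix(values)
  n <- nrow(values); A <- ncol(values)
  if (n < 2L || A < 2L) stopf("need >= 2 subjects and >= 2 approaches")
  if (anyNA(values)) stopf("no missing cells allowed")
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("A", seq_len(A))
  tmat <- pmat <- dmat <- matrix(NA_real_, A, A, dimnames = list(nm, nm))
  pairs <- which(upper.tri(tmat), arr.ind = TRUE)
  pvec <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    d <- values[, a] - values[, b]
    dmat[a, b] <- sign(mean(d)); dmat[b, a] <- -dmat[a, b]
    # zero-variance differences (up to roundoff) have no defined t
    if (sd(d) <= 1e-12 * max(abs(d), 1e-300)) next
    tt <- tryCatch(t.test(values[, a], values[, b], paired = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) next
    tmat[a, b] <- tt$statistic; tmat[b, a] <- -tt$statistic
    pmat[a, b] <- pmat[b, a] <- tt$p.value
    pvec[i] <- tt$p.value
  }
  adj <- bh_fdr(pvec[!is.na(pvec)], q_level)
  qvec <- rep(NA_real_, length(pvec))
  qvec[!is.na(pvec)] <- adj$q
  qmat <- matrix(NA_real_, A, A, dimnames = list(nm, nm))
  for (i in seq_len(nrow(pairs))) {
    qmat[pairs[i, 1L], pairs[i, 2L]] <- qmat[pairs[i, 2L], pairs[i, 1L]] <- qvec[i]
  }
  structure(
    list(t = tmat, p = pmat, q = qmat,
         significant = !is.na(qmat) & qmat < q_level,
         direction = dmat, dof = n - 1L, n_pairs = nrow(pairs)),
    class = "pairwise_stats"
  )
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment; a hypothesis is rejected when its adjusted value
#' falls below `q_level`.
#'
#' @param p Vector of p-values in [0, 1].
#' @param q_level FDR level (default 0.05).
#' @return List with `rejected` (logical) and `q` (BH-adjusted values).
#' @export
bh_fdr <- function(p, q_level = 0.05) {
  if (length(p) == 0L) return(list(rejected = logical(0), q = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(rejected = !is.na(q) & q < q_level, q = q)
}

#' DVARS of a run
#'
#' Root-mean-square, over frames, of the spatial RMS of the temporal
#' backward difference of the vertex time series — a standard index of
#' frame-to-frame signal change.
#'
#' @param run A `run_time_series` with >= 2 frames.
#' @return A single nonnegative number.
#' @export
dvars <- function(run) {
  Y <- run$vertex_ts
  if (nrow(Y) < 2L) stopf("need >= 2 frames")
  d <- diff(Y)
  sqrt(mean(d^2))
}
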