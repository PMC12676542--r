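#' Compute binarized, unit-normalized connectivity profiles
#'
#' For each vertex, Pearson correlations with every ROI time course are
#' computed, the largest `ceiling(top_fraction * R)` are kept as 1 and the
#' rest set to 0, and the row is L2-normalized. Keeping only the strongest
#' tenth of correlations (the default) discards weak, noise-dominated edges
#' while the unit normalization puts every vertex on the hypersphere where
#' the von Mises-Fisher machinery operates. Ties at the cutoff are broken
#' by larger correlation, then by lower ROI index.
#'
#' @param run A `run_time_series` (vertex and ROI series share T).
#' @param mask Logical per-vertex vector; vertices outside the mask get
#'   all-zero rows. Defaults to all `TRUE`.
#' @param top_fraction Fraction of ROIs kept per vertex, in (0, 1];
#'   default 0.10.
#' @return A `connectivity_profile`: `matrix` (V x R sparse `dgCMatrix`,
#'   rows unit-norm with exactly `n_kept` nonzeros), `n_kept`,
#'   `top_fraction`, `subject_id`, `session_id`.
#' @export
compute_profile <- function(run, mask = NULL, top_fraction = 0.10) {
  stopifnot(inherits(run, "run_time_series"))
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stopf("top_fraction must be in (0, 1]")
  Y <- run$vertex_ts; Z <- run$roi_ts
  if (nrow(Y) != nrow(Z)) stopf("vertex and ROI series must share T")
  V <- ncol(Y); R <- ncol(Z)
  if (is.null(mask)) mask <- rep(TRUE, V)
  stopifnot(length(mask) == V)

  roi_sd <- apply(Z, 2L, sd)
  if (any(roi_sd == 0)) stopf("zero-variance ROI time series (ROI %d)",
                              which(roi_sd == 0)[1L])
  v_sd <- apply(Y, 2L, sd)
  dead <- mask & v_sd == 0
  if (any(dead)) {
    warnf("%d zero-variance vertices inside mask excluded (zero rows)", sum(dead))
    mask <- mask & !dead
  }

  n_kept <- as.integer(ceiling(top_fraction * R))
  C <- suppressWarnings(cor(Y, Z))            # V x R
  live <- which(mask)
  ii <- integer(0); jj <- integer(0)
  for (v in live) {
    ord <- order(-C[v, ], seq_len(R))[seq_len(n_kept)]
    ii <- c(ii, rep(v, n_kept)); jj <- c(jj, ord)
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / sqrt(n_kept),
                            dims = c(V, R))
  structure(
    list(matrix = m, n_kept = n_kept, top_fraction = top_fraction,
         mask = mask, subject_id = run$subject_id,
         session_id = run$session_id),
    class = "connectivity_profile"
  )
}

#' Censor a stimulation run down to rest-only frames
#'
#' Keeps only the no-stimulation blocks, discarding the first
#' `design$discard_frames` frames of each rest block to remove residual
#' hemodynamic carry-over from the preceding stimulation block, and
#' concatenates the surviving frames in temporal order.
#'
#' @param run A `run_time_series` whose length matches the design.
#' @param design A `stim_design`.
#' @return A `run_time_series` with
#'   `T = sum(rest duration - discard_frames)` frames.
#' @export
censor_stim_blocks <- function(run, design) {
  stopifnot(inherits(run, "run_time_series"), inherits(design, "stim_design"))
  if (design$total_frames != nrow(run$vertex_ts))
    stopf("design covers %d frames but run has %d",
          design$total_frames, nrow(run$vertex_ts))
  keep <- integer(0)
  for (b in seq_along(design$block_kinds)) {
    if (design$block_kinds[b] != "rest") next
    dur <- design$block_durations[b]
    if (dur <= design$discard_frames)
      stopf("rest block %d (%d frames) is not longer than discard_frames=%d",
            b, dur, design$discard_frames)
    on <- design$block_onsets[b]
    keep <- c(keep, (on + design$discard_frames):(on + dur - 1L))
  }
  if (length(keep) == 0L) stopf("no rest frames survive censoring")
  out <- run
  out$vertex_ts <- run$vertex_ts[keep, , drop = FALSE]
  out$roi_ts <- run$roi_ts[keep, , drop = FALSE]
  out
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat(sprintf(
    "connectivity_profile: %d x %d, %d kept per row (top %.0f%%), subject %s session %s\n",
    nrow(x$matrix), ncol(x$matrix), x$n_kept, 100 * x$top_fraction,
    format(x$subject_id), format(x$session_id)))
  invisible(x)
}

# Dense unit-norm row matrix view used by the clustering / MS-HBM fitters.
profile_rows <- function(profile) as.matrix(profile$matrix)
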