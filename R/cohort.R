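#' Sample a group-level ground-truth parcellation and network directions
#'
#' Plants a K-network group parcellation on a cortical surrogate graph by
#' seeded region growing (each network occupies one spatially contiguous
#' patch per hemisphere) and constructs the K true mean connectivity
#' directions in ROI space. Each ROI is assigned a parent network
#' round-robin; the true direction of network k is the unit-normalized
#' indicator of its ROI set plus a small nonnegative jitter, so directions
#' are near-orthogonal and profiles computed from simulated runs point at
#' them.
#'
#' @param graph A `cortical_graph`.
#' @param K Number of networks (>= 2). The full-scale model uses 15;
#'   small synthetic studies typically use 5.
#' @param R Number of ROIs (>= K); the full-scale analysis uses 1175,
#'   scaled down to 50 by default here.
#' @param min_angle Minimum pairwise angle (radians) between true network
#'   directions; sampling fails after bounded retries if infeasible.
#' @param language_ids Two network labels designated Language A and
#'   Language/Default B; defaults to the last two labels.
#' @param seed Integer seed.
#' @return A `cohort_truth` object (group part): `group_labels` (per-vertex
#'   integer in 0..K, 0 = masked), `mu_true` (K x R unit rows), `roi_parent`
#'   (length-R parent labels), `language_ids`, `K`, `R`, `graph`, and
#'   `generator_params`.
#' @export
sample_group_truth <- function(graph, K, R = 50L, min_angle = 1.0,
                               language_ids = NULL, seed = 1L) {
  validate_cortical_graph(graph)
  if (!is_count(K, 2L)) stopf("K must be an integer >= 2")
  if (!is_count(R, 2L) || R < K) stopf("R must be an integer >= K")
  n_hemi_min <- min(table(graph$hemisphere))
  if (n_hemi_min < K) stopf("each hemisphere needs at least K vertices")
  set.seed(derive_seed(seed, "group-truth"))

  labels <- integer(graph$n_vertices)
  for (h in c("L", "R")) {
    hv <- which(graph$hemisphere == h & graph$cortex_mask)
    labels[hv] <- grow_patches(graph, hv, K)
  }

  roi_parent <- ((seq_len(R) - 1L) %% K) + 1L
  mu_true <- sample_network_directions(K, R, roi_parent, min_angle)

  if (is.null(language_ids)) language_ids <- c(K - 1L, K)
  language_ids <- as.integer(language_ids)
  if (length(language_ids) != 2L || any(language_ids < 1L | language_ids > K))
    stopf("language_ids must be two labels in 1..K")

  structure(
    list(
      graph = graph, K = as.integer(K), R = as.integer(R),
      group_labels = labels, mu_true = mu_true, roi_parent = roi_parent,
      language_ids = language_ids, subjects = NULL,
      generator_params = list(min_angle = min_angle, seed = as.integer(seed))
    ),
    class = "cohort_truth"
  )
}

# Multi-source randomized BFS growth of K contiguous patches over the
# vertex set hv (one hemisphere). Seeds are spread by farthest-point
# sampling on graph distance.
grow_patches <- function(graph, hv, K) {
  nb <- graph$neighbors
  lab <- setNames(integer(length(hv)), hv)
  seeds <- hv[sample.int(length(hv), 1L)]
  dist_to <- function(src) {
    d <- setNames(rep(Inf, length(hv)), hv)
    d[as.character(src)] <- 0
    q <- src
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (u in nb[[v]]) {
        cu <- as.character(u)
        if (!is.na(d[cu]) && is.infinite(d[cu])) {
          d[cu] <- d[as.character(v)] + 1
          q <- c(q, u)
        }
      }
    }
    d
  }
  dmin <- dist_to(seeds)
  while (length(seeds) < K) {
    far <- hv[which.max(dmin + runif(length(hv)) * 0.5)]
    seeds <- c(seeds, far)
    dmin <- pmin(dmin, dist_to(far))
  }
  for (k in seq_len(K)) lab[as.character(seeds[k])] <- k
  frontier <- as.list(seeds)
  while (any(lab == 0L)) {
    progressed <- FALSE
    for (k in sample.int(K)) {
      f <- frontier[[k]]
      cand <- integer(0)
      for (v in f) cand <- c(cand, nb[[v]])
      cand <- unique(cand[cand %in% hv])
      cand <- cand[lab[as.character(cand)] == 0L]
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), 1L)]
        lab[as.character(pick)] <- k
        frontier[[k]] <- c(frontier[[k]], pick)
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  # orphaned vertices (disconnected corners): attach to a labeled neighbor
  for (v in hv[lab == 0L]) {
    nl <- lab[as.character(intersect(nb[[v]], hv))]
    nl <- nl[nl > 0L]
    lab[as.character(v)] <- if (length(nl)) nl[1L] else 1L
  }
  unname(lab)
}

# K near-orthogonal nonnegative unit directions anchored at the ROI
# indicator sets; jitter shrinks over retries until min_angle is satisfied.
sample_network_directions <- function(K, R, roi_parent, min_angle, retries = 20L) {
  eps <- 0.1
  for (try in seq_len(retries)) {
    mu <- t(vapply(seq_len(K), function(k) {
      l2_normalize(as.numeric(roi_parent == k) + eps * runif(R))
    }, numeric(R)))
    g <- mu %*% t(mu)
    diag(g) <- -1
    if (max(g) <= cos(min_angle)) return(mu)
    eps <- eps / 2
  }
  stopf("could not sample %d directions in dimension %d with pairwise angle >= %.3f rad",
        K, R, min_angle)
}

#' Plant per-subject parcellations with individual deviations and laterality
#'
#' Derives each subject's parcellation from the group truth in two steps:
#' (1) boundary-adjacent vertices are reassigned to a neighboring network
#' with probability `deviation_rate`, preserving spatial coherence; (2) for
#' subjects with a dominance group, vertices are transferred between the two
#' language networks and adjacent donor networks, per hemisphere, until the
#' subject's laterality index LI = (LH - RH)/(LH + RH) is within `li_tol`
#' of a draw from Normal(group mean, group SD) truncated to [-1, 1]. Group
#' LI moments default to the reported left/bilateral/right study values
#' (0.165 +/- 0.106, 0.056 +/- 0.074, 0.023 +/- 0.055).
#'
#' @param truth A `cohort_truth` from [sample_group_truth()].
#' @param dominance Character vector, one of `"left"`, `"bilateral"`,
#'   `"right"`, or `"none"` per subject (`"none"` skips LI targeting).
#' @param deviation_rate Probability in [0, 0.5) that a boundary vertex
#'   deviates from the group label.
#' @param li_targets Named list of `c(mean, sd)` per dominance group.
#' @param li_tol Tolerance around the drawn target LI (default 0.02).
#' @param donor Optional network label used as the transfer partner in both
#'   hemispheres; by default the non-language network sharing the longest
#'   border with the language patches is used, per hemisphere.
#' @param seed Integer seed.
#' @return `truth` with `$subjects`: per subject a list with `id`, `labels`,
#'   `dominance`, `target_li`, `achieved_li`, and `flagged` (`TRUE` when the
#'   target could not be reached with the available vertices).
#' @export
sample_subject_labels <- function(truth, dominance, deviation_rate = 0.1,
                                  li_targets = default_li_targets(),
                                  li_tol = 0.02, donor = NULL, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!is.numeric(deviation_rate) || deviation_rate < 0 || deviation_rate >= 0.5)
    stopf("deviation_rate must be in [0, 0.5)")
  dominance <- match.arg(dominance, c("left", "bilateral", "right", "none"),
                         several.ok = TRUE)
  graph <- truth$graph
  subjects <- vector("list", length(dominance))
  for (s in seq_along(dominance)) {
    set.seed(derive_seed(seed, "subject-labels", s))
    lab <- perturb_boundaries(graph, truth$group_labels, deviation_rate)
    target <- NA_real_; achieved <- NA_real_; flagged <- FALSE
    if (dominance[s] != "none") {
      mom <- li_targets[[dominance[s]]]
      target <- rnorm_truncated(mom[1L], mom[2L], -1, 1)
      res <- steer_laterality(graph, lab, truth$language_ids, target, li_tol,
                              donor = donor)
      lab <- res$labels
      achieved <- res$li
      flagged <- res$flagged
    }
    subjects[[s]] <- list(
      id = s, labels = lab, dominance = dominance[s],
      target_li = target, achieved_li = achieved, flagged = flagged
    )
  }
  truth$subjects <- subjects
  truth$generator_params$deviation_rate <- deviation_rate
  truth$generator_params$li_targets <- li_targets
  truth$generator_params$subject_seed <- as.integer(seed)
  truth
}

#' Reported laterality-index moments per dominance group
#'
#' Group mean and SD of the resting-state laterality index for left,
#' bilateral and right task-based language dominance, used as generator
#' defaults when planting hemispheric asymmetry.
#' @return Named list of `c(mean, sd)`.
#' @export
default_li_targets <- function() {
  list(left = c(0.165, 0.106), bilateral = c(0.056, 0.074),
       right = c(0.023, 0.055))
}

rnorm_truncated <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(hi, max(lo, mean))
}

# Flip boundary vertices to a neighboring network with probability p.
perturb_boundaries <- function(graph, labels, p) {
  if (p <= 0) return(labels)
  nb <- graph$neighbors
  out <- labels
  boundary <- which(vapply(seq_along(labels), function(v) {
    labels[v] > 0L && any(labels[nb[[v]]] != labels[v] & labels[nb[[v]]] > 0L)
  }, logical(1)))
  flip <- boundary[runif(length(boundary)) < p]
  for (v in flip) {
    cand <- labels[nb[[v]]]
    cand <- cand[cand != labels[v] & cand > 0L]
    if (length(cand)) out[v] <- cand[sample.int(length(cand), 1L)]
  }
  out
}

# Transfer vertices between the language networks and one designated donor
# network per hemisphere until the laterality index reaches the target
# within tol. Restricting transfers to a single donor keeps the asymmetry
# planted in the language system only (other network borders are untouched,
# which the specificity control relies on). Reports the achieved LI and a
# flag when the supply of transferable border vertices runs out.
steer_laterality <- function(graph, labels, language_ids, target, tol,
                             donor = NULL, max_moves = graph$n_vertices) {
  nb <- graph$neighbors
  hemi <- graph$hemisphere
  is_lang <- function(l) l %in% language_ids
  li_of <- function(lab) {
    lh <- sum(is_lang(lab) & hemi == "L")
    rh <- sum(is_lang(lab) & hemi == "R")
    if (lh + rh == 0L) NA_real_ else (lh - rh) / (lh + rh)
  }
  # per-hemisphere donor: the non-language network sharing the longest
  # border with the language patches (ties to the lowest label)
  pick_donor <- function(h) {
    border <- integer(0)
    for (v in which(hemi == h & is_lang(labels))) {
      nl <- labels[nb[[v]]]
      border <- c(border, nl[!is_lang(nl) & nl > 0L])
    }
    if (!length(border)) return(NA_integer_)
    tb <- tabulate(border)
    which.max(tb)
  }
  donor_h <- if (is.null(donor)) {
    c(L = pick_donor("L"), R = pick_donor("R"))
  } else c(L = as.integer(donor), R = as.integer(donor))

  li <- li_of(labels)
  moves <- 0L
  # keep transferring while a move strictly reduces the distance to the
  # target; stopping at the first entry into the tolerance band would bias
  # the achieved LI low by up to tol
  while (!is.na(li) && moves < max_moves) {
    grow_h <- if (li < target) "L" else "R"
    shrink_h <- if (li < target) "R" else "L"
    dg <- donor_h[[grow_h]]; ds <- donor_h[[shrink_h]]
    # annex a donor vertex bordering a language patch in the growing side
    grow_cand <- if (is.na(dg)) integer(0) else
      which(hemi == grow_h & labels == dg &
              vapply(seq_along(labels), function(v)
                any(is_lang(labels[nb[[v]]])), logical(1)))
    # cede a language border vertex back to the donor on the shrinking side
    shrink_cand <- if (is.na(ds)) integer(0) else
      which(hemi == shrink_h & is_lang(labels) &
              vapply(seq_along(labels), function(v)
                any(labels[nb[[v]]] == ds), logical(1)))
    new_labels <- labels
    if (length(grow_cand)) {
      v <- grow_cand[sample.int(length(grow_cand), 1L)]
      ln <- labels[nb[[v]]]
      ln <- ln[is_lang(ln)]
      new_labels[v] <- ln[sample.int(length(ln), 1L)]
    } else if (length(shrink_cand)) {
      v <- shrink_cand[sample.int(length(shrink_cand), 1L)]
      new_labels[v] <- ds
    } else break
    new_li <- li_of(new_labels)
    if (is.na(new_li) || abs(new_li - target) >= abs(li - target)) break
    labels <- new_labels
    li <- new_li
    moves <- moves + 1L
  }
  list(labels = labels, li = li,
       flagged = is.na(li) || abs(li - target) > tol)
}

#' Simulate one resting-state run for a subject
#'
#' Each network k carries an i.i.d. standard-normal latent signal per run;
#' a vertex with label k observes `sqrt(snr) * g_k(t)` plus unit-variance
#' noise, and each ROI observes the signal of its parent network plus
#' noise. Unlabeled (masked) vertices observe pure noise.
#'
#' @param truth A `cohort_truth` with subjects attached.
#' @param subject_id Subject index into `truth$subjects`.
#' @param session_id Session identifier (integer; part of the seed).
#' @param T_frames Number of frames (>= 20).
#' @param snr Signal-to-noise variance ratio (> 0).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param seed Integer seed.
#' @return A `run_time_series`: list with `subject_id`, `session_id`,
#'   `vertex_ts` (T x V), `roi_ts` (T x R), `tr_seconds`.
#' @export
simulate_run <- function(truth, subject_id, session_id, T_frames = 200L,
                         snr = 4, tr_seconds = 2, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (is.null(truth$subjects)) stopf("truth has no subjects; call sample_subject_labels() first")
  if (!is_count(T_frames, 20L)) stopf("T_frames must be an integer >= 20")
  if (!is.numeric(snr) || snr <= 0) stopf("snr must be > 0")
  sub <- truth$subjects[[subject_id]]
  set.seed(derive_seed(seed, sprintf("run-%d", subject_id), session_id))
  K <- truth$K; R <- truth$R; V <- truth$graph$n_vertices
  g <- matrix(rnorm(T_frames * K), T_frames, K)
  vertex_ts <- matrix(rnorm(T_frames * V), T_frames, V)
  lab <- sub$labels
  on <- which(lab > 0L)
  vertex_ts[, on] <- vertex_ts[, on] + sqrt(snr) * g[, lab[on], drop = FALSE]
  roi_ts <- matrix(rnorm(T_frames * R), T_frames, R) +
    sqrt(snr) * g[, truth$roi_parent, drop = FALSE]
  structure(
    list(subject_id = subject_id, session_id = session_id,
         vertex_ts = vertex_ts, roi_ts = roi_ts, tr_seconds = tr_seconds),
    class = "run_time_series"
  )
}

#' Construct a stimulation block design
#'
#' Alternating stimulation/rest blocks, in frames. Blocks must tile a run
#' without overlap and alternate kinds; the first `discard_frames` frames of
#' each block are dropped when censoring to rest-only data, removing
#' residual hemodynamic carry-over from the previous block.
#'
#' @param block_durations Integer vector of block lengths in frames.
#' @param block_kinds Character vector, `"stim"`/`"rest"`, same length,
#'   strictly alternating.
#' @param discard_frames Frames discarded at the start of each block when
#'   censoring (default 4).
#' @return A `stim_design`: `block_onsets` (1-based first frame),
#'   `block_durations`, `block_kinds`, `discard_frames`, `total_frames`.
#' @export
stim_design <- function(block_durations, block_kinds, discard_frames = 4L) {
  n <- length(block_durations)
  stopifnot(length(block_kinds) == n, n >= 1L)
  if (!all(block_kinds %in% c("stim", "rest"))) stopf("block kinds must be 'stim' or 'rest'")
  if (n > 1L && any(block_kinds[-1L] == block_kinds[-n]))
    stopf("blocks must alternate stim/rest")
  if (any(block_durations < 1L)) stopf("block durations must be >= 1 frame")
  onsets <- cumsum(c(1L, block_durations[-n]))
  structure(
    list(block_onsets = as.integer(onsets),
         block_durations = as.integer(block_durations),
         block_kinds = block_kinds,
         discard_frames = as.integer(discard_frames),
         total_frames = as.integer(sum(block_durations))),
    class = "stim_design"
  )
}

#' Alternating ~30 s stimulation design
#'
#' Convenience constructor for the alternating stimulation/rest paradigm:
#' `n_cycles` repetitions of a rest block followed by a stimulation block
#' (ending on rest), each approximately 30 seconds long at the given TR.
#'
#' @param n_cycles Number of stim/rest cycles.
#' @param block_seconds Nominal block length in seconds (default 30).
#' @param tr_seconds Repetition time (default 2), so 15 frames per block.
#' @param discard_frames Frames dropped per block at censoring (default 4).
#' @export
alternating_design <- function(n_cycles = 4L, block_seconds = 30,
                               tr_seconds = 2, discard_frames = 4L) {
  frames <- as.integer(round(block_seconds / tr_seconds))
  kinds <- rep(c("rest", "stim"), n_cycles)
  kinds <- c(kinds, "rest")
  stim_design(rep(frames, length(kinds)), kinds, discard_frames)
}

#' Simulate a run with stimulation-evoked responses
#'
#' Generates a resting-state run as [simulate_run()] and adds, to every
#' vertex of the stimulated networks, a boxcar over the stimulation blocks
#' convolved with the canonical double-gamma hemodynamic response function
#' and scaled by `effect`. Vertices outside `stim_networks` receive no
#' evoked component.
#'
#' @inheritParams simulate_run
#' @param design A `stim_design` defining the blocks.
#' @param stim_networks Integer labels of the stimulated networks.
#' @param effect Evoked response amplitude (0 reduces to [simulate_run()]).
#' @return List with `run` (a `run_time_series`, T = design total frames)
#'   and `design`.
#' @export
simulate_stim_run <- function(truth, subject_id, design, stim_networks,
                              effect = 1, session_id = 1L, snr = 4,
                              tr_seconds = 2, seed = 1L) {
  stopifnot(inherits(design, "stim_design"))
  if (length(stim_networks) == 0L) {
    warnf("empty stim_networks: run has no evoked component")
  } else if (any(stim_networks < 1L | stim_networks > truth$K)) {
    stopf("stim_networks must be labels in 1..K")
  }
  run <- simulate_run(truth, subject_id, session_id,
                      T_frames = design$total_frames, snr = snr,
                      tr_seconds = tr_seconds, seed = seed)
  if (effect != 0 && length(stim_networks)) {
    reg <- stim_regressor(design, tr_seconds)
    lab <- truth$subjects[[subject_id]]$labels
    hit <- which(lab %in% stim_networks)
    run$vertex_ts[, hit] <- run$vertex_ts[, hit] + effect * reg
  }
  list(run = run, design = design)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "cohort_truth: V=%d, K=%d, R=%d, language networks {%s}, %s subjects\n",
    x$graph$n_vertices, x$K, x$R, paste(x$language_ids, collapse = ", "),
    if (is.null(x$subjects)) "no" else length(x$subjects)
  ))
  invisible(x)
}
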