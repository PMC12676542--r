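#' Resting-state laterality index of the language networks
#'
#' LI = (LH - RH) / (LH + RH), where LH and RH are the numbers of left- and
#' right-hemisphere vertices assigned to the designated language networks
#' (Language A plus Language/Default B). Positive LI indicates
#' left-lateralized language topography. When no vertex is assigned to a
#' language network the LI is undefined and flagged rather than set to 0.
#'
#' @param labels Per-vertex integer labels (or an
#'   `individual_parcellation`).
#' @param language_ids Labels of the two language networks (non-empty).
#' @param hemisphere Per-vertex `"L"`/`"R"` factor covering the vertices.
#' @param subject_id Optional identifier carried into the record.
#' @param dominance Optional dominance group carried into the record.
#' @return A `laterality_record`: `subject_id`, `lh_count`, `rh_count`,
#'   `li` (`NA` when undefined), `defined`, `dominance`.
#' @export
compute_li <- function(labels, language_ids, hemisphere, subject_id = NA,
                       dominance = NA_character_) {
  if (inherits(labels, "individual_parcellation")) {
    if (is.na(subject_id)) subject_id <- labels$subject_id
    labels <- labels$labels
  }
  if (length(language_ids) == 0L) stopf("language_ids must be non-empty")
  if (length(hemisphere) != length(labels))
    stopf("hemisphere map must cover the vertices")
  lang <- labels %in% language_ids
  lh <- sum(lang & hemisphere == "L")
  rh <- sum(lang & hemisphere == "R")
  defined <- (lh + rh) > 0L
  if (!defined)
    warnf("subject %s: no language-network vertices; LI undefined", format(subject_id))
  structure(
    list(subject_id = subject_id, lh_count = lh, rh_count = rh,
         li = if (defined) (lh - rh) / (lh + rh) else NA_real_,
         defined = defined, dominance = dominance),
    class = "laterality_record"
  )
}

records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = as.character(r$subject_id), lh_count = r$lh_count,
               rh_count = r$rh_count, li = r$li, defined = r$defined,
               dominance = r$dominance, stringsAsFactors = FALSE)
  }))
}

#' One-way ANOVA of laterality index across dominance groups
#'
#' Classic fixed-effects one-way ANOVA of LI on the dominance grouping.
#' Subjects with undefined LI are excluded with a warning. If every group
#' is the same constant the F statistic is undefined (0/0) and flagged.
#'
#' @param records List of `laterality_record`s (with dominance set), or a
#'   data frame with columns `li` and `dominance`.
#' @return A `dominance_comparison`: `group_means`, `group_sds`,
#'   `n_per_group`, `F`, `p`, `df`.
#' @export
anova_li <- function(records) {
  df <- if (is.data.frame(records)) records else records_to_df(records)
  drop <- is.na(df$li)
  if (any(drop)) {
    warnf("%d subject(s) with undefined LI excluded from ANOVA", sum(drop))
    df <- df[!drop, ]
  }
  groups <- split(df$li, df$dominance)
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 2L || any(vapply(groups, length, integer(1)) < 2L))
    stopf("need >= 2 groups with >= 2 members each")
  g <- factor(df$dominance)
  fit <- stats::anova(stats::lm(li ~ g, data = df))
  Fv <- fit$`F value`[1L]; pv <- fit$`Pr(>F)`[1L]
  if (!is.finite(Fv)) warnf("F undefined: all groups constant")
  structure(
    list(group_means = vapply(groups, mean, numeric(1)),
         group_sds = vapply(groups, sd, numeric(1)),
         n_per_group = vapply(groups, length, integer(1)),
         F = Fv, p = pv, df = unname(fit$Df)),
    class = "dominance_comparison"
  )
}

#' ROC curve and AUC for predicting one dominance group from LI
#'
#' One-vs-rest receiver operating characteristic of the laterality index.
#' AUC is the Mann-Whitney concordance (ties get half credit) of the
#' oriented scores. Orientation +1 treats higher LI as evidence for the
#' positive group (the natural choice for left dominance); -1 flips the
#' score (right dominance, where lower LI is the signal).
#'
#' @param records List of `laterality_record`s or a data frame with `li`
#'   and `dominance`.
#' @param positive_group Dominance level treated as positive.
#' @param orientation +1 or -1; default +1 for `"left"`, -1 for `"right"`,
#'   +1 otherwise.
#' @return A `roc_result`: `auc`, `thresholds`, `tpr`, `fpr`,
#'   `orientation`, `positive_group`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(records, positive_group, orientation = NULL) {
  df <- if (is.data.frame(records)) records else records_to_df(records)
  df <- df[!is.na(df$li), ]
  pos <- df$dominance == positive_group
  if (!any(pos) || all(pos)) stopf("both classes must be non-empty")
  if (is.null(orientation))
    orientation <- if (identical(positive_group, "right")) -1 else 1
  s <- orientation * df$li
  sp <- s[pos]; sn <- s[!pos]
  conc <- 0
  for (x in sp) conc <- conc + sum(x > sn) + 0.5 * sum(x == sn)
  auc <- conc / (length(sp) * length(sn))
  thr <- sort(unique(s), decreasing = TRUE)
  thr <- c(Inf, thr)
  tpr <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sn >= t), numeric(1))
  structure(
    list(auc = auc, thresholds = thr, tpr = tpr, fpr = fpr,
         orientation = orientation, positive_group = positive_group,
         n_pos = length(sp), n_neg = length(sn)),
    class = "roc_result"
  )
}

#' Inter-subject Dice similarity of network topography
#'
#' For every network and subject pair, the Dice coefficient
#' `2 |A ∩ B| / (|A| + |B|)` of the two subjects' vertex sets for that
#' network. Pairs where both sets are empty are recorded as missing.
#'
#' @param parcellations List of per-vertex label vectors (or
#'   `individual_parcellation`s) on a common vertex set.
#' @param K Number of networks.
#' @return A `dice_matrix`: `per_network` (K x n_pairs matrix),
#'   `network_mean` (length K, mean over pairs), `pairs` (2 x n_pairs).
#' @export
inter_subject_dice <- function(parcellations, K) {
  labs <- lapply(parcellations, function(p) {
    if (inherits(p, "individual_parcellation")) p$labels else p
  })
  n <- length(labs)
  if (n < 2L) stopf("need >= 2 parcellations")
  V <- length(labs[[1L]])
  for (l in labs) if (length(l) != V) stopf("parcellations must share the vertex set")
  pairs <- utils::combn(n, 2L)
  per <- matrix(NA_real_, K, ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    d <- dice_coefficient(labs[[pairs[1L, j]]], labs[[pairs[2L, j]]], K)
    per[, j] <- d$per_network
  }
  structure(
    list(per_network = per,
         network_mean = rowMeans(per, na.rm = TRUE),
         pairs = pairs, K = K),
    class = "dice_matrix"
  )
}
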