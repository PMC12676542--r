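#' Train a multi-session hierarchical Bayesian parcellation model
#'
#' Fits the three-level von Mises-Fisher hierarchy with a Markov random
#' field spatial label prior. Generatively: subject mean directions
#' `mu_k^s ~ vMF(mu_k, epsilon_k)`, session means
#' `mu_k^{s,t} ~ vMF(mu_k^s, sigma_k)`, observed vertex profiles
#' `x_v^{s,t} ~ vMF(mu_{l_v}^{s,t}, kappa)` with shared observation
#' concentration, and a label field prior
#' `P(l) ∝ exp(sum_v log theta_v(l_v) + c * sum_(u,v in E) 1[l_u = l_v])`.
#' Fitting is blocked coordinate ascent on the (pseudo-)log-joint:
#' ICM label sweeps per subject, closed-form resultant updates for
#' session/subject/group means, likelihood-refined concentration updates,
#' and a Dirichlet-smoothed update of the spatial prior `theta`.
#'
#' @param profiles Nested list: `profiles[[s]][[t]]` is the
#'   `connectivity_profile` of subject s, session t; every subject needs
#'   >= 2 sessions.
#' @param graph The `cortical_graph` shared by all profiles.
#' @param init Initialization: a list with `mu` (K x R unit rows) and
#'   `labels` (per-vertex group labels), typically from
#'   [fit_vmf_mixture()].
#' @param c_smooth MRF smoothness weight (>= 0, default 5).
#' @param theta_alpha Dirichlet pseudocount for the spatial prior
#'   (default 1).
#' @param max_iter Maximum outer iterations.
#' @param max_sweeps Maximum ICM sweeps per label update (default 10).
#' @param tol Relative objective convergence tolerance.
#' @param kappa_init,max_kappa Initial and maximum concentrations.
#' @param verbose Print per-iteration objectives.
#' @return An `mshbm_params` object: `mu` (K x R), `epsilon`, `sigma`
#'   (per-network), `kappa` (shared), `theta` (V x K rows on the simplex),
#'   `c_smooth`, `K`, `R`, `V`, `objective_trace`, `subject_labels`
#'   (training-set individual parcellations), `converged`.
#' @export
train_mshbm <- function(profiles, graph, init, c_smooth = 5,
                        theta_alpha = 1, max_iter = 30L, max_sweeps = 10L,
                        tol = 1e-6, kappa_init = NULL, max_kappa = 1e5,
                        verbose = FALSE) {
  S <- length(profiles)
  if (S < 1L) stopf("need at least one training subject")
  for (s in seq_len(S)) {
    if (length(profiles[[s]]) < 2L)
      stopf("subject %d rejected: hierarchical training needs >= 2 sessions", s)
  }
  if (c_smooth < 0) stopf("c_smooth must be >= 0")
  X <- lapply(profiles, function(ps) lapply(ps, profile_rows))
  V <- nrow(X[[1L]][[1L]]); R <- ncol(X[[1L]][[1L]])
  for (s in seq_len(S)) for (t in seq_along(X[[s]]))
    if (!all(dim(X[[s]][[t]]) == c(V, R))) stopf("profile dimensions inconsistent")
  mu <- init$mu
  K <- nrow(mu)
  stopifnot(ncol(mu) == R, length(init$labels) == V)
  mask <- graph$cortex_mask & rowSums(X[[1L]][[1L]]^2) > 0

  # initial state: everything at the group solution
  sub_mu <- rep(list(mu), S)
  ses_mu <- lapply(X, function(ps) rep(list(mu), length(ps)))
  labels <- lapply(seq_len(S), function(s) init$labels)
  epsilon <- rep(50, K); sigma <- rep(50, K)
  kappa <- if (is.null(kappa_init)) 50 else kappa_init
  theta <- theta_from_labels(labels, V, K, theta_alpha, mask)

  obj_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # (a) label ICM per subject
    for (s in seq_len(S)) {
      labels[[s]] <- icm_labels(X[[s]], ses_mu[[s]], kappa, theta, c_smooth,
                                graph, labels[[s]], mask, max_sweeps)
    }
    # (b) mean direction updates, bottom-up then top-down normalization
    for (s in seq_len(S)) {
      for (t in seq_along(X[[s]])) {
        ses_mu[[s]][[t]] <- update_session_mu(X[[s]][[t]], labels[[s]],
                                              sub_mu[[s]], kappa, sigma, K)
      }
      sub_mu[[s]] <- update_subject_mu(ses_mu[[s]], mu, sigma, epsilon, K)
    }
    mu <- update_group_mu(sub_mu, epsilon, K, mu)
    # (c) concentrations from the appropriate mean resultants
    conc <- update_concentrations(X, labels, ses_mu, sub_mu, mu, K, R,
                                  max_kappa)
    epsilon <- conc$epsilon; sigma <- conc$sigma; kappa <- conc$kappa
    # (d) spatial prior
    theta <- theta_from_labels(labels, V, K, theta_alpha, mask)

    obj <- mshbm_objective(X, labels, ses_mu, sub_mu, mu, epsilon, sigma,
                           kappa, theta, c_smooth, graph, theta_alpha, R)
    obj_trace <- c(obj_trace, obj)
    if (!is.finite(obj)) stopf("objective became non-finite at iteration %d", it)
    if (verbose) message(sprintf("  iter %d: objective %.4f", it, obj))
    if (it > 1L && abs(obj - obj_trace[it - 1L]) < tol * abs(obj)) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(mu = mu, epsilon = epsilon, sigma = sigma, kappa = kappa,
         theta = theta, c_smooth = c_smooth, K = K, R = R, V = V,
         theta_alpha = theta_alpha, objective_trace = obj_trace,
         subject_labels = labels, converged = converged,
         mask = mask),
    class = "mshbm_params"
  )
}

# Smoothed empirical label frequencies across subjects (Dirichlet MAP).
theta_from_labels <- function(labels, V, K, alpha, mask) {
  counts <- matrix(0, V, K)
  for (lab in labels) {
    on <- which(lab > 0L)
    counts[cbind(on, lab[on])] <- counts[cbind(on, lab[on])] + 1
  }
  th <- counts + alpha
  th <- th / rowSums(th)
  th[!mask, ] <- 1 / K
  th
}

# ICM sweeps in fixed ascending vertex order; local energy of label k at
# vertex v: kappa * sum_t x_v^t . mu_k^t + log theta_v(k) + c * (# same-label
# neighbors). Ties broken by larger theta, then lower label index. The
# shared observation kappa makes the vMF normalizer constant across labels.
icm_labels <- function(Xs, ses_mu, kappa, theta, c_smooth, graph, labels,
                       mask, max_sweeps) {
  V <- nrow(Xs[[1L]]); K <- nrow(ses_mu[[1L]])
  data_term <- matrix(0, V, K)
  for (t in seq_along(Xs)) data_term <- data_term + Xs[[t]] %*% t(ses_mu[[t]])
  data_term <- kappa * data_term
  base <- data_term + log(theta)
  nb <- graph$neighbors
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (v in seq_len(V)) {
      if (!mask[v]) { labels[v] <- 0L; next }
      e <- base[v, ]
      if (c_smooth > 0) {
        nl <- labels[nb[[v]]]
        nl <- nl[nl > 0L]
        if (length(nl)) {
          tb <- tabulate(nl, nbins = K)
          e <- e + c_smooth * tb
        }
      }
      best <- which(e == max(e))
      if (length(best) > 1L) {
        th <- theta[v, best]
        best <- best[th == max(th)]
        best <- best[1L]
      }
      if (best != labels[v]) { labels[v] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  labels
}

# MAP session mean: normalize(kappa * labeled resultant + sigma_k * subject mu)
update_session_mu <- function(Xt, labels, sub_mu, kappa, sigma, K) {
  out <- matrix(0, K, ncol(Xt))
  for (k in seq_len(K)) {
    memb <- which(labels == k)
    r <- if (length(memb)) colSums(Xt[memb, , drop = FALSE]) else 0
    v <- kappa * r + sigma[k] * sub_mu[k, ]
    out[k, ] <- if (sum(v^2) > 0) l2_normalize(v) else sub_mu[k, ]
  }
  out
}

update_subject_mu <- function(ses_mu, mu, sigma, epsilon, K) {
  out <- matrix(0, K, ncol(mu))
  for (k in seq_len(K)) {
    r <- Reduce(`+`, lapply(ses_mu, function(m) m[k, ]))
    v <- sigma[k] * r + epsilon[k] * mu[k, ]
    out[k, ] <- if (sum(v^2) > 0) l2_normalize(v) else mu[k, ]
  }
  out
}

update_group_mu <- function(sub_mu, epsilon, K, mu_old) {
  out <- matrix(0, K, ncol(mu_old))
  for (k in seq_len(K)) {
    r <- Reduce(`+`, lapply(sub_mu, function(m) m[k, ]))
    out[k, ] <- if (sum(r^2) > 0) l2_normalize(r) else mu_old[k, ]
  }
  out
}

update_concentrations <- function(X, labels, ses_mu, sub_mu, mu, K, R,
                                  max_kappa) {
  S <- length(X)
  # epsilon_k: subject means around the group mean
  epsilon <- sigma <- numeric(K)
  for (k in seq_len(K)) {
    rs <- vapply(sub_mu, function(m) sum(m[k, ] * mu[k, ]), numeric(1))
    epsilon[k] <- kappa_mle(clamp_rbar(mean(rs)), R, max_kappa)
    rt <- unlist(lapply(seq_len(S), function(s) {
      vapply(ses_mu[[s]], function(m) sum(m[k, ] * sub_mu[[s]][k, ]), numeric(1))
    }))
    sigma[k] <- kappa_mle(clamp_rbar(mean(rt)), R, max_kappa)
  }
  # shared kappa: observations around their session/label means
  tot <- 0; nobs <- 0
  for (s in seq_len(S)) for (t in seq_along(X[[s]])) {
    on <- which(labels[[s]] > 0L)
    if (!length(on)) next
    dots <- rowSums(X[[s]][[t]][on, , drop = FALSE] *
                      ses_mu[[s]][[t]][labels[[s]][on], , drop = FALSE])
    tot <- tot + sum(dots); nobs <- nobs + length(dots)
  }
  kappa <- kappa_mle(clamp_rbar(tot / max(nobs, 1)), R, max_kappa)
  list(epsilon = epsilon, sigma = sigma, kappa = kappa)
}

clamp_rbar <- function(r) min(max(r, 0), 1 - 1e-9)

# Pseudo-log-joint tracked during training (MRF partition constant omitted).
mshbm_objective <- function(X, labels, ses_mu, sub_mu, mu, epsilon, sigma,
                            kappa, theta, c_smooth, graph, alpha, R) {
  S <- length(X)
  obj <- 0
  lcd_k <- vmf_log_cd(kappa, R)
  for (s in seq_len(S)) {
    on <- which(labels[[s]] > 0L)
    for (t in seq_along(X[[s]])) {
      dots <- rowSums(X[[s]][[t]][on, , drop = FALSE] *
                        ses_mu[[s]][[t]][labels[[s]][on], , drop = FALSE])
      obj <- obj + sum(kappa * dots) + length(on) * lcd_k
      for (k in seq_len(nrow(mu)))
        obj <- obj + vmf_log_cd(sigma[k], R) +
          sigma[k] * sum(ses_mu[[s]][[t]][k, ] * sub_mu[[s]][k, ])
    }
    for (k in seq_len(nrow(mu)))
      obj <- obj + vmf_log_cd(epsilon[k], R) +
        epsilon[k] * sum(sub_mu[[s]][k, ] * mu[k, ])
    obj <- obj + sum(log(theta[cbind(on, labels[[s]][on])]))
    e <- graph$edges
    same <- labels[[s]][e[, 1L]] == labels[[s]][e[, 2L]] & labels[[s]][e[, 1L]] > 0L
    obj <- obj + c_smooth * sum(same)
  }
  obj + (alpha - 1) * sum(log(theta[graph$cortex_mask, ]))
}

#' Infer an individual-specific parcellation from new subject data
#'
#' With group-level parameters frozen, alternates closed-form session and
#' subject mean-direction updates with ICM label sweeps (fixed ascending
#' vertex order) until no label changes or `max_iter` is reached. Works
#' from a single session: the hierarchy shrinks the subject's means toward
#' the group directions in proportion to the learned variability.
#'
#' @param params An `mshbm_params` from [train_mshbm()].
#' @param profiles List of >= 1 `connectivity_profile` for the new subject.
#' @param max_iter Maximum alternations (default 20).
#' @param max_sweeps ICM sweeps per alternation.
#' @param graph The `cortical_graph` (edge structure for the MRF term).
#' @return An `individual_parcellation`: `labels`, `subject_mu`,
#'   `session_mu`, `converged`, `n_iter`.
#' @export
infer_individual <- function(params, profiles, graph, max_iter = 20L,
                             max_sweeps = 10L) {
  stopifnot(inherits(params, "mshbm_params"))
  if (length(profiles) < 1L) stopf("need at least one session profile")
  X <- lapply(profiles, profile_rows)
  V <- nrow(X[[1L]]); R <- ncol(X[[1L]])
  if (V != params$V || R != params$R)
    stopf("profile dimensions (%d x %d) do not match model (%d x %d)",
          V, R, params$V, params$R)
  K <- params$K
  mask <- graph$cortex_mask & rowSums(X[[1L]]^2) > 0
  labels <- integer(V)
  labels[mask] <- max.col(params$theta[mask, , drop = FALSE],
                          ties.method = "first")
  sub_mu <- params$mu
  ses_mu <- rep(list(params$mu), length(X))
  n_iter <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    for (t in seq_along(X)) {
      ses_mu[[t]] <- update_session_mu(X[[t]], labels, sub_mu, params$kappa,
                                       params$sigma, K)
    }
    sub_mu <- update_subject_mu(ses_mu, params$mu, params$sigma,
                                params$epsilon, K)
    new_labels <- icm_labels(X, ses_mu, params$kappa, params$theta,
                             params$c_smooth, graph, labels, mask, max_sweeps)
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
  }
  structure(
    list(subject_id = profiles[[1L]]$subject_id, labels = labels,
         subject_mu = sub_mu, session_mu = ses_mu,
         converged = converged, n_iter = n_iter),
    class = "individual_parcellation"
  )
}

#' Match network labels between two parcellations
#'
#' Finds the permutation of 1..K maximizing total vertex overlap between
#' labelings `a` and `b` by Hungarian assignment on the K x K contingency
#' table. `match_networks(a, b)[k]` is the label in `b` corresponding to
#' label `k` in `a`.
#'
#' @param a,b Integer label vectors over the same vertex set (0 = masked).
#' @param K Number of networks.
#' @return Integer permutation of 1..K.
#' @export
match_networks <- function(a, b, K) {
  if (length(a) != length(b)) stopf("labelings must share the vertex set")
  if (max(a, b) > K) stopf("labels exceed K")
  overlap <- matrix(0, K, K)
  on <- a > 0L & b > 0L
  for (k in seq_len(K)) {
    bk <- b[on & a == k]
    if (length(bk)) overlap[k, ] <- tabulate(bk, nbins = K)
  }
  hungarian_max(overlap)
}

# Hungarian algorithm (potentials + augmenting paths, O(K^3)) maximizing
# total weight; deterministic for a fixed cost matrix.
hungarian_max <- function(w) {
  n <- nrow(w)
  cost <- max(w) - w                    # minimize
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)                  # p[j]: row assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) perm[p[j + 1L]] <- j
  perm
}

#' Dice similarity coefficient between two labelings
#'
#' Per network k: `2 |A ∩ B| / (|A| + |B|)` over the vertex sets labeled k.
#' The `overall` summary weights networks by their combined size.
#'
#' @param a,b Integer label vectors on a common vertex set.
#' @param K Number of networks.
#' @return List with `per_network` (length K, `NA` when both sets are
#'   empty) and `overall`.
#' @export
dice_coefficient <- function(a, b, K = max(a, b)) {
  if (length(a) != length(b)) stopf("labelings must share the vertex set")
  per <- rep(NA_real_, K)
  wt <- numeric(K)
  for (k in seq_len(K)) {
    na_ <- sum(a == k); nb_ <- sum(b == k)
    wt[k] <- na_ + nb_
    if (na_ + nb_ == 0L) next
    per[k] <- 2 * sum(a == k & b == k) / (na_ + nb_)
  }
  ok <- wt > 0
  list(per_network = per,
       overall = if (any(ok)) sum(per[ok] * wt[ok]) / sum(wt[ok]) else NA_real_)
}

#' @export
print.mshbm_params <- function(x, ...) {
  cat(sprintf(
    "mshbm_params: K=%d, R=%d, V=%d, kappa=%.1f, c=%.1f, %d iterations%s\n",
    x$K, x$R, x$V, x$kappa, x$c_smooth, length(x$objective_trace),
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
print.individual_parcellation <- function(x, ...) {
  cat(sprintf(
    "individual_parcellation: subject %s, %d labeled vertices, %d iterations%s\n",
    format(x$subject_id), sum(x$labels > 0L), x$n_iter,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}
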