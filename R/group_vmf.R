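#' Fit a mixture of von Mises-Fisher distributions to connectivity profiles
#'
#' Clusters unit-norm connectivity profiles on the hypersphere with EM:
#' responsibilities are proportional to `weight_k * C_d(kappa_k) *
#' exp(kappa_k * mu_k . x)` (computed in the log domain), mean directions are
#' responsibility-weighted resultants, and concentrations are estimated from
#' the mean resultant length with a likelihood-refined closed-form inverse.
#' The best of `n_init` seeded restarts by final log-likelihood is returned.
#' Group-level network labels are assigned per vertex by the majority
#' (summed) responsibility across all pooled rows belonging to that vertex.
#'
#' @param x Numeric matrix (or list of `connectivity_profile` objects) of
#'   unit-norm rows: pooled profiles from all training subjects/sessions.
#' @param K Number of networks/clusters.
#' @param vertex_id Optional integer vector mapping each row of `x` to a
#'   vertex (used to pool responsibilities into per-vertex group labels).
#'   Rows of masked vertices (all-zero) are dropped automatically.
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param shared_kappa If `TRUE`, a single concentration is shared across
#'   clusters; default is per-cluster concentrations.
#' @param max_kappa Concentration clip.
#' @param seed Integer seed controlling all restarts.
#' @return A list with `params` (class `vmf_mixture`: `mu` K x d, `kappa`,
#'   `weights`, `loglik`, `n_iter`, `seed`) and `labels` (per-vertex integer
#'   labels if `vertex_id` given, else per-row labels).
#' @export
fit_vmf_mixture <- function(x, K, vertex_id = NULL, n_init = 10L,
                            max_iter = 100L, tol = 1e-5,
                            shared_kappa = FALSE, max_kappa = 1e5,
                            seed = 1L) {
  x <- as.matrix(x)
  if (!is_count(K, 1L)) stopf("K must be a positive integer")
  nz <- rowSums(x^2) > 0
  if (!is.null(vertex_id)) {
    stopifnot(length(vertex_id) == nrow(x))
    vid <- vertex_id[nz]
  }
  xr <- x[nz, , drop = FALSE]
  norms <- sqrt(rowSums(xr^2))
  if (any(abs(norms - 1) > 1e-6)) stopf("profile rows must be unit-norm")
  n <- nrow(xr); d <- ncol(xr)
  if (n < K) stopf("need at least K rows (%d < %d)", n, K)

  best <- NULL
  for (init in seq_len(n_init)) {
    set.seed(derive_seed(seed, "vmf-init", init))
    fit <- vmf_em_once(xr, K, max_iter, tol, shared_kappa, max_kappa)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$init <- init
    }
  }
  best$seed <- as.integer(seed)
  class(best) <- "vmf_mixture"

  resp <- vmf_responsibilities(xr, best)
  if (is.null(vertex_id)) {
    labels <- max.col(resp, ties.method = "first")
  } else {
    V <- max(vertex_id)
    labels <- integer(V)
    acc <- rowsum(resp, group = vid)
    labels[as.integer(rownames(acc))] <- max.col(acc, ties.method = "first")
  }
  list(params = best, labels = labels)
}

# One EM run from a random start (rows as initial means).
vmf_em_once <- function(x, K, max_iter, tol, shared_kappa, max_kappa) {
  n <- nrow(x); d <- ncol(x)
  mu <- x[sample.int(n, K), , drop = FALSE]
  kappa <- rep(10, K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    es <- vmf_estep(x, mu, kappa, w)
    ll <- es$loglik
    ll_trace <- c(ll_trace, ll)
    resp <- es$resp

    nk <- colSums(resp)
    # empty cluster: reseed from the worst-fit row
    for (k in which(nk < 1e-8)) {
      worst <- which.min(es$rowmax)
      mu[k, ] <- x[worst, ]
      kappa[k] <- max(kappa)
      nk[k] <- 1e-8
    }
    r <- crossprod(resp, x)                      # K x d resultants
    rlen <- sqrt(rowSums(r^2))
    for (k in seq_len(K)) if (rlen[k] > 0) mu[k, ] <- r[k, ] / rlen[k]
    rbar <- pmin(rlen / pmax(nk, 1e-12), 1 - 1e-12)
    if (shared_kappa) {
      kappa <- rep(kappa_mle(sum(rlen) / n, d, max_kappa), K)
    } else {
      kappa <- vapply(rbar, kappa_mle, numeric(1), d = d, max_kappa = max_kappa)
    }
    w <- nk / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  es <- vmf_estep(x, mu, kappa, w)
  list(mu = mu, kappa = kappa, weights = w,
       loglik = es$loglik, loglik_trace = c(ll_trace, es$loglik),
       n_iter = length(ll_trace))
}

# Log-domain E-step; returns responsibilities, total loglik, per-row max.
vmf_estep <- function(x, mu, kappa, w) {
  K <- nrow(mu); d <- ncol(mu)
  logc <- vapply(seq_len(K), function(k) vmf_log_cd(kappa[k], d), numeric(1))
  s <- x %*% t(mu)                               # n x K dot products
  lp <- sweep(s, 2L, kappa, `*`)
  lp <- sweep(lp, 2L, log(pmax(w, 1e-300)) + logc, `+`)
  m <- apply(lp, 1L, max)
  p <- exp(lp - m)
  rs <- rowSums(p)
  list(resp = p / rs, loglik = sum(m + log(rs)), rowmax = m + log(rs))
}

vmf_responsibilities <- function(x, params) {
  vmf_estep(x, params$mu, params$kappa, params$weights)$resp
}

#' @export
print.vmf_mixture <- function(x, ...) {
  cat(sprintf("vmf_mixture: K=%d, d=%d, loglik=%.3f after %d iterations\n",
              nrow(x$mu), ncol(x$mu), x$loglik, x$n_iter))
  invisible(x)
}
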