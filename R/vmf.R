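#' Sample from a von Mises-Fisher distribution
#'
#' Draws unit vectors on the (d-1)-sphere concentrated around a mean
#' direction `mu` with concentration `kappa`. The radial component is drawn
#' by Wood's rejection scheme (a beta-distributed envelope for the cosine of
#' the angle to `mu`); the tangential component is uniform on the orthogonal
#' subsphere. `kappa = 0` gives the uniform distribution on the sphere.
#'
#' @param mu Unit-norm mean direction (numeric vector, length d >= 2).
#' @param kappa Concentration parameter, >= 0.
#' @param n Number of samples.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n x d` matrix with unit-norm rows.
#' @examples
#' x <- sample_vmf(c(1, 0, 0), kappa = 50, n = 5, seed = 1)
#' rowSums(x^2)
#' @export
sample_vmf <- function(mu, kappa, n, seed = NULL) {
  if (abs(sqrt(sum(mu^2)) - 1) > 1e-8) stopf("mu must be unit-norm within 1e-8")
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stopf("kappa must be a single number >= 0")
  if (!is_count(n, 1L)) stopf("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  d <- length(mu)
  if (d < 2L) stopf("dimension must be >= 2")

  if (kappa == 0) {
    x <- matrix(rnorm(n * d), n, d)
    return(x / sqrt(rowSums(x^2)))
  }

  # Wood-style rejection for w = cos(angle to mu)
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  cc <- kappa * x0 + (d - 1) * log(1 - x0^2)
  w <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- rbeta(m, (d - 1) / 2, (d - 1) / 2)
    wcand <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    u <- runif(m)
    ok <- kappa * wcand + (d - 1) * log(1 - x0 * wcand) - cc >= log(u)
    k <- sum(ok)
    if (k > 0L) {
      w[(got + 1L):(got + k)] <- wcand[ok]
      got <- got + k
    }
  }

  # tangential directions: isotropic Gaussian projected orthogonal to mu
  v <- matrix(rnorm(n * d), n, d)
  v <- v - outer(as.vector(v %*% mu), mu)
  v <- v / sqrt(rowSums(v^2))
  out <- w %o% mu + sqrt(pmax(0, 1 - w^2)) * v
  out / sqrt(rowSums(out^2))
}

#' Mean resultant length of a von Mises-Fisher distribution
#'
#' Computes `A_d(kappa) = I_{d/2}(kappa) / I_{d/2-1}(kappa)`, the expected
#' dot product of a vMF(mu, kappa) draw with mu in dimension `d`.
#' Exponentially scaled Bessel evaluation keeps the ratio stable; for
#' arguments past the Bessel range a large-`kappa` asymptotic expansion is
#' used.
#'
#' @param kappa Concentration >= 0.
#' @param d Dimension >= 2.
#' @return The mean resultant length in [0, 1).
#' @export
vmf_mean_resultant <- function(kappa, d) {
  stopifnot(kappa >= 0, d >= 2)
  if (kappa == 0) return(0)
  num <- besselI(kappa, d / 2, expon.scaled = TRUE)
  den <- besselI(kappa, d / 2 - 1, expon.scaled = TRUE)
  if (is.finite(num) && is.finite(den) && den > 0) return(num / den)
  # asymptotic: A_d(k) ~ 1 - (d-1)/(2k) - (d-1)(d-3)/(8k^2)
  1 - (d - 1) / (2 * kappa) - (d - 1) * (d - 3) / (8 * kappa^2)
}

#' Estimate a vMF concentration from a mean resultant length
#'
#' Closed-form approximation `kappa = rbar * (d - rbar^2) / (1 - rbar^2)`
#' to the inverse of the Bessel ratio `A_d`. The estimate is clipped to
#' `max_kappa` to keep downstream exponentials finite when `rbar`
#' approaches 1.
#'
#' @param rbar Mean resultant length in [0, 1).
#' @param d Dimension (number of ROIs) >= 2.
#' @param max_kappa Upper clip for the returned concentration.
#' @return Estimated concentration (scalar, >= 0).
#' @examples
#' estimate_kappa(0.5, 3) # 0.5 * (3 - 0.25) / 0.75
#' @export
estimate_kappa <- function(rbar, d, max_kappa = 1e5) {
  if (!is.numeric(rbar) || length(rbar) != 1L || is.na(rbar) || rbar < 0)
    stopf("rbar must be a single number in [0, 1)")
  if (rbar >= 1) stopf("rbar >= 1: concentration is degenerate (infinite)")
  if (d < 2) stopf("d must be >= 2")
  min(max_kappa, rbar * (d - rbar^2) / (1 - rbar^2))
}

# Maximum-likelihood concentration given rbar: refines the closed-form
# estimate by 1-D maximization of n * (log C_d(kappa) + kappa * rbar), so the
# EM objectives that include the normalizing constant stay monotone.
kappa_mle <- function(rbar, d, max_kappa = 1e5) {
  if (rbar <= 1e-12) return(0)
  k0 <- estimate_kappa(min(rbar, 1 - 1e-12), d, max_kappa)
  if (k0 >= max_kappa) return(max_kappa)
  obj <- function(k) vmf_log_cd(k, d) + k * rbar
  lo <- max(1e-8, k0 / 4)
  hi <- min(max_kappa, max(k0 * 4, 1))
  opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (obj(k0) > opt$objective) k0 else opt$maximum
}

# log normalizing constant of vMF in dimension d:
# C_d(k) = k^{d/2-1} / ((2 pi)^{d/2} I_{d/2-1}(k)); uniform limit at k -> 0.
vmf_log_cd <- function(kappa, d) {
  if (kappa < 1e-10) return(lgamma(d / 2) - log(2) - (d / 2) * log(pi))
  nu <- d / 2 - 1
  bi <- besselI(kappa, nu, expon.scaled = TRUE)
  if (is.finite(bi) && bi > 0) {
    logI <- log(bi) + kappa
  } else {
    # uniform asymptotic expansion of log I_nu for large argument
    logI <- kappa - 0.5 * log(2 * pi * kappa)
  }
  (d / 2 - 1) * log(kappa) - (d / 2) * log(2 * pi) - logI
}
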