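## Watson-distribution machinery: ODI <-> kappa, the dispersion factor
## tau(kappa) = <(mu' n)^2> via the Dawson function, and numeric inversions.

## Watson concentration cap used when converting ODI -> kappa for ODI near 0
## ("parallel fibers" saturation).
KAPPA_CAP <- 1e6

## Dawson function F(x) = exp(-x^2) * integral_0^x exp(t^2) dt.
## pracma::erfi route below x = 5; asymptotic series above (erfi overflows).
dawson <- function(x) {
  out <- numeric(length(x))
  small <- x < 5
  if (any(small)) {
    xs <- x[small]
    out[small] <- sqrt(pi) / 2 * exp(-xs^2) * pracma::erfi(xs)
  }
  if (any(!small)) {
    xl <- x[!small]
    s <- 0; term <- 1 / (2 * xl)
    for (k in 0:14) {           # (2k-1)!! / (2^(k+1) x^(2k+1)); converges fast
      s <- s + term
      term <- term * (2 * k + 1) / (2 * xl^2)
    }
    out[!small] <- s
  }
  out
}

#' Orientation dispersion index from Watson concentration
#'
#' ODI = (2/pi) * arctan(1/kappa), mapping kappa = 0 (isotropic) to 1 and
#' kappa -> Inf (parallel fibers) to 0.
#'
#' @param kappa Watson concentration, >= 0 (vectorised).
#' @return ODI in (0, 1].
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  ifelse(kappa == 0, 1, 2 / pi * atan(1 / kappa))
}

#' Watson concentration from orientation dispersion index
#'
#' Exact inverse of \code{odi_from_kappa}: kappa = 1/tan(pi * odi / 2),
#' capped at 1e6 for ODI near 0.
#'
#' @param odi ODI in (0, 1] (vectorised).
#' @return Watson concentration.
#' @export
kappa_from_odi <- function(odi) {
  if (any(odi <= 0 | odi > 1)) stop("odi must lie in (0, 1]", call. = FALSE)
  k <- ifelse(odi == 1, 0, 1 / tan(pi * odi / 2))
  pmin(k, KAPPA_CAP)
}

#' Watson dispersion factor tau(kappa)
#'
#' The mean squared cosine <(mu' n)^2> of the Watson distribution:
#' tau = 1/(2 sqrt(kappa) F(sqrt(kappa))) - 1/(2 kappa) with F the Dawson
#' function; tau(0) = 1/3 (isotropic) and tau -> 1 as kappa -> Inf. Below
#' kappa = 2e-3 the Taylor expansion
#' tau = 1/3 + 4 kappa/45 + 8 kappa^2/945 is used: the closed form is 0/0 at
#' kappa = 0 and loses ~7 significant digits to cancellation near it.
#'
#' @param kappa Watson concentration, >= 0 (vectorised).
#' @return tau in [1/3, 1).
#' @export
tau_from_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  out <- numeric(length(kappa))
  tiny <- kappa < 2e-3
  kt <- kappa[tiny]
  out[tiny] <- 1 / 3 + 4 * kt / 45 + 8 * kt^2 / 945
  if (any(!tiny)) {
    k <- kappa[!tiny]
    sk <- sqrt(k)
    out[!tiny] <- 1 / (2 * sk * dawson(sk)) - 1 / (2 * k)
  }
  out
}

#' Invert the dispersion factor: kappa from tau
#'
#' Monotone bracketing inverse of \code{tau_from_kappa} with residual
#' tolerance 1e-9 on tau. tau = 1/3 maps to kappa = 0; tau above
#' 1 - 1e-9 is a range error (an FA/MD combination outside model support).
#'
#' @param tau Dispersion factor in [1/3, 1) (vectorised).
#' @return Watson concentration.
#' @export
kappa_from_tau <- function(tau) {
  eps <- 1e-9
  if (any(tau < 1 / 3 - 1e-12 | tau > 1 - eps))
    stop("tau must lie in [1/3, 1 - 1e-9]", call. = FALSE)
  tau_cap <- tau_from_kappa(KAPPA_CAP)
  vapply(tau, function(tt) {
    if (tt <= 1 / 3 + 1e-14) return(0)
    if (tt >= tau_cap) return(KAPPA_CAP)   # parallel-fiber saturation
    uniroot(function(k) tau_from_kappa(k) - tt,
            lower = 0, upper = KAPPA_CAP, tol = 1e-13)$root
  }, numeric(1))
}

#' Watson probability density on the sphere
#'
#' Density proportional to exp(kappa * (mu' n)^2), normalised to integrate to
#' 1 over the whole sphere via the Kummer function M(1/2, 3/2, kappa)
#' (evaluated through the Dawson function).
#'
#' @param n Unit 3-vector (or matrix of row vectors) at which to evaluate.
#' @param mu Unit 3-vector mean orientation.
#' @param kappa Watson concentration, >= 0.
#' @return Density value(s), 1/steradian.
#' @export
watson_density <- function(n, mu, kappa) {
  stopifnot_scalar(kappa, "kappa", lo = 0)
  n <- rbind(n)
  if (abs(sqrt(sum(mu^2)) - 1) > 1e-6) stop("mu must be unit", call. = FALSE)
  nrm <- sqrt(rowSums(n^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("n must be unit", call. = FALSE)
  ct2 <- (n %*% mu)^2
  ## M(1/2, 3/2, k) = integral_0^1 exp(k u^2) du = exp(k) F(sqrt(k))/sqrt(k)
  ## log-normaliser written with exp(k (ct2 - 1)) to avoid overflow
  if (kappa < 1e-8) {
    dens <- rep(1 / (4 * pi), nrow(n))
  } else {
    logM_scaled <- log(dawson(sqrt(kappa)) / sqrt(kappa))  # log(M) - kappa
    dens <- exp(kappa * (ct2 - 1) - logM_scaled) / (4 * pi)
  }
  drop(dens)
}
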