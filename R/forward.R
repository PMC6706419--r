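## Three-compartment NODDI forward signal model:
## S/S0 = (1 - v_iso) * (nu * A_ic + (1 - nu) * A_ec) + v_iso * exp(-b d_iso)
## with a Watson-dispersed stick intra-neurite compartment, a dispersion-
## averaged axially symmetric extra-neurite tensor with tortuosity coupling
## d_perp = d_par (1 - nu), and free isotropic CSF.

#' Ground-truth tissue parameters of one voxel/parcel
#'
#' @param nu Intra-neurite (neurite density) fraction in [0, 1].
#' @param odi Orientation dispersion index in (0, 1]; give either \code{odi}
#'   or \code{kappa}.
#' @param kappa Watson concentration, >= 0.
#' @param v_iso CSF (isotropic) volume fraction in [0, 1].
#' @param mu Unit 3-vector mean neurite orientation.
#' @param d_par Intrinsic parallel diffusivity, mm2/s. The default 1.1e-3 is
#'   the value optimised for cortical gray matter.
#' @param d_iso Free-water diffusivity, mm2/s (standard 3.0e-3).
#' @return An object of class \code{tissue_params}.
#' @export
tissue_params <- function(nu, odi = NULL, kappa = NULL, v_iso = 0,
                          mu = c(0, 0, 1), d_par = 1.1e-3, d_iso = 3.0e-3) {
  stopifnot_scalar(nu, "nu", 0, 1)
  stopifnot_scalar(v_iso, "v_iso", 0, 1)
  if (is.null(kappa)) {
    if (is.null(odi)) stop("give odi or kappa", call. = FALSE)
    kappa <- kappa_from_odi(odi)
  } else if (!is.null(odi)) stop("give only one of odi, kappa", call. = FALSE)
  stopifnot_scalar(kappa, "kappa", lo = 0)
  if (d_par <= 0 || d_iso <= 0) stop("diffusivities must be > 0", call. = FALSE)
  mu <- as.numeric(mu)
  if (abs(sqrt(sum(mu^2)) - 1) > 1e-6) stop("mu must be unit", call. = FALSE)
  structure(list(nu = nu, kappa = kappa, odi = odi_from_kappa(kappa),
                 v_iso = v_iso, mu = mu / sqrt(sum(mu^2)),
                 d_par = d_par, d_iso = d_iso),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "Tissue: nu=%.3f odi=%.3f (kappa=%.3g) v_iso=%.3f d_par=%.3g d_iso=%.3g\n",
    x$nu, x$odi, x$kappa, x$v_iso, x$d_par, x$d_iso))
  invisible(x)
}

## Product quadrature grid on the unit sphere, exploiting the antipodal
## symmetry of all integrands: Gauss-Legendre in u = cos(theta) on [0, 1]
## (doubled) x midpoint rule in phi (spectrally accurate for periodic
## integrands). Cached per (n_u, n_phi).
.grid_cache <- new.env(parent = emptyenv())
sphere_grid <- function(n_u = 64L, n_phi = 48L) {
  key <- paste(n_u, n_phi)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  gl <- pracma::gaussLegendre(n_u, 0, 1)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  u <- rep(gl$x, each = n_phi)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi) * 2  # x2: both hemispheres
  ph <- rep(phi, n_u)
  s <- sqrt(pmax(0, 1 - u^2))
  pts <- cbind(s * cos(ph), s * sin(ph), u)
  g <- list(pts = pts, w = w, u = u)
  .grid_cache[[key]] <- g
  g
}

## Rotation taking e_z to unit vector mu.
rotation_to <- function(mu) {
  z <- c(0, 0, 1)
  c_ <- sum(z * mu)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * mu[3] - z[3] * mu[2],
         z[3] * mu[1] - z[1] * mu[3],
         z[1] * mu[2] - z[2] * mu[1])
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

## Watson quadrature weights in the frame with mu = e_z, normalised so the
## density integrates to exactly 1 on the grid. Errors if the grid is too
## coarse to normalise the analytic density to 1e-4.
watson_weights <- function(kappa, grid) {
  wraw <- grid$w * exp(kappa * (grid$u^2 - 1))
  tot <- sum(wraw)
  ## analytic scaled integral: 4 pi exp(-kappa) M(1/2,3/2,kappa)
  ana <- if (kappa < 1e-8) 4 * pi else
    4 * pi * dawson(sqrt(kappa)) / sqrt(kappa)
  if (abs(tot / ana - 1) > 1e-4)
    stop("spherical quadrature grid too coarse for kappa = ", kappa,
         " (normalisation check failed at 1e-4)", call. = FALSE)
  wraw / tot
}

#' Intra-neurite (Watson-dispersed stick) attenuation
#'
#' Per-volume attenuation \eqn{\int W(n; \mu, \kappa) e^{-b d_{par} (g'n)^2} dn}
#' evaluated by fixed spherical product quadrature. For kappa >= 1e4 the
#' Watson density is effectively a delta and the stick closed form
#' \eqn{e^{-b d_{par} (g'\mu)^2}} is used.
#'
#' @param scheme A \code{gradient_scheme}.
#' @param mu Unit mean orientation.
#' @param kappa Watson concentration.
#' @param d_par Parallel diffusivity, mm2/s.
#' @param grid Optional quadrature grid from \code{sphere_grid()}.
#' @return Per-volume attenuation in (0, 1].
#' @export
intra_neurite_attenuation <- function(scheme, mu, kappa, d_par = 1.1e-3,
                                      grid = sphere_grid()) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (kappa >= 1e4) {
    ct2 <- drop(scheme$bvecs %*% mu)^2
    return(exp(-scheme$bvals * d_par * ct2))
  }
  wW <- watson_weights(kappa, grid)
  n_world <- grid$pts %*% t(rotation_to(mu))
  ct2 <- (scheme$bvecs %*% t(n_world))^2          # V x N
  drop(exp(-scheme$bvals * d_par * ct2) %*% wW)
}

#' Extra-neurite (hindered tensor) attenuation
#'
#' Gaussian attenuation of the dispersion-averaged axially symmetric tensor
#' with tortuosity coupling d_perp = d_par (1 - nu): axial diffusivity
#' d_perp + (d_par - d_perp) tau and radial d_perp + (d_par - d_perp)(1 - tau)/2,
#' where tau = tau_from_kappa(kappa). The tensor trace is
#' d_par (3 - 2 nu) independent of kappa.
#'
#' @inheritParams intra_neurite_attenuation
#' @param nu Intra-neurite fraction (enters through tortuosity).
#' @return Per-volume attenuation in (0, 1].
#' @export
extra_neurite_attenuation <- function(scheme, mu, kappa, nu,
                                      d_par = 1.1e-3) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  tau <- tau_from_kappa(kappa)
  d_perp <- d_par * (1 - nu)
  ad <- d_perp + (d_par - d_perp) * tau
  rd <- d_perp + (d_par - d_perp) * (1 - tau) / 2
  ct2 <- drop(scheme$bvecs %*% mu)^2
  exp(-scheme$bvals * (rd + (ad - rd) * ct2))
}

#' Forward NODDI signal
#'
#' Noiseless per-volume signal attenuations S/S0 of the three-compartment
#' model; equals 1 at every b = 0 volume.
#'
#' @param scheme A \code{gradient_scheme}.
#' @param params A \code{tissue_params}.
#' @param s0 Non-diffusion-weighted amplitude (arbitrary units).
#' @param grid Optional quadrature grid.
#' @return An object of class \code{signal_set}: list with \code{scheme},
#'   \code{s0} and \code{attenuation}.
#' @export
forward_signal <- function(scheme, params, s0 = 1, grid = sphere_grid()) {
  stopifnot(inherits(params, "tissue_params"))
  aic <- intra_neurite_attenuation(scheme, params$mu, params$kappa,
                                   params$d_par, grid)
  aec <- extra_neurite_attenuation(scheme, params$mu, params$kappa,
                                   params$nu, params$d_par)
  aiso <- exp(-scheme$bvals * params$d_iso)
  att <- (1 - params$v_iso) * (params$nu * aic + (1 - params$nu) * aec) +
    params$v_iso * aiso
  structure(list(scheme = scheme, s0 = s0, attenuation = att),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("Signal set on scheme '%s': %d volumes, s0 = %g\n",
              x$scheme$name, length(x$attenuation), x$s0))
  invisible(x)
}

#' Add Rician noise to a signal set
#'
#' Each signal value x (on the S scale) is replaced by
#' sqrt((x + e1)^2 + e2^2) with e1, e2 independent zero-mean Gaussians of
#' standard deviation S0/snr; deterministic given \code{seed}.
#'
#' @param signal A \code{signal_set}.
#' @param snr S0-relative signal-to-noise ratio, > 0.
#' @param seed Integer seed.
#' @return A \code{signal_set} with noisy attenuations.
#' @export
add_rician_noise <- function(signal, snr, seed = NULL) {
  stopifnot(inherits(signal, "signal_set"))
  stopifnot_scalar(snr, "snr", lo = 1e-12)
  s <- signal$attenuation * signal$s0
  sigma <- signal$s0 / snr
  noisy <- with_seed(seed, {
    e1 <- rnorm(length(s), 0, sigma)
    e2 <- rnorm(length(s), 0, sigma)
    sqrt((s + e1)^2 + e2^2)
  })
  signal$attenuation <- noisy / signal$s0
  signal
}
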