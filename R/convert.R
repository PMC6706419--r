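## Analytic DTI -> NODDI conversion under the zero-CSF assumption.
##
## With no CSF compartment, the composite (neurite + hindered) mean tensor
## obeys 3 MD / d_par = 1 + 2 (1 - nu)^2, which inverts to
## nu = 1 - sqrt((3 MD/d_par - 1)/2). The anisotropy then identifies the
## dispersion factor through the axially symmetric eigenvalue gap
## Delta = l1 - l23 = FA * sqrt(3 MD^2 / (1 - (2/3) FA^2)) and
## tau = (1/3) (1 + 2 Delta / (d_par nu (2 - nu))), from which kappa and ODI
## follow. The chain is exact for noiseless zero-CSF Gaussian signals; with
## CSF contamination it is biased - that bias is the object of study.

TAU_CEIL_EPS <- 1e-9

#' Neurite density from mean diffusivity
#'
#' nu = 1 - sqrt((3 MD/d_par - 1)/2), exact for d_par/3 <= MD <= d_par.
#' Out-of-domain MD (possible with CSF contamination at low b) is clamped:
#' MD > d_par gives nu = 0 with a \code{"csf_suspect"} flag, MD < d_par/3
#' gives nu = 1 with a \code{"stick_limit"} flag, so that sweep tables stay
#' dense rather than going NaN.
#'
#' @param md Mean diffusivity, mm2/s (vectorised); must be > 0.
#' @param d_par Intrinsic parallel diffusivity, mm2/s.
#' @return Numeric vector of nu with attribute \code{"flags"} (character).
#' @export
ndi_from_md <- function(md, d_par = 1.1e-3) {
  if (d_par <= 0) stop("d_par must be > 0", call. = FALSE)
  if (any(md <= 0)) stop("md must be > 0", call. = FALSE)
  flags <- rep("", length(md))
  x <- 3 * md / d_par
  hi <- x > 3          # MD > d_par
  lo <- x < 1          # MD < d_par/3
  flags[hi] <- "csf_suspect"
  flags[lo] <- "stick_limit"
  xc <- pmin(pmax(x, 1), 3)
  nu <- 1 - sqrt((xc - 1) / 2)
  attr(nu, "flags") <- flags
  nu
}

#' Dispersion factor from FA, MD and neurite density
#'
#' Delta = FA * sqrt(3 MD^2 / (1 - (2/3) FA^2));
#' tau = (1/3) (1 + 2 Delta / (d_par nu (2 - nu))). Values of tau above
#' 1 - 1e-9 are clamped (kappa saturates at the parallel-fiber cap, ODI -> 0)
#' and flagged. nu = 0 leaves dispersion undefined (no neurites).
#'
#' @param fa Fractional anisotropy in [0, sqrt(3/2)).
#' @param md Mean diffusivity, mm2/s.
#' @param nu_hat Neurite density (from \code{ndi_from_md}); must be > 0.
#' @param d_par Parallel diffusivity, mm2/s.
#' @return tau (vectorised) with attribute \code{"flags"}.
#' @export
tau_from_fa_md <- function(fa, md, nu_hat, d_par = 1.1e-3) {
  if (any(fa < 0 | fa >= sqrt(1.5))) stop("fa must lie in [0, sqrt(3/2))",
                                          call. = FALSE)
  if (any(nu_hat <= 0)) stop("dispersion undefined for nu = 0 (no neurites)",
                             call. = FALSE)
  delta <- fa * sqrt(3 * md^2 / (1 - (2 / 3) * fa^2))
  tau <- (1 / 3) * (1 + 2 * delta / (d_par * nu_hat * (2 - nu_hat)))
  flags <- rep("", length(tau))
  over <- tau > 1 - TAU_CEIL_EPS
  flags[over] <- "tau_ceiling"
  tau <- pmin(tau, 1 - TAU_CEIL_EPS)
  attr(tau, "flags") <- flags
  tau
}

#' NODDI estimate container
#'
#' @param nu_hat Estimated neurite density in [0, 1].
#' @param odi_hat Estimated orientation dispersion in (0, 1] (NA when
#'   undefined).
#' @param kappa_hat Watson concentration.
#' @param v_iso_hat Estimated CSF fraction (fixed 0 for DTI conversions).
#' @param mu_hat Orientation estimate or NULL.
#' @param source "ORIG" (NLLS fit) or "DTI" (analytic conversion).
#' @param flags Character vector of domain/convergence flags.
#' @return An object of class \code{noddi_estimate}.
#' @export
noddi_estimate <- function(nu_hat, odi_hat, kappa_hat, v_iso_hat = 0,
                           mu_hat = NULL, source = c("ORIG", "DTI"),
                           flags = character(0)) {
  source <- match.arg(source)
  structure(list(nu_hat = nu_hat, odi_hat = odi_hat, kappa_hat = kappa_hat,
                 v_iso_hat = v_iso_hat, mu_hat = mu_hat, source = source,
                 flags = flags),
            class = "noddi_estimate")
}

#' @export
print.noddi_estimate <- function(x, ...) {
  cat(sprintf("NODDI estimate [%s]: nu = %.4f, odi = %s, v_iso = %.4f\n",
              x$source, x$nu_hat,
              if (is.na(x$odi_hat)) "NA" else sprintf("%.4f", x$odi_hat),
              x$v_iso_hat))
  if (length(x$flags) && any(nzchar(x$flags)))
    cat("  flags:", paste(unique(x$flags[nzchar(x$flags)]), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.noddi_estimate <- function(object, ...) {
  c(nu = object$nu_hat, odi = object$odi_hat, kappa = object$kappa_hat,
    v_iso = object$v_iso_hat)
}

## Vectorised conversion on bare (md, fa) columns; workhorse for experiments.
convert_dti <- function(md, fa, d_par = 1.1e-3) {
  nu <- ndi_from_md(md, d_par)
  flags <- attr(nu, "flags")
  nu <- as.numeric(nu)
  odi <- rep(NA_real_, length(md))
  kap <- rep(NA_real_, length(md))
  ok <- nu > 0
  if (any(ok)) {
    tau <- tau_from_fa_md(fa[ok], md[ok], nu[ok], d_par)
    tflags <- attr(tau, "flags")
    flags[ok] <- ifelse(nzchar(tflags),
                        ifelse(nzchar(flags[ok]),
                               paste(flags[ok], tflags, sep = ";"), tflags),
                        flags[ok])
    kap[ok] <- pmin(kappa_from_tau(as.numeric(tau)), KAPPA_CAP)
    odi[ok] <- odi_from_kappa(kap[ok])
  }
  flags[!ok] <- ifelse(nzchar(flags[!ok]),
                       paste(flags[!ok], "odi_undefined", sep = ";"),
                       "odi_undefined")
  data.frame(nu_hat = nu, odi_hat = odi, kappa_hat = kap,
             v_iso_hat = 0, flags = flags, stringsAsFactors = FALSE)
}

#' Convert a tensor fit into DTI-derived NODDI parameters
#'
#' Chains \code{ndi_from_md} -> \code{tau_from_fa_md} -> \code{kappa_from_tau}
#' -> \code{odi_from_kappa}; v_iso is fixed at 0 (the conversion's defining
#' assumption). Never throws on in-range tensors; out-of-domain values are
#' clamped and flagged.
#'
#' @param tensor A \code{tensor_fit}.
#' @param d_par Parallel diffusivity, mm2/s.
#' @return A \code{noddi_estimate} with \code{source = "DTI"}.
#' @export
convert_tensorfit <- function(tensor, d_par = 1.1e-3) {
  stopifnot(inherits(tensor, "tensor_fit"))
  res <- convert_dti(tensor$md, tensor$fa, d_par)
  fl <- unlist(strsplit(res$flags[1], ";"))
  fl <- fl[nzchar(fl)]
  noddi_estimate(res$nu_hat[1], res$odi_hat[1], res$kappa_hat[1],
                 v_iso_hat = 0, source = "DTI",
                 flags = c(tensor$flags, fl))
}

## Exact composite (dispersed stick + hindered tensor, zero CSF) tensor
## eigenvalues; the Gaussian limit used by round-trip tests and Fig-1 style
## curves. Returns c(axial, radial).
composite_tensor_eigenvalues <- function(nu, kappa, d_par = 1.1e-3) {
  tau <- tau_from_kappa(kappa)
  d_perp <- d_par * (1 - nu)
  l_par <- nu * d_par * tau + (1 - nu) * (d_perp + (d_par - d_perp) * tau)
  l_perp <- nu * d_par * (1 - tau) / 2 +
    (1 - nu) * (d_perp + (d_par - d_perp) * (1 - tau) / 2)
  c(axial = l_par, radial = l_perp)
}
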