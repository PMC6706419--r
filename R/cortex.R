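## Synthetic parcellated-cortex generator: per-parcel ground-truth tissue
## parameters and tSNR values emulating a 360-parcel (180 per hemisphere)
## cortical analysis, so the full parcel-level pipeline (fit -> convert ->
## correlate -> Bland-Altman -> filter) runs without any imaging download.

#' Configuration for the synthetic cortex generator
#'
#' Per-parcel truths are drawn as clipped Gaussians. The gray-matter preset
#' centres nu at 0.25 and ODI at 0.30 (cortical means) with
#' v_iso ~ N(0.09, 0.06^2) clipped to [0, 0.6]; the white-matter preset uses
#' v_iso ~ N(0.21, 0.1^2). A designated "sensory" parcel subset receives
#' elevated nu and ODI to create nontrivial spatial contrast, and a
#' designated low-tSNR subset (default 29 parcels) exercises the
#' tSNR < 17 exclusion arithmetic.
#'
#' @param preset "gray" or "white".
#' @param n_parcels Total parcel count (split over hemispheres L/R).
#' @param nu_mean,nu_sd,odi_mean,odi_sd,viso_mean,viso_sd Distribution
#'   parameters of the truths.
#' @param viso_clip Clipping bounds for v_iso.
#' @param n_sensory Number of elevated-contrast parcels.
#' @param sensory_nu_boost,sensory_odi_boost Additive offsets for those.
#' @param tsnr_mean,tsnr_sd Gaussian tSNR of ordinary parcels (clipped at
#'   the cutoff so only the designated subset falls below it).
#' @param n_low_tsnr Number of parcels drawn below the exclusion cutoff.
#' @param low_tsnr_range Uniform range for the low-tSNR subset.
#' @return A list of class \code{cortex_config}.
#' @export
cortex_config <- function(preset = c("gray", "white"), n_parcels = 360L,
                          nu_mean = 0.25, nu_sd = 0.05,
                          odi_mean = 0.30, odi_sd = 0.07,
                          viso_mean = NULL, viso_sd = NULL,
                          viso_clip = c(0, 0.6),
                          n_sensory = 60L,
                          sensory_nu_boost = 0.08, sensory_odi_boost = 0.10,
                          tsnr_mean = 35, tsnr_sd = 8,
                          n_low_tsnr = 29L, low_tsnr_range = c(10, 16.9)) {
  preset <- match.arg(preset)
  if (is.null(viso_mean)) viso_mean <- if (preset == "gray") 0.09 else 0.21
  if (is.null(viso_sd)) viso_sd <- if (preset == "gray") 0.06 else 0.10
  if (n_sensory + n_low_tsnr > n_parcels)
    stop("designated subsets exceed parcel count", call. = FALSE)
  structure(list(preset = preset, n_parcels = as.integer(n_parcels),
                 nu_mean = nu_mean, nu_sd = nu_sd,
                 odi_mean = odi_mean, odi_sd = odi_sd,
                 viso_mean = viso_mean, viso_sd = viso_sd,
                 viso_clip = viso_clip, n_sensory = as.integer(n_sensory),
                 sensory_nu_boost = sensory_nu_boost,
                 sensory_odi_boost = sensory_odi_boost,
                 tsnr_mean = tsnr_mean, tsnr_sd = tsnr_sd,
                 n_low_tsnr = as.integer(n_low_tsnr),
                 low_tsnr_range = low_tsnr_range),
            class = "cortex_config")
}

#' Generate a synthetic parcellated cortex
#'
#' Draws per-parcel ground-truth NODDI parameters, orientations and tSNR
#' values according to a \code{cortex_config}; fully deterministic given
#' \code{seed}.
#'
#' @param config A \code{cortex_config}, or a preset name ("gray"/"white").
#' @param seed Integer seed.
#' @return A data.frame of class \code{parcel_table} with columns
#'   \code{parcel_id}, \code{hemisphere}, \code{nu}, \code{odi},
#'   \code{kappa}, \code{v_iso}, \code{mu_x/y/z}, \code{tsnr},
#'   \code{sensory}.
#' @export
generate_cortex <- function(config = "gray", seed = 0L) {
  if (is.character(config)) config <- cortex_config(preset = config)
  stopifnot(inherits(config, "cortex_config"))
  n <- config$n_parcels
  with_seed(seed, {
    nu <- rnorm(n, config$nu_mean, config$nu_sd)
    odi <- rnorm(n, config$odi_mean, config$odi_sd)
    viso <- rnorm(n, config$viso_mean, config$viso_sd)
    sensory <- rep(FALSE, n)
    sensory[sample.int(n, config$n_sensory)] <- TRUE
    nu[sensory] <- nu[sensory] + config$sensory_nu_boost
    odi[sensory] <- odi[sensory] + config$sensory_odi_boost
    nu <- pmin(pmax(nu, 0.05), 0.95)
    odi <- pmin(pmax(odi, 0.02), 0.95)
    viso <- pmin(pmax(viso, config$viso_clip[1]), config$viso_clip[2])
    ## random unit orientations
    mu <- matrix(rnorm(3 * n), n, 3)
    mu <- unit_rows(mu)
    tsnr <- pmax(rnorm(n, config$tsnr_mean, config$tsnr_sd), 17)
    if (config$n_low_tsnr > 0) {
      low <- sample.int(n, config$n_low_tsnr)
      tsnr[low] <- runif(config$n_low_tsnr,
                         config$low_tsnr_range[1], config$low_tsnr_range[2])
    }
    out <- data.frame(
      parcel_id = seq_len(n),
      hemisphere = rep(c("L", "R"), length.out = n),
      nu = nu, odi = odi, kappa = kappa_from_odi(odi), v_iso = viso,
      mu_x = mu[, 1], mu_y = mu[, 2], mu_z = mu[, 3],
      tsnr = tsnr, sensory = sensory)
    class(out) <- c("parcel_table", "data.frame")
    attr(out, "config") <- config
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate diffusion signals for every parcel
#'
#' Runs the NODDI forward model per parcel on one scheme, optionally adding
#' Rician noise. \code{snr = NULL} gives noiseless attenuations;
#' \code{snr = "tsnr"} uses each parcel's assigned tSNR as its
#' signal-to-noise ratio (so the generated b = 0 series is consistent with
#' the bookkeeping tSNR); a numeric value applies one SNR to all parcels.
#'
#' @param table A \code{parcel_table}.
#' @param scheme A \code{gradient_scheme}.
#' @param snr NULL, numeric scalar, or "tsnr".
#' @param seed Integer seed (noise only).
#' @param d_par,d_iso Fixed diffusivities, mm2/s.
#' @param grid Spherical quadrature grid.
#' @return Object of class \code{parcel_signals}: list with \code{scheme},
#'   \code{attenuation} (n_parcel x V matrix) and \code{table}.
#' @export
simulate_parcel_dataset <- function(table, scheme, snr = NULL, seed = 0L,
                                    d_par = 1.1e-3, d_iso = 3.0e-3,
                                    grid = sphere_grid()) {
  stopifnot(inherits(table, "parcel_table"),
            inherits(scheme, "gradient_scheme"))
  n <- nrow(table)
  A <- matrix(NA_real_, n, length(scheme$bvals))
  for (i in seq_len(n)) {
    pars <- tissue_params(nu = table$nu[i], kappa = table$kappa[i],
                          v_iso = table$v_iso[i],
                          mu = c(table$mu_x[i], table$mu_y[i], table$mu_z[i]),
                          d_par = d_par, d_iso = d_iso)
    sig <- forward_signal(scheme, pars, grid = grid)
    if (!is.null(snr)) {
      s <- if (identical(snr, "tsnr")) table$tsnr[i] else snr
      sig <- add_rician_noise(sig, snr = s, seed = seed + i)
    }
    A[i, ] <- sig$attenuation
  }
  structure(list(scheme = scheme, attenuation = A, table = table,
                 snr = snr, seed = seed),
            class = "parcel_signals")
}

#' @export
print.parcel_signals <- function(x, ...) {
  cat(sprintf("Parcel signals: %d parcels x %d volumes (scheme '%s', %s)\n",
              nrow(x$attenuation), ncol(x$attenuation), x$scheme$name,
              if (is.null(x$snr)) "noiseless" else
                paste0("snr = ", paste(x$snr, collapse = ""))))
  invisible(x)
}
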