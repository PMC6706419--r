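## Computational experiments: the theoretical DTI->NODDI curves, the CSF
## volume-fraction sweep across the seven b-shell datasets, and the
## homogeneous-vs-heterogeneous CSF correlation comparison.

#' Theoretical DTI-to-NODDI relationship curves
#'
#' Curve A: neurite density as a function of inverse mean diffusivity over
#' the valid zero-CSF domain MD in [d_par/3, d_par]. Curve B: ODI as a
#' function of MD at each fixed FA. Cells where the (FA, MD) pair leaves the
#' model domain are flagged, not dropped.
#'
#' @param d_par Parallel diffusivity, mm2/s.
#' @param fa_grid FA values for curve B, each in [0, 1).
#' @param n_md Number of MD grid points.
#' @return Object of class \code{fig_curves}: list of data.frames
#'   \code{curve_a} (md, inv_md, ndi) and \code{curve_b}
#'   (fa, md, odi, flags).
#' @export
fig1_curves <- function(d_par = 1.1e-3, fa_grid = seq(0.1, 0.6, by = 0.1),
                        n_md = 101L) {
  if (any(fa_grid < 0 | fa_grid >= 1)) stop("fa_grid must lie in [0, 1)",
                                            call. = FALSE)
  md <- seq(d_par / 3, d_par, length.out = n_md)
  nu <- as.numeric(ndi_from_md(md, d_par))
  curve_a <- data.frame(md = md, inv_md = 1 / md, ndi = nu)
  rows <- list()
  for (fa in fa_grid) {
    conv <- convert_dti(rep(md, 1), rep(fa, length(md)), d_par)
    rows[[length(rows) + 1L]] <- data.frame(
      fa = fa, md = md, odi = conv$odi_hat, flags = conv$flags,
      stringsAsFactors = FALSE)
  }
  structure(list(curve_a = curve_a, curve_b = do.call(rbind, rows),
                 d_par = d_par),
            class = "fig_curves")
}

#' @export
plot.fig_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$curve_a$inv_md, x$curve_a$ndi, type = "l",
                 xlab = "1/MD (s/mm2)", ylab = "NDI",
                 main = "NDI vs 1/MD (zero CSF)")
  fas <- unique(x$curve_b$fa)
  cols <- grDevices::hcl.colors(length(fas), "viridis")
  graphics::plot(NA, xlim = range(x$curve_b$md),
                 ylim = c(0, 1), xlab = "MD (mm2/s)", ylab = "ODI",
                 main = "ODI vs MD by FA")
  for (i in seq_along(fas)) {
    sub <- x$curve_b[x$curve_b$fa == fas[i] & !nzchar(x$curve_b$flags), ]
    graphics::lines(sub$md, sub$odi, col = cols[i])
  }
  graphics::legend("topright", legend = sprintf("FA=%.1f", fas),
                   col = cols, lty = 1, cex = 0.7)
  invisible(x)
}

## DTI metrics + conversion for one attenuation vector on one scheme subset.
dti_and_convert <- function(full_scheme, attenuation, label, d_par) {
  sub <- subset_scheme(full_scheme, label)
  idx <- attr(sub, "volume_index")
  tf <- fit_tensor(sub, attenuation[idx])
  est <- convert_tensorfit(tf, d_par)
  list(md = tf$md, fa = tf$fa, est = est)
}

#' CSF volume-fraction sweep across b-shell datasets
#'
#' Holds the tissue at a reference condition (defaults: nu = 0.25,
#' ODI = 0.30, v_iso = 0.1, the cortical mean) and sweeps the CSF volume
#' fraction over \code{levels}, generating noiseless signals at each level.
#' DTI metrics and the DTI-derived NODDI conversion are computed on every
#' scheme in \code{schemes}; original-NODDI NLLS estimates are computed on
#' the schemes in \code{noddi_schemes} (default the three-shell set only).
#' Percent error is 100 (x - x_ref)/x_ref against the same scheme/metric at
#' the reference level.
#'
#' @param reference A \code{tissue_params} giving the reference condition;
#'   its \code{v_iso} must be one of \code{levels}.
#' @param levels CSF volume fractions to simulate.
#' @param schemes Character vector of b-shell dataset labels.
#' @param seed Integer seed for direction generation.
#' @param noddi_schemes Labels on which to run the NODDI NLLS fit.
#' @param full_scheme Optional prebuilt three-shell scheme.
#' @param grid Spherical quadrature grid.
#' @return Data.frame of class \code{csf_sweep} with columns \code{scheme},
#'   \code{v_iso}, \code{metric} (NDI_ORIG, ODI_ORIG, MD, FA, NDI_DTI,
#'   ODI_DTI), \code{value}, \code{pct_error}, \code{flags}.
#' @export
csf_sweep <- function(reference = tissue_params(nu = 0.25, odi = 0.30,
                                                v_iso = 0.1),
                      levels = seq(0, 0.6, by = 0.1),
                      schemes = scheme_labels(), seed = 0L,
                      noddi_schemes = "b_All", full_scheme = NULL,
                      grid = sphere_grid()) {
  stopifnot(inherits(reference, "tissue_params"))
  if (!any(abs(levels - reference$v_iso) < 1e-12))
    stop("levels must include the reference v_iso", call. = FALSE)
  if (is.null(full_scheme)) full_scheme <- build_hcp_like_scheme(seed = seed)
  rows <- list()
  for (v in levels) {
    pars <- tissue_params(nu = reference$nu, kappa = reference$kappa,
                          v_iso = v, mu = reference$mu,
                          d_par = reference$d_par, d_iso = reference$d_iso)
    att <- forward_signal(full_scheme, pars, grid = grid)$attenuation
    for (lab in schemes) {
      r <- dti_and_convert(full_scheme, att, lab, reference$d_par)
      fl <- paste(r$est$flags, collapse = ";")
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = lab, v_iso = v,
        metric = c("MD", "FA", "NDI_DTI", "ODI_DTI"),
        value = c(r$md, r$fa, r$est$nu_hat, r$est$odi_hat),
        flags = fl, stringsAsFactors = FALSE)
    }
    for (lab in noddi_schemes) {
      sub <- subset_scheme(full_scheme, lab)
      idx <- attr(sub, "volume_index")
      sig <- structure(list(scheme = sub, s0 = 1, attenuation = att[idx]),
                       class = "signal_set")
      nf <- fit_noddi(sub, sig, d_par = reference$d_par,
                      d_iso = reference$d_iso, grid = grid)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = lab, v_iso = v,
        metric = c("NDI_ORIG", "ODI_ORIG"),
        value = c(nf$nu_hat, nf$odi_hat),
        flags = paste(nf$flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ## percent error against same scheme/metric at the reference level
  ref_rows <- out[abs(out$v_iso - reference$v_iso) < 1e-12, ]
  key <- paste(out$scheme, out$metric)
  ref_key <- paste(ref_rows$scheme, ref_rows$metric)
  ref_val <- ref_rows$value[match(key, ref_key)]
  out$pct_error <- 100 * (out$value - ref_val) / ref_val
  class(out) <- c("csf_sweep", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' @export
plot.csf_sweep <- function(x, metrics = c("NDI_DTI", "ODI_DTI", "MD", "FA"),
                           ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ref <- attr(x, "reference")
  for (m in metrics) {
    sub <- x[x$metric == m, ]
    if (!nrow(sub)) next
    schemes <- unique(sub$scheme)
    cols <- grDevices::hcl.colors(length(schemes), "Dark 3")
    graphics::plot(NA, xlim = range(sub$v_iso - ref$v_iso),
                   ylim = range(sub$pct_error, na.rm = TRUE),
                   xlab = "delta V_iso", ylab = paste0("% error ", m),
                   main = m)
    for (i in seq_along(schemes)) {
      s <- sub[sub$scheme == schemes[i], ]
      graphics::lines(s$v_iso - ref$v_iso, s$pct_error, col = cols[i])
    }
    graphics::legend("topleft", legend = schemes, col = cols, lty = 1,
                     cex = 0.5)
  }
  invisible(x)
}

#' Homogeneous vs heterogeneous CSF correlation experiment
#'
#' Generates parcel truths with heterogeneous nu and ODI but CSF volume
#' fraction drawn as N(\code{v_iso}, \code{v_iso_sd}^2) (sd 0 = strictly
#' homogeneous), simulates noiseless signals, estimates original NODDI on
#' the three-shell set and DTI-derived NODDI on every scheme, and reports
#' the cross-parcel Pearson correlation of each DTI-derived parameter with
#' its original-NODDI counterpart.
#'
#' @param v_iso Mean CSF volume fraction.
#' @param v_iso_sd Across-parcel standard deviation of v_iso.
#' @param n_parcels Number of parcels.
#' @param schemes b-shell dataset labels for the DTI side.
#' @param seed Integer seed.
#' @param parcel_truths Optional \code{parcel_table} overriding generation.
#' @param full_scheme Optional prebuilt three-shell scheme.
#' @param grid Spherical quadrature grid.
#' @return Data.frame of class \code{csf_correlations} with columns
#'   \code{scheme}, \code{metric} (NDI, ODI), \code{r}, \code{n}, \code{p},
#'   \code{flags}; parcel-level values attached as attribute
#'   \code{"parcel_metrics"}.
#' @export
homogeneous_csf_experiment <- function(v_iso = 0.05, v_iso_sd = 0,
                                       n_parcels = 100L,
                                       schemes = scheme_labels(), seed = 0L,
                                       parcel_truths = NULL,
                                       full_scheme = NULL,
                                       grid = sphere_grid()) {
  if (is.null(full_scheme)) full_scheme <- build_hcp_like_scheme(seed = seed)
  if (is.null(parcel_truths)) {
    cfg <- cortex_config(preset = "gray", n_parcels = n_parcels,
                         viso_mean = v_iso, viso_sd = v_iso_sd,
                         n_low_tsnr = 0L,
                         n_sensory = max(1L, round(n_parcels / 6)))
    parcel_truths <- generate_cortex(cfg, seed = seed)
  }
  sig <- simulate_parcel_dataset(parcel_truths, full_scheme, snr = NULL,
                                 grid = grid)
  n <- nrow(parcel_truths)

  ## original NODDI on the three-shell set (gold standard)
  sub_all <- subset_scheme(full_scheme, "b_All")
  ndi_orig <- odi_orig <- numeric(n)
  for (i in seq_len(n)) {
    s <- structure(list(scheme = sub_all, s0 = 1,
                        attenuation = sig$attenuation[i, ]),
                   class = "signal_set")
    nf <- fit_noddi(sub_all, s, grid = grid)
    ndi_orig[i] <- nf$nu_hat
    odi_orig[i] <- nf$odi_hat
  }

  parcel_metrics <- data.frame(parcel_id = parcel_truths$parcel_id,
                               ndi_orig = ndi_orig, odi_orig = odi_orig)
  rows <- list()
  for (lab in schemes) {
    sub <- subset_scheme(full_scheme, lab)
    idx <- attr(sub, "volume_index")
    tf <- fit_tensor_many(sub, sig$attenuation[, idx, drop = FALSE])
    conv <- convert_dti(tf$md, tf$fa)
    parcel_metrics[[paste0("ndi_dti_", lab)]] <- conv$nu_hat
    parcel_metrics[[paste0("odi_dti_", lab)]] <- conv$odi_hat
    for (metric in c("NDI", "ODI")) {
      x <- if (metric == "NDI") conv$nu_hat else conv$odi_hat
      y <- if (metric == "NDI") ndi_orig else odi_orig
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- pearson(x[ok], y[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = lab, metric = metric, r = ct$r, n = ct$n, p = ct$p,
          flags = "", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          scheme = lab, metric = metric, r = NA_real_, n = sum(ok),
          p = NA_real_, flags = "undefined_correlation",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("csf_correlations", "data.frame")
  attr(out, "parcel_metrics") <- parcel_metrics
  attr(out, "truths") <- parcel_truths
  out
}
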