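## Agreement and screening statistics: Pearson correlation, Bland-Altman
## analysis, temporal SNR and the parcel-exclusion filter.

#' Pearson correlation with p-value
#'
#' Product-moment correlation; the p-value comes from the standard t
#' transform (two-sided, via \code{stats::cor.test}). Zero variance in
#' either series leaves the coefficient undefined and flagged.
#'
#' @param x,y Equal-length numeric series (n >= 3, finite).
#' @return An object of class \code{correlation_result}: list with \code{r},
#'   \code{n}, \code{p}, \code{flags}.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(r = NA_real_, n = length(x), p = NA_real_,
                flags = "zero_variance")
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    out <- list(r = unname(ct$estimate), n = length(x), p = ct$p.value,
                flags = character(0))
  }
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (length(x$flags) && "zero_variance" %in% x$flags) {
    cat("Pearson correlation undefined (zero variance), n =", x$n, "\n")
  } else {
    cat(sprintf("Pearson R = %.4f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  }
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are computed as test - reference; limits of agreement are
#' bias +/- 1.96 times the sample (n - 1) standard deviation of the
#' differences.
#'
#' @param reference,test Equal-length numeric series (n >= 2).
#' @return An object of class \code{bland_altman}: list with \code{bias},
#'   \code{sd}, \code{loa_low}, \code{loa_high} and \code{pairs}
#'   (data.frame of means and differences).
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test)) stop("series lengths differ",
                                              call. = FALSE)
  if (length(reference) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- test - reference
  m <- (test + reference) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 pairs = data.frame(mean = m, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, sd = %.4g, LoA = [%.4g, %.4g], n = %d\n",
              x$bias, x$sd, x$loa_low, x$loa_high, nrow(x$pairs)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$difference,
                 xlab = "mean of pair", ylab = "difference (test - reference)",
                 ...)
  graphics::abline(h = x$bias, col = "red")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "blue", lty = 2)
  invisible(x)
}

#' Temporal signal-to-noise ratio
#'
#' Mean over sample standard deviation of repeated b = 0 measurements.
#' A constant series has undefined (infinite) tSNR and is flagged.
#'
#' @param b0_series Numeric vector of repeated b = 0 values (n >= 2).
#' @return Scalar tSNR (Inf for a constant series, with attribute
#'   \code{"flags" = "zero_sd"}).
#' @export
tsnr <- function(b0_series) {
  if (length(b0_series) < 2) stop("need at least 2 b = 0 values",
                                  call. = FALSE)
  s <- stats::sd(b0_series)
  if (s == 0) {
    out <- Inf
    attr(out, "flags") <- "zero_sd"
    return(out)
  }
  mean(b0_series) / s
}

#' Filter parcels by tSNR cutoff
#'
#' Removes rows with tSNR strictly below the cutoff (ties at the cutoff are
#' kept). The retained count is recorded as attribute \code{"n_retained"}.
#'
#' @param table A data.frame with a \code{tsnr} column (e.g. a parcel table).
#' @param cutoff tSNR exclusion threshold (default 17).
#' @return The filtered table.
#' @export
filter_parcels <- function(table, cutoff = 17) {
  if (!"tsnr" %in% names(table)) stop("table lacks a 'tsnr' column",
                                      call. = FALSE)
  keep <- table$tsnr >= cutoff
  out <- table[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}
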