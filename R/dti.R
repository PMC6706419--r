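## Linear diffusion-tensor fitting (OLS on log signal) and MD/FA extraction.
## The same linear model is deliberately applicable to high-b and multi-shell
## data ("forced" fitting), which is where its biases become informative.

## Design matrix rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz,
## -2b gygz]; b = 0 volumes contribute pure intercept rows so log S0 is
## estimated jointly.
dti_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(3/2) * sqrt(sum((l_i - lbar)^2)) / sqrt(sum(l_i^2)), clamped to
#' [0, 1]; 0 when all eigenvalues are 0. Negative eigenvalues are permitted
#' (they occur in forced fits of non-Gaussian signals).
#'
#' @param l1,l2,l3 Tensor eigenvalues, mm2/s (vectorised).
#' @return FA in [0, 1].
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- ifelse(den == 0, 0, sqrt(1.5 * num / den))
  pmin(pmax(fa, 0), 1)
}

## Core multi-voxel OLS fit: A is an n_voxel x V attenuation matrix.
## Returns a data.frame of tensor metrics, one row per voxel.
fit_tensor_core <- function(scheme, A, floor_eps = 1e-10) {
  V <- length(scheme$bvals)
  if (ncol(A) != V) stop("signal length does not match scheme", call. = FALSE)
  dw <- scheme$bvals > 0
  if (sum(!dw) < 1) stop("need at least one b = 0 volume", call. = FALSE)
  dirs <- unique(round(scheme$bvecs[dw, , drop = FALSE], 6))
  if (nrow(dirs) < 6) stop("need >= 6 distinct diffusion directions",
                           call. = FALSE)
  if (any(A <= 0)) {
    warning("non-positive signals floored at ", floor_eps)
    A[A <= 0] <- floor_eps
  }
  X <- dti_design(scheme)
  qx <- qr(X)
  if (qx$rank < 7) stop("rank-deficient tensor design", call. = FALSE)
  beta <- qr.coef(qx, t(log(A)))               # 7 x n_voxel
  out <- data.frame(md = numeric(ncol(beta)), fa = NA_real_,
                    l1 = NA_real_, l2 = NA_real_, l3 = NA_real_,
                    log_s0 = beta[1, ], neg_eig = FALSE)
  for (i in seq_len(ncol(beta))) {
    cf <- beta[, i]
    D <- matrix(c(cf[2], cf[5], cf[6],
                  cf[5], cf[3], cf[7],
                  cf[6], cf[7], cf[4]), 3, 3)
    ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    out$l1[i] <- ev[1]; out$l2[i] <- ev[2]; out$l3[i] <- ev[3]
    out$md[i] <- mean(ev)
    out$fa[i] <- fa_from_eigenvalues(ev[1], ev[2], ev[3])
    out$neg_eig[i] <- ev[3] < 0
  }
  attr(out, "beta") <- beta
  out
}

#' Fit the diffusion tensor to one signal set
#'
#' Ordinary least squares on the log signal (the default behaviour of
#' standard tensor-fitting tools); eigenvalues sorted descending. Negative
#' eigenvalues are retained for MD/FA computation (only FA itself is clamped
#' to [0, 1]) and flagged.
#'
#' @param scheme A \code{gradient_scheme} with >= 6 distinct diffusion
#'   directions and >= 1 b = 0 volume.
#' @param signal A \code{signal_set} (or bare attenuation vector).
#' @return An object of class \code{tensor_fit} with elements
#'   \code{d_tensor} (3 x 3, mm2/s), \code{eigenvalues} (descending),
#'   \code{md}, \code{fa}, \code{log_s0} and \code{flags}.
#' @export
fit_tensor <- function(scheme, signal) {
  att <- if (inherits(signal, "signal_set")) signal$attenuation
         else as.numeric(signal)
  res <- fit_tensor_core(scheme, matrix(att, nrow = 1))
  cf <- attr(res, "beta")[, 1]
  D <- matrix(c(cf[2], cf[5], cf[6],
                cf[5], cf[3], cf[7],
                cf[6], cf[7], cf[4]), 3, 3)
  flags <- character(0)
  if (res$neg_eig[1]) flags <- c(flags, "negative_eigenvalue")
  structure(list(d_tensor = D,
                 eigenvalues = c(res$l1[1], res$l2[1], res$l3[1]),
                 md = res$md[1], fa = res$fa[1], log_s0 = res$log_s0[1],
                 scheme_name = scheme$name, flags = flags),
            class = "tensor_fit")
}

#' Fit the diffusion tensor to many voxels/parcels at once
#'
#' Vectorised version of \code{fit_tensor} sharing one design-matrix
#' factorisation across rows.
#'
#' @param scheme A \code{gradient_scheme}.
#' @param attenuation n_voxel x V matrix of attenuations.
#' @return A data.frame with columns \code{md}, \code{fa}, \code{l1}-\code{l3},
#'   \code{log_s0}, \code{neg_eig}.
#' @export
fit_tensor_many <- function(scheme, attenuation) {
  out <- fit_tensor_core(scheme, as.matrix(attenuation))
  attr(out, "beta") <- NULL
  out
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit (scheme '%s')\n", x$scheme_name))
  cat(sprintf("  MD = %.4g mm2/s, FA = %.4f\n", x$md, x$fa))
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.4g", x$eigenvalues), collapse = ", ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.tensor_fit <- function(object, ...) {
  c(md = object$md, fa = object$fa,
    l1 = object$eigenvalues[1], l2 = object$eigenvalues[2],
    l3 = object$eigenvalues[3], log_s0 = object$log_s0)
}
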