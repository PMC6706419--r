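## FSL bval/bvec reading and writing.
## Dialect: bvals is a single whitespace-separated row; bvecs has three rows
## (x, y, z), one column per volume.

#' Write a gradient scheme as FSL bval/bvec files
#'
#' Integer b-values are written without decimals so that write/read
#' round-trips are bit-identical.
#'
#' @param scheme A \code{gradient_scheme}.
#' @param bval_path,bvec_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  fmt_b <- ifelse(scheme$bvals == round(scheme$bvals),
                  sprintf("%d", as.integer(round(scheme$bvals))),
                  sprintf("%.10g", scheme$bvals))
  writeLines(paste(fmt_b, collapse = " "), bval_path)
  rows <- apply(scheme$bvecs, 2, function(col)
    paste(sprintf("%.17g", col), collapse = " "))
  writeLines(rows, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL bval/bvec files into a gradient scheme
#'
#' b-values are snapped to inferred shell values: volumes within
#' \code{shell_tol} s/mm2 of each other form one shell and are assigned the
#' rounded shell mean (values below \code{shell_tol} become b = 0). Direction
#' columns whose norm deviates from 1 by more than 1e-6 are renormalised with
#' a warning; a zero direction on a b > 0 volume is an error.
#'
#' @param bval_path,bvec_path Input file paths.
#' @param shell_tol Shell grouping tolerance, s/mm2.
#' @param name Label for the returned scheme.
#' @return A \code{gradient_scheme}.
#' @export
read_bval_bvec <- function(bval_path, bvec_path, shell_tol = 50,
                           name = "custom") {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path,
                                    call. = FALSE)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path,
                                    call. = FALSE)
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L) stop("bvec file must have exactly 3 rows",
                               call. = FALSE)
  mat <- lapply(rows, function(r) scan(text = r, quiet = TRUE))
  if (length(unique(vapply(mat, length, 1L))) != 1L ||
      length(mat[[1]]) != length(bvals))
    stop("bval/bvec column counts do not match", call. = FALSE)
  bvecs <- t(do.call(rbind, mat))

  ## snap b-values to shells
  b <- bvals
  b[b < shell_tol] <- 0
  nz <- sort(unique(b[b > 0]))
  if (length(nz)) {
    groups <- list()
    for (v in nz) {
      placed <- FALSE
      for (j in seq_along(groups)) {
        if (abs(v - mean(groups[[j]])) <= shell_tol) {
          groups[[j]] <- c(groups[[j]], v); placed <- TRUE; break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- v
    }
    for (g in groups) {
      shell <- round(mean(g))
      b[b %in% g] <- shell
    }
  }

  b0 <- b == 0
  bvecs[b0, ] <- 0
  if (any(!b0)) {
    nrm <- sqrt(rowSums(bvecs[!b0, , drop = FALSE]^2))
    if (any(nrm < 1e-6))
      stop("zero gradient direction on a b > 0 volume", call. = FALSE)
    if (any(abs(nrm - 1) > 1e-6))
      warning("renormalising gradient directions with non-unit norm")
    ## renormalise only when needed so exact files round-trip bit-identically
    sel <- which(!b0)[abs(nrm - 1) > 1e-12]
    if (length(sel))
      bvecs[sel, ] <- bvecs[sel, , drop = FALSE] /
        sqrt(rowSums(bvecs[sel, , drop = FALSE]^2))
  }
  gradient_scheme(b, bvecs, name = name)
}
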