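## Multi-shell acquisition schemes and the seven named b-shell datasets.

#' Named b-shell dataset labels
#'
#' The seven b-shell dataset labels used throughout the package: three
#' one-shell, three two-shell and the full three-shell ("b_All") subsets of an
#' HCP-style b = 1000/2000/3000 s/mm2 acquisition.
#'
#' @return Character vector of the seven labels.
#' @export
scheme_labels <- function() {
  c("b_1000", "b_2000", "b_3000",
    "b_1000-2000", "b_1000-3000", "b_2000-3000", "b_All")
}

#' Construct a gradient scheme
#'
#' A gradient scheme holds, per volume, a b-value (s/mm2) and a unit gradient
#' direction; b = 0 volumes carry the placeholder direction (0, 0, 0).
#' Diffusivities throughout the package are in mm2/s so that b * d is
#' dimensionless.
#'
#' @param bvals Numeric vector of b-values, s/mm2.
#' @param bvecs Numeric matrix, one row per volume, 3 columns (x, y, z).
#' @param name Text label for the scheme.
#' @return An object of class \code{gradient_scheme}: a list with elements
#'   \code{name}, \code{bvals}, \code{bvecs} (V x 3), \code{shells} (sorted
#'   nonzero b-values) and \code{shell_index} (list mapping shell value to
#'   volume indices).
#' @export
gradient_scheme <- function(bvals, bvecs, name = "custom") {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3L)
    stop("bvecs must be a length(bvals) x 3 matrix", call. = FALSE)
  if (any(bvals < 0)) stop("negative b-values", call. = FALSE)
  b0 <- bvals == 0
  if (any(b0)) {
    if (any(abs(bvecs[b0, , drop = FALSE]) > 1e-12))
      stop("b = 0 volumes must carry the zero placeholder direction",
           call. = FALSE)
  }
  if (any(!b0)) {
    nrm <- sqrt(rowSums(bvecs[!b0, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("diffusion-weighted directions must be unit vectors (1e-9)",
           call. = FALSE)
  }
  shells <- sort(unique(bvals[!b0]))
  shell_index <- lapply(shells, function(b) which(bvals == b))
  names(shell_index) <- as.character(shells)
  structure(list(name = name, bvals = bvals, bvecs = bvecs,
                 shells = shells, shell_index = shell_index),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Gradient scheme '%s': %d volumes (%d b=0)\n",
              x$name, length(x$bvals), sum(x$bvals == 0)))
  for (b in x$shells)
    cat(sprintf("  b = %g s/mm2: %d directions\n", b,
                length(x$shell_index[[as.character(b)]])))
  invisible(x)
}

#' Near-uniform unit directions on the sphere
#'
#' Generates \code{n} unit 3-vectors approximately uniform on the hemisphere
#' (antipodal symmetry is assumed for diffusion encoding) using a spherical
#' Fibonacci lattice, then applies a seed-determined random rotation so that
#' independently generated shells do not share directions.
#'
#' @param n Number of directions; at least 6 (a diffusion tensor fit is
#'   under-determined below 6 distinct directions).
#' @param seed Integer seed controlling the rotation; deterministic output.
#' @return An \code{n} x 3 matrix of unit row vectors.
#' @export
generate_directions <- function(n, seed = 0L) {
  stopifnot_scalar(n, "n", lo = 1)
  if (n < 6) stop("need at least 6 directions for a tensor fit", call. = FALSE)
  i <- seq_len(n) - 0.5
  z <- i / n                      # hemisphere z in (0, 1)
  golden <- (sqrt(5) - 1) / 2
  phi <- 2 * pi * (seq_len(n) - 1) * golden
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  rot <- with_seed(seed, random_rotation())
  unit_rows(pts %*% t(rot))
}

#' Build an HCP-like multi-shell scheme
#'
#' Defaults mirror the HCP dMRI protocol: 18 b = 0 volumes plus 90 directions
#' at each of b = 1000, 2000, 3000 s/mm2 (288 volumes in total), labelled
#' \code{b_All}. The b = 0 volumes come first, then shells in order.
#'
#' @param n_b0 Number of b = 0 volumes.
#' @param n_per_shell Directions per shell.
#' @param shells Nonzero shell b-values, s/mm2.
#' @param seed Integer seed; each shell gets an independently rotated lattice.
#' @return A \code{gradient_scheme}.
#' @export
build_hcp_like_scheme <- function(n_b0 = 18L, n_per_shell = 90L,
                                  shells = c(1000, 2000, 3000), seed = 0L) {
  if (length(shells) == 0 || any(shells <= 0))
    stop("shells must be non-empty and positive", call. = FALSE)
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, n_b0, 3)
  for (k in seq_along(shells)) {
    dirs <- generate_directions(n_per_shell, seed = seed + k)
    bvals <- c(bvals, rep(shells[k], n_per_shell))
    bvecs <- rbind(bvecs, dirs)
  }
  gradient_scheme(bvals, bvecs, name = "b_All")
}

## Parse a Table-1 style label into its shell b-values.
parse_scheme_label <- function(dataset_name, available) {
  if (identical(dataset_name, "b_All")) return(available)
  if (!grepl("^b_[0-9]+(-[0-9]+)*$", dataset_name))
    stop(sprintf("unknown b-shell dataset label '%s'", dataset_name),
         call. = FALSE)
  as.numeric(strsplit(sub("^b_", "", dataset_name), "-")[[1]])
}

#' Subset a scheme to a named b-shell dataset
#'
#' Returns the b = 0 volumes plus exactly the shells named by the label,
#' preserving the original volume order (e.g. \code{"b_1000-3000"} keeps
#' b in {0, 1000, 3000}).
#'
#' @param full A \code{gradient_scheme} containing all requested shells.
#' @param dataset_name One of \code{scheme_labels()} or a custom
#'   \code{"b_<v1>-<v2>..."} label.
#' @return A \code{gradient_scheme}; attribute \code{"volume_index"} records
#'   the retained volume indices in \code{full}.
#' @export
subset_scheme <- function(full, dataset_name) {
  stopifnot(inherits(full, "gradient_scheme"))
  want <- parse_scheme_label(dataset_name, full$shells)
  missing <- setdiff(want, full$shells)
  if (length(missing))
    stop(sprintf("scheme '%s' lacks shell(s): %s", full$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  keep <- which(full$bvals == 0 | full$bvals %in% want)
  out <- gradient_scheme(full$bvals[keep], full$bvecs[keep, , drop = FALSE],
                         name = dataset_name)
  attr(out, "volume_index") <- keep
  out
}
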