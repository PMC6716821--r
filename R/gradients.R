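#' Diffusion gradient schemes
#'
#' The acquisition protocol this pipeline targets uses 30 diffusion
#' directions at b = 1000 s/mm^2 plus 5 unweighted b = 0 volumes. The
#' scanner vendor's direction table is not redistributable, so the simulator
#' ships a deterministic, well-spread replacement: points of a Fibonacci
#' spiral on the upper hemisphere (antipodal directions are equivalent for
#' diffusion encoding). All downstream code accepts any gradient table, and
#' results are required to be robust to the choice of well-spread scheme.
#'
#' @param n_dir number of diffusion directions (default 30).
#' @param n_b0 number of unweighted volumes (default 5), placed first.
#' @param b diffusion weighting in s/mm^2 (default 1000).
#' @return A list with `bvals` (length `n_b0 + n_dir`) and `bvecs`
#'   (3 x (n_b0 + n_dir) matrix, unit columns, zero columns for b = 0).
#' @export
gradient_scheme <- function(n_dir = 30L, n_b0 = 5L, b = 1000) {
  stopifnot(n_dir >= 6L, n_b0 >= 1L, b > 0)
  i <- seq_len(n_dir) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- i / n_dir            # upper hemisphere only
  r <- sqrt(1 - z^2)
  phi <- golden * i
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  bvecs <- cbind(matrix(0, 3L, n_b0), dirs)
  bvals <- c(rep(0, n_b0), rep(b, n_dir))
  list(bvals = bvals, bvecs = bvecs)
}

#' Read / write FSL-dialect bval and bvec files
#'
#' bval: one row of whitespace-separated b-values. bvec: three rows
#' (x, y, z) of N columns. Nonzero vectors are normalized to unit length on
#' read; zero vectors (b = 0 entries) are kept as zeros.
#'
#' @param bval_path,bvec_path file paths.
#' @return A list with `bvals` and `bvecs` as in [gradient_scheme()].
#' @export
read_gradients <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0]
  if (length(rows) != 3L)
    stop("bvec file must have exactly 3 rows (FSL dialect), got ",
         length(rows))
  bvecs <- do.call(rbind, rows)
  if (ncol(bvecs) != length(bvals))
    stop("gradient table mismatch: ", length(bvals), " b-values vs ",
         ncol(bvecs), " b-vectors")
  nrm <- sqrt(colSums(bvecs^2))
  nz <- nrm > 0
  if (any(abs(nrm[nz & bvals > 0] - 1) > 0.05))
    stop("non-unit b-vector for a diffusion-weighted volume ",
         "(norm deviates by more than 5%)")
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2L, nrm[nz], `/`)
  list(bvals = bvals, bvecs = bvecs)
}

#' @rdname read_gradients
#' @param grad a list with `bvals` and `bvecs`.
#' @export
write_gradients <- function(grad, bval_path, bvec_path) {
  writeLines(paste(format(grad$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(grad$bvecs, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(list(bval_path, bvec_path))
}
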