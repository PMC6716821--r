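#' Diffusion tensor estimation and scalar metrics
#'
#' The tensor is estimated per voxel by log-linear least squares on the
#' mono-exponential signal model S_k = S0 exp(-b_k g_k' D g_k), with S0
#' taken as the arithmetic mean of the unweighted (b = 0) volumes. This
#' estimator is deterministic and adequate for single-shell data at
#' b = 1000 s/mm^2; a weighted variant (weights S_k^2) is available via
#' `weighted`. Negative eigenvalues are clamped to zero before metric
#' computation (keeping FA <= 1) and counted in `n_neg_clamped`.
#'
#' Tensor components are kept in the order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
#' internally; [write_tensor_nifti()] reorders to lower-triangular on disk.
#'
#' @param stack a [dwi_stack()] with >= 6 independent diffusion directions
#'   and >= 1 unweighted volume.
#' @param s0_floor voxels whose mean b0 signal falls at or below this are
#'   masked invalid (default 0: only non-positive S0 is excluded).
#' @param weighted use the weighted (S_k^2) fit; slower, per-voxel solve.
#' @return A `tensor_field`: list with `D` (4-D array, last dim 6), `S0`,
#'   `mask` (validity), `grid`, `n_neg_clamped`.
#' @export
fit_tensor <- function(stack, s0_floor = 0, weighted = FALSE) {
  dw <- stack$bvals > 0
  if (sum(dw) < 6L) stop("need >= 6 diffusion-weighted volumes, got ",
                         sum(dw))
  if (sum(!dw) < 1L) stop("need >= 1 unweighted (b = 0) volume")
  X <- design_matrix(stack$bvals[dw], stack$bvecs[, dw, drop = FALSE])
  if (qr(X)$rank < 6L)
    stop("fewer than 6 independent diffusion directions")
  d3 <- dim(stack$data)[1:3]
  nvox <- prod(d3)
  S <- matrix(stack$data, nvox, dim(stack$data)[4])
  S0 <- rowMeans(S[, !dw, drop = FALSE])
  mask <- S0 > s0_floor & S0 > 0
  Sdw <- S[mask, dw, drop = FALSE]
  # guard against zero/negative intensities entering the log
  floorv <- pmax(S0[mask] * 1e-8, .Machine$double.xmin)
  Sdw <- pmax(Sdw, floorv)
  Y <- -log(Sdw / S0[mask])                      # nvox_valid x nDW
  Dmat <- matrix(0, nvox, 6L)
  if (!weighted) {
    coef <- solve(crossprod(X), crossprod(X, t(Y)))  # 6 x nvox_valid
    Dmat[mask, ] <- t(coef)
  } else {
    idx <- which(mask)
    for (i in seq_along(idx)) {
      w <- Sdw[i, ]^2
      Xw <- X * w
      Dmat[idx[i], ] <- solve(crossprod(Xw, X), crossprod(Xw, Y[i, ]))
    }
  }
  grid <- im_grid(d3, stack$voxel_um / 1000)
  ev <- eig3_values(Dmat[mask, , drop = FALSE])
  structure(list(D = array(Dmat, c(d3, 6L)), S0 = array(S0, d3),
                 mask = array(mask, d3), grid = grid,
                 n_neg_clamped = sum(ev < 0)),
            class = "tensor_field")
}

design_matrix <- function(bvals, bvecs) {
  g <- t(bvecs)
  bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                2 * g[, 2] * g[, 3])
}

#' Eigenvalues of many symmetric 3x3 matrices (closed form)
#'
#' Non-iterative trigonometric solution, vectorized over rows. Rows hold
#' components in (xx, yy, zz, xy, xz, yz) order.
#'
#' @param D6 n x 6 matrix of tensor components.
#' @return n x 3 matrix of eigenvalues sorted descending (l1 >= l2 >= l3).
#' @export
eig3_values <- function(D6) {
  D6 <- rbind2mat6(D6)
  a11 <- D6[, 1]; a22 <- D6[, 2]; a33 <- D6[, 3]
  a12 <- D6[, 4]; a13 <- D6[, 5]; a23 <- D6[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 0
  l1 <- l2 <- l3 <- q
  if (any(ok)) {
    b11 <- (a11[ok] - q[ok]) / p[ok]; b22 <- (a22[ok] - q[ok]) / p[ok]
    b33 <- (a33[ok] - q[ok]) / p[ok]
    b12 <- a12[ok] / p[ok]; b13 <- a13[ok] / p[ok]; b23 <- a23[ok] / p[ok]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[ok] <- q[ok] + 2 * p[ok] * cos(phi)
    l3[ok] <- q[ok] + 2 * p[ok] * cos(phi + 2 * pi / 3)
    l2[ok] <- 3 * q[ok] - l1[ok] - l3[ok]
  }
  cbind(l1, l2, l3, deparse.level = 0)
}

#' Principal eigenvectors of many symmetric 3x3 matrices
#'
#' The eigenvector of the largest eigenvalue, computed as the most stable
#' cross product of rows of (D - l1 I); vectorized. Near-isotropic rows
#' (degenerate largest eigenvalue) yield the zero vector.
#'
#' @param D6 n x 6 matrix (xx, yy, zz, xy, xz, yz).
#' @param l1 optional precomputed largest eigenvalues.
#' @return n x 3 matrix of unit (or zero) vectors.
#' @export
eig3_principal <- function(D6, l1 = NULL) {
  D6 <- rbind2mat6(D6)
  if (is.null(l1)) l1 <- eig3_values(D6)[, 1]
  r1 <- cbind(D6[, 1] - l1, D6[, 4], D6[, 5])
  r2 <- cbind(D6[, 4], D6[, 2] - l1, D6[, 6])
  r3 <- cbind(D6[, 5], D6[, 6], D6[, 3] - l1)
  c12 <- vcross(r1, r2); c13 <- vcross(r1, r3); c23 <- vcross(r2, r3)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  v <- c12
  use13 <- n13 > n12; v[use13, ] <- c13[use13, , drop = FALSE]
  nbest <- pmax(n12, n13)
  use23 <- n23 > nbest; v[use23, ] <- c23[use23, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  scale_ref <- sqrt(pmax(rowSums(D6^2), .Machine$double.xmin))
  good <- nrm > 1e-12 * scale_ref^2 + 1e-300
  v[good, ] <- v[good, , drop = FALSE] / nrm[good]
  v[!good, ] <- 0
  v
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rbind2mat6 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 6L) else as.matrix(x)
}

#' Scalar diffusion metrics from eigenvalues
#'
#' With eigenvalues l1 >= l2 >= l3 (negatives clamped to 0) and their mean
#' lbar: FA = sqrt(3/2) sqrt(sum (li - lbar)^2) / sqrt(sum li^2) (0 where
#' all li = 0), MD = lbar, AD = l1, RD = (l2 + l3)/2.
#'
#' @param ev n x 3 matrix of eigenvalues (descending).
#' @return n x 4 matrix with columns FA, MD, AD, RD.
#' @export
metrics_from_eigenvalues <- function(ev) {
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  dev2 <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  ssq <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(ssq > 0, sqrt(1.5 * dev2 / ssq), 0)
  cbind(FA = pmin(fa, 1), MD = md, AD = ev[, 1],
        RD = (ev[, 2] + ev[, 3]) / 2)
}

#' Compute FA, AD, RD and MD maps from a tensor field
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @param space space label to attach to the maps.
#' @return Named list of four [metric_map()]s: FA, AD, RD, MD. Invalid
#'   voxels carry 0.
#' @export
compute_metrics <- function(field, space = "native") {
  d3 <- field$grid$dim
  D6 <- matrix(field$D, prod(d3), 6L)
  m <- metrics_from_eigenvalues(eig3_values(D6))
  m[!as.vector(field$mask), ] <- 0
  mk <- function(col, name)
    metric_map(array(m[, col], d3), name, field$grid, space)
  list(FA = mk("FA", "FA"), AD = mk("AD", "AD"),
       RD = mk("RD", "RD"), MD = mk("MD", "MD"))
}
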