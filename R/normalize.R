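#' Interpolation on regular grids
#'
#' Vectorized nearest-neighbour and trilinear sampling of a 3-D array at
#' arbitrary mm points. Points outside the grid return `outside`.
#'
#' @param values 3-D array.
#' @param grid the `im_grid` of `values`.
#' @param pts n x 3 mm points.
#' @param outside fill value for out-of-grid points (default 0).
#' @return numeric vector of length n.
#' @export
interp_nn <- function(values, grid, pts, outside = 0) {
  vox <- round(mm_to_vox(grid, pts))
  d <- grid$dim
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
        vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
  out <- rep(outside, nrow(vox))
  ix <- vox[ok, 1] + d[1] * (vox[ok, 2] - 1) +
    d[1] * d[2] * (vox[ok, 3] - 1)
  out[ok] <- values[ix]
  out
}

#' @rdname interp_nn
#' @export
interp_trilinear <- function(values, grid, pts, outside = 0) {
  vox <- mm_to_vox(grid, pts)
  d <- grid$dim
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
        vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
  out <- rep(outside, nrow(vox))
  if (!any(ok)) return(out)
  v <- vox[ok, , drop = FALSE]
  f0 <- pmin(floor(v), matrix(d - 1L, nrow(v), 3L, byrow = TRUE))
  w <- v - f0
  acc <- numeric(nrow(v))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ix <- (f0[, 1] + dx) + d[1] * (f0[, 2] + dy - 1) +
      d[1] * d[2] * (f0[, 3] + dz - 1)
    acc <- acc + wt * values[ix]
  }
  out[ok] <- acc
  out
}

#' Resample a map or DWI stack onto an isotropic grid
#'
#' Nearest-neighbour interpolation onto an isotropic grid (default 50 um),
#' minimizing partial-volume mixing: the output value set is a subset of
#' the input's. The default target grid spans floor(extent / spacing)
#' voxels per axis, centered on the source volume. A supplied target grid
#' must be covered by the source extent.
#'
#' @param x a [metric_map()] or [dwi_stack()].
#' @param spacing_um isotropic spacing in um (default 50).
#' @param target optional explicit target `im_grid`.
#' @return Same kind of object as `x`, on the isotropic grid.
#' @export
resample_isogrid <- function(x, spacing_um = 50, target = NULL) {
  UseMethod("resample_isogrid")
}

iso_target <- function(src_grid, spacing_mm, target) {
  if (is.null(target)) {
    extent <- src_grid$dim * src_grid$spacing
    im_grid(pmax(floor(extent / spacing_mm), 1), spacing_mm)
  } else {
    src_lo <- src_grid$origin - src_grid$spacing / 2
    src_hi <- src_lo + src_grid$dim * src_grid$spacing
    tg_lo <- target$origin - target$spacing / 2
    tg_hi <- tg_lo + target$dim * target$spacing
    if (any(tg_lo < src_lo - 1e-9) || any(tg_hi > src_hi + 1e-9))
      stop(sprintf(
        "target grid [%s..%s] mm not covered by source extent [%s..%s] mm",
        paste(round(tg_lo, 3), collapse = ","),
        paste(round(tg_hi, 3), collapse = ","),
        paste(round(src_lo, 3), collapse = ","),
        paste(round(src_hi, 3), collapse = ",")))
    target
  }
}

#' @export
resample_isogrid.metric_map <- function(x, spacing_um = 50, target = NULL) {
  tg <- iso_target(x$grid, spacing_um / 1000, target)
  vals <- interp_nn(x$values, x$grid, grid_coords(tg))
  metric_map(array(vals, tg$dim), x$metric, tg, x$space, x$subject_id,
             x$timepoint)
}

#' @export
resample_isogrid.dwi_stack <- function(x, spacing_um = 50, target = NULL) {
  src_grid <- im_grid(dim(x$data)[1:3], x$voxel_um / 1000)
  tg <- iso_target(src_grid, spacing_um / 1000, target)
  pts <- grid_coords(tg)
  nvol <- dim(x$data)[4]
  out <- array(0, c(tg$dim, nvol))
  for (v in seq_len(nvol))
    out[, , , v] <- interp_nn(x$data[, , , v], src_grid, pts)
  dwi_stack(out, rep(spacing_um, 3L), x$bvals, x$bvecs, x$subject_id,
            x$timepoint, x$scan_date)
}

#' Least-squares affine from landmark correspondences
#'
#' Finds the affine A minimizing sum ||A(m_i) - f_i||^2 over >= 4
#' non-coplanar landmark pairs (exact for >= 4 pairs in general position).
#'
#' @param moving_landmarks,fixed_landmarks n x 3 mm point matrices (or
#'   data.frames with x, y, z columns) in corresponding row order.
#' @return A list of class `affine3`: `M` (3 x 3), `t` (length 3), and the
#'   residual `rms` in mm.
#' @export
landmark_affine <- function(moving_landmarks, fixed_landmarks) {
  m <- as_pts(moving_landmarks); f <- as_pts(fixed_landmarks)
  stopifnot(nrow(m) == nrow(f))
  if (nrow(m) < 4L) stop("need >= 4 landmark pairs")
  X <- cbind(m, 1)
  if (qr(X)$rank < 4L)
    stop("degenerate (coplanar or collinear) landmark set")
  B <- qr.solve(X, f)                      # 4 x 3
  res <- X %*% B - f
  structure(list(M = t(B[1:3, , drop = FALSE]), t = as.numeric(B[4, ]),
                 rms = sqrt(mean(rowSums(res^2)))),
            class = "affine3")
}

as_pts <- function(x) {
  if (is.data.frame(x)) as.matrix(x[, c("x", "y", "z")]) else rbind2mat(x)
}

#' Apply / invert an affine transform on points
#' @param aff an `affine3`.
#' @param pts n x 3 mm points.
#' @export
affine_apply <- function(aff, pts) {
  sweep(rbind2mat(pts) %*% t(aff$M), 2L, aff$t, `+`)
}

#' @rdname affine_apply
#' @export
affine_invert <- function(aff) {
  Mi <- solve(aff$M)
  structure(list(M = Mi, t = as.numeric(-Mi %*% aff$t), rms = aff$rms),
            class = "affine3")
}

#' Subject-to-template transform (linear then nonlinear)
#'
#' Template point y samples the subject's native map at
#' `A^-1 (y + u(y))`: the dense displacement `u` (mm, on the template grid)
#' refines the landmark affine `A`.
#'
#' @param affine an `affine3` mapping native -> template mm.
#' @param disp optional displacement array (template dims x 3), mm.
#' @param grid the template `im_grid`.
#' @export
subject_transform <- function(affine, disp = NULL, grid = NULL) {
  structure(list(affine = affine, disp = disp, grid = grid),
            class = "subject_transform")
}

disp_at <- function(disp, grid, pts) {
  if (is.null(disp)) return(matrix(0, nrow(pts), 3L))
  cbind(interp_trilinear(disp[, , , 1], grid, pts),
        interp_trilinear(disp[, , , 2], grid, pts),
        interp_trilinear(disp[, , , 3], grid, pts))
}

#' Warp a native-space map into template space (or back)
#'
#' `warp_map` resamples a subject map onto the template grid through the
#' subject transform; `unwarp_map` inverts the transform (fixed-point
#' iteration for the displacement part) to carry a template-space map back
#' to a native grid.
#'
#' @param map a [metric_map()].
#' @param tf a [subject_transform()].
#' @param target target `im_grid` (template grid for `warp_map`, native
#'   grid for `unwarp_map`).
#' @param interp "trilinear" (default) or "nn".
#' @return A [metric_map()] on `target`.
#' @export
warp_map <- function(map, tf, target, interp = "trilinear") {
  y <- grid_coords(target)
  src <- affine_apply(affine_invert(tf$affine),
                      y + disp_at(tf$disp, tf$grid, y))
  fun <- if (interp == "nn") interp_nn else interp_trilinear
  vals <- fun(map$values, map$grid, src)
  metric_map(array(vals, target$dim), map$metric, target, "template",
             map$subject_id, map$timepoint)
}

#' @rdname warp_map
#' @export
unwarp_map <- function(map, tf, target, interp = "trilinear") {
  x <- grid_coords(target)                    # native points
  y <- affine_apply(tf$affine, x)             # initial guess: linear only
  if (!is.null(tf$disp)) {
    ax <- affine_apply(tf$affine, x)
    for (i in seq_len(8L)) y <- ax - disp_at(tf$disp, tf$grid, y)
  }
  fun <- if (interp == "nn") interp_nn else interp_trilinear
  vals <- fun(map$values, map$grid, y)
  metric_map(array(vals, target$dim), map$metric, target, "native",
             map$subject_id, map$timepoint)
}

#' Nonlinear refinement of a warped map against a template
#'
#' Small-deformation registration minimizing the sum of squared differences
#' with a smoothness penalty: demons-style gradient descent where each
#' update is Gaussian-smoothed and scaled by 1/(1 + lambda). If the final
#' field does not improve the masked Pearson correlation with the template,
#' the zero field is returned.
#'
#' @param moving a [metric_map()] on the template grid.
#' @param fixed 3-D template array on the same grid.
#' @param reg_weight smoothness weight lambda >= 0; Inf forces the zero
#'   field.
#' @param n_iter gradient-descent iterations (default 30).
#' @param smooth_sigma_vox Gaussian sigma (voxels) applied to each update.
#' @param mask optional logical array: correlation is evaluated inside it.
#' @return Displacement array (dims x 3) in mm, to be used as the `disp`
#'   slot of a [subject_transform()].
#' @export
nonlinear_refine <- function(moving, fixed, reg_weight = 1, n_iter = 30L,
                             smooth_sigma_vox = 1.5, mask = NULL) {
  if (any(!is.finite(moving$values)) || any(!is.finite(fixed)))
    stop("non-finite values in registration inputs")
  grid <- moving$grid
  d <- grid$dim
  if (is.null(mask)) mask <- array(TRUE, d)
  u <- array(0, c(d, 3L))
  cor0 <- masked_cor(moving$values, fixed, mask)
  if (!is.finite(reg_weight) || reg_weight >= 1e12) return(u)
  pts <- grid_coords(grid)
  scale <- 1 / (1 + reg_weight)
  warped <- moving$values
  for (it in seq_len(n_iter)) {
    gr <- array_gradient(warped, grid$spacing)         # per mm
    diffv <- warped - fixed
    g2 <- gr[, , , 1]^2 + gr[, , , 2]^2 + gr[, , , 3]^2
    denom <- g2 + diffv^2 / mean(grid$spacing)^2 + 1e-12
    for (a in 1:3) {
      du <- -scale * diffv * gr[, , , a] / denom
      u[, , , a] <- u[, , , a] +
        gauss_smooth3(du, smooth_sigma_vox)
    }
    src <- pts + matrix(u, length(warped), 3L)
    warped <- array(interp_trilinear(moving$values, grid, src), d)
  }
  if (masked_cor(warped, fixed, mask) >= cor0) u else array(0, c(d, 3L))
}

masked_cor <- function(a, b, mask) {
  av <- a[mask]; bv <- b[mask]
  if (stats::sd(av) == 0 && stats::sd(bv) == 0) return(1)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(0)
  stats::cor(av, bv)
}

# central-difference gradient of a 3-D array, per mm
array_gradient <- function(a, spacing) {
  d <- dim(a)
  g <- array(0, c(d, 3L))
  g[2:(d[1] - 1), , , 1] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  g[, 2:(d[2] - 1), , 2] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  g[, , 2:(d[3] - 1), 3] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) /
    (2 * spacing[3])
  g
}

#' Iterative study-specific template construction
#'
#' Iteration 1: landmark affine per subject, arithmetic mean of the warped
#' FA (and b0) maps on the isogrid. Later iterations add a nonlinear
#' refinement per subject and re-average. Iteration stops once the minimum
#' masked Pearson correlation between each subject's warped FA map and the
#' current FA template exceeds `config$template_corr_stop` (default 0.7),
#' or at `config$max_iter` with a warning.
#'
#' @param fa_maps named list of native-space FA [metric_map()]s (one per
#'   included scan).
#' @param b0_maps matching list of native-space b0 maps (may be `NULL`).
#' @param landmarks named list of subject landmark data.frames (x, y, z).
#' @param fixed_landmarks template-side landmark data.frame.
#' @param config a [pipeline_config()].
#' @param target optional template `im_grid`; defaults to the isogrid
#'   spanned by the first subject's extent.
#' @return A list: `space` (a [template_space()] with FA and b0 templates),
#'   `transforms` (named [subject_transform()] list), `correlations`
#'   (per subject, final iteration), `n_iter`, `converged`.
#' @export
build_templates <- function(fa_maps, b0_maps = NULL, landmarks,
                            fixed_landmarks, config = pipeline_config(),
                            target = NULL) {
  stopifnot(length(fa_maps) >= 1L)
  if (length(fa_maps) >= 2L && length(landmarks) != length(fa_maps))
    stop("need one landmark set per subject map")
  if (is.null(target)) {
    g1 <- fa_maps[[1]]$grid
    extent <- g1$dim * g1$spacing
    sp <- config$iso_grid_spacing / 1000
    target <- im_grid(pmax(floor(extent / sp), 1), sp)
  }
  fixed_pts <- as_pts(fixed_landmarks)
  tfs <- lapply(seq_along(fa_maps), function(i)
    subject_transform(landmark_affine(as_pts(landmarks[[i]]), fixed_pts),
                      NULL, target))
  names(tfs) <- names(fa_maps)
  warped <- lapply(seq_along(fa_maps), function(i)
    warp_map(fa_maps[[i]], tfs[[i]], target))
  template <- clamp01(Reduce(`+`, lapply(warped, `[[`, "values")) /
                        length(warped))
  converged <- FALSE; iter <- 1L; cors <- NULL
  repeat {
    mask <- template >= config$fa_threshold
    if (sum(mask) < 10L) mask <- template > 0
    cors <- vapply(warped, function(w)
      masked_cor(w$values, template, mask), 0)
    if (min(cors) > config$template_corr_stop) { converged <- TRUE; break }
    if (iter >= config$max_iter) break
    iter <- iter + 1L
    for (i in seq_along(fa_maps)) {
      u <- nonlinear_refine(warped[[i]], template, mask = mask)
      prev <- tfs[[i]]$disp
      tfs[[i]]$disp <- if (is.null(prev)) u else prev + u
      warped[[i]] <- warp_map(fa_maps[[i]], tfs[[i]], target)
    }
    template <- clamp01(Reduce(`+`, lapply(warped, `[[`, "values")) /
                          length(warped))
  }
  if (!converged)
    warning(sprintf(
      "template correlation %.3f below %.2f after %d iterations",
      min(cors), config$template_corr_stop, iter))
  b0_template <- NULL
  if (!is.null(b0_maps)) {
    wb0 <- lapply(seq_along(b0_maps), function(i)
      warp_map(b0_maps[[i]], tfs[[i]], target))
    b0_template <- Reduce(`+`, lapply(wb0, `[[`, "values")) / length(wb0)
  }
  space <- template_space(target, b0_template = b0_template,
                          fa_template = template)
  list(space = space, transforms = tfs, correlations = cors,
       n_iter = iter, converged = converged)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# rowwise median of a matrix via one vectorized sort (fast for small ncol)
row_median <- function(M) {
  k <- ncol(M)
  Ms <- matrix(M[order(row(M), M)], ncol = k, byrow = TRUE)
  if (k %% 2L) Ms[, (k + 1L) %/% 2L]
  else (Ms[, k %/% 2L] + Ms[, k %/% 2L + 1L]) / 2
}

#' Motion quality check of a DWI stack
#'
#' Scores every diffusion-weighted volume by its Pearson correlation with
#' the voxelwise median of its angular neighbourhood: the `qc_neighbours`
#' DW volumes whose gradient directions are closest (by |g_i . g_j|,
#' directions being axes) after per-volume mean-intensity normalization
#' (correlation is defined as 1 when both sides are constant). Comparing
#' within an angular neighbourhood keeps the reference image contrast
#' comparable — anisotropy makes distant diffusion directions genuinely
#' different images — so artefact-free volumes score high for every
#' direction while displaced or dropout volumes decorrelate from their
#' neighbours. Volumes scoring below `config$qc_score_threshold` are
#' flagged; the scan fails when more than `config$qc_max_bad_fraction` of
#' DW volumes is flagged. Deterministic.
#'
#' @param stack a [dwi_stack()].
#' @param config a [pipeline_config()].
#' @param qc_neighbours size of the angular neighbourhood (default 7).
#' @return A list: `verdict` ("pass"/"fail"), `scores` (per DW volume),
#'   `flagged` (indices into the stack's volumes), `mean_score`.
#' @export
quality_check <- function(stack, config = pipeline_config(),
                          qc_neighbours = 7L) {
  dw <- which(stack$bvals > 0)
  S <- matrix(stack$data, ncol = dim(stack$data)[4])[, dw, drop = FALSE]
  mns <- colMeans(S)
  mns[mns == 0] <- 1
  S <- sweep(S, 2L, mns, `/`)
  G <- t(stack$bvecs[, dw, drop = FALSE])
  aff <- abs(G %*% t(G))                 # angular affinity, axes not arrows
  k <- min(qc_neighbours, ncol(S) - 1L)
  scores <- vapply(seq_len(ncol(S)), function(j) {
    nb <- order(aff[j, -j], decreasing = TRUE)[seq_len(k)]
    nb <- seq_len(ncol(S))[-j][nb]
    med <- row_median(S[, nb, drop = FALSE])
    sj <- stats::sd(S[, j]); sm <- stats::sd(med)
    if (sj == 0 && sm == 0) 1 else if (sj == 0 || sm == 0) 0
    else stats::cor(S[, j], med)
  }, 0)
  flagged <- dw[scores < config$qc_score_threshold]
  verdict <- if (length(flagged) > config$qc_max_bad_fraction * length(dw))
    "fail" else "pass"
  list(verdict = verdict, scores = scores, flagged = flagged,
       mean_score = mean(scores))
}

#' Pick the best-quality scan per subject-timepoint
#'
#' Among replicate scans of one subject-timepoint, keep the pass-verdict
#' scan with the highest mean volume score.
#'
#' @param stacks named list of [dwi_stack()] candidates.
#' @param config a [pipeline_config()].
#' @return Name of the selected stack, or `NA` if none passes.
#' @export
select_best_scan <- function(stacks, config = pipeline_config()) {
  qc <- lapply(stacks, quality_check, config = config)
  ok <- vapply(qc, function(q) q$verdict == "pass", TRUE)
  if (!any(ok)) return(NA_character_)
  names(stacks)[ok][which.max(vapply(qc[ok], `[[`, 0, "mean_score"))]
}
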