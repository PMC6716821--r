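#' Averaged direction field for fiber tracking
#'
#' Averages tensor fields voxelwise across subjects in template space, then
#' eigen-decomposes the mean tensor: the principal eigenvector and the FA
#' of the mean tensor drive deterministic tracking. Eigenvectors are zeroed
#' where FA falls below `fa_threshold` (no tracking there).
#'
#' @param tensor_list list of n x 6 tensor matrices or (dims x 6) arrays in
#'   template space (component order xx, yy, zz, xy, xz, yz).
#' @param grid the template `im_grid`.
#' @param fa_threshold FA below which directions are zeroed (default 0.2).
#' @return A `direction_field`: list with `dir` (dims x 3 array of unit or
#'   zero vectors), `fa` (array), `grid`, `fa_threshold`.
#' @export
average_dataset <- function(tensor_list, grid, fa_threshold = 0.2) {
  if (length(tensor_list) == 0L) stop("empty cohort")
  nvox <- prod(grid$dim)
  acc <- matrix(0, nvox, 6L)
  for (D in tensor_list) acc <- acc + matrix(D, nvox, 6L)
  Dbar <- acc / length(tensor_list)
  ev <- eig3_values(Dbar)
  fa <- metrics_from_eigenvalues(ev)[, "FA"]
  dirv <- eig3_principal(Dbar, ev[, 1])
  dirv[fa < fa_threshold, ] <- 0
  structure(list(dir = array(dirv, c(grid$dim, 3L)),
                 fa = array(fa, grid$dim), grid = grid,
                 fa_threshold = fa_threshold),
            class = "direction_field")
}

#' Warp a native-space tensor field into template space
#'
#' Each of the six components is resampled through the subject transform;
#' tensors are then reoriented by the rotation component of the affine
#' (polar decomposition). Displacement fields are applied without
#' reorientation (small-deformation regime).
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @param tf a [subject_transform()].
#' @param target template `im_grid`.
#' @return n x 6 tensor matrix on `target` (row-major over the grid).
#' @export
warp_tensor_field <- function(field, tf, target) {
  y <- grid_coords(target)
  src <- affine_apply(affine_invert(tf$affine),
                      y + disp_at(tf$disp, tf$grid, y))
  D <- sapply(1:6, function(c6)
    interp_trilinear(field$D[, , , c6], field$grid, src))
  sv <- svd(tf$affine$M)
  R <- sv$u %*% t(sv$v)                     # rotation part
  D %*% t(rotation_on_sym6(t(R)))           # R D R' per voxel
}

#' Deterministic streamline tracking
#'
#' From each seed point, integrates bidirectionally along the trilinearly
#' interpolated principal-eigenvector field with per-step sign alignment
#' (eigenvectors are axes, not arrows): at each step the eight neighbouring
#' eigenvectors are flipped to the hemisphere of the incoming direction
#' before interpolation. A streamline terminates when local FA drops below
#' `fa_stop`, the turning angle exceeds `angle_max_deg`, or it leaves the
#' grid. Streamlines shorter than `min_len_mm` are discarded. Tracking is
#' fully deterministic.
#'
#' @param field a `direction_field` from [average_dataset()].
#' @param seeds n x 3 matrix of seed points (mm), e.g. from [seed_points()].
#' @param step_mm step length (default 0.025 mm, half an isogrid voxel).
#' @param angle_max_deg maximum turning angle per step (default 45).
#' @param fa_stop FA termination threshold (default the field's).
#' @param min_len_mm minimum streamline length (default 0.5).
#' @param max_steps per-direction step cap (default: 4 x grid diagonal).
#' @return A [tract()].
#' @export
track_streamlines <- function(field, seeds, step_mm = 0.025,
                              angle_max_deg = 45,
                              fa_stop = field$fa_threshold,
                              min_len_mm = 0.5, max_steps = NULL) {
  seeds <- rbind2mat(seeds)
  if (nrow(seeds) == 0L) {
    warning("no seed points; returning an empty tract")
    return(tract(list(), field$grid))
  }
  if (is.null(max_steps))
    max_steps <- ceiling(4 * sqrt(sum((field$grid$dim *
                                         field$grid$spacing)^2)) / step_mm)
  cos_max <- cos(angle_max_deg * pi / 180)
  d0 <- interp_dir(field, seeds, ref = NULL)
  halves <- lapply(c(1, -1), function(sgn)
    integrate_half(field, seeds, sgn * d0, step_mm, cos_max, fa_stop,
                   max_steps))
  streamlines <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    fwd <- halves[[1]][[i]]; bwd <- halves[[2]][[i]]
    pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
                 seeds[i, , drop = FALSE], fwd)
    streamlines[[i]] <- pts
  }
  lens <- vapply(streamlines, function(s)
    if (nrow(s) < 2L) 0 else sum(sqrt(rowSums(diff(s)^2))), 0)
  tract(streamlines[lens >= min_len_mm], field$grid)
}

# trilinear interpolation of sign-aligned eigenvectors; ref = incoming
# direction per point (NULL: align to the nearest voxel's eigenvector)
interp_dir <- function(field, pts, ref = NULL) {
  grid <- field$grid
  d <- grid$dim
  n <- nrow(pts)
  if (is.null(ref)) {
    vox <- pmin(pmax(round(mm_to_vox(grid, pts)), 1),
                matrix(d, n, 3L, byrow = TRUE))
    ix <- vox[, 1] + d[1] * (vox[, 2] - 1) + d[1] * d[2] * (vox[, 3] - 1)
    nv <- prod(d)
    ref <- cbind(field$dir[ix], field$dir[ix + nv], field$dir[ix + 2 * nv])
  }
  vox <- mm_to_vox(grid, pts)
  inb <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
    vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
  out <- matrix(0, n, 3L)
  if (!any(inb)) return(out)
  v <- vox[inb, , drop = FALSE]
  r <- ref[inb, , drop = FALSE]
  f0 <- pmin(floor(v), matrix(d - 1L, nrow(v), 3L, byrow = TRUE))
  w <- v - f0
  nv <- prod(d)
  acc <- matrix(0, nrow(v), 3L)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ix <- (f0[, 1] + dx) + d[1] * (f0[, 2] + dy - 1) +
      d[1] * d[2] * (f0[, 3] + dz - 1)
    vc <- cbind(field$dir[ix], field$dir[ix + nv], field$dir[ix + 2 * nv])
    sgn <- sign(rowSums(vc * r))
    sgn[sgn == 0] <- 1
    acc <- acc + wt * sgn * vc
  }
  nrm <- sqrt(rowSums(acc^2))
  ok <- nrm > 1e-8
  acc[ok, ] <- acc[ok, , drop = FALSE] / nrm[ok]
  acc[!ok, ] <- 0
  out[inb, ] <- acc
  out
}

integrate_half <- function(field, seeds, dir0, step_mm, cos_max, fa_stop,
                           max_steps) {
  n <- nrow(seeds)
  active <- rowSums(dir0^2) > 0
  pos <- seeds; dir <- dir0
  buf <- array(NA_real_, c(n, 3L, max_steps))
  counts <- integer(n)
  step_count <- 0L
  while (any(active) && step_count < max_steps) {
    step_count <- step_count + 1L
    idx <- which(active)
    newpos <- pos[idx, , drop = FALSE] + step_mm * dir[idx, , drop = FALSE]
    fa_here <- interp_trilinear(field$fa, field$grid, newpos, outside = 0)
    newdir <- interp_dir(field, newpos, ref = dir[idx, , drop = FALSE])
    ndn <- rowSums(newdir^2) > 0
    turn_ok <- rowSums(newdir * dir[idx, , drop = FALSE]) >= cos_max
    keep <- fa_here >= fa_stop & ndn & turn_ok
    kidx <- idx[keep]
    if (length(kidx)) {
      buf[cbind(rep(kidx, 3L),
                rep(1:3, each = length(kidx)),
                step_count)] <- newpos[keep, , drop = FALSE]
      counts[kidx] <- step_count
      pos[kidx, ] <- newpos[keep, , drop = FALSE]
      dir[kidx, ] <- newdir[keep, , drop = FALSE]
    }
    active[idx[!keep]] <- FALSE
  }
  lapply(seq_len(n), function(i) {
    if (counts[i] == 0L) return(matrix(0, 0, 3L))
    t(buf[i, , seq_len(counts[i]), drop = TRUE])
  })
}

#' Seed points for tracking: centers of eligible voxels in a region
#'
#' One seed per voxel center (or `density^(1/3)`-subdivided sub-centers)
#' where the field FA is at or above its threshold and the center lies in
#' `region`.
#'
#' @param field a `direction_field`.
#' @param region a shape ([shape_box()], [shape_sphere()],
#'   [shape_cylinder()]) or `NULL` for the whole grid.
#' @param density seeds per voxel (default 1).
#' @return n x 3 matrix of mm seed points.
#' @export
seed_points <- function(field, region = NULL, density = 1L) {
  pts <- grid_coords(field$grid)
  ok <- as.vector(field$fa) >= field$fa_threshold
  if (!is.null(region)) ok <- ok & in_shape(region, pts)
  pts[ok, , drop = FALSE]
}

#' Canonical tract definitions for the default phantom
#'
#' Seed and waypoint regions for the two fiber systems of
#' [default_structures()]: the transcallosal system ("cc": seeded in the
#' interhemispheric cylinder, required to reach both cortices) and the
#' descending "cst" (seeded at mid-height, required to span the
#' dorsoventral extent). Coordinates are template-space mm.
#'
#' @return Named list with elements `cc` and `cst`, each a list of
#'   `seed_region` and `must_pass` (list of shapes).
#' @export
default_tract_rois <- function() {
  list(
    cc = list(
      seed_region = shape_cylinder(c(-0.5, 0, 0.55), c(0.5, 0, 0.55), 0.2),
      must_pass = list(shape_box(c(-1.0, -0.5, 0.15), c(-0.5, 0.5, 0.95)),
                       shape_box(c(0.5, -0.5, 0.15), c(1.0, 0.5, 0.95)))),
    cst = list(
      seed_region = shape_cylinder(c(0, -0.7, -0.3), c(0, -0.7, 0.3), 0.18),
      must_pass = list(
        shape_box(c(-1.2, -1.2, -1.25), c(1.2, 1.2, -0.9)),
        shape_box(c(-1.2, -1.2, 0.9), c(1.2, 1.2, 1.25)))))
}

#' Select streamlines by waypoint and endpoint regions
#'
#' Keeps streamlines that intersect every `must_pass` region and whose two
#' endpoints fall one in each of `endpoints` (order-free). The occupancy
#' mask is recomputed.
#'
#' @param tr a [tract()].
#' @param must_pass list of shapes every kept streamline must visit.
#' @param endpoints optional list of two shapes.
#' @return The filtered [tract()].
#' @export
select_tract <- function(tr, must_pass = list(), endpoints = NULL) {
  keep <- vapply(tr$streamlines, function(s) {
    if (nrow(s) < 2L) return(FALSE)
    for (r in must_pass) if (!any(in_shape(r, s))) return(FALSE)
    if (!is.null(endpoints)) {
      e1 <- s[1, , drop = FALSE]; e2 <- s[nrow(s), , drop = FALSE]
      a1 <- in_shape(endpoints[[1]], e1); a2 <- in_shape(endpoints[[2]], e2)
      b1 <- in_shape(endpoints[[2]], e1); b2 <- in_shape(endpoints[[1]], e2)
      if (!((a1 && a2) || (b1 && b2))) return(FALSE)
    }
    TRUE
  }, TRUE)
  tract(tr$streamlines[keep], tr$grid, tr$seed_label, tr$target_label)
}

#' Tractwise statistics of a DTI metric
#'
#' Per subject, the mean of the metric over the tract's occupancy-mask
#' voxels where that subject's FA is at or above `fa_threshold` (matching
#' the whole-brain masking convention); then a two-sample t-test between
#' genotypes at each timepoint, with per-cell means and standard errors.
#'
#' @param tr a [tract()] with a nonempty occupancy mask.
#' @param metric_maps named list of template-space [metric_map()]s
#'   (names `<subject>_<timepoint>`) for the metric under test.
#' @param fa_maps matching named list of FA maps for sub-masking.
#' @param manifest the [cohort_manifest()].
#' @param fa_threshold per-subject FA sub-mask threshold (default 0.2).
#' @return A list: `per_subject` (data.frame subject_id, genotype,
#'   timepoint, value), `cells` (mean/SEM/n per genotype x timepoint),
#'   `tests` (t, df, p per timepoint).
#' @export
tfas <- function(tr, metric_maps, fa_maps, manifest, fa_threshold = 0.2) {
  if (sum(tr$mask) == 0L) stop("tract occupancy mask is empty")
  mask_lin <- which(tr$mask)
  man <- manifest[manifest$included, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(man))) {
    nm <- paste(man$subject_id[r], man$timepoint[r], sep = "_")
    if (!nm %in% names(metric_maps)) next
    mvals <- metric_maps[[nm]]$values[mask_lin]
    favals <- fa_maps[[nm]]$values[mask_lin]
    sel <- favals >= fa_threshold
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = man$subject_id[r], genotype = man$genotype[r],
      timepoint = man$timepoint[r],
      value = if (any(sel)) mean(mvals[sel]) else NA_real_)
  }
  per_subject <- do.call(rbind, rows)
  # subjects with no supra-threshold voxel carry NA and drop out of the
  # cell summaries and tests
  avail <- per_subject[!is.na(per_subject$value), , drop = FALSE]
  cells <- do.call(rbind, lapply(split(avail,
      list(avail$genotype, avail$timepoint)), function(g)
    data.frame(genotype = g$genotype[1], timepoint = g$timepoint[1],
               n = nrow(g), mean = mean(g$value),
               sem = stats::sd(g$value) / sqrt(nrow(g)))))
  rownames(cells) <- NULL
  tests <- do.call(rbind, lapply(c("baseline", "followup"), function(tp) {
    a <- avail$value[avail$timepoint == tp & avail$genotype == "mutant"]
    b <- avail$value[avail$timepoint == tp & avail$genotype == "wildtype"]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(timepoint = tp, t = NA_real_, df = NA_real_,
                        p = NA_real_))
    if (stats::sd(c(a, b)) == 0)
      return(data.frame(timepoint = tp, t = 0, df = length(a) +
                          length(b) - 2, p = 1))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(timepoint = tp, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  list(per_subject = per_subject, cells = cells, tests = tests)
}
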