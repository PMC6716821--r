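#' Synthetic DWI phantom specification
#'
#' Describes a mouse-brain-like diffusion phantom: a native acquisition grid
#' (default 102 x 102 x 250 um voxels), an isotropic background, a set of
#' anisotropic "tract" structures (boxes/cylinders/spheres with prescribed
#' tensor eigenvalues and principal direction), and focal lesions that
#' perturb eigenvalues multiplicatively in one (genotype, timepoint) cell.
#' The default phantom carries the anatomy the cohort design needs: two
#' lateral "cortex" boxes joined by a midline "corpus callosum" cylinder
#' (the structures a focal lesion targets) and a descending, spared "CST"
#' cylinder, so an affected-cortex/spared-CST dissociation can be encoded
#' as ground truth.
#'
#' @param grid_dim native voxel counts (default c(24, 24, 10)).
#' @param voxel_um native voxel size in um (default c(102, 102, 250)).
#' @param background_d isotropic background diffusivity in mm^2/s.
#' @param structures list of structures; see [phantom_structure()].
#' @param lesions list of lesions; see [phantom_lesion()].
#' @param S0 unweighted signal amplitude (arbitrary units).
#' @param s0_contrast amplitude of the smooth radial "anatomy" profile of
#'   the unweighted signal: S0(x) = S0 (0.6 + a exp(-|x|^2 / 2 s^2)) with
#'   s = 35% of the half-extent (default a = 0.8; 0 gives uniform S0).
#'   Spatial S0 contrast is what makes the motion quality check and b0
#'   template meaningful.
#' @param noise_sigma Rician noise sigma in signal units (default S0/40).
#' @param n_per_group subjects per genotype (default 9).
#' @param scan_interval_days nominal baseline-to-follow-up interval
#'   (default 150, about 5 months).
#' @param interval_jitter_days half-width of the uniform per-subject
#'   interval jitter (default 10).
#' @param jitter_vox,jitter_deg half-widths of the per-subject rigid offset
#'   (default 1 native voxel, 3 degrees); set both 0 to disable.
#' @param pv_samples partial-volume supersampling factor per axis (default
#'   3): each native voxel's generating tensor is the average of the
#'   phantom tensor over `pv_samples^3` sub-voxel midpoints, so structure
#'   edges carry continuous mixed tensors rather than flipping whole voxels
#'   with sub-voxel position — the tensor-level analogue of the MR voxel
#'   integrating signal over its volume. The voxel signal stays exactly
#'   mono-exponential in the averaged tensor. 1 reverts to center sampling.
#' @param grad gradient scheme (default [gradient_scheme()]: 30 directions
#'   at b = 1000 s/mm^2, 5 b = 0).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(24L, 24L, 10L),
                         voxel_um = c(102, 102, 250),
                         background_d = 0.7e-3,
                         structures = default_structures(),
                         lesions = list(),
                         S0 = 1000,
                         s0_contrast = 0.8,
                         noise_sigma = 25,
                         n_per_group = 9L,
                         scan_interval_days = 150L,
                         interval_jitter_days = 10L,
                         jitter_vox = 1,
                         jitter_deg = 3,
                         pv_samples = 3L,
                         grad = gradient_scheme()) {
  spec <- structure(list(grid_dim = as.integer(grid_dim),
                         voxel_um = voxel_um, background_d = background_d,
                         structures = structures, lesions = lesions,
                         S0 = S0, s0_contrast = s0_contrast,
                         noise_sigma = noise_sigma,
                         n_per_group = as.integer(n_per_group),
                         scan_interval_days = scan_interval_days,
                         interval_jitter_days = interval_jitter_days,
                         jitter_vox = jitter_vox, jitter_deg = jitter_deg,
                         pv_samples = as.integer(pv_samples),
                         grad = grad),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param shape a shape from [shape_box()], [shape_cylinder()] or
#'   [shape_sphere()] (mm coordinates).
#' @param eigenvalues length-3, descending, strictly positive (mm^2/s).
#' @param direction principal diffusion direction (normalized internally).
#' @param name free-text structure label.
#' @export
phantom_structure <- function(shape, eigenvalues, direction, name = "") {
  direction <- direction / sqrt(sum(direction^2))
  list(shape = shape, eigenvalues = as.numeric(eigenvalues),
       direction = direction, name = name)
}

#' @rdname phantom_spec
#' @param region a shape delimiting the lesion.
#' @param group affected genotype label.
#' @param timepoint affected timepoint label.
#' @param factors multiplicative perturbation of (l1, l2, l3). Factors that
#'   move l2, l3 toward l1 lower FA and raise RD/MD, the co-occurring
#'   signature of cortical microstructural damage.
#' @export
phantom_lesion <- function(region = NULL, structures = NULL,
                           group = "mutant", timepoint = "followup",
                           factors = c(1, 1.25, 1.25)) {
  if (is.null(region) && is.null(structures))
    stop("a lesion needs a region, target structures, or both")
  list(region = region, structures = structures, group = group,
       timepoint = timepoint, factors = as.numeric(factors))
}

# voxels a lesion perturbs: region AND targeted structures (NULL = all)
lesion_hits <- function(L, pts, struct_id, spec) {
  hit <- if (is.null(L$region)) rep(TRUE, nrow(pts))
         else in_shape(L$region, pts)
  if (!is.null(L$structures)) {
    nm <- vapply(spec$structures, `[[`, "", "name")
    hit <- hit & struct_id %in% which(nm %in% L$structures)
  }
  hit
}

#' Geometric shapes in mm coordinates
#' @param min,max box corners (length-3 mm).
#' @export
shape_box <- function(min, max) list(type = "box", min = min, max = max)

#' @rdname shape_box
#' @param p0,p1 cylinder axis endpoints (mm).
#' @param radius radius in mm.
#' @export
shape_cylinder <- function(p0, p1, radius)
  list(type = "cylinder", p0 = p0, p1 = p1, radius = radius)

#' @rdname shape_box
#' @param center sphere center (mm).
#' @export
shape_sphere <- function(center, radius)
  list(type = "sphere", center = center, radius = radius)

#' Point-in-shape test, vectorized
#' @param shape a shape object.
#' @param pts n x 3 matrix of mm points.
#' @return logical vector of length n.
#' @export
in_shape <- function(shape, pts) {
  pts <- rbind2mat(pts)
  switch(shape$type,
    box = pts[, 1] >= shape$min[1] & pts[, 1] <= shape$max[1] &
          pts[, 2] >= shape$min[2] & pts[, 2] <= shape$max[2] &
          pts[, 3] >= shape$min[3] & pts[, 3] <= shape$max[3],
    sphere = colSums((t(pts) - shape$center)^2) <= shape$radius^2,
    cylinder = {
      ax <- shape$p1 - shape$p0
      len2 <- sum(ax^2)
      rel <- sweep(pts, 2L, shape$p0, `-`)
      t_ <- as.vector(rel %*% ax) / len2
      perp2 <- rowSums(rel^2) - t_^2 * len2
      t_ >= 0 & t_ <= 1 & perp2 <= shape$radius^2
    },
    stop("unknown shape type: ", shape$type))
}

# Structure sizes satisfy sampling adequacy on the native grid: every
# structure spans >= 3 voxels along each axis (in particular >= 3 of the
# 250 um slices), so partial-volume rendering of the boundaries stays a
# minor fraction of each structure's volume under the +/-1-voxel
# repositioning jitter.
default_structures <- function() {
  d <- 1e-3
  list(
    phantom_structure(shape_box(c(0.5, -0.5, 0.15), c(1.0, 0.5, 0.95)),
                      c(1.0, 0.55, 0.55) * d, c(1, 0, 0), "cortex_right"),
    phantom_structure(shape_box(c(-1.0, -0.5, 0.15), c(-0.5, 0.5, 0.95)),
                      c(1.0, 0.55, 0.55) * d, c(1, 0, 0), "cortex_left"),
    phantom_structure(shape_cylinder(c(-0.6, 0, 0.55), c(0.6, 0, 0.55),
                                     0.4),
                      c(1.6, 0.3, 0.3) * d, c(1, 0, 0), "callosum"),
    phantom_structure(shape_cylinder(c(0, -0.7, -1.1), c(0, -0.7, 1.1),
                                     0.2),
                      c(1.6, 0.3, 0.3) * d, c(0, 0, 1), "cst"))
}

#' The default lesion: cortico-callosal degeneration at mutant follow-up
#'
#' Targets the whole cortex and callosum structures while sparing the
#' descending "cst" structure, modelling the widespread cortical and
#' interhemispheric white-matter damage of the study design (affected
#' regions span thousands of 50 um isogrid voxels, well above the
#' 256-voxel cluster floor) with an intact corticospinal system as the
#' negative control for tractwise statistics.
#' @export
default_lesion <- function() {
  phantom_lesion(structures = c("cortex_right", "cortex_left", "callosum"))
}

validate_phantom_spec <- function(spec) {
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.na(spec$pv_samples) || spec$pv_samples < 1L)
    stop("pv_samples must be a positive integer")
  if (spec$background_d <= 0) stop("background diffusivity must be > 0")
  for (s in spec$structures) {
    ev <- s$eigenvalues
    if (any(diff(ev) > 0) || any(ev <= 0))
      stop("structure '", s$name,
           "': eigenvalues must satisfy l1 >= l2 >= l3 > 0")
    for (L in spec$lesions) {
      if (!is.null(L$structures) && !s$name %in% L$structures) next
      pv <- ev * L$factors
      if (any(diff(pv) > 0) || any(pv <= 0))
        stop("lesion perturbation violates eigenvalue ordering for ",
             "structure '", s$name, "'")
    }
  }
  grid <- native_grid(spec)
  half <- (grid$dim) * grid$spacing / 2
  nm <- vapply(spec$structures, `[[`, "", "name")
  for (L in spec$lesions) {
    if (!is.null(L$structures) && !all(L$structures %in% nm))
      stop("lesion targets unknown structure(s): ",
           paste(setdiff(L$structures, nm), collapse = ", "))
    if (!is.null(L$region)) {
      ctr <- switch(L$region$type, sphere = L$region$center,
                    box = (L$region$min + L$region$max) / 2,
                    cylinder = (L$region$p0 + L$region$p1) / 2)
      if (any(abs(ctr) > half))
        stop("lesion region lies outside the phantom grid")
    }
  }
  invisible(spec)
}

#' Native acquisition grid of a phantom
#' @param spec a `phantom_spec`.
#' @export
native_grid <- function(spec) im_grid(spec$grid_dim, spec$voxel_um / 1000)

# orthonormal frame completing a principal direction
complete_frame <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- c(v[2] * a[3] - v[3] * a[2], v[3] * a[1] - v[1] * a[3],
          v[1] * a[2] - v[2] * a[1])
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(v[2] * e2[3] - v[3] * e2[2], v[3] * e2[1] - v[1] * e2[3],
          v[1] * e2[2] - v[2] * e2[1])
  cbind(v, e2, e3)
}

tensor6_from_frame <- function(ev, frame) {
  D <- frame %*% diag(ev) %*% t(frame)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# 6x6 linear action of D -> R' D R on (xx,yy,zz,xy,xz,yz) components
rotation_on_sym6 <- function(R) {
  basis <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  L <- matrix(0, 6L, 6L)
  for (m in seq_len(6L)) {
    E <- matrix(0, 3L, 3L)
    E[basis[[m]][1], basis[[m]][2]] <- 1
    E[basis[[m]][2], basis[[m]][1]] <- 1
    if (m <= 3L) E[basis[[m]][1], basis[[m]][2]] <- 1
    M <- t(R) %*% E %*% R
    L[, m] <- c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  }
  L
}

# evaluate the phantom's (eigenvalues, frame id) at template-space points
eval_phantom <- function(spec, pts, genotype, timepoint) {
  n <- nrow(pts)
  lambda <- matrix(spec$background_d, n, 3L)
  struct_id <- integer(n)              # 0 = background
  for (i in seq_along(spec$structures)) {
    idx <- in_shape(spec$structures[[i]]$shape, pts)
    struct_id[idx] <- i
    lambda[idx, ] <- matrix(spec$structures[[i]]$eigenvalues, sum(idx), 3L,
                            byrow = TRUE)
  }
  lesioned <- rep(FALSE, n)
  for (L in spec$lesions) {
    if (L$group == genotype && L$timepoint == timepoint) {
      idx <- lesion_hits(L, pts, struct_id, spec)
      lambda[idx, ] <- sweep(lambda[idx, , drop = FALSE], 2L, L$factors,
                             `*`)
      lesioned <- lesioned | idx
    }
  }
  list(lambda = lambda, struct_id = struct_id, lesioned = lesioned)
}

# compose n x 6 tensors from eigenvalues and per-structure frames
compose_tensors <- function(spec, ph) {
  n <- nrow(ph$lambda)
  D6 <- matrix(0, n, 6L)
  iso <- ph$struct_id == 0L
  D6[iso, 1:3] <- ph$lambda[iso, , drop = FALSE]
  for (i in seq_along(spec$structures)) {
    idx <- which(ph$struct_id == i)
    if (!length(idx)) next
    frame <- complete_frame(spec$structures[[i]]$direction)
    # lesioned and intact voxels share the structure's frame
    D6[idx, ] <- ph$lambda[idx, , drop = FALSE] %*% basis_outer(frame)
  }
  D6
}

# 3 x 6 matrix: row i gives components of e_i e_i' in (xx,yy,zz,xy,xz,yz)
basis_outer <- function(frame) {
  t(apply(frame, 2L, function(e)
    c(e[1]^2, e[2]^2, e[3]^2, e[1] * e[2], e[1] * e[3], e[2] * e[3])))
}

# sub-voxel midpoint offsets (mm, subject-space axes) for partial-volume
# supersampling: the s^3 cell midpoints of each native voxel
pv_offsets <- function(spec) {
  s <- spec$pv_samples
  ax <- ((seq_len(s) - 0.5) / s - 0.5)
  off <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  sweep(off, 2L, spec$voxel_um / 1000, `*`)
}

# random rigid jitter transform about the grid center
draw_jitter <- function(spec) {
  ang <- stats::runif(3, -spec$jitter_deg, spec$jitter_deg) * pi / 180
  tvec <- stats::runif(3, -spec$jitter_vox, spec$jitter_vox) *
    spec$voxel_um / 1000
  Rx <- rot_axis(1, ang[1]); Ry <- rot_axis(2, ang[2])
  Rz <- rot_axis(3, ang[3])
  list(R = Rz %*% Ry %*% Rx, t = tvec)
}

rot_axis <- function(axis, a) {
  R <- diag(3)
  i <- setdiff(1:3, axis)
  R[i[1], i[1]] <- cos(a); R[i[2], i[2]] <- cos(a)
  R[i[1], i[2]] <- -sin(a); R[i[2], i[1]] <- sin(a)
  R
}

#' Simulate one subject-timepoint DWI stack with ground truth
#'
#' The noise-free signal follows the mono-exponential tensor model
#' S_k = S0 exp(-b_k g_k' D g_k); Rician corruption then sets
#' S~ = sqrt((S + e1)^2 + e2^2) with e1, e2 ~ N(0, sigma^2). A small random
#' rigid offset (the subject's "head position") is applied by evaluating
#' the phantom at rigidly transformed coordinates and counter-rotating the
#' tensors, so stereotaxic normalization is nontrivial yet the ground truth
#' stays analytic. Lesions apply only when (genotype, timepoint) matches.
#'
#' @param spec a [phantom_spec()].
#' @param genotype,timepoint labels selecting lesion applicability.
#' @param subject_id,scan_date stack metadata.
#' @param seed integer seed for this subject's randomness (jitter + noise);
#'   `NULL` uses the current RNG state.
#' @return A list with `stack` (a [dwi_stack()]) and `truth` (subject-space
#'   tensor components `D6` of the partial-volume-averaged voxel tensors,
#'   their eigenvalues `lambda`, `ideal` metric matrix (FA, MD, AD, RD),
#'   logical `lesion_mask` (voxel centers), the rigid `jitter`, subject
#'   `landmarks` data.frame, and the native `grid`).
#' @export
simulate_subject <- function(spec, genotype, timepoint,
                             subject_id = "sub", scan_date = as.Date(NA),
                             seed = NULL) {
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  grid <- native_grid(spec)
  pts_s <- grid_coords(grid)
  jit <- if (spec$jitter_vox > 0 || spec$jitter_deg > 0) draw_jitter(spec)
         else list(R = diag(3), t = c(0, 0, 0))
  pts_t <- sweep(pts_s %*% t(jit$R), 2L, jit$t, `+`)   # T_s(x) = R x + t
  # center evaluation fixes the truth masks (structure id, lesion)
  ph <- eval_phantom(spec, pts_t, genotype, timepoint)
  # partial volume: the voxel's generating tensor is the average of the
  # phantom tensor over sub-voxel midpoints, so edges mix continuously
  offs <- pv_offsets(spec)
  D6_t <- matrix(0, nrow(pts_s), 6L)
  for (o in seq_len(nrow(offs))) {
    pts_o <- sweep(sweep(pts_s, 2L, offs[o, ], `+`) %*% t(jit$R), 2L,
                   jit$t, `+`)
    ph_o <- eval_phantom(spec, pts_o, genotype, timepoint)
    D6_t <- D6_t + compose_tensors(spec, ph_o)
  }
  D6_t <- D6_t / nrow(offs)
  lambda <- eig3_values(D6_t)
  D6 <- D6_t %*% t(rotation_on_sym6(jit$R))            # R' D R per voxel
  X <- design_matrix(spec$grad$bvals, spec$grad$bvecs)
  s0vox <- s0_profile(spec, pts_t, grid)
  S <- s0vox * exp(-(D6 %*% t(X)))                     # b0 rows of X are 0
  if (spec$noise_sigma > 0) {
    e1 <- stats::rnorm(length(S), 0, spec$noise_sigma)
    e2 <- stats::rnorm(length(S), 0, spec$noise_sigma)
    S <- sqrt((S + e1)^2 + e2^2)
  }
  stack <- dwi_stack(array(S, c(grid$dim, length(spec$grad$bvals))),
                     spec$voxel_um, spec$grad$bvals, spec$grad$bvecs,
                     subject_id, timepoint, scan_date)
  lm_t <- default_landmarks(grid)
  lm_s <- sweep(as.matrix(lm_t[, c("x", "y", "z")]), 2L, jit$t, `-`) %*%
    jit$R                                              # T_s^-1(f)
  landmarks <- data.frame(name = lm_t$name, x = lm_s[, 1], y = lm_s[, 2],
                          z = lm_s[, 3])
  truth <- list(D6 = D6, lambda = lambda, s0 = array(s0vox, grid$dim),
                ideal = metrics_from_eigenvalues(lambda),
                lesion_mask = array(ph$lesioned, grid$dim),
                jitter = jit, landmarks = landmarks, grid = grid)
  list(stack = stack, truth = truth)
}

# smooth radial S0 "anatomy" profile, evaluated in template coordinates
s0_profile <- function(spec, pts, grid) {
  if (spec$s0_contrast == 0) return(rep(spec$S0, nrow(pts)))
  s <- 0.35 * min(grid$dim * grid$spacing) / 2
  spec$S0 * (0.6 + spec$s0_contrast * exp(-rowSums(pts^2) / (2 * s^2)))
}

#' Fixed landmark set of a phantom grid (template side)
#'
#' Eight non-coplanar points at 60% of the half-extent, the correspondence
#' targets for the linear normalization step.
#' @param grid an `im_grid`.
#' @export
default_landmarks <- function(grid) {
  half <- grid$dim * grid$spacing / 2 * 0.6
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  data.frame(name = sprintf("L%d", seq_len(nrow(s))),
             x = s$x * half[1], y = s$y * half[2], z = s$z * half[3])
}

#' Simulate a full two-genotype, two-timepoint cohort
#'
#' `n_per_group` subjects per genotype, each with a baseline and a
#' follow-up scan separated by `scan_interval_days` plus a small uniform
#' per-subject jitter (so per-day normalization of longitudinal differences
#' is exercised). Fully reproducible from `master_seed`.
#'
#' @param spec a [phantom_spec()].
#' @param master_seed integer master seed.
#' @return A list: `manifest` (a [cohort_manifest()]), `stacks` (named list
#'   of [dwi_stack()], names `<subject>_<timepoint>`), `truths` (matching
#'   ground-truth list), `spec`.
#' @export
simulate_cohort <- function(spec, master_seed = 1L) {
  if (spec$n_per_group < 2L) stop("n_per_group must be >= 2")
  set.seed(master_seed)
  subjects <- c(sprintf("mut%02d", seq_len(spec$n_per_group)),
                sprintf("wt%02d", seq_len(spec$n_per_group)))
  genotypes <- rep(c("mutant", "wildtype"), each = spec$n_per_group)
  base_date <- as.Date("2025-01-01")
  rows <- list(); stacks <- list(); truths <- list()
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * length(subjects))
  k <- 0L
  for (i in seq_along(subjects)) {
    t0 <- base_date + sample.int(30L, 1L)
    interval <- spec$scan_interval_days +
      sample.int(2L * spec$interval_jitter_days + 1L, 1L) -
      spec$interval_jitter_days - 1L
    for (tp in c("baseline", "followup")) {
      k <- k + 1L
      date <- if (tp == "baseline") t0 else t0 + interval
      sim <- simulate_subject(spec, genotypes[i], tp, subjects[i], date,
                              seed = seeds[k])
      nm <- paste(subjects[i], tp, sep = "_")
      stacks[[nm]] <- sim$stack
      truths[[nm]] <- sim$truth
      rows[[k]] <- data.frame(subject_id = subjects[i],
                              genotype = genotypes[i], timepoint = tp,
                              scan_date = date, dwi_path = "",
                              included = TRUE)
    }
  }
  manifest <- cohort_manifest(do.call(rbind, rows))
  list(manifest = manifest, stacks = stacks, truths = truths, spec = spec)
}

#' Lesion mask of a phantom on an arbitrary grid
#'
#' The voxels whose centers fall inside any lesion region affecting the
#' given (genotype, timepoint) cell — the detection ground truth for
#' cluster overlap scoring.
#'
#' @param spec a [phantom_spec()].
#' @param grid target `im_grid` (e.g. the template isogrid).
#' @param genotype,timepoint cell selector.
#' @return Logical 3-D array on `grid`.
#' @export
lesion_mask_on_grid <- function(spec, grid, genotype = "mutant",
                                timepoint = "followup") {
  pts <- grid_coords(grid)
  ph <- eval_phantom(spec, pts, genotype, timepoint)
  array(ph$lesioned, grid$dim)
}

#' Corrupt a DWI stack with motion artefacts
#'
#' Displaces `n_bad_volumes` randomly chosen diffusion-weighted volumes by
#' a rigid in-plane shift of at least 2 native voxels and darkens a random
#' band of slices (intensity dropout), producing positive cases for
#' [quality_check()].
#'
#' @param stack a [dwi_stack()].
#' @param n_bad_volumes how many DW volumes to corrupt
#'   (0 returns the stack unchanged).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return The corrupted [dwi_stack()], with the affected volume indices in
#'   attribute `"bad_volumes"`.
#' @export
corrupt_with_motion <- function(stack, n_bad_volumes, seed = NULL) {
  dw <- which(stack$bvals > 0)
  if (n_bad_volumes < 0 || n_bad_volumes >= length(dw))
    stop("n_bad_volumes must lie in [0, number of DW volumes)")
  if (n_bad_volumes == 0L) {
    attr(stack, "bad_volumes") <- integer()
    return(stack)
  }
  if (!is.null(seed)) set.seed(seed)
  bad <- sort(sample(dw, n_bad_volumes))
  d <- dim(stack$data)
  for (v in bad) {
    sh <- sample(2:4, 2L, replace = TRUE) * sample(c(-1L, 1L), 2L,
                                                   replace = TRUE)
    vol <- stack$data[, , , v]
    vol <- vol[shift_idx(d[1], sh[1]), shift_idx(d[2], sh[2]), ,
               drop = FALSE]
    z0 <- sample.int(d[3], 1L)
    zs <- z0:min(d[3], z0 + max(1L, d[3] %/% 5L))
    vol[, , zs] <- vol[, , zs] * 0.3
    stack$data[, , , v] <- vol
  }
  attr(stack, "bad_volumes") <- bad
  stack
}

shift_idx <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L
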