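#' Regular image grids and stereotaxic template space
#'
#' All template-space volumes live on a regular grid with an explicit affine
#' mapping voxel indices to stereotaxic millimetre coordinates. Voxel indices
#' are 1-based in R; coordinates refer to voxel centers. Stereotaxic (BREGMA)
#' coordinates are reported in (coronal, horizontal, sagittal) order with the
#' bregma voxel at (0, 0, 0) mm.
#'
#' @param dim integer length-3 voxel counts.
#' @param spacing voxel spacing in mm, scalar (isotropic) or length-3.
#' @param origin mm coordinate of the center of voxel (1,1,1).
#' @return An object of class `im_grid`.
#' @export
im_grid <- function(dim, spacing, origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(origin)) {
    # center the grid on the coordinate origin
    origin <- -(dim - 1) / 2 * spacing
  }
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "im_grid")
}

#' Convert voxel indices (1-based) to mm coordinates
#'
#' @param grid an `im_grid`.
#' @param vox n x 3 matrix of (possibly fractional) voxel indices.
#' @return n x 3 matrix of mm coordinates of voxel centers.
#' @export
vox_to_mm <- function(grid, vox) {
  vox <- rbind2mat(vox)
  sweep(sweep(vox - 1, 2L, grid$spacing, `*`), 2L, grid$origin, `+`)
}

#' Convert mm coordinates to (fractional, 1-based) voxel indices
#' @param grid an `im_grid`.
#' @param mm n x 3 matrix of mm coordinates.
#' @export
mm_to_vox <- function(grid, mm) {
  mm <- rbind2mat(mm)
  sweep(sweep(mm, 2L, grid$origin, `-`), 2L, grid$spacing, `/`) + 1
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

#' mm coordinates of every voxel center, as an n x 3 matrix
#' @param grid an `im_grid`.
#' @export
grid_coords <- function(grid) {
  d <- grid$dim
  idx <- cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  vox_to_mm(grid, idx)
}

#' Stereotaxic template space
#'
#' Couples an isotropic grid with the bregma origin and axis sign convention
#' used for reporting cluster peaks: BREGMA mm coordinates in
#' (coronal, horizontal, sagittal) order. The b0 and FA templates built by
#' [build_templates()] are attached when available.
#'
#' @param grid an `im_grid` (50 um isotropic by default in this pipeline).
#' @param bregma_vox 1-based voxel index triple mapping to (0,0,0) mm.
#' @param axis_signs +1/-1 per axis; fixes the left-right (sagittal) sign.
#' @param b0_template,fa_template optional 3-D arrays on `grid`.
#' @return An object of class `template_space`.
#' @export
template_space <- function(grid, bregma_vox = (grid$dim + 1) / 2,
                           axis_signs = c(1, 1, 1),
                           b0_template = NULL, fa_template = NULL) {
  stopifnot(inherits(grid, "im_grid"), all(abs(axis_signs) == 1))
  if (!is.null(fa_template))
    stopifnot(min(fa_template, na.rm = TRUE) >= 0,
              max(fa_template, na.rm = TRUE) <= 1)
  structure(list(grid = grid, bregma_vox = as.numeric(bregma_vox),
                 axis_signs = as.numeric(axis_signs),
                 b0_template = b0_template, fa_template = fa_template),
            class = "template_space")
}

#' Voxel index to BREGMA mm coordinates (and back)
#'
#' @param space a `template_space`.
#' @param vox n x 3 voxel indices (1-based).
#' @return n x 3 BREGMA mm coordinates (coronal, horizontal, sagittal).
#' @export
vox_to_bregma <- function(space, vox) {
  vox <- rbind2mat(vox)
  mm <- sweep(sweep(vox, 2L, space$bregma_vox, `-`), 2L,
              space$grid$spacing, `*`)
  sweep(mm, 2L, space$axis_signs, `*`)
}

#' @rdname vox_to_bregma
#' @param mm n x 3 BREGMA mm coordinates.
#' @export
bregma_to_vox <- function(space, mm) {
  mm <- rbind2mat(mm)
  sweep(sweep(mm, 2L, space$axis_signs, `*`), 2L,
        space$grid$spacing, `/`) + matrix(space$bregma_vox,
                                          nrow(mm), 3L, byrow = TRUE)
}

#' A scalar metric map on a grid
#'
#' @param values 3-D numeric array.
#' @param metric one of "FA", "AD", "RD", "MD" (or "b0" for reference maps).
#' @param grid the `im_grid` the values live on.
#' @param space "native" or "template".
#' @param subject_id,timepoint optional provenance labels.
#' @export
metric_map <- function(values, metric, grid, space = "native",
                       subject_id = NA_character_, timepoint = NA_character_) {
  stopifnot(length(dim(values)) == 3L, all(dim(values) == grid$dim))
  structure(list(values = values, metric = metric, grid = grid,
                 space = space, subject_id = subject_id,
                 timepoint = timepoint),
            class = "metric_map")
}
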