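#' Diffusion-weighted image stacks
#'
#' A `dwi_stack` bundles one subject-timepoint 4-D diffusion-weighted
#' volume with its gradient scheme and acquisition metadata. Voxel sizes are
#' carried in micrometres; intensities must be finite and non-negative;
#' fitting requires at least 6 diffusion-weighted and 1 unweighted volume.
#'
#' @param data 4-D array (x, y, z, volume).
#' @param voxel_um length-3 voxel size in micrometres.
#' @param bvals,bvecs gradient table (bvecs: 3 x N, unit or zero columns).
#' @param subject_id,timepoint,scan_date provenance; `scan_date` is a
#'   [Date].
#' @export
dwi_stack <- function(data, voxel_um, bvals, bvecs,
                      subject_id = NA_character_,
                      timepoint = NA_character_,
                      scan_date = as.Date(NA)) {
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[4] != length(bvals))
    stop("volume count mismatch: ", dim(data)[4], " volumes vs ",
         length(bvals), " gradient table entries")
  stopifnot(ncol(bvecs) == length(bvals), length(voxel_um) == 3L,
            all(voxel_um > 0))
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 bvals = as.numeric(bvals), bvecs = bvecs,
                 subject_id = subject_id, timepoint = timepoint,
                 scan_date = as.Date(scan_date)),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  cat(sprintf("<dwi_stack %s/%s: %s voxels @ (%g, %g, %g) um, %d b0 + %d DW>\n",
              x$subject_id, x$timepoint,
              paste(dim(x$data)[1:3], collapse = "x"),
              x$voxel_um[1], x$voxel_um[2], x$voxel_um[3],
              sum(x$bvals == 0), sum(x$bvals > 0)))
  invisible(x)
}

#' Read a DWI stack from NIfTI-1 plus FSL bval/bvec
#'
#' The 4th NIfTI dimension must equal the number of gradient table entries;
#' a mismatch is a hard error naming both counts. Voxel sizes are taken from
#' the NIfTI header (mm) and converted to micrometres. Nonzero gradient
#' directions are normalized to unit length.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @inheritParams dwi_stack
#' @return A [dwi_stack()].
#' @export
read_dwi <- function(path, bval_path, bvec_path,
                     subject_id = NA_character_, timepoint = NA_character_,
                     scan_date = as.Date(NA)) {
  img <- RNifti::readNifti(path)
  grad <- read_gradients(bval_path, bvec_path)
  arr <- unclass(img)[, , , , drop = FALSE]
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D NIfTI volume, got ", length(dim(arr)), "-D")
  if (dim(arr)[4] != length(grad$bvals))
    stop("volume count mismatch: ", dim(arr)[4], " volumes vs ",
         length(grad$bvals), " gradient table entries")
  vox_mm <- RNifti::pixdim(img)[1:3]
  dwi_stack(array(as.numeric(arr), dim = dim(arr)), vox_mm * 1000,
            grad$bvals, grad$bvecs, subject_id, timepoint, scan_date)
}

#' @rdname read_dwi
#' @param stack a [dwi_stack()].
#' @export
write_dwi <- function(stack, path, bval_path, bvec_path) {
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(stack$voxel_um / 1000, 1)
  RNifti::writeNifti(img, path)
  write_gradients(list(bvals = stack$bvals, bvecs = stack$bvecs),
                  bval_path, bvec_path)
  invisible(path)
}

#' Read / write a scalar metric map as NIfTI
#'
#' @param map a [metric_map()].
#' @param path NIfTI file path.
#' @export
write_metric_nifti <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_metric_nifti
#' @param metric metric label to attach.
#' @param space space label ("native" or "template").
#' @export
read_metric_nifti <- function(path, metric, space = "template") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  grid <- im_grid(dim(vals), RNifti::pixdim(img)[1:3])
  metric_map(vals, metric, grid, space)
}

#' Write a tensor field as a 6-component NIfTI
#'
#' Components in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the
#' convention used by common DTI toolchains.
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @param path NIfTI file path.
#' @export
write_tensor_nifti <- function(field, path) {
  # internal order: xx, yy, zz, xy, xz, yz -> lower-triangular on disk
  lt <- field$D[, , , c(1L, 4L, 2L, 5L, 6L, 3L), drop = FALSE]
  img <- RNifti::asNifti(lt)
  RNifti::pixdim(img) <- c(field$grid$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
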