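#' Streamline bundles (tracts)
#'
#' A `tract` is a list of streamlines (ordered n x 3 matrices of
#' template-space mm points) plus the voxel-occupancy mask on the template
#' grid: exactly the voxels containing at least one streamline point. The
#' occupancy mask is the unit over which tractwise statistics average.
#'
#' @param streamlines list of n_i x 3 numeric matrices (mm coordinates).
#' @param grid the template `im_grid`.
#' @param seed_label,target_label free-text region descriptors.
#' @export
tract <- function(streamlines, grid, seed_label = "", target_label = "") {
  stopifnot(is.list(streamlines))
  structure(list(streamlines = streamlines, grid = grid,
                 mask = occupancy_mask(streamlines, grid),
                 seed_label = seed_label, target_label = target_label),
            class = "tract")
}

#' Voxel occupancy mask of a set of streamlines
#' @param streamlines list of n x 3 mm point matrices.
#' @param grid an `im_grid`.
#' @return logical 3-D array: TRUE where >= 1 streamline point falls.
#' @export
occupancy_mask <- function(streamlines, grid) {
  mask <- array(FALSE, grid$dim)
  if (length(streamlines) == 0L) return(mask)
  pts <- do.call(rbind, streamlines)
  vox <- round(mm_to_vox(grid, pts))
  keep <- vox[, 1] >= 1 & vox[, 1] <= grid$dim[1] &
          vox[, 2] >= 1 & vox[, 2] <= grid$dim[2] &
          vox[, 3] >= 1 & vox[, 3] <= grid$dim[3]
  mask[vox[keep, , drop = FALSE]] <- TRUE
  mask
}

#' @export
print.tract <- function(x, ...) {
  cat(sprintf("<tract: %d streamlines, %d occupied voxels>\n",
              length(x$streamlines), sum(x$mask)))
  invisible(x)
}

#' Write / read streamlines in TrackVis TRK or MRtrix TCK format
#'
#' Format is selected from the file extension (.trk or .tck). The TRK
#' header's voxel size and dimensions are taken from the tract's grid.
#' Points are stored as 32-bit floats, so read-back reproduces coordinates
#' to single precision. An empty tract yields a valid zero-streamline file
#' with a warning.
#'
#' @param tr a [tract()].
#' @param path output path ending in .trk or .tck.
#' @export
write_streamlines <- function(tr, path) {
  if (length(tr$streamlines) == 0L)
    warning("writing an empty tract: ", path)
  if (grepl("\\.tck$", path)) write_tck(tr, path) else write_trk(tr, path)
  invisible(path)
}

#' @rdname write_streamlines
#' @param grid grid to attach to the tract on read (TCK stores none).
#' @export
read_streamlines <- function(path, grid = NULL) {
  if (grepl("\\.tck$", path)) read_tck(path, grid) else read_trk(path, grid)
}

write_trk <- function(tr, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)            # id_string[6]
  writeBin(as.integer(tr$grid$dim), con, size = 2L)          # dim[3]
  writeBin(as.numeric(tr$grid$spacing), con, size = 4L)      # voxel_size[3]
  writeBin(as.numeric(tr$grid$origin), con, size = 4L)       # origin[3]
  writeBin(0L, con, size = 2L)                               # n_scalars
  writeBin(raw(200), con)                                    # scalar names
  writeBin(0L, con, size = 2L)                               # n_properties
  writeBin(raw(200), con)                                    # property names
  m <- diag(4); m[1:3, 1:3] <- diag(tr$grid$spacing)
  m[1:3, 4] <- tr$grid$origin
  writeBin(as.numeric(t(m)), con, size = 4L)                 # vox_to_ras
  writeBin(raw(444), con)                                    # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0)), con)              # voxel_order
  writeBin(raw(4), con)                                      # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L)  # orientation
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # inverts/swaps
  writeBin(length(tr$streamlines), con, size = 4L)           # n_count
  writeBin(2L, con, size = 4L)                               # version
  writeBin(1000L, con, size = 4L)                            # hdr_size
  for (s in tr$streamlines) {
    writeBin(nrow(s), con, size = 4L)
    writeBin(as.numeric(t(s)), con, size = 4L)
  }
}

read_trk <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (id != "TRACK") stop("not a TRK file: ", path)
  dims <- readBin(con, "integer", 3L, size = 2L)
  spacing <- readBin(con, "numeric", 3L, size = 4L)
  origin <- readBin(con, "numeric", 3L, size = 4L)
  n_scalars <- readBin(con, "integer", 1L, size = 2L)
  invisible(readBin(con, "raw", 200L))
  n_props <- readBin(con, "integer", 1L, size = 2L)
  invisible(readBin(con, "raw", 200L + 64L + 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", 1L, size = 4L)
  invisible(readBin(con, "integer", 2L, size = 4L))  # version, hdr_size
  streamlines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1L, size = 4L)
    pts <- readBin(con, "numeric", np * (3L + n_scalars), size = 4L)
    if (n_props > 0L) invisible(readBin(con, "numeric", n_props, size = 4L))
    streamlines[[i]] <- matrix(pts, ncol = 3L + n_scalars,
                               byrow = TRUE)[, 1:3, drop = FALSE]
  }
  if (is.null(grid)) grid <- im_grid(dims, spacing, origin)
  tract(streamlines, grid)
}

write_tck <- function(tr, path) {
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(tr$streamlines)))
  # fixed-width offset field so the header length is known before writing
  offset_line <- "file: . OFFSET0000"
  n <- sum(nchar(c(hdr, offset_line, "END"))) + length(hdr) + 2L
  hdr <- c(hdr, sprintf("file: . %10d", n), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  for (s in tr$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L)
    writeBin(rep(NaN, 3), con, size = 4L)
  }
  writeBin(rep(Inf, 3), con, size = 4L)
}

read_tck <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ch <- character()
    repeat {
      b <- readBin(con, "raw", 1L)
      if (rawToChar(b) == "\n") break
      ch <- c(ch, rawToChar(b))
    }
    line <- paste(ch, collapse = "")
    if (line == "END") break
    lines <- c(lines, line)
  }
  off_line <- grep("^file:", lines, value = TRUE)
  off <- as.integer(sub("^file: \\. +", "", off_line))
  seek(con, off)
  vals <- readBin(con, "numeric", file.size(path), size = 4L)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  ends <- which(!is.finite(pts[, 1]))
  streamlines <- list(); start <- 1L
  for (e in ends) {
    if (e > start) streamlines <- c(streamlines,
                                    list(pts[start:(e - 1L), , drop = FALSE]))
    start <- e + 1L
    if (is.infinite(pts[e, 1])) break
  }
  if (is.null(grid)) grid <- im_grid(c(1L, 1L, 1L), 1)
  tract(streamlines, grid)
}
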