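#' Cohort manifests
#'
#' One row per subject-timepoint scan: subject id, genotype ("mutant" or
#' "wildtype"), timepoint ("baseline" or "followup"), scan date, path to the
#' DWI volume and the quality-check verdict. Subject x timepoint pairs must
#' be unique and each subject contributes at most one baseline and one
#' follow-up row.
#'
#' @param df a data.frame with columns subject_id, genotype, timepoint,
#'   scan_date, dwi_path, included.
#' @return The validated data.frame, classed `cohort_manifest`.
#' @export
cohort_manifest <- function(df) {
  need <- c("subject_id", "genotype", "timepoint", "scan_date",
            "dwi_path", "included")
  if (!all(need %in% names(df)))
    stop("manifest missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!all(df$genotype %in% c("mutant", "wildtype")))
    stop("genotype must be 'mutant' or 'wildtype'")
  if (!all(df$timepoint %in% c("baseline", "followup")))
    stop("timepoint must be 'baseline' or 'followup'")
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key))
    stop("duplicate subject x timepoint rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  df$scan_date <- as.Date(df$scan_date)
  df$included <- as.logical(df$included)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Read / write a cohort manifest (TSV)
#' @param path TSV file path.
#' @export
read_manifest <- function(path) {
  cohort_manifest(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cluster table (CSV)
#'
#' Columns: id, size_voxels, bregma_cor, bregma_hor, bregma_sag, p, label;
#' peak coordinates in stereotaxic mm, rows sorted by descending size. An
#' empty table yields a header-only CSV.
#'
#' @param clusters a `cluster_table` data.frame from [cluster_filter()].
#' @param path CSV file path.
#' @param config optional `pipeline_config`; its hash is recorded in a
#'   comment header line.
#' @export
write_cluster_table <- function(clusters, path, config = NULL) {
  cols <- c("id", "size_voxels", "bregma_cor", "bregma_hor", "bregma_sag",
            "p", "label")
  df <- as.data.frame(clusters)[, cols, drop = FALSE]
  if (nrow(df) > 1L) df <- df[order(-df$size_voxels), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# dtipipe cluster table, config ",
                      config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read / write spherical ROI specifications (TSV)
#'
#' Columns: name, cor, hor, sag (BREGMA mm), radius_mm, side
#' (left/right/bilateral).
#' @param path TSV path.
#' @export
read_roi_specs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "cor", "hor", "sag", "radius_mm", "side")
  if (!all(need %in% names(df)))
    stop("ROI spec missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$radius_mm <= 0)) stop("ROI radius must be > 0")
  df
}

#' @rdname read_roi_specs
#' @param rois ROI spec data.frame.
#' @export
write_roi_specs <- function(rois, path) {
  utils::write.table(rois, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write landmark files (TSV: name, x, y, z in mm)
#' @param path TSV path.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "z") %in% names(df)))
  df
}

#' @rdname read_landmarks
#' @param landmarks data.frame with name, x, y, z.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.table(landmarks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
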