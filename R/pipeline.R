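#' Run the preprocessing cascade on a cohort
#'
#' Quality-checks every scan, fits tensors in native space, computes native
#' metric maps, and builds the study-specific FA/b0 templates with one
#' subject transform per scan. Scans failing the quality check are marked
#' `included = FALSE` in the returned manifest and excluded from template
#' building.
#'
#' @param cohort a cohort as returned by [simulate_cohort()]: `manifest`
#'   plus named `stacks` (and, for simulated cohorts, `truths` providing
#'   subject landmarks).
#' @param config a [pipeline_config()].
#' @param landmarks optional named list of subject landmark data.frames
#'   (defaults to the simulation ground-truth landmarks).
#' @param fixed_landmarks template-side landmarks (defaults to
#'   [default_landmarks()] of the first stack's grid).
#' @return A list: `manifest`, `space` (a [template_space()]),
#'   `transforms`, `fields` (native `tensor_field`s), `native_metrics`
#'   (per scan: named list of four native [metric_map()]s), `qc`,
#'   `template_fit` (correlations, n_iter, converged).
#' @export
process_cohort <- function(cohort, config = pipeline_config(),
                           landmarks = NULL, fixed_landmarks = NULL) {
  manifest <- cohort$manifest
  stacks <- cohort$stacks
  if (is.null(landmarks) && !is.null(cohort$truths))
    landmarks <- lapply(cohort$truths, `[[`, "landmarks")
  qc <- lapply(stacks, quality_check, config = config)
  for (r in seq_len(nrow(manifest))) {
    nm <- paste(manifest$subject_id[r], manifest$timepoint[r], sep = "_")
    if (qc[[nm]]$verdict != "pass") manifest$included[r] <- FALSE
  }
  keep <- paste(manifest$subject_id, manifest$timepoint,
                sep = "_")[manifest$included]
  fields <- lapply(stacks[keep], fit_tensor,
                   weighted = config$weighted_fit)
  native_metrics <- lapply(fields, compute_metrics)
  fa_maps <- lapply(native_metrics, `[[`, "FA")
  b0_maps <- lapply(seq_along(fields), function(i)
    metric_map(fields[[i]]$S0, "b0", fields[[i]]$grid, "native",
               stacks[keep][[i]]$subject_id,
               stacks[keep][[i]]$timepoint))
  names(b0_maps) <- keep
  if (is.null(fixed_landmarks))
    fixed_landmarks <- default_landmarks(fields[[1]]$grid)
  tmpl <- build_templates(fa_maps, b0_maps, landmarks[keep],
                          fixed_landmarks, config)
  list(manifest = manifest, space = tmpl$space,
       transforms = tmpl$transforms, fields = fields,
       native_metrics = native_metrics, qc = qc,
       template_fit = tmpl[c("correlations", "n_iter", "converged")])
}

#' Template-space metric maps of a processed cohort
#'
#' Warps each included scan's native metric map onto the template grid and
#' (by default) smooths it with the configured Gaussian kernel.
#'
#' @param res result of [process_cohort()].
#' @param metric one of "FA", "AD", "RD", "MD".
#' @param smooth apply [smooth_map()] at `config$smoothing_fwhm`.
#' @param config a [pipeline_config()].
#' @return Named list of template-space [metric_map()]s.
#' @export
template_metric_maps <- function(res, metric, smooth = TRUE,
                                 config = pipeline_config()) {
  out <- lapply(names(res$transforms), function(nm) {
    m <- warp_map(res$native_metrics[[nm]][[metric]],
                  res$transforms[[nm]], res$space$grid)
    if (smooth) m <- smooth_map(m, config$smoothing_fwhm) else m
  })
  names(out) <- names(res$transforms)
  out
}

#' Template-space tensor fields of a processed cohort
#'
#' @param res result of [process_cohort()].
#' @return List of n x 6 tensor matrices on the template grid, ready for
#'   [average_dataset()].
#' @export
template_tensor_fields <- function(res) {
  lapply(names(res$transforms), function(nm)
    warp_tensor_field(res$fields[[nm]], res$transforms[[nm]],
                      res$space$grid))
}

#' Dice overlap between a cluster and a ground-truth mask
#'
#' @param labels cluster-label array (e.g. `attr(clusters, "labels")`).
#' @param truth logical ground-truth array of the same dimensions.
#' @param cluster_id which cluster (default: union of all).
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(labels, truth, cluster_id = NULL) {
  sel <- if (is.null(cluster_id)) labels > 0L else labels == cluster_id
  denom <- sum(sel) + sum(truth)
  if (denom == 0L) return(0)
  2 * sum(sel & truth) / denom
}

#' Write a simulated cohort to disk (NIfTI + gradients + manifest)
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest with `dwi_path` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  for (r in seq_len(nrow(man))) {
    nm <- paste(man$subject_id[r], man$timepoint[r], sep = "_")
    base <- file.path(dir, nm)
    write_dwi(cohort$stacks[[nm]], paste0(base, ".nii.gz"),
              paste0(base, ".bval"), paste0(base, ".bvec"))
    write_landmarks(cohort$truths[[nm]]$landmarks,
                    paste0(base, "_landmarks.tsv"))
    man$dwi_path[r] <- paste0(base, ".nii.gz")
  }
  write_manifest(man, file.path(dir, "manifest.tsv"))
  write_landmarks(default_landmarks(native_grid(cohort$spec)),
                  file.path(dir, "template_landmarks.tsv"))
  invisible(man)
}
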