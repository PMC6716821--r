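#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis cascade in one object
#' that serializes losslessly to a YAML file. Lengths are in micrometres
#' unless noted; diffusivities are in mm^2/s throughout the package.
#'
#' @param iso_grid_spacing isogrid spacing in um (default 50).
#' @param smoothing_fwhm Gaussian smoothing full-width-at-half-maximum in um
#'   (default 200, about 2-3x the native in-plane voxel size).
#' @param fa_threshold FA mask threshold for statistics and tracking
#'   (default 0.2).
#' @param fdr_q false-discovery-rate level (default 0.05).
#' @param cluster_min_voxels minimum surviving cluster size (default 256,
#'   the size range of the smoothing kernel).
#' @param template_corr_stop stop template iteration once the minimum
#'   subject-to-template FA correlation exceeds this (default 0.7).
#' @param max_iter maximum template iterations (default 10).
#' @param step_um tracking step length in um (default 25, half an isogrid
#'   voxel).
#' @param angle_max_deg maximum turning angle per step in degrees
#'   (default 45).
#' @param min_track_len_mm minimum streamline length in mm (default 0.5).
#' @param seed_density streamline seeds per eligible voxel (default 1,
#'   placed at voxel centers).
#' @param qc_score_threshold per-volume correlation score below which a DW
#'   volume is flagged by [quality_check()] (default 0.65, the midpoint of
#'   the measured score gap between displaced/dropout volumes and
#'   artefact-free volumes under the simulator's corruption model).
#' @param qc_max_bad_fraction scan fails QC when more than this fraction of
#'   DW volumes is flagged (default 0.1).
#' @param connectivity cluster connectivity, 26 (default) or 6.
#' @param paired_longitudinal paired-by-subject t-test for the
#'   within-genotype follow-up vs baseline contrast (default TRUE).
#' @param welch use Welch instead of pooled-variance t-tests (default FALSE).
#' @param weighted_fit weighted instead of ordinary log-linear tensor fit
#'   (default FALSE).
#' @param fit_after_warp fit tensors on nearest-neighbour-warped DWI instead
#'   of warping native-space metric maps (default FALSE).
#' @param rng_seed integer seed for all simulation randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(iso_grid_spacing = 50,
                            smoothing_fwhm = 200,
                            fa_threshold = 0.2,
                            fdr_q = 0.05,
                            cluster_min_voxels = 256L,
                            template_corr_stop = 0.7,
                            max_iter = 10L,
                            step_um = 25,
                            angle_max_deg = 45,
                            min_track_len_mm = 0.5,
                            seed_density = 1L,
                            qc_score_threshold = 0.65,
                            qc_max_bad_fraction = 0.1,
                            connectivity = 26L,
                            paired_longitudinal = TRUE,
                            welch = FALSE,
                            weighted_fit = FALSE,
                            fit_after_warp = FALSE,
                            rng_seed = 1L) {
  cfg <- list(iso_grid_spacing = iso_grid_spacing,
              smoothing_fwhm = smoothing_fwhm,
              fa_threshold = fa_threshold,
              fdr_q = fdr_q,
              cluster_min_voxels = as.integer(cluster_min_voxels),
              template_corr_stop = template_corr_stop,
              max_iter = as.integer(max_iter),
              step_um = step_um,
              angle_max_deg = angle_max_deg,
              min_track_len_mm = min_track_len_mm,
              seed_density = as.integer(seed_density),
              qc_score_threshold = qc_score_threshold,
              qc_max_bad_fraction = qc_max_bad_fraction,
              connectivity = as.integer(connectivity),
              paired_longitudinal = paired_longitudinal,
              welch = welch,
              weighted_fit = weighted_fit,
              fit_after_warp = fit_after_warp,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (iso_grid_spacing <= 0 || smoothing_fwhm <= 0 || step_um <= 0 ||
        min_track_len_mm <= 0)
      stop("all lengths must be strictly positive")
    if (fa_threshold < 0 || fa_threshold >= 1)
      stop("fa_threshold must lie in [0, 1)")
    if (fdr_q <= 0 || fdr_q >= 1)
      stop("fdr_q must lie in (0, 1)")
    if (!connectivity %in% c(6L, 26L))
      stop("connectivity must be 6 or 26")
  })
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' Round trips are lossless: `read_config(write_config(cfg, f))` equals
#' `cfg` for every field.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Short hash of a configuration, recorded in output file headers
#' @param cfg a `pipeline_config`.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  # small rolling hash; stable across sessions, no extra dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^28
  sprintf("%07x", h)
}
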