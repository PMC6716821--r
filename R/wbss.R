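#' Separable Gaussian smoothing of a 3-D array
#'
#' Boundary-renormalized (truncated kernel weights are rescaled to sum to
#' one), so constant arrays are exactly preserved.
#'
#' @param a 3-D array.
#' @param sigma_vox Gaussian sigma in voxels, scalar or per-axis.
#' @export
gauss_smooth3 <- function(a, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    K <- exp(-outer(seq_len(n), seq_len(n), `-`)^2 / (2 * s^2))
    K[K < exp(-9 / 2)] <- 0            # truncate at 3 sigma
    K <- K / rowSums(K)
    a <- apply_axis(a, ax, K)
  }
  a
}

# multiply along one axis: out[i,...] = sum_j K[i,j] a[j,...]
apply_axis <- function(a, ax, K) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), d[ax])
  out <- K %*% m
  aperm(array(out, d[perm]), order(perm))
}

#' Smooth a metric map with a Gaussian of given FWHM
#'
#' sigma = fwhm / (2 sqrt(2 ln 2)); at the default 200 um FWHM on a 50 um
#' isogrid this is about 1.70 voxels. With a mask, off-mask voxels are
#' excluded and kernel weights renormalized (masked-normalized
#' convolution); off-mask output is 0.
#'
#' @param map a [metric_map()].
#' @param fwhm_um full width at half maximum in um (> 0).
#' @param mask optional logical array.
#' @return The smoothed [metric_map()].
#' @export
smooth_map <- function(map, fwhm_um = 200, mask = NULL) {
  if (fwhm_um <= 0) stop("fwhm must be > 0")
  sigma_mm <- fwhm_um / (2 * sqrt(2 * log(2))) / 1000
  sigma_vox <- sigma_mm / map$grid$spacing
  if (is.null(mask)) {
    vals <- gauss_smooth3(map$values, sigma_vox)
  } else {
    num <- gauss_smooth3(map$values * mask, sigma_vox)
    den <- gauss_smooth3(mask * 1, sigma_vox)
    vals <- array(0, dim(map$values))
    inside <- mask & den > 0
    vals[inside] <- num[inside] / den[inside]
  }
  metric_map(vals, map$metric, map$grid, map$space, map$subject_id,
             map$timepoint)
}

#' Voxelwise two-sample t-test between groups of maps
#'
#' Equal-variance (pooled) Student t by default, two-sided p-values with
#' df = nA + nB - 2; Welch via `welch = TRUE`. Zero-variance voxels with
#' equal means give t = 0, p = 1.
#'
#' @param groupA,groupB lists of [metric_map()]s (or 3-D arrays) on a
#'   common grid, >= 2 per group.
#' @param mask logical array restricting the analysis.
#' @param welch unequal-variance test.
#' @return A `stat_map`: list with `t`, `p` (arrays; NA off mask), `mask`,
#'   `df`, `contrast`.
#' @export
voxelwise_ttest <- function(groupA, groupB, mask, welch = FALSE,
                            contrast = "") {
  A <- maps_to_matrix(groupA); B <- maps_to_matrix(groupB)
  if (ncol(A) < 2L || ncol(B) < 2L) stop("need >= 2 maps per group")
  nA <- ncol(A); nB <- ncol(B)
  mv <- as.vector(mask)
  A <- A[mv, , drop = FALSE]; B <- B[mv, , drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- ifelse(se2 > 0,
                 se2^2 / (vA^2 / (nA^2 * (nA - 1)) +
                            vB^2 / (nB^2 * (nB - 1))), 1)
    tv <- tstat_guarded(mA - mB, sqrt(se2))
    pv <- 2 * stats::pt(-abs(tv), df)
  } else {
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
    tv <- tstat_guarded(mA - mB, sqrt(sp2 * (1 / nA + 1 / nB)))
    pv <- 2 * stats::pt(-abs(tv), df)
  }
  stat_map_from_vectors(tv, pv, mask, if (welch) NA else df, contrast)
}

#' Voxelwise paired t-test (subject-matched maps)
#'
#' @param group1,group2 lists of maps in matching subject order.
#' @inheritParams voxelwise_ttest
#' @export
voxelwise_paired_ttest <- function(group1, group2, mask, contrast = "") {
  A <- maps_to_matrix(group1); B <- maps_to_matrix(group2)
  if (ncol(A) != ncol(B)) stop("paired groups must have equal size")
  if (ncol(A) < 2L) stop("need >= 2 pairs")
  n <- ncol(A)
  mv <- as.vector(mask)
  D <- A[mv, , drop = FALSE] - B[mv, , drop = FALSE]
  mD <- rowMeans(D)
  sD <- sqrt(rowSums((D - mD)^2) / (n - 1))
  tv <- tstat_guarded(mD, sD / sqrt(n))
  pv <- 2 * stats::pt(-abs(tv), n - 1)
  stat_map_from_vectors(tv, pv, mask, n - 1, contrast)
}

tstat_guarded <- function(num, se) {
  ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * Inf))
}

stat_map_from_vectors <- function(tv, pv, mask, df, contrast) {
  d <- dim(mask)
  tarr <- array(NA_real_, d); parr <- array(NA_real_, d)
  tarr[mask] <- tv
  parr[mask] <- ifelse(is.infinite(tv), 0, pv)
  structure(list(t = tarr, p = parr, mask = mask, df = df,
                 contrast = contrast),
            class = "stat_map")
}

maps_to_matrix <- function(maps) {
  do.call(cbind, lapply(maps, function(m)
    as.vector(if (inherits(m, "metric_map")) m$values else m)))
}

#' Longitudinal per-day rate-of-change map
#'
#' DeltaDM = (DM(t1) - DM(t2)) / (t1 - t2) * 1 day, voxelwise, where t1 and
#' t2 are the baseline and follow-up scan dates: map differences linearly
#' normalized to a common one-day interval so subjects with different
#' inter-scan intervals are comparable.
#'
#' @param baseline,followup [metric_map()]s of one subject on a common
#'   grid.
#' @param t1,t2 scan [Date]s (t1 != t2).
#' @return A [metric_map()] in metric units per day (metric label suffixed
#'   "_delta").
#' @export
delta_map <- function(baseline, followup, t1, t2) {
  t1 <- as.Date(t1); t2 <- as.Date(t2)
  dt <- as.numeric(t1 - t2)
  if (dt == 0) stop("t1 and t2 must differ")
  vals <- (baseline$values - followup$values) / dt
  metric_map(vals, paste0(baseline$metric, "_delta"), baseline$grid,
             baseline$space, baseline$subject_id, "delta")
}

#' Benjamini-Hochberg FDR correction over a mask
#'
#' Step-up procedure over all mask voxels: sort p(1) <= ... <= p(m), find
#' the largest k with p(k) <= k q / m and reject every voxel with
#' p <= p(k); no rejections if no such k exists.
#'
#' @param p p-value array.
#' @param q FDR level in (0, 1).
#' @param mask logical array; an empty mask yields no rejections.
#' @return Logical rejection array (FALSE off mask).
#' @export
fdr_correct <- function(p, q = 0.05, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(p)
  rej <- array(FALSE, dim(p))
  pm <- p[mask]
  if (length(pm) == 0L) return(rej)
  rej[mask] <- stats::p.adjust(pm, method = "BH") <= q
  rej
}

#' Connected-component cluster filtering of a rejection field
#'
#' Labels maximal connected components (26-connectivity by default, the
#' neuroimaging standard; 6 available), drops components below `min_size`,
#' and reports survivors with size, peak (minimum-p) voxel, stereotaxic
#' peak coordinates, minimum p and mean t.
#'
#' @param rej logical rejection array.
#' @param min_size minimum cluster size in voxels (default 256).
#' @param space a [template_space()] for BREGMA reporting; `NULL` uses a
#'   bregma at the grid center.
#' @param p,t optional matching arrays for peak localization and mean t.
#' @param connectivity 26 (default) or 6.
#' @return A `cluster_table` data.frame with columns id, size_voxels,
#'   peak_i, peak_j, peak_k, bregma_cor, bregma_hor, bregma_sag, p, mean_t,
#'   label; attribute `"labels"` holds the full cluster-label array.
#' @export
cluster_filter <- function(rej, min_size = 256L, space = NULL, p = NULL,
                           t = NULL, connectivity = 26L) {
  lab <- label_components(rej, connectivity)
  empty <- data.frame(id = integer(), size_voxels = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), bregma_cor = numeric(),
                      bregma_hor = numeric(), bregma_sag = numeric(),
                      p = numeric(), mean_t = numeric(),
                      label = character())
  class(empty) <- c("cluster_table", "data.frame")
  if (max(lab) == 0L) { attr(empty, "labels") <- lab; return(empty) }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) {
    lab[] <- 0L
    attr(empty, "labels") <- lab
    return(empty)
  }
  if (is.null(space)) {
    grid <- im_grid(dim(rej), if (is.null(attr(rej, "spacing"))) 1
                    else attr(rej, "spacing"))
    space <- template_space(grid)
  }
  rows <- lapply(seq_along(keep), function(i) {
    cl <- keep[i]
    vox_lin <- which(lab == cl)
    pv <- if (is.null(p)) rep(NA_real_, length(vox_lin)) else p[vox_lin]
    peak <- vox_lin[if (all(is.na(pv))) 1L else which.min(pv)]
    pk <- arrayInd(peak, dim(rej))
    br <- vox_to_bregma(space, pk)
    data.frame(id = i, size_voxels = sizes[cl],
               peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
               bregma_cor = br[1], bregma_hor = br[2], bregma_sag = br[3],
               p = if (all(is.na(pv))) NA_real_ else min(pv, na.rm = TRUE),
               mean_t = if (is.null(t)) NA_real_
                        else mean(t[vox_lin], na.rm = TRUE),
               label = "")
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size_voxels), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  relab <- array(0L, dim(rej))
  for (i in seq_len(nrow(out)))
    relab[lab == keep[order(-sizes[keep])][i]] <- i
  attr(out, "labels") <- relab
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Label connected components of a binary 3-D array
#'
#' @param x logical array.
#' @param connectivity 26 or 6.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(x, connectivity = 26L) {
  d <- dim(x)
  lab <- array(0L, d)
  fg <- which(x)
  if (length(fg) == 0L) return(lab)
  rank <- array(0L, d)
  rank[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offsets <- neighbor_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    nb <- co + matrix(offsets[r, ], nrow(co), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) +
      d[1] * d[2] * (nb[ok, 3] - 1)
    nb_rank <- rank[nb_lin]
    hit <- nb_rank > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        cbind(rank[fg[ok]][hit], nb_rank[hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# positive half of the neighbourhood (each undirected adjacency once)
neighbor_offsets <- function(connectivity) {
  if (connectivity == 6L)
    return(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
      (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]
}

#' Run one whole-brain spatial statistics contrast
#'
#' Dispatches the study's four analyses on normalized smoothed maps:
#' (a) mutant vs wildtype at baseline, (b) mutant vs wildtype at follow-up,
#' (c) mutant follow-up vs baseline (paired by subject by default),
#' (d) per-day rate-of-change (DeltaDM) mutant vs wildtype. Each is
#' followed by FDR correction over the FA-template mask (FA >=
#' `config$fa_threshold`) and cluster-size filtering.
#'
#' @param maps named list of smoothed template-space [metric_map()]s, names
#'   `<subject>_<timepoint>`.
#' @param manifest the [cohort_manifest()].
#' @param contrast one of "a", "b", "c", "d".
#' @param space the [template_space()] (supplies the FA-template mask).
#' @param config a [pipeline_config()].
#' @return A list: `stat` (stat_map), `rejections` (logical array),
#'   `clusters` (cluster_table).
#' @export
run_wbss <- function(maps, manifest, contrast, space,
                     config = pipeline_config()) {
  mask <- space$fa_template >= config$fa_threshold
  man <- manifest[manifest$included, , drop = FALSE]
  pick <- function(geno, tp) {
    sel <- man$subject_id[man$genotype == geno & man$timepoint == tp]
    nm <- paste(sel, tp, sep = "_")
    maps[nm[nm %in% names(maps)]]
  }
  stat <- switch(contrast,
    a = voxelwise_ttest(pick("mutant", "baseline"),
                        pick("wildtype", "baseline"), mask,
                        welch = config$welch, contrast = "a"),
    b = voxelwise_ttest(pick("mutant", "followup"),
                        pick("wildtype", "followup"), mask,
                        welch = config$welch, contrast = "b"),
    c = {
      pairs <- longitudinal_pairs(man, maps, "mutant")
      if (config$paired_longitudinal)
        voxelwise_paired_ttest(pairs$followup, pairs$baseline, mask,
                               contrast = "c")
      else voxelwise_ttest(pairs$followup, pairs$baseline, mask,
                           welch = config$welch, contrast = "c")
    },
    d = {
      dm <- lapply(c("mutant", "wildtype"), function(g) {
        pr <- longitudinal_pairs(man, maps, g)
        lapply(seq_along(pr$baseline), function(i)
          delta_map(pr$baseline[[i]], pr$followup[[i]],
                    pr$t1[i], pr$t2[i]))
      })
      voxelwise_ttest(dm[[1]], dm[[2]], mask, welch = config$welch,
                      contrast = "d")
    },
    stop("contrast must be one of a, b, c, d"))
  rej <- fdr_correct(stat$p, config$fdr_q, mask)
  clusters <- cluster_filter(rej, config$cluster_min_voxels, space,
                             p = stat$p, t = stat$t,
                             connectivity = config$connectivity)
  list(stat = stat, rejections = rej, clusters = clusters)
}

longitudinal_pairs <- function(man, maps, genotype) {
  subs <- unique(man$subject_id[man$genotype == genotype])
  base <- list(); fup <- list(); t1 <- as.Date(character())
  t2 <- as.Date(character())
  for (s in subs) {
    nb <- paste(s, "baseline", sep = "_")
    nf <- paste(s, "followup", sep = "_")
    hb <- nb %in% names(maps) &
      any(man$subject_id == s & man$timepoint == "baseline")
    hf <- nf %in% names(maps) &
      any(man$subject_id == s & man$timepoint == "followup")
    if (!hb || !hf) {
      warning("subject ", s, " lacks a timepoint; excluded from ",
              "longitudinal contrast")
      next
    }
    base[[length(base) + 1L]] <- maps[[nb]]
    fup[[length(fup) + 1L]] <- maps[[nf]]
    t1 <- c(t1, man$scan_date[man$subject_id == s &
                                man$timepoint == "baseline"])
    t2 <- c(t2, man$scan_date[man$subject_id == s &
                                man$timepoint == "followup"])
  }
  list(baseline = base, followup = fup, t1 = t1, t2 = t2)
}
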