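#' Spherical ROI means
#'
#' Mean of a metric over the voxels whose centers lie within the ROI radius
#' of its stereotaxic center (no partial-volume weighting). Bilateral ROIs
#' take the union of the sphere and its sagittal mirror image.
#'
#' @param maps named list of template-space [metric_map()]s.
#' @param roi one row of an ROI spec: list/data.frame with `name`, `cor`,
#'   `hor`, `sag` (BREGMA mm), `radius_mm`, `side`
#'   ("left"/"right"/"bilateral").
#' @param space the [template_space()] fixing the BREGMA convention.
#' @return Named numeric vector of per-map ROI means.
#' @export
roi_means <- function(maps, roi, space) {
  grid <- space$grid
  pts_vox <- cbind(rep(seq_len(grid$dim[1]), times = prod(grid$dim[2:3])),
                   rep(rep(seq_len(grid$dim[2]), each = grid$dim[1]),
                       times = grid$dim[3]),
                   rep(seq_len(grid$dim[3]),
                       each = prod(grid$dim[1:2])))
  br <- vox_to_bregma(space, pts_vox)
  ctr <- c(roi$cor, roi$hor, roi$sag)
  inside <- colSums((t(br) - ctr)^2) <= roi$radius_mm^2
  if (identical(roi$side, "bilateral")) {
    ctr2 <- ctr * c(1, 1, -1)
    inside <- inside | colSums((t(br) - ctr2)^2) <= roi$radius_mm^2
  }
  if (!any(inside))
    stop("ROI '", roi$name, "' contains no voxel centers")
  vapply(maps, function(m) mean(m$values[inside]), 0)
}

#' Per-cell summary statistics for a 2 x 2 design
#'
#' @param genotype,age factor-level labels.
#' @param n cell size (>= 2).
#' @param mean cell mean.
#' @param dispersion cell dispersion (sd or sem).
#' @param dispersion_kind "sd" (default) or "sem"; sem is converted via
#'   sd = sem * sqrt(n).
#' @return A one-row data.frame of class `cell_summary`.
#' @export
cell_summary <- function(genotype, age, n, mean, dispersion,
                         dispersion_kind = "sd") {
  if (n < 2L) stop("cell n must be >= 2")
  if (dispersion < 0) stop("dispersion must be >= 0")
  sd <- if (dispersion_kind == "sem") dispersion * sqrt(n) else dispersion
  structure(data.frame(genotype = genotype, age = age, n = as.integer(n),
                       mean = mean, sd = sd),
            class = c("cell_summary", "data.frame"))
}

#' Two-way ANOVA (2 x 2, Type III) with Tukey post-hoc comparisons
#'
#' Accepts either raw observations or per-cell summaries; the two paths
#' agree exactly because the Type III sums of squares of a 2 x 2 design are
#' functions of (n, mean, sd) per cell alone. With unequal cell sizes the
#' main-effect contrasts are unweighted marginal mean differences
#' (Type III); with balanced cells this reduces to the classical two-way
#' decomposition. Pooled MSE = sum (n_ij - 1) s_ij^2 / sum (n_ij - 1);
#' each F has df (1, sum (n_ij - 1)). Pairwise cell comparisons use the
#' Tukey studentized-range distribution with 4 groups.
#'
#' @param data either a data.frame of raw values with columns `genotype`,
#'   `age`, `value`, or a data.frame of 4 cell summaries with columns
#'   `genotype`, `age`, `n`, `mean`, and `sd` (or `dispersion` +
#'   `dispersion_kind`).
#' @return An `anova_result`: list with `effects` (data.frame: effect, F,
#'   df1, df2, p), `tukey` (pairwise data.frame with adjusted p), `mse`,
#'   `cells`.
#' @export
anova_two_way <- function(data) {
  if ("value" %in% names(data)) {
    cells <- do.call(rbind, lapply(split(data,
        list(data$genotype, data$age), drop = TRUE), function(g) {
      if (nrow(g) < 2L) stop("every cell needs n >= 2")
      data.frame(genotype = g$genotype[1], age = g$age[1], n = nrow(g),
                 mean = mean(g$value), sd = stats::sd(g$value))
    }))
  } else {
    cells <- as.data.frame(data)
    if (!"sd" %in% names(cells)) {
      if (!all(c("dispersion", "dispersion_kind") %in% names(cells)))
        stop("cell summaries need an 'sd' column (or dispersion + kind)")
      cells$sd <- ifelse(cells$dispersion_kind == "sem",
                         cells$dispersion * sqrt(cells$n),
                         cells$dispersion)
    }
    if (any(is.na(cells$sd))) stop("missing sd in cell summaries")
    if (any(cells$n < 2L)) stop("every cell needs n >= 2")
  }
  g_lev <- sort(unique(cells$genotype)); a_lev <- sort(unique(cells$age))
  if (length(g_lev) != 2L || length(a_lev) != 2L || nrow(cells) != 4L)
    stop("design must be exactly 2 x 2")
  # order cells (g1a1, g1a2, g2a1, g2a2)
  key <- paste(cells$genotype, cells$age)
  ord <- match(c(paste(g_lev[1], a_lev[1]), paste(g_lev[1], a_lev[2]),
                 paste(g_lev[2], a_lev[1]), paste(g_lev[2], a_lev[2])),
               key)
  cells <- cells[ord, ]
  n <- cells$n; m <- cells$mean; s <- cells$sd
  df_err <- sum(n - 1L)
  mse <- sum((n - 1L) * s^2) / df_err
  # Type III contrasts on cell means (g1a1, g1a2, g2a1, g2a2)
  contrasts <- list(
    genotype = c(0.5, 0.5, -0.5, -0.5),
    age = c(0.5, -0.5, 0.5, -0.5),
    interaction = c(1, -1, -1, 1))
  effects <- do.call(rbind, lapply(names(contrasts), function(e) {
    cvec <- contrasts[[e]]
    L <- sum(cvec * m)
    varfac <- sum(cvec^2 / n)
    Fv <- L^2 / (varfac * mse)
    data.frame(effect = e, F = Fv, df1 = 1L, df2 = df_err,
               p = stats::pf(Fv, 1L, df_err, lower.tail = FALSE))
  }))
  # Tukey HSD among the four cell means
  lbl <- paste(cells$genotype, cells$age, sep = ":")
  cmp <- utils::combn(4L, 2L)
  tukey <- do.call(rbind, lapply(seq_len(ncol(cmp)), function(k) {
    i <- cmp[1, k]; j <- cmp[2, k]
    se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    qv <- abs(m[i] - m[j]) / se
    data.frame(comparison = paste(lbl[i], "vs", lbl[j]),
               diff = m[i] - m[j],
               p_adj = stats::ptukey(qv, 4L, df_err, lower.tail = FALSE))
  }))
  structure(list(effects = effects, tukey = tukey, mse = mse,
                 cells = cells),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (Type III), df error =", x$effects$df2[1], "\n")
  for (r in seq_len(nrow(x$effects)))
    cat(sprintf("  %-12s F(1,%d) = %6.2f, p = %.4g\n",
                x$effects$effect[r], x$effects$df2[r], x$effects$F[r],
                x$effects$p[r]))
  invisible(x)
}

#' Group bar-plot statistics: cell means, SEM and pairwise tests
#'
#' Per (genotype x timepoint) cell mean and standard error of the mean,
#' plus two-sided two-sample t-tests for the displayed comparisons
#' (mutant vs wildtype at each timepoint), flagged at p < 0.05.
#'
#' @param values data.frame with columns `genotype`, `timepoint`, `value`
#'   (>= 2 values per cell).
#' @return A list: `cells` (mean, sem, n per cell) and `tests`
#'   (timepoint, t, df, p, significant).
#' @export
group_bar_stats <- function(values) {
  cells <- do.call(rbind, lapply(split(values,
      list(values$genotype, values$timepoint), drop = TRUE), function(g)
    data.frame(genotype = g$genotype[1], timepoint = g$timepoint[1],
               n = nrow(g), mean = mean(g$value),
               sem = stats::sd(g$value) / sqrt(nrow(g)))))
  rownames(cells) <- NULL
  tests <- do.call(rbind, lapply(unique(values$timepoint), function(tp) {
    a <- values$value[values$timepoint == tp &
                        values$genotype == "mutant"]
    b <- values$value[values$timepoint == tp &
                        values$genotype == "wildtype"]
    if (length(a) < 2L || length(b) < 2L)
      return(NULL)
    if (stats::sd(c(a, b)) == 0) {
      p <- 1; tv <- 0; df <- length(a) + length(b) - 2
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      p <- tt$p.value; tv <- unname(tt$statistic)
      df <- unname(tt$parameter)
    }
    data.frame(timepoint = tp, t = tv, df = df, p = p,
               significant = p < 0.05)
  }))
  list(cells = cells, tests = tests)
}
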