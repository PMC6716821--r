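# Independent brute-force oracles used to validate the package's
# implementations, written from the defining formulas, not from the code
# under test.

# Benjamini-Hochberg by exhaustive all-k scan: reject the k* smallest
# p-values where k* is the largest k with p_(k) <= k*q/m.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# Connected-component labeling by explicit stack-based flood fill.
flood_fill_labels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[idx[r, 1], idx[r, 2], idx[r, 3]] != 0L) next
    cur <- cur + 1L
    stack <- list(idx[r, ])
    lab[idx[r, 1], idx[r, 2], idx[r, 3]] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        nb <- v + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] &&
            lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cur
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# Classical raw-data two-way ANOVA sums of squares for a 2 x 2 design via
# explicit Type III model comparison on cell-mean contrasts.
fa_formula <- function(ev) {
  md <- mean(ev)
  sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
}

# A tiny noise-free single-voxel stack for closed-form fit checks.
one_voxel_stack <- function(D6, s0 = 1000, grad = gradient_scheme()) {
  G <- t(grad$bvecs)
  batt <- grad$bvals *
    (G[, 1]^2 * D6[1] + G[, 2]^2 * D6[2] + G[, 3]^2 * D6[3] +
       2 * G[, 1] * G[, 2] * D6[4] + 2 * G[, 1] * G[, 3] * D6[5] +
       2 * G[, 2] * G[, 3] * D6[6])
  sig <- s0 * exp(-batt)
  dwi_stack(array(rep(sig, each = 8), c(2, 2, 2, length(sig))),
            voxel_um = c(100, 100, 100), bvals = grad$bvals,
            bvecs = grad$bvecs)
}

# Straight +x direction field on an isotropic grid.
straight_field <- function(dim = c(40L, 20L, 20L), spacing = 0.05) {
  g <- im_grid(dim, spacing)
  dirarr <- array(0, c(g$dim, 3L))
  dirarr[, , , 1] <- 1
  structure(list(dir = dirarr, fa = array(0.5, g$dim), grid = g,
                 fa_threshold = 0.2), class = "direction_field")
}

# Quarter-circle arc field: tangent vectors (-y, x, 0)/r inside an annulus
# of radius R clipped to the first quadrant.
arc_field <- function(R = 1, spacing = 0.02, width = 0.15) {
  n_xy <- ceiling(2 * (R + 2 * width) / spacing)
  g <- im_grid(c(n_xy, n_xy, 7L), spacing)
  pts <- grid_coords(g)
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ann <- r > R - width & r < R + width & pts[, 1] >= 0 & pts[, 2] >= 0 &
    abs(pts[, 3]) < 2.5 * spacing
  tang <- cbind(-pts[, 2], pts[, 1], 0) / pmax(r, 1e-9)
  tang[!ann, ] <- 0
  structure(list(dir = array(tang, c(g$dim, 3L)),
                 fa = array(ifelse(ann, 0.5, 0), g$dim), grid = g,
                 fa_threshold = 0.2), class = "direction_field")
}

# Reference cortical layer-V neuron-density dataset (NeuN+ counts per
# 1e5 um^2): four genotype x age cell summaries with published F values
# interaction 14.75, genotype 7.90, age 46.90 (df 1, 9).
neuron_density_cells <- function() {
  rbind(cell_summary("wildtype", "age06", 3, 122.3, 2.7),
        cell_summary("wildtype", "age12", 3, 114.9, 1.9),
        cell_summary("mutant", "age06", 3, 124.8, 5.5),
        cell_summary("mutant", "age12", 4, 98.5, 5.5))
}

# Shared small cohorts, simulated once per test run.
lesion_cohort_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(lesions = list(default_lesion()))
      coh <- simulate_cohort(spec, master_seed = 1)
      cfg <- pipeline_config()
      res <- process_cohort(coh, cfg)
      cache <<- list(spec = spec, cohort = coh, config = cfg, result = res)
    }
    cache
  }
})
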