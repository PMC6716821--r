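test_that("unit impulse smooths to a sampled Gaussian with unit sum", {
  g <- im_grid(c(21L, 21L, 21L), 0.05)     # 50 um isogrid
  vals <- array(0, g$dim)
  vals[11, 11, 11] <- 1
  sm <- smooth_map(metric_map(vals, "FA", g, "template"), fwhm_um = 200)
  sigma_vox <- 200 / (2 * sqrt(2 * log(2))) / 50
  expect_equal(sigma_vox, 1.699, tolerance = 1e-3)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  # compare against the separable sampled Gaussian (kernel truncation and
  # renormalization make tiny differences)
  ax <- (-10):10
  k1 <- exp(-ax^2 / (2 * sigma_vox^2)); k1 <- k1 / sum(k1)
  want <- outer(outer(k1, k1), k1)
  expect_lt(max(abs(sm$values - want)), 1e-4)
})

test_that("smoothing twice approximates one pass at fwhm * sqrt(2)", {
  g <- im_grid(c(24L, 24L, 24L), 0.05)
  set.seed(14)
  m <- metric_map(array(runif(prod(g$dim)), g$dim), "FA", g, "template")
  twice <- smooth_map(smooth_map(m, 200), 200)
  once <- smooth_map(m, 200 * sqrt(2))
  core <- array(FALSE, g$dim); core[6:19, 6:19, 6:19] <- TRUE
  expect_lt(max(abs(twice$values[core] - once$values[core])), 5e-3)
})

test_that("pooled t-test matches the hand-computed {1,2,3} vs {4,5,6} oracle", {
  g <- im_grid(c(2L, 2L, 1L), 0.05)
  mk <- function(v) metric_map(array(v, g$dim), "FA", g, "template")
  A <- lapply(1:3, function(i) mk(i))
  B <- lapply(4:6, function(i) mk(i))
  mask <- array(TRUE, g$dim)
  st <- voxelwise_ttest(A, B, mask)
  expect_equal(st$t[1, 1, 1], -3.674, tolerance = 1e-3)
  expect_equal(st$p[1, 1, 1], 0.02131, tolerance = 1e-3)
  expect_equal(st$df, 4)
})

test_that("voxelwise tests agree with stats::t.test on random data", {
  g <- im_grid(c(6L, 5L, 4L), 0.05)
  set.seed(3)
  A <- lapply(1:5, function(i)
    metric_map(array(rnorm(prod(g$dim)), g$dim), "FA", g, "template"))
  B <- lapply(1:4, function(i)
    metric_map(array(rnorm(prod(g$dim), 0.3), g$dim), "FA", g,
               "template"))
  mask <- array(TRUE, g$dim)
  for (welch in c(FALSE, TRUE)) {
    st <- voxelwise_ttest(A, B, mask, welch = welch)
    for (v in sample(prod(g$dim), 10)) {
      a <- vapply(A, function(m) m$values[v], 0)
      b <- vapply(B, function(m) m$values[v], 0)
      tt <- stats::t.test(a, b, var.equal = !welch)
      expect_equal(st$t[v], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(st$p[v], tt$p.value, tolerance = 1e-10)
    }
  }
  # paired
  stp <- voxelwise_paired_ttest(A[1:4], B, mask)
  for (v in sample(prod(g$dim), 5)) {
    a <- vapply(A[1:4], function(m) m$values[v], 0)
    b <- vapply(B, function(m) m$values[v], 0)
    tt <- stats::t.test(a, b, paired = TRUE)
    expect_equal(stp$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(stp$p[v], tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH rejects all four of p = {0.01, 0.02, 0.03, 0.04} at q = 0.05", {
  g <- im_grid(c(2L, 2L, 1L), 0.05)
  p <- array(c(0.01, 0.02, 0.03, 0.04), g$dim)
  mask <- array(TRUE, g$dim)
  rej <- fdr_correct(p, mask, q = 0.05)
  expect_true(all(rej))
  expect_equal(rej, array(bh_oracle(as.vector(p), 0.05), g$dim),
               ignore_attr = TRUE)
})

test_that("fdr_correct equals the brute-force all-k scan on random fields", {
  set.seed(6)
  g <- im_grid(c(10L, 10L, 10L), 0.05)
  for (i in 1:25) {
    p <- array(runif(prod(g$dim))^sample(1:3, 1), g$dim)
    mask <- array(runif(prod(g$dim)) < 0.8, g$dim)
    rej <- fdr_correct(p, mask, q = 0.05)
    want <- array(FALSE, g$dim)
    want[mask] <- bh_oracle(p[mask], 0.05)
    expect_identical(rej, want)
  }
})

test_that("cluster labels match an independent flood fill (26 and 6)", {
  set.seed(19)
  for (i in 1:6) {
    mask <- array(runif(6000) < 0.25, c(20L, 20L, 15L))
    for (conn in c(26L, 6L)) {
      lab <- label_components(mask, connectivity = conn)
      want <- flood_fill_labels(mask, conn)
      # labels may be permuted; compare component size multisets and
      # co-membership on sampled voxel pairs
      expect_setequal(as.integer(table(lab[lab > 0])),
                      as.integer(table(want[want > 0])))
      on <- which(mask)
      pick <- sample(on, min(200, length(on)))
      expect_identical(outer(lab[pick], lab[pick], "=="),
                       outer(want[pick], want[pick], "=="))
    }
  }
})

test_that("cluster_filter drops clusters below the size floor and sorts", {
  g <- im_grid(c(30L, 30L, 30L), 0.05)
  p <- array(1, g$dim)
  p[2:14, 2:14, 2:14] <- 1e-6        # 2197 voxels
  p[20:22, 20:22, 20:22] <- 1e-6     # 27 voxels, below the floor
  rej <- p < 0.05
  space <- template_space(g)
  cl <- cluster_filter(rej, min_size = 256L, space = space, p = p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size_voxels, 13^3)
  labels <- attr(cl, "labels")
  expect_equal(sum(labels > 0), 13^3)
  # peak is the minimum-p voxel and bregma coordinates are finite
  expect_true(all(is.finite(unlist(cl[, c("bregma_cor", "bregma_hor",
                                          "bregma_sag")]))))
})

test_that("delta maps obey Eq. 1: zero for identical maps, exact scaling", {
  g <- im_grid(c(5L, 5L, 5L), 0.05)
  set.seed(23)
  v1 <- array(runif(prod(g$dim), 0.2, 0.9), g$dim)
  v2 <- array(runif(prod(g$dim), 0.2, 0.9), g$dim)
  m1 <- metric_map(v1, "FA", g, "template", "s", "baseline")
  m2 <- metric_map(v2, "FA", g, "template", "s", "followup")
  t1 <- as.Date("2025-01-01")

  same <- delta_map(m1, metric_map(v1, "FA", g, "template", "s",
                                   "followup"), t1, t1 + 150)
  expect_true(all(same$values == 0))

  d150 <- delta_map(m1, m2, t1, t1 + 150)
  d300 <- delta_map(m1, m2, t1, t1 + 300)
  expect_equal(d150$values, 2 * d300$values, tolerance = 1e-12)
  expect_identical(d150$metric, "FA_delta")

  # worked example: 0.50 -> 0.40 over 150 days = -6.67e-4 / day
  ex <- delta_map(metric_map(array(0.4, g$dim), "FA", g, "template"),
                  metric_map(array(0.5, g$dim), "FA", g, "template"),
                  t1 + 150, t1)
  expect_equal(ex$values[1], (0.5 - 0.4) / (0 - 150), tolerance = 1e-12)

  expect_error(delta_map(m1, m2, t1, t1), "differ")
})

test_that("degenerate voxels produce guarded t statistics", {
  g <- im_grid(c(2L, 1L, 1L), 0.05)
  mk <- function(a, b) metric_map(array(c(a, b), g$dim), "FA", g,
                                  "template")
  mask <- array(TRUE, g$dim)
  # voxel 1: all values equal -> t = 0, p = 1
  # voxel 2: zero variance but different means -> p = 0
  A <- list(mk(0.5, 0.2), mk(0.5, 0.2))
  B <- list(mk(0.5, 0.8), mk(0.5, 0.8))
  st <- voxelwise_ttest(A, B, mask)
  expect_equal(st$t[1], 0)
  expect_equal(st$p[1], 1)
  expect_equal(st$p[2], 0)
})

test_that("run_wbss wires the four contrasts and respects the FA mask", {
  lc <- lesion_cohort_result()
  res <- lc$result
  cfg <- lc$config
  maps <- template_metric_maps(res, "FA", smooth = TRUE, config = cfg)
  mask <- res$space$fa_template >= cfg$fa_threshold

  wa <- run_wbss(maps, res$manifest, "a", res$space, cfg)
  wb <- run_wbss(maps, res$manifest, "b", res$space, cfg)
  expect_equal(nrow(wa$clusters), 0L)
  expect_gte(nrow(wb$clusters), 1L)
  # rejections never leave the mask
  expect_true(all(wb$rejections[!mask] == FALSE))
  # the surviving cluster sits inside the lesion's statistical truth
  truth <- lesion_mask_on_grid(lc$spec, res$space$grid) & mask
  lab <- attr(wb$clusters, "labels")
  peak <- wb$clusters[1, c("bregma_cor", "bregma_hor", "bregma_sag")]
  vox <- round(bregma_to_vox(res$space, as.numeric(peak)))
  expect_true(truth[vox[1], vox[2], vox[3]])
  expect_gt(dice_overlap(lab, truth), 0.3)
})
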