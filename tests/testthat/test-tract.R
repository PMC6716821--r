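test_that("tracking a uniform +x field yields a straight streamline", {
  field <- straight_field()
  tr <- track_streamlines(field, matrix(c(0, 0, 0), 1),
                          step_mm = 0.01)
  expect_length(tr$streamlines, 1L)
  s <- tr$streamlines[[1]]
  # off-axis deviation stays below one voxel (should be ~machine zero)
  expect_lt(max(abs(s[, 2])), field$grid$spacing[2])
  expect_lt(max(abs(s[, 3])), field$grid$spacing[3])
  expect_lt(max(abs(s[, 2])), 1e-9)
  # the streamline spans most of the x extent in both directions
  half_extent <- field$grid$dim[1] * field$grid$spacing[1] / 2
  expect_gt(max(s[, 1]), 0.9 * half_extent)
  expect_lt(min(s[, 1]), -0.9 * half_extent)
})

test_that("quarter-arc streamline length is within 5% of (pi/2) R", {
  R <- 1
  field <- arc_field(R = R, spacing = 0.02)
  seed <- matrix(c(R / sqrt(2), R / sqrt(2), 0), 1)
  tr <- track_streamlines(field, seed, step_mm = 0.005)
  expect_length(tr$streamlines, 1L)
  s <- tr$streamlines[[1]]
  len <- sum(sqrt(rowSums(diff(s)^2)))
  expect_lt(abs(len - pi / 2 * R) / (pi / 2 * R), 0.05)
  # every point stays on the annulus
  r <- sqrt(s[, 1]^2 + s[, 2]^2)
  expect_lt(max(abs(r - R)), 0.1)
})

test_that("no eligible seeds produce an empty tract with a warning", {
  field <- straight_field(c(10L, 10L, 10L))
  field$fa[] <- 0
  expect_warning(tr <- track_streamlines(field, seed_points(field)),
                 "no seed")
  expect_length(tr$streamlines, 0L)
})

test_that("seed_points matches an in_shape voxel-center oracle", {
  field <- straight_field(c(20L, 16L, 12L))
  pts <- grid_coords(field$grid)
  expect_equal(nrow(seed_points(field)), prod(field$grid$dim))
  box <- shape_box(c(-0.2, -0.1, -0.1), c(0.2, 0.1, 0.1))
  want <- pts[in_shape(box, pts), , drop = FALSE]
  expect_equal(seed_points(field, box), want, ignore_attr = TRUE)
  # sub-threshold FA voxels are never seeded
  field$fa[1:5, , ] <- 0
  sds <- seed_points(field)
  expect_equal(nrow(sds), (20L - 5L) * 16L * 12L)
})

test_that("average_dataset: crossing sticks blend to an oblate mean tensor", {
  g <- im_grid(c(4L, 4L, 4L), 0.05)
  n <- prod(g$dim)
  row6 <- function(v) matrix(rep(v, each = n), n, 6L)
  x_stick <- row6(c(1.7, 0.3, 0.3, 0, 0, 0) * 1e-3)
  y_stick <- row6(c(0.3, 1.7, 0.3, 0, 0, 0) * 1e-3)

  fx <- average_dataset(list(x_stick), g)
  expect_equal(fx$fa[1], fa_formula(c(1.7, 0.3, 0.3) * 1e-3),
               tolerance = 1e-10)
  expect_equal(abs(fx$dir[1, 1, 1, 1]), 1, tolerance = 1e-10)
  expect_equal(fx$dir[1, 1, 1, 2], 0, tolerance = 1e-10)

  both <- average_dataset(list(x_stick, y_stick), g)
  # mean tensor diag(1.0, 1.0, 0.3)e-3: lower FA than either stick
  expect_equal(both$fa[1], fa_formula(c(1.0, 1.0, 0.3) * 1e-3),
               tolerance = 1e-10)
  expect_lt(both$fa[1], fx$fa[1])

  iso <- average_dataset(list(row6(c(0.7, 0.7, 0.7, 0, 0, 0) * 1e-3)), g)
  expect_equal(max(abs(iso$dir)), 0)          # FA 0 < threshold
  expect_error(average_dataset(list(), g), "empty")
})

test_that("warp_tensor_field reorients tensors by the affine rotation", {
  g <- im_grid(c(12L, 12L, 12L), 0.1)
  D6 <- c(1.7, 0.3, 0.3, 0, 0, 0) * 1e-3
  Darr <- array(0, c(g$dim, 6L))
  for (i in 1:6) Darr[, , , i] <- D6[i]
  field <- structure(list(D = Darr, grid = g), class = "tensor_field")

  ident <- structure(list(M = diag(3), t = c(0, 0, 0), rms = 0),
                     class = "affine3")
  same <- warp_tensor_field(field, subject_transform(ident, NULL, g), g)
  expect_equal(same, matrix(D6, prod(g$dim), 6L, byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)

  rot <- structure(list(M = rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)),
                        t = c(0, 0, 0), rms = 0), class = "affine3")
  turned <- warp_tensor_field(field, subject_transform(rot, NULL, g), g)
  # R D R' for a 90-degree z rotation swaps the xx and yy components
  want <- c(0.3, 1.7, 0.3, 0, 0, 0) * 1e-3
  expect_equal(turned, matrix(want, prod(g$dim), 6L, byrow = TRUE),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("select_tract applies waypoint and endpoint logic like the oracle", {
  g <- im_grid(c(20L, 20L, 20L), 0.05)
  line <- function(from, to, n = 9) {
    cbind(seq(from[1], to[1], length.out = n),
          seq(from[2], to[2], length.out = n),
          seq(from[3], to[3], length.out = n))
  }
  spans <- line(c(-0.4, 0, 0), c(0.4, 0, 0))          # visits both boxes
  stays <- line(c(-0.1, 0, 0), c(0.1, 0, 0))          # visits neither
  oneside <- line(c(0, 0, 0), c(0.4, 0, 0))           # right box only
  there_and_back <- rbind(line(c(0, 0, 0), c(-0.4, 0, 0)),
                          line(c(-0.4, 0, 0), c(0.4, 0, 0)),
                          line(c(0.4, 0, 0), c(0, 0, 0)))
  tr <- tract(list(spans, stays, oneside, there_and_back), g)
  left <- shape_box(c(-0.5, -0.5, -0.5), c(-0.3, 0.5, 0.5))
  right <- shape_box(c(0.3, -0.5, -0.5), c(0.5, 0.5, 0.5))

  by_waypoint <- select_tract(tr, must_pass = list(left, right))
  expect_length(by_waypoint$streamlines, 2L)   # spans, there_and_back

  by_ends <- select_tract(tr, must_pass = list(left, right),
                          endpoints = list(left, right))
  expect_length(by_ends$streamlines, 1L)       # only spans ends in both
  expect_equal(by_ends$streamlines[[1]], spans)
  # order-free endpoints: the reversed streamline is also kept
  rev_tr <- tract(list(spans[nrow(spans):1, ]), g)
  expect_length(select_tract(rev_tr, endpoints = list(left, right))$
                  streamlines, 1L)
  # occupancy mask is recomputed for the survivors
  expect_equal(by_ends$mask, occupancy_mask(list(spans), g))
})

test_that("tfas reduces per-subject means and matches stats::t.test", {
  g <- im_grid(c(10L, 10L, 10L), 0.05)
  tr <- tract(list(cbind(seq(-0.2, 0.2, 0.05), 0, 0)), g)
  man <- cohort_manifest(data.frame(
    subject_id = rep(c("m1", "m2", "w1", "w2"), each = 2),
    genotype = rep(c("mutant", "mutant", "wildtype", "wildtype"),
                   each = 2),
    timepoint = rep(c("baseline", "followup"), 4),
    scan_date = as.Date("2025-01-01") + 1:8,
    dwi_path = sprintf("s%d.nii.gz", 1:8),
    included = TRUE))
  vals <- c(m1_baseline = 0.40, m1_followup = 0.30,
            m2_baseline = 0.42, m2_followup = 0.32,
            w1_baseline = 0.41, w1_followup = 0.44,
            w2_baseline = 0.43, w2_followup = 0.46)
  mk <- function(v) metric_map(array(v, g$dim), "FA", g, "template")
  metric_maps <- lapply(vals, mk)
  fa_maps <- lapply(vals, function(...) mk(0.5))

  res <- tfas(tr, metric_maps, fa_maps, man)
  expect_equal(nrow(res$per_subject), 8L)
  for (r in seq_len(nrow(res$per_subject)))
    expect_equal(res$per_subject$value[r],
                 unname(vals[paste(res$per_subject$subject_id[r],
                                   res$per_subject$timepoint[r],
                                   sep = "_")]),
                 tolerance = 1e-12)
  mb <- res$cells[res$cells$genotype == "mutant" &
                    res$cells$timepoint == "baseline", ]
  expect_equal(mb$mean, 0.41, tolerance = 1e-12)
  expect_equal(mb$sem, stats::sd(c(0.40, 0.42)) / sqrt(2),
               tolerance = 1e-12)
  tt <- stats::t.test(c(0.30, 0.32), c(0.44, 0.46), var.equal = TRUE)
  fu <- res$tests[res$tests$timepoint == "followup", ]
  expect_equal(fu$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fu$p, tt$p.value, tolerance = 1e-10)

  # all-identical cells hit the guarded zero-variance branch
  flat <- lapply(vals, function(...) mk(0.5))
  res0 <- tfas(tr, flat, fa_maps, man)
  expect_equal(res0$tests$t, c(0, 0))
  expect_equal(res0$tests$p, c(1, 1))

  # a sub-threshold subject FA excludes those voxels -> NA value
  fa_maps$m1_baseline <- mk(0.1)
  resna <- tfas(tr, metric_maps, fa_maps, man)
  expect_true(is.na(resna$per_subject$value[
    resna$per_subject$subject_id == "m1" &
      resna$per_subject$timepoint == "baseline"]))

  empty <- tract(list(), g)
  expect_error(tfas(empty, metric_maps, fa_maps, man), "empty")
})

test_that("phantom cohort tracking dissociates the lesioned and spared tracts", {
  lc <- lesion_cohort_result()
  res <- lc$result
  cfg <- lc$config
  field <- average_dataset(template_tensor_fields(res), res$space$grid,
                           cfg$fa_threshold)
  rois <- default_tract_rois()
  cc <- select_tract(track_streamlines(field,
                                       seed_points(field,
                                                   rois$cc$seed_region)),
                     must_pass = rois$cc$must_pass)
  cst <- select_tract(track_streamlines(field,
                                        seed_points(field,
                                                    rois$cst$seed_region)),
                      must_pass = rois$cst$must_pass)
  expect_gt(length(cc$streamlines), 10L)
  expect_gt(length(cst$streamlines), 10L)

  fa_maps <- template_metric_maps(res, "FA", smooth = TRUE, config = cfg)
  t_cc <- tfas(cc, fa_maps, fa_maps, res$manifest, cfg$fa_threshold)
  t_cst <- tfas(cst, fa_maps, fa_maps, res$manifest, cfg$fa_threshold)
  p_cc <- t_cc$tests$p[t_cc$tests$timepoint == "followup"]
  p_cst <- t_cst$tests$p[t_cst$tests$timepoint == "followup"]
  expect_lt(p_cc, 0.05)
  expect_gte(p_cst, 0.05)
  # the lesioned genotype's follow-up tract FA is the depressed one
  cells <- t_cc$cells
  mu <- cells$mean[cells$genotype == "mutant" &
                     cells$timepoint == "followup"]
  wt <- cells$mean[cells$genotype == "wildtype" &
                     cells$timepoint == "followup"]
  expect_lt(mu, wt)
})
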