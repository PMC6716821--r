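test_that("roi_means: constant maps, single-voxel reduction, bilaterality", {
  g <- im_grid(c(11L, 11L, 11L), 0.1)
  space <- template_space(g)                 # bregma at the grid center
  const <- metric_map(array(0.37, g$dim), "FA", g, "template")
  roi <- list(name = "r", cor = 0.2, hor = -0.1, sag = 0.3,
              radius_mm = 0.25, side = "right")
  expect_equal(unname(roi_means(list(m = const), roi, space)), 0.37)

  set.seed(41)
  vals <- array(runif(prod(g$dim)), g$dim)
  m <- metric_map(vals, "FA", g, "template")
  # radius under half a voxel diagonal centered on voxel (7, 6, 6):
  # bregma (0.1, 0, 0) -> exactly that voxel's value
  tiny <- list(name = "v", cor = 0.1, hor = 0, sag = 0,
               radius_mm = 0.05, side = "right")
  expect_equal(unname(roi_means(list(m = m), tiny, space)), vals[7, 6, 6])

  # bilateral: union of the sphere and its sagittal mirror
  one <- list(name = "s", cor = 0, hor = 0, sag = 0.3, radius_mm = 0.05,
              side = "right")
  mirr <- list(name = "s", cor = 0, hor = 0, sag = -0.3, radius_mm = 0.05,
               side = "left")
  both <- list(name = "s", cor = 0, hor = 0, sag = 0.3, radius_mm = 0.05,
               side = "bilateral")
  v1 <- unname(roi_means(list(m = m), one, space))
  v2 <- unname(roi_means(list(m = m), mirr, space))
  expect_equal(unname(roi_means(list(m = m), both, space)),
               mean(c(v1, v2)))

  far <- list(name = "f", cor = 9, hor = 9, sag = 9, radius_mm = 0.01,
              side = "right")
  expect_error(roi_means(list(m = m), far, space), "no voxel")
})

test_that("lesion ROI mean drops at follow-up on noise-free truth maps", {
  spec <- phantom_spec(lesions = list(default_lesion()), noise_sigma = 0,
                       jitter_vox = 0, jitter_deg = 0)
  g <- native_grid(spec)
  space <- template_space(g)
  fa_of <- function(tp) {
    sim <- simulate_subject(spec, "mutant", tp, seed = 2)
    metric_map(array(sim$truth$ideal[, "FA"], g$dim), "FA", g, "native")
  }
  roi <- list(name = "lesioned_cortex", cor = 0.75, hor = 0, sag = 0.55,
              radius_mm = 0.2, side = "right")
  base <- unname(roi_means(list(m = fa_of("baseline")), roi, space))
  fup <- unname(roi_means(list(m = fa_of("followup")), roi, space))
  expect_lt(fup, base)
})

test_that("anova_two_way reproduces the published neuron-density F values", {
  res <- anova_two_way(neuron_density_cells())
  eff <- res$effects
  f_of <- function(e) eff$F[eff$effect == e]
  expect_equal(eff$df2, rep(9L, 3))
  expect_lt(abs(f_of("interaction") - 14.75) / 14.75, 0.05)
  expect_lt(abs(f_of("genotype") - 7.90) / 7.90, 0.05)
  expect_lt(abs(f_of("age") - 46.90) / 46.90, 0.05)
  expect_true(all(eff$p[eff$effect %in% c("interaction", "age")] < 0.05))
})

test_that("summary-statistics path equals the raw-data path exactly", {
  set.seed(47)
  raw <- data.frame(
    genotype = rep(rep(c("a", "b"), each = 4), 2),
    age = rep(c("young", "old"), each = 8),
    value = rnorm(16, mean = rep(c(10, 12, 11, 16), each = 4)))
  raw <- raw[-c(3, 9), ]                    # make it unbalanced
  from_raw <- anova_two_way(raw)
  cells <- do.call(rbind, lapply(split(raw, list(raw$genotype, raw$age)),
    function(g) cell_summary(g$genotype[1], g$age[1], nrow(g),
                             mean(g$value), stats::sd(g$value))))
  from_sum <- anova_two_way(cells)
  expect_equal(from_raw$effects$F, from_sum$effects$F, tolerance = 1e-10)
  expect_equal(from_raw$tukey$p_adj, from_sum$tukey$p_adj,
               tolerance = 1e-10)
  expect_equal(from_raw$mse, from_sum$mse, tolerance = 1e-10)
})

test_that("Type III F matches base-R drop1 on sum-to-zero contrasts", {
  set.seed(53)
  raw <- data.frame(
    genotype = factor(rep(rep(c("a", "b"), each = 5), 2)),
    age = factor(rep(c("young", "old"), each = 10)),
    value = rnorm(20, mean = rep(c(3, 5, 4, 9), each = 5)))
  raw <- raw[-c(2, 7, 20), ]                # unbalanced on purpose
  fit <- stats::lm(value ~ genotype * age, data = raw,
                   contrasts = list(genotype = "contr.sum",
                                    age = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  res <- anova_two_way(raw)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "genotype"],
               a3["genotype", "F value"], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "age"],
               a3["age", "F value"], tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "interaction"],
               a3["genotype:age", "F value"], tolerance = 1e-8)
})

test_that("balanced designs reduce to the classical two-way ANOVA", {
  set.seed(59)
  raw <- data.frame(
    genotype = factor(rep(rep(c("a", "b"), each = 4), 2)),
    age = factor(rep(c("young", "old"), each = 8)),
    value = rnorm(16, mean = rep(c(1, 2, 3, 7), each = 4)))
  classical <- stats::anova(stats::lm(value ~ genotype * age, data = raw))
  res <- anova_two_way(raw)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "genotype"],
               classical["genotype", "F value"], tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "age"],
               classical["age", "F value"], tolerance = 1e-10)
  expect_equal(eff$F[eff$effect == "interaction"],
               classical["genotype:age", "F value"], tolerance = 1e-10)
})

test_that("degenerate and invalid ANOVA inputs behave as specified", {
  flat <- rbind(cell_summary("a", "y", 3, 5, 1),
                cell_summary("a", "o", 3, 5, 1),
                cell_summary("b", "y", 3, 5, 1),
                cell_summary("b", "o", 3, 5, 1))
  res <- anova_two_way(flat)
  expect_equal(res$effects$F, rep(0, 3))
  expect_equal(res$effects$p, rep(1, 3))

  expect_error(cell_summary("a", "y", 1, 5, 1), "n")
  expect_error(cell_summary("a", "y", 3, 5, -1), "dispersion")
  expect_error(anova_two_way(flat[1:3, ]), "2 x 2")
  raw1 <- data.frame(genotype = c("a", "a", "b", "b", "a"),
                     age = c("y", "y", "y", "y", "o"),
                     value = 1:5)
  expect_error(anova_two_way(raw1), "n >= 2|2 x 2")
  # sem -> sd conversion is exact
  via_sem <- cell_summary("a", "y", 4, 5, 0.5, dispersion_kind = "sem")
  expect_equal(via_sem$sd, 1)
})

test_that("scaling all deviations from the grand mean leaves F unchanged", {
  set.seed(61)
  raw <- data.frame(
    genotype = rep(rep(c("a", "b"), each = 3), 2),
    age = rep(c("y", "o"), each = 6),
    value = rnorm(12, mean = rep(c(2, 4, 3, 8), each = 3)))
  grand <- mean(raw$value)
  scaled <- raw
  scaled$value <- grand + 2 * (raw$value - grand)
  r1 <- anova_two_way(raw)
  r2 <- anova_two_way(scaled)
  # every SS quadruples, MSE included, so every F is invariant
  expect_equal(r2$mse, 4 * r1$mse, tolerance = 1e-10)
  expect_equal(r1$effects$F, r2$effects$F, tolerance = 1e-10)
})

test_that("Tukey-adjusted p never undercuts the unadjusted pairwise p", {
  res <- anova_two_way(neuron_density_cells())
  cells <- res$cells
  cmp <- utils::combn(4L, 2L)
  for (k in seq_len(ncol(cmp))) {
    i <- cmp[1, k]; j <- cmp[2, k]
    se <- sqrt(res$mse * (1 / cells$n[i] + 1 / cells$n[j]))
    tv <- abs(cells$mean[i] - cells$mean[j]) / se
    p_raw <- 2 * stats::pt(-tv, res$effects$df2[1])
    expect_gte(res$tukey$p_adj[k] + 1e-12, p_raw)
  }
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
})

test_that("group_bar_stats computes SEM and flags displayed comparisons", {
  vals <- data.frame(
    genotype = rep(c("mutant", "wildtype"), each = 3),
    timepoint = "followup",
    value = c(1, 2, 3, 7, 8, 9))
  gb <- group_bar_stats(vals)
  mu <- gb$cells[gb$cells$genotype == "mutant", ]
  expect_equal(mu$mean, 2)
  expect_equal(mu$sem, stats::sd(1:3) / sqrt(3))
  expect_equal(mu$sem, 0.5774, tolerance = 1e-4)
  tt <- stats::t.test(1:3, 7:9, var.equal = TRUE)
  expect_equal(gb$tests$p, tt$p.value, tolerance = 1e-12)
  expect_true(gb$tests$significant)

  same <- vals; same$value <- 5
  gb0 <- group_bar_stats(same)
  expect_equal(gb0$tests$t, 0)
  expect_equal(gb0$tests$p, 1)
  expect_false(gb0$tests$significant)
})
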