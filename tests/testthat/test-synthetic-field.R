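test_that("alpha-lattice layout reproduces the study design", {
  cfg <- sim_config(seed = 1)
  layout <- build_alpha_lattice_layout(cfg)
  expect_equal(nrow(layout), 1320L)
  # conservation: trials x reps x subblocks x plots
  expect_equal(nrow(layout),
               cfg$n_trials * cfg$n_reps * cfg$subblocks_per_rep *
                 cfg$plots_per_subblock)
  # each non-check entry occurs exactly once per rep within its trial
  nc <- layout[!layout$is_check, ]
  counts <- table(nc$trial, nc$rep, nc$entry_id)
  expect_true(all(counts %in% c(0L, 1L)))
  per_rep <- aggregate(entry_id ~ trial + rep, nc,
                       function(x) length(unique(x)))
  expect_true(all(per_rep$entry_id == cfg$entries_per_trial))
  # sub-blocks hold exactly plots_per_subblock plots
  sb <- table(layout$trial, layout$rep, layout$subblock)
  expect_true(all(sb == cfg$plots_per_subblock))
  # 590 unique lines: 11 x 53 entries + 7 shared checks
  expect_equal(length(unique(layout$entry_id)), 590L)
})

test_that("layout polygons are pairwise disjoint and seeded deterministically", {
  cfg <- sim_config(seed = 3, n_trials = 1, entries_per_trial = 8,
                    checks_per_trial = 2, n_reps = 1,
                    subblocks_per_rep = 1, plots_per_subblock = 10)
  layout <- build_alpha_lattice_layout(cfg)
  expect_equal(nrow(layout), 10L)
  # disjoint rectangles: no pair overlaps
  for (i in 1:9) for (j in (i + 1):10) {
    overlap <- layout$x_min[i] < layout$x_max[j] &
      layout$x_max[i] > layout$x_min[j] &
      layout$y_min[i] < layout$y_max[j] &
      layout$y_max[i] > layout$y_min[j]
    expect_false(overlap)
  }
  expect_identical(layout, build_alpha_lattice_layout(cfg))
  cfg2 <- sim_config(seed = 4, n_trials = 1, entries_per_trial = 8,
                     checks_per_trial = 2, n_reps = 1,
                     subblocks_per_rep = 1, plots_per_subblock = 10)
  layout2 <- build_alpha_lattice_layout(cfg2)
  expect_false(identical(layout$entry_id, layout2$entry_id))
})

test_that("inconsistent design dimensions are rejected", {
  expect_error(sim_config(entries_per_trial = 50),
               "must equal")
})

test_that("simulated genotypes respect coding, MAF and determinism", {
  cfg <- sim_config(seed = 11, n_markers = 1000)
  G <- simulate_genotypes(cfg, line_ids = sprintf("L%03d", 1:100))
  expect_true(all(G$calls %in% c(-1L, 0L, 1L)))
  maf <- apply(G$calls, 2, function(g) {
    p <- mean(g + 1) / 2
    min(p, 1 - p)
  })
  expect_true(all(maf > 0))
  expect_true(all(maf <= 0.55))
  expect_false(any(is.na(G$calls)))  # missing_rate = 0
  G2 <- simulate_genotypes(cfg, line_ids = sprintf("L%03d", 1:100))
  expect_identical(G$calls, G2$calls)
})

test_that("missing and het rates generate the QC-relevant codes", {
  cfg <- sim_config(seed = 12, n_markers = 300, missing_rate = 0.2,
                    het_rate = 0.1)
  G <- simulate_genotypes(cfg, line_ids = sprintf("L%03d", 1:80))
  expect_gt(mean(is.na(G$calls)), 0.1)
  expect_gt(mean(G$calls == 0L, na.rm = TRUE), 0.03)
})

test_that("breeding values scale to the target architecture", {
  cfg <- sim_config(seed = 5, n_markers = 400)
  G <- simulate_genotypes(cfg, line_ids = sprintf("L%03d", 1:200))
  # h2 = 0: exactly zero genetic values
  bv0 <- simulate_breeding_values(G, h2 = 0, n_qtl = 50, seed = 5)
  expect_true(all(bv0$u == 0))
  expect_equal(bv0$sigma2_G, 0)
  # single major locus: liability collinear with its dosage
  bv1 <- simulate_breeding_values(G, h2 = 0.9, n_qtl = 1,
                                  major_effect = 2, seed = 5)
  dos <- G$calls[, bv1$major_marker]
  expect_equal(abs(cor(bv1$u, dos)), 1, tolerance = 1e-12)
  # polygenic case: standardized to unit variance
  bv <- simulate_breeding_values(G, h2 = 0.6, n_qtl = 100, seed = 5)
  expect_equal(var(bv$u), 1, tolerance = 1e-12)
})

test_that("entry-mean heritability is recovered from the liability model", {
  cfg <- sim_config(seed = 21, n_markers = 300)
  est <- vapply(1:20, function(s) {
    cfg_s <- sim_config(seed = 21 + s, n_markers = 300)
    G <- simulate_genotypes(cfg_s, line_ids = sprintf("L%03d", 1:200))
    bv <- simulate_breeding_values(G, h2 = 0.6, n_qtl = 100, seed = 21 + s)
    layout <- data.frame(plot_id = sprintf("P%04d", 1:400),
                         trial = 1L, rep = rep(1:2, each = 200),
                         subblock = rep(1:20, 20),
                         entry_id = rep(names(bv$u), 2),
                         stringsAsFactors = FALSE)
    st <- simulate_plot_lodging(layout, bv, cfg_s, seed = 21 + s)
    vc <- reml_variance_components(st$liability, st$entry_id)
    entry_mean_heritability(vc, 2)$H2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.6), 0.1)
})

test_that("liability maps to lodging monotonically with exact limits", {
  cfg <- sim_config(seed = 2, sigma2_rep = 0, sigma2_subblock = 0,
                    h2_lodging = 1, canopy_height_sd_m = 0)
  layout <- build_alpha_lattice_layout(
    sim_config(seed = 2, n_trials = 1, entries_per_trial = 8,
               checks_per_trial = 2, n_reps = 1, subblocks_per_rep = 1,
               plots_per_subblock = 10))
  u <- setNames(seq(-6, 6, length.out = 10), sort(unique(layout$entry_id)))
  st <- simulate_plot_lodging(layout, u, cfg)
  o <- order(st$liability)
  expect_true(all(diff(st$lodged_fraction[o]) >= 0))
  expect_true(all(st$mean_drop <= st$canopy_height + 1e-12))
  expect_true(all(st$mean_drop[st$lodged_fraction == 0] == 0))
  # severity 90 deg with 1 m canopy drops the full meter
  expect_equal(max(st$mean_drop[st$severity_angle == 90]),
               1 * (1 - cos(pi / 2)), tolerance = 1e-12)
})

test_that("visual scores follow the incidence/severity/index definitions", {
  cfg <- sim_config(seed = 2, loi_noise_sd = 0, los_noise_sd = 0)
  lodging <- data.frame(plot_id = c("a", "b"),
                        lodged_fraction = c(0.5, 0),
                        severity_angle = c(72, 30))
  vs <- simulate_visual_scores(lodging, cfg)
  expect_equal(vs$LOI, c(50, 0))
  expect_equal(vs$LOS, c(8, 3))
  expect_equal(vs$LI, c(400, 0))  # LI = LOI x LOS; zero incidence kills it
})

test_that("observer noise keeps mean absolute LOI error small", {
  cfg <- sim_config(seed = 31, loi_noise_sd = 5, los_noise_sd = 0.5)
  set.seed(99)
  lodging <- data.frame(plot_id = sprintf("p%04d", 1:1000),
                        lodged_fraction = runif(1000, 0.05, 0.95),
                        severity_angle = runif(1000, 0, 90))
  vs <- simulate_visual_scores(lodging, cfg)
  # folded-normal mean of sd-5 noise plus round-to-5 error stays under ~4
  expect_lt(mean(abs(vs$LOI - 100 * lodging$lodged_fraction)), 4.5)
})

test_that("tag counts follow the binomial carrier model", {
  tc <- simulate_tag_counts(c("a", "b"), c(TRUE, FALSE), depth = 100,
                            seed = 1, p_pos = 1, p_neg = 0)
  expect_equal(tc$alien_count, c(100, 0))
  expect_equal(tc$wheat_count, c(0, 100))
  tc0 <- simulate_tag_counts("a", TRUE, depth = 0, seed = 1)
  expect_equal(tc0$alien_count + tc0$wheat_count, 0)
  expect_equal(call_2ns(tc0)$status, "missing")
})

test_that("rendered DEM pair matches the generative contract", {
  # no lodging, no growth, no noise: pre == post
  hp <- one_plot_layout(frac = 0, drop = 0)
  cfg <- sim_config(seed = 1, pixel_noise_sd_m = 0, growth_offset_m = 0,
                    pixel_size_m = 0.1)
  dems <- render_dem_pair(hp$layout, hp$lodging, cfg)
  expect_identical(dems$pre$values, dems$post$values)
  # fully lodged plot, drop 0.6, noiseless: all plot differentials 0.6
  hp2 <- one_plot_layout(frac = 1, drop = 0.6)
  dems2 <- render_dem_pair(hp2$layout, hp2$lodging, cfg)
  d <- differential_dem(dems2$pre, dems2$post)
  px <- extract_plot_pixels(d, hp2$layout[1, c("x_min", "x_max",
                                               "y_min", "y_max")])
  expect_true(all(abs(px - 0.6) < 1e-12))
  # too-coarse grid is rejected
  cfg_coarse <- sim_config(seed = 1, pixel_size_m = 0.8)
  expect_error(render_dem_pair(hp$layout, hp$lodging, cfg_coarse),
               "too coarse")
})

test_that("differential pixels satisfy the two-component moment identity", {
  # mean differential = lambda x drop - growth_offset (noise is mean-zero)
  for (go in c(0, 0.05)) {
    hp <- one_plot_layout(frac = 0.6, drop = 0.45)
    cfg <- sim_config(seed = 17, pixel_noise_sd_m = 0.03,
                      growth_offset_m = go, pixel_size_m = 0.05)
    dems <- render_dem_pair(hp$layout, hp$lodging, cfg)
    d <- differential_dem(dems$pre, dems$post)
    px <- extract_plot_pixels(d, hp$layout[1, c("x_min", "x_max",
                                                "y_min", "y_max")])
    mc_se <- sd(px) / sqrt(length(px))
    # contiguous-patch rounding shifts the realized lambda by < 1 pixel row
    expect_lt(abs(mean(px) - (0.6 * 0.45 - go)), 3 * mc_se + 0.45 / 38)
  }
})

test_that("the full synthetic study is bit-reproducible under its seed", {
  cfg <- small_config(seed = 77)
  f1 <- simulate_field(cfg)
  f2 <- simulate_field(cfg)
  expect_identical(f1$layout, f2$layout)
  expect_identical(f1$genotypes$calls, f2$genotypes$calls)
  expect_identical(f1$pre$values, f2$pre$values)
  expect_identical(f1$visual, f2$visual)
  expect_identical(f1$tags, f2$tags)
})
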