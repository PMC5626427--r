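test_that("trajectory model is deterministic, arcuate, and raphe-consistent", {
  tm <- trajectory_map(bundle_model())
  expect_identical(tm, trajectory_map(bundle_model()))
  expect_true(all(tm$sector %in% 7:11))
  # papillomacular band: rows flanking the raphe map to 9
  expect_true(all(tm$sector[tm$row %in% 5:6] == 9L))
  # superior half only 9-11, inferior half only 7-9
  expect_true(all(tm$sector[tm$row <= 5] %in% 9:11))
  expect_true(all(tm$sector[tm$row >= 6] %in% 7:9))
  # arcs: the superior-temporal corner reaches 11, the far superior-nasal
  # edge stays in 10 (arcuate bending is temporal)
  expect_equal(tm$sector[tm$row == 2 & tm$col == 1], 11L)
  expect_equal(tm$sector[tm$row == 3 & tm$col == 10], 10L)
})

test_that("healthy templates hit the configured region targets", {
  g <- healthy_template("mGCIPL")
  expect_equal(mean(g), 67.96, tolerance = 1e-12)
  expect_identical(g, healthy_template("mGCIPL"))
  r <- healthy_template("mRNFL")
  expect_equal(mean(r), 35.06, tolerance = 1e-12)
  tmat <- matrix(trajectory_map()$sector, 10, 10, byrow = TRUE)
  # papillomacular mRNFL is thinner than the inferior arcuate sector
  expect_lt(mean(r[tmat == 9]), mean(r[tmat == 7]))
  # sector means preserve the configured ordering up to a common offset
  sector_means <- vapply(7:11, function(s) mean(r[tmat == s]), numeric(1))
  targets <- c(37.47, 37.41, 29.71, 37.18, 21.02)
  expect_equal(order(sector_means), order(targets))
  offs <- sector_means - targets
  expect_lt(diff(range(offs)), 1e-9)
  # mGCIPL annulus: mid-ring thicker than the foveal centre (same sector)
  expect_gt(g[5, 3], g[5, 5])
})

test_that("noise-free, damage-free cohorts reproduce the template exactly", {
  cfg <- cohort_config(
    n_eyes = 2, noise_sd_macular = 0, noise_sd_cprnfl = 0,
    visit_offset_sd = 0, visit_jitter_days = 0, vf_noise_sd = 0,
    susceptibility = c(mRNFL = 0, mGCIPL = 0), cprnfl_susceptibility = 0,
    fraction_progressors = 0, slope_background_mean = 0,
    slope_background_sd = 0)
  sim <- generate_cohort(cfg, seed = 5)
  tm <- healthy_template("mRNFL")
  mac <- sim$cohort$macular
  mr <- mac[mac$layer == "mRNFL", ]
  expect_equal(mr$thickness, tm[cbind(mr$row, mr$col)], tolerance = 1e-12)
})

test_that("a single fast bundle changes only its own trajectory points", {
  cfg <- cohort_config(
    n_eyes = 1, noise_sd_macular = 0, noise_sd_cprnfl = 0,
    visit_offset_sd = 0, visit_jitter_days = 0, vf_noise_sd = 0,
    susceptibility = c(mRNFL = 0, mGCIPL = 0), cprnfl_susceptibility = 0,
    fraction_progressors = 0, slope_background_mean = 0,
    slope_background_sd = 0)
  # all-progressor config with a degenerate slope distribution: the fast
  # bundles are then known exactly from the ground truth
  cfg2 <- cfg
  cfg2$fraction_progressors <- 1
  cfg2$slope_progressor_mean <- -2
  cfg2$slope_progressor_sd <- 0
  sim2 <- generate_cohort(cfg2, seed = 11)
  tr <- sim2$truth$bundles
  fast <- tr$sector[tr$slope_mRNFL < 0]
  mac <- sim2$cohort$macular
  tmap <- trajectory_map(cfg2$bundle)
  first <- mac[mac$date == 0 & mac$layer == "mRNFL", ]
  last <- mac[mac$date == max(mac$date) & mac$layer == "mRNFL", ]
  delta <- last$thickness - first$thickness
  sect <- tmap$sector[match(paste(last$row, last$col),
                            paste(tmap$row, tmap$col))]
  expect_true(all(abs(delta[!(sect %in% fast)]) < 1e-9))
  expect_true(all(delta[sect %in% fast] < -2))
})

test_that("the generator is seed-deterministic", {
  cfg <- cohort_config(n_eyes = 6)
  s1 <- generate_cohort(cfg, seed = 42)
  s2 <- generate_cohort(cfg, seed = 42)
  expect_equal(s1$cohort$macular, s2$cohort$macular, tolerance = 0)
  expect_equal(s1$truth$bundles, s2$truth$bundles, tolerance = 0)
  s3 <- generate_cohort(cfg, seed = 43)
  expect_false(isTRUE(all.equal(s1$cohort$macular$thickness,
                                s3$cohort$macular$thickness)))
})

test_that("healthy-cohort baseline average matches the template target", {
  # healthy eyes: susceptibility zero, stable slopes, default noise
  cfg <- cohort_config(
    n_eyes = 200, n_visits = 5,
    susceptibility = c(mRNFL = 0, mGCIPL = 0), cprnfl_susceptibility = 0,
    fraction_progressors = 0)
  sim <- generate_cohort(cfg, seed = 21)
  mac <- sim$cohort$macular
  base <- mac[mac$date == 0 & mac$layer == "mRNFL", ]
  eye_means <- tapply(base$thickness, base$eye_id, mean)
  se <- sd(eye_means) / sqrt(length(eye_means))
  expect_lt(abs(mean(eye_means) - 35.06), 2 * se + 1e-6)
})

test_that("true bundle slopes and mapped VF point slopes co-vary", {
  sim <- generate_cohort(cohort_config(n_eyes = 150), seed = 31)
  vfm <- sim$truth$vf_point_map
  tr <- sim$truth$bundles
  # per eye: mean true mGCIPL slope over bundles present in the central 16
  sectors_c16 <- unique(vfm$sector)
  true_slope <- tr |>
    dplyr::filter(sector %in% sectors_c16) |>
    dplyr::group_by(eye_id) |>
    dplyr::summarise(s = mean(slope_mGCIPL))
  # per eye: fitted mean VF slope over the central 16
  vf <- vf_analysis(sim$cohort)
  j <- dplyr::inner_join(true_slope, vf, by = "eye_id")
  expect_gt(cor(j$s, j$td_c16_slope, method = "spearman"), 0.3)
})
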