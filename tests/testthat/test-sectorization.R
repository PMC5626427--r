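test_that("spearman_rho handles exact monotone and constant inputs", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_rho(1:4, c(4, 3, 2, 1))$rho, -1)
  out <- spearman_rho(1:10, rep(5, 10))
  expect_true(is.na(out$rho))
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("spearman_rho matches the brute-force mid-rank oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.1 * (i %% 2))
    y <- sample(1:8, n, replace = TRUE)
    got <- spearman_rho(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("correlate_grid recovers the generating bundle as argmax sector", {
  sim <- generate_cohort(cohort_config(n_eyes = 120), seed = 13)
  maps <- correlate_grid(sim$cohort, "mRNFL")
  tmap <- trajectory_map()
  arg <- maps |>
    dplyr::group_by(row, col) |>
    dplyr::slice_max(rho, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  j <- dplyr::inner_join(arg, tmap, by = c("row", "col"),
                         suffix = c("", "_true"))
  expect_gt(mean(j$sector == j$sector_true), 0.9)
})

test_that("degenerate cohorts give flagged (NA) correlations", {
  cfg <- cohort_config(
    n_eyes = 25, noise_sd_macular = 0, noise_sd_cprnfl = 0,
    visit_offset_sd = 0, vf_noise_sd = 0,
    susceptibility = c(mRNFL = 0, mGCIPL = 0), cprnfl_susceptibility = 0,
    fraction_progressors = 0, slope_background_sd = 0)
  sim <- generate_cohort(cfg, seed = 2)      # all eyes identical at baseline
  maps <- correlate_grid(sim$cohort, "mRNFL")
  expect_true(all(is.na(maps$rho)))
  sm <- assign_sectors(maps)
  expect_true(all(is.na(sm$sector)))
})

test_that("correlations are invariant to eye order", {
  sim <- shared_sim()
  coh <- sim$cohort
  m1 <- correlate_grid(coh, "mGCIPL")
  coh2 <- coh
  for (tab in c("eyes", "visits", "macular", "cprnfl", "vf")) {
    coh2[[tab]] <- dplyr::arrange(coh2[[tab]], dplyr::desc(eye_id))
  }
  m2 <- correlate_grid(coh2, "mGCIPL")
  expect_equal(m1$rho, m2$rho, tolerance = 1e-12)
})

test_that("assign_sectors applies threshold, argmax and tie rules", {
  mk <- function(rho, p = rep(0.01, 5)) {
    tibble::tibble(layer = "mRNFL", row = 1L, col = 1L, sector = 7:11,
                   rho = rho, p_value = p, n = 100L)
  }
  # plain argmax
  sm <- assign_sectors(mk(c(0.6, 0.3, 0.2, 0.1, 0.1)))
  expect_equal(sm$sector, 7L)
  # below r_min -> unassigned
  sm <- assign_sectors(mk(c(0.35, 0.3, 0.2, 0.1, 0.1)))
  expect_true(is.na(sm$sector))
  # significant rho but p >= alpha -> unassigned
  sm <- assign_sectors(mk(c(0.6, 0.3, 0.2, 0.1, 0.1),
                          p = c(0.2, rep(0.01, 4))))
  expect_true(is.na(sm$sector))
  # tie at (1,1): trajectory there is 11 (superior-temporal corner);
  # a 10/11 tie resolves to the trajectory sector
  sm <- assign_sectors(mk(c(0.1, 0.1, 0.2, 0.5, 0.5)))
  expect_equal(sm$sector, 11L)
  # tie between sectors not containing the trajectory label -> lower hour
  sm <- assign_sectors(mk(c(0.5, 0.5, 0.2, 0.1, 0.1)))
  expect_equal(sm$sector, 7L)
})

test_that("anatomical correction is a no-op on a consistent map", {
  tmap <- trajectory_map()
  raw <- tibble::tibble(layer = "mRNFL", row = tmap$row, col = tmap$col,
                        sector = tmap$sector)
  class(raw) <- c("oct_sector_map", class(tibble::tibble()))
  fixed <- anatomical_correction(raw)
  expect_equal(fixed$sector, raw$sector)
})

test_that("isolated points are absorbed and raphe violations repaired", {
  tmap <- trajectory_map()
  lab <- tmap$sector
  # single 10 inside the 11 arc at (1,5) (trajectory there is 11)
  stopifnot(tmap$sector[tmap$row == 1 & tmap$col == 5] == 11L)
  lab[tmap$row == 1 & tmap$col == 5] <- 10L
  # a superior label deep in the inferior hemifield
  lab[tmap$row == 9 & tmap$col == 5] <- 11L
  raw <- tibble::tibble(layer = "mRNFL", row = tmap$row, col = tmap$col,
                        sector = lab)
  class(raw) <- c("oct_sector_map", class(tibble::tibble()))
  fixed <- anatomical_correction(raw)
  expect_equal(fixed$sector[fixed$row == 1 & fixed$col == 5], 11L)
  expect_true(fixed$sector[fixed$row == 9 & fixed$col == 5] %in% 7:9)
  expect_equal(fixed$sector[lab == tmap$sector],
               tmap$sector[lab == tmap$sector])
})

test_that("unassigned points are filled only from a trajectory consensus", {
  tmap <- trajectory_map()
  lab <- tmap$sector
  lab[tmap$row == 8 & tmap$col == 5] <- NA           # interior hole
  lab[tmap$row == 1 & tmap$col == 1] <- NA           # corner: 2 neighbours only
  raw <- tibble::tibble(layer = "mRNFL", row = tmap$row, col = tmap$col,
                        sector = lab)
  class(raw) <- c("oct_sector_map", class(tibble::tibble()))
  fixed <- anatomical_correction(raw)
  expect_equal(fixed$sector[fixed$row == 8 & fixed$col == 5], 8L)
  expect_true(is.na(fixed$sector[fixed$row == 1 & fixed$col == 1]))
})

test_that("recovery degrades monotonically with noise (mismatched correction)", {
  correction <- bundle_model(superior_curvature = 0.6, inferior_curvature = 0.6)
  acc <- vapply(c(1, 4, 10), function(ns) {
    sim <- generate_cohort(cohort_config(n_eyes = 60, noise_sd_macular = ns,
                                         noise_sd_cprnfl = 2 * ns),
                           seed = 77)
    sm <- derive_sector_map(sim$cohort, layers = "mRNFL", bundle = correction)
    j <- dplyr::inner_join(sm, sim$truth$sector_map,
                           by = c("layer", "row", "col"),
                           suffix = c("", "_true"))
    ok <- !is.na(j$sector)
    sum(j$sector[ok] == j$sector_true[ok]) / max(sum(ok), 1)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02))   # non-increasing up to seed jitter
  expect_gt(acc[1], 0.9)
})
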