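make_grid_tbl <- function(value) {
  g <- grid_points()
  g$thickness <- value
  g
}

test_that("region means follow partition arithmetic", {
  g <- make_grid_tbl(30)
  expect_equal(region_mean(g, "average"), 30)
  expect_equal(region_mean(g, "superior"), 30)
  g2 <- make_grid_tbl(seq_len(100))
  avg <- region_mean(g2, "average")
  expect_equal(avg, (region_mean(g2, "superior") +
                       region_mean(g2, "inferior")) / 2)
  # healthy mGCIPL template average lands on the configured target
  tmpl <- healthy_template("mGCIPL")
  gt <- make_grid_tbl(tmpl[cbind(grid_points()$row, grid_points()$col)])
  expect_equal(region_mean(gt, "average"), 67.96, tolerance = 1e-10)
})

test_that("fit_slope is exact on noiseless lines and matches lm on noise", {
  d <- round(seq(0, 800, length.out = 8))
  y <- 30 - 1.0 * d / 365.25
  f <- fit_slope(d, y)
  expect_equal(f$slope, -1, tolerance = 1e-12)
  expect_equal(f$se, 0, tolerance = 1e-9)
  f0 <- fit_slope(d, rep(12, 8))
  expect_equal(f0$slope, 0)
  # scale equivariance
  y2 <- 2 * (30 - 0.7 * d / 365.25)
  expect_equal(fit_slope(d, y2)$slope, -1.4, tolerance = 1e-12)
  # independent oracle: stats::lm
  set.seed(3)
  yn <- 25 - 0.4 * d / 365.25 + rnorm(8, 0, 1.2)
  f2 <- fit_slope(d, yn)
  ora <- summary(stats::lm(yn ~ I(d / 365.25)))$coefficients[2, 1:2]
  expect_equal(f2$slope, unname(ora[1]), tolerance = 1e-10)
  expect_equal(f2$se, unname(ora[2]), tolerance = 1e-10)
  expect_error(fit_slope(d[1:4], y[1:4]), ">= 5")
  expect_error(fit_slope(rep(0, 5), y[1:5]), "distinct")
})

test_that("normative trend classification behaves at the null and extremes", {
  out <- classify_trend(-0.1, 0.2, slope_mean = -0.1, slope_sd = 0.3)
  expect_false(out$progressive)
  expect_equal(out$p_vs_normative, 0.5)
  denom <- sqrt(0.2^2 + 0.3^2)
  out2 <- classify_trend(-0.1 - 10 * denom, 0.2, -0.1, 0.3)
  expect_true(out2$progressive)
  # a fast slope still above the normative mean is never progressive
  out3 <- classify_trend(0.2, 1e-9, -0.1, 0.3)
  expect_false(out3$progressive)
  expect_error(classify_trend(-0.5, 0.2, NA, 0.3), "normative")
})

test_that("extreme-region selection is the argmin with stated tie-breaks", {
  base <- tibble::tibble(
    eye_id = "e1", layer = "mRNFL",
    region = c("superior", "inferior", paste0("clock", 7:11)),
    slope = c(-0.1, -0.6, -0.3, -0.3, -0.3, -0.3, -0.3),
    se = 0.1, r_squared = 0.5, n_visits = 8L)
  sel <- select_extreme_regions(base)
  fh <- sel[sel$region == "faster_hemifield", ]
  expect_equal(fh$selected_from, "inferior")
  expect_equal(fh$slope, -0.6)
  fs <- sel[sel$region == "fastest_sector", ]
  expect_equal(fs$selected_from, "clock7")   # all equal -> lowest clock hour
  expect_equal(fs$slope, -0.3)
  fo <- sel[sel$region == "fastest_overall", ]
  expect_equal(fo$selected_from, "inferior")
})

test_that("trend analysis: fastest sector bounds every clock slope per eye", {
  sim <- shared_sim()
  sectors <- sim$truth$sector_map
  tr <- tidy(trend_analysis(sim$cohort, sectors))
  per_eye <- split(tr, interaction(tr$eye_id, tr$layer))
  for (df in per_eye) {
    fastest <- df$slope[df$region == "fastest_sector"]
    clocks <- df$slope[grepl("^clock", df$region)]
    expect_true(all(fastest <= clocks + 1e-12))
    expect_lte(df$slope[df$region == "fastest_overall"],
               min(df$slope[df$region %in% c("superior", "inferior")],
                   clocks))
  }
})

test_that("eyes with short follow-up are excluded from progression analyses", {
  sim <- shared_sim()
  coh <- sim$cohort
  # truncate one eye to 4 visits
  drop_eye <- coh$eyes$eye_id[1]
  keep_dates <- head(sort(coh$visits$date[coh$visits$eye_id == drop_eye]), 4)
  for (tab in c("visits", "macular", "cprnfl", "vf")) {
    t <- coh[[tab]]
    coh[[tab]] <- t[t$eye_id != drop_eye |
                      t$date %in% keep_dates, ]
  }
  expect_warning(tr <- trend_analysis(coh, sim$truth$sector_map), "excluded")
  expect_false(drop_eye %in% tidy(tr)$eye_id)
})
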