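make_vf_series <- function(slopes, n_exams = 6, noise = 0, years = 2.2,
                           base = 28) {
  # slopes: 4x4 matrix of dB/year
  pts <- central16_points()
  dates <- round(seq(0, years * 365.25, length.out = n_exams))
  do.call(rbind, lapply(seq_along(dates), function(i) {
    t <- dates[i] / 365.25
    tibble::tibble(
      date = dates[i], row = pts$row, col = pts$col,
      sensitivity = base + slopes[cbind(pts$row, pts$col)] * t +
        rnorm(16, 0, noise),
      total_deviation = base + slopes[cbind(pts$row, pts$col)] * t - 30)
  }))
}

test_that("pointwise slopes recover noise-free decline and thresholds", {
  sl <- matrix(0, 4, 4)
  sl[1, 1] <- -2
  sl[2, 2] <- -0.9
  vf <- make_vf_series(sl)
  out <- vf_pointwise_slopes(vf)
  expect_equal(out$slope[out$row == 1 & out$col == 1], -2, tolerance = 1e-9)
  expect_true(out$progressive[out$row == 1 & out$col == 1])
  # -0.9 dB/year is not "worse than -1"
  expect_false(out$progressive[out$row == 2 & out$col == 2])
  # stable points: slope 0, not progressive
  expect_equal(out$slope[out$row == 4 & out$col == 4], 0, tolerance = 1e-9)
  expect_false(out$progressive[out$row == 4 & out$col == 4])
  expect_error(vf_pointwise_slopes(vf[vf$date < 300, ]), ">= 3")
})

test_that("significance mode gates borderline noisy points", {
  sl <- matrix(0, 4, 4)
  sl[3, 3] <- -1.4
  set.seed(5)
  vf <- make_vf_series(sl, n_exams = 5, noise = 4)  # heavy perimetric noise
  strict <- vf_pointwise_slopes(vf, require_significance = TRUE)
  lax <- vf_pointwise_slopes(vf, require_significance = FALSE)
  expect_true(all(lax$progressive >= strict$progressive))
})

test_that("the cluster rule distinguishes contiguous from scattered points", {
  grid_flag <- function(cells) {
    m <- matrix(FALSE, 4, 4)
    for (cl in cells) m[cl[1], cl[2]] <- TRUE
    m
  }
  as_slopes <- function(m) {
    pts <- central16_points()
    tibble::tibble(row = pts$row, col = pts$col,
                   progressive = m[cbind(pts$row, pts$col)])
  }
  l_shape <- as_slopes(grid_flag(list(c(1, 1), c(2, 1), c(2, 2))))
  expect_true(classify_progressor(l_shape, min_points = 3))
  scattered <- as_slopes(grid_flag(list(c(1, 1), c(3, 3), c(1, 4))))
  expect_false(classify_progressor(scattered, min_points = 3))
  expect_false(classify_progressor(scattered, min_points = 2))
  expect_true(classify_progressor(scattered, min_points = 3,
                                  contiguous = FALSE))
  none <- as_slopes(grid_flag(list()))
  expect_false(classify_progressor(none, min_points = 3))
  pair <- as_slopes(grid_flag(list(c(4, 3), c(4, 4))))
  expect_false(classify_progressor(pair, min_points = 3))
  expect_true(classify_progressor(pair, min_points = 2))
})

test_that("td_c16 is the plain mean and rejects incomplete exams", {
  pts <- central16_points()
  exam <- tibble::tibble(row = pts$row, col = pts$col,
                         total_deviation = -9)
  expect_equal(td_c16(exam), -9)
  exam$total_deviation <- c(rep(0, 8), rep(-2, 8))
  expect_equal(td_c16(exam), -1)
  expect_equal(td_c16(exam[sample(16), ]), -1)
  expect_error(td_c16(exam[-1, ]), "16")
})

test_that("classification is monotone in the slope threshold", {
  sim <- shared_sim()
  vf_strict <- vf_analysis(sim$cohort, threshold = -1)
  vf_lax <- vf_analysis(sim$cohort, threshold = -0.5)
  expect_true(all(vf_lax$vf_progressor >= vf_strict$vf_progressor))
})

test_that("VF progressors carry faster true structural loss (sign test)", {
  sim <- generate_cohort(cohort_config(n_eyes = 200), seed = 17)
  vf <- vf_analysis(sim$cohort)
  vfm <- sim$truth$vf_point_map
  true_slope <- sim$truth$bundles |>
    dplyr::filter(sector %in% unique(vfm$sector)) |>
    dplyr::group_by(eye_id) |>
    dplyr::summarise(s = mean(slope_mGCIPL))
  j <- dplyr::inner_join(vf, true_slope, by = "eye_id")
  expect_gt(sum(j$vf_progressor), 5)
  w <- stats::wilcox.test(j$s[j$vf_progressor], j$s[!j$vf_progressor],
                          alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 0.05)
})
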