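# Visual-field progression: pointwise linear regression on the central 16
# points of the 24-2 pattern, with a contiguous-cluster progressor rule.

# internal: OLS slope of y on t (years) with t-test p-value; n >= 3
ols_slope_p <- function(t, y) {
  n <- length(t)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * y) / sxx
  resid <- y - (mean(y) + slope * tc)
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  p <- if (se == 0) (if (slope == 0) 1 else 0) else
    2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  c(slope = slope, se = se, p_value = p)
}

#' Pointwise visual-field slopes
#'
#' Per-test-point OLS regression of sensitivity (dB) on time (years). A point
#' is progressive when its slope is worse than `threshold` dB/year (default
#' -1) and, when `require_significance` is `TRUE`, its slope p-value is below
#' 0.05.
#'
#' @param vf Tibble of VF observations for one eye: `date` (days), `row`,
#'   `col`, `sensitivity`. Baseline exams belong in the series.
#' @param threshold Progression threshold, dB/year.
#' @param require_significance Also require p < 0.05 on the point slope.
#' @return Tibble per point: `row`, `col`, `slope`, `se`, `p_value`,
#'   `progressive`, `n_exams`.
#' @export
vf_pointwise_slopes <- function(vf, threshold = -1,
                                require_significance = TRUE) {
  n_ex <- dplyr::n_distinct(vf$date)
  if (n_ex < 3L) abort("pointwise VF regression needs >= 3 exams")
  out <- vf |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      res = list(ols_slope_p(.data$date / 365.25, .data$sensitivity)),
      n_exams = dplyr::n(), .groups = "drop") |>
    tidyr::unnest_wider("res")
  out$progressive <- out$slope < threshold &
    (!require_significance | out$p_value < 0.05)
  out
}

# internal: is there a 4-connected cluster of >= min_points TRUE cells?
has_cluster <- function(row, col, flag, min_points = 3L) {
  if (sum(flag) < min_points) return(FALSE)
  pts <- cbind(row, col)[flag, , drop = FALSE]
  key <- paste(pts[, 1], pts[, 2])
  seen <- rep(FALSE, nrow(pts))
  for (start in seq_len(nrow(pts))) {
    if (seen[start]) next
    stack <- start
    comp <- 0L
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[i]) next
      seen[i] <- TRUE
      comp <- comp + 1L
      nb <- paste(pts[i, 1] + c(-1, 1, 0, 0), pts[i, 2] + c(0, 0, -1, 1))
      stack <- c(stack, which(key %in% nb & !seen))
    }
    if (comp >= min_points) return(TRUE)
  }
  FALSE
}

#' Classify an eye as a visual-field progressor
#'
#' Progressor iff the central 16 points contain a 4-connected cluster of at
#' least `min_points` progressive points ("more than 2 continuous progressive
#' test points" read literally as >= 3; set `min_points = 2` for the laxer
#' convention).
#'
#' @param slopes Output of [vf_pointwise_slopes()] restricted to (or
#'   containing) the central 4x4 block.
#' @param min_points Minimum cluster size (default 3).
#' @param contiguous Require 4-connectivity (default `TRUE`); if `FALSE`, any
#'   `min_points` progressive points suffice.
#' @return Logical.
#' @export
classify_progressor <- function(slopes, min_points = 3L, contiguous = TRUE) {
  c16 <- dplyr::semi_join(slopes, central16_points(), by = c("row", "col"))
  if (!contiguous) return(sum(c16$progressive) >= min_points)
  has_cluster(c16$row, c16$col, c16$progressive, min_points = min_points)
}

#' Mean total deviation over the central 16 points
#'
#' @param exam Tibble of one VF exam with `row`, `col`, `total_deviation`
#'   covering the central 4x4 block.
#' @return Arithmetic mean (dB) of the 16 central total-deviation values.
#' @export
td_c16 <- function(exam) {
  c16 <- dplyr::semi_join(exam, central16_points(), by = c("row", "col"))
  if (nrow(c16) != 16L || anyNA(c16$total_deviation)) {
    abort("td_c16 needs all 16 central total-deviation values")
  }
  mean(c16$total_deviation)
}

#' Per-eye visual-field progression analysis
#'
#' Applies [vf_pointwise_slopes()] and [classify_progressor()] to every eye
#' with at least 3 VF exams.
#'
#' @param cohort An `oct_cohort` with VF data.
#' @param threshold,require_significance,min_points,contiguous Rule
#'   parameters, see [vf_pointwise_slopes()] and [classify_progressor()].
#' @return Tibble per eye: `eye_id`, `n_exams`, `n_progressive_points`,
#'   `vf_progressor`, `td_c16_baseline`, `td_c16_slope`.
#' @export
vf_analysis <- function(cohort, threshold = -1, require_significance = TRUE,
                        min_points = 3L, contiguous = TRUE) {
  stopifnot(inherits(cohort, "oct_cohort"))
  if (!nrow(cohort$vf)) abort("cohort has no VF data")
  cohort$vf |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::group_modify(function(df, key) {
      sl <- vf_pointwise_slopes(df, threshold = threshold,
                                require_significance = require_significance)
      first_exam <- df[df$date == min(df$date), ]
      td_series <- df |>
        dplyr::group_by(date = .data$date) |>
        dplyr::summarise(td = mean(.data$total_deviation))
      td_fit <- ols_slope_p(td_series$date / 365.25, td_series$td)
      tibble(
        n_exams = dplyr::n_distinct(df$date),
        n_progressive_points = sum(sl$progressive),
        vf_progressor = classify_progressor(sl, min_points = min_points,
                                            contiguous = contiguous),
        td_c16_baseline = td_c16(first_exam),
        td_c16_slope = unname(td_fit["slope"]))
    }) |>
    dplyr::ungroup()
}
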