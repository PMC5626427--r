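# Trend analysis: per-eye, per-region OLS slopes with normative comparison
# and per-eye faster-hemifield / fastest-sector selection.

#' Mean thickness of a region at one visit
#'
#' @param grid_values Tibble with `row`, `col`, `thickness` for one eye,
#'   visit and layer (100 rows).
#' @param region A maskable region id (see [region_points()]).
#' @param sector_map One layer's sector map (required for clock regions).
#' @return Unweighted mean thickness (um) over the region's grid points.
#' @export
region_mean <- function(grid_values, region, sector_map = NULL) {
  pts <- region_points(region, sector_map)
  vals <- dplyr::semi_join(grid_values, pts, by = c("row", "col"))
  if (nrow(vals) != nrow(pts)) {
    abort(sprintf("region '%s': %d of %d points missing from grid",
                  region, nrow(pts) - nrow(vals), nrow(pts)))
  }
  mean(vals$thickness)
}

# internal: per-visit region means for all eyes x base regions of one layer.
# Returns tibble eye_id, date, region, value.
region_series <- function(cohort, layer, sector_map) {
  sm <- sector_map[sector_map$layer == layer, ]
  masks <- lapply(setNames(BASE_REGIONS, BASE_REGIONS), function(rg) {
    pts <- tryCatch(region_points(rg, sm), error = function(e) NULL)
    pts
  })
  masks <- masks[!vapply(masks, is.null, logical(1))]
  mac <- cohort$macular[cohort$macular$layer == layer, ]
  dplyr::bind_rows(lapply(names(masks), function(rg) {
    mac |>
      dplyr::semi_join(masks[[rg]], by = c("row", "col")) |>
      dplyr::group_by(.data$eye_id, .data$date) |>
      dplyr::summarise(value = mean(.data$thickness), .groups = "drop") |>
      dplyr::mutate(region = rg)
  }))
}

#' Ordinary least-squares slope of thickness on time
#'
#' Time is measured in years (365.25 days) from the first visit.
#'
#' @param date Visit dates in days.
#' @param value Region-mean thickness (um) per visit.
#' @return One-row tibble: `slope` (um/year), `se`, `r_squared`, `n_visits`.
#'   `se` is 0 for an exact fit.
#' @examples
#' fit_slope(c(0, 200, 400, 600, 800), 30 - c(0, 200, 400, 600, 800) / 365.25)
#' @export
fit_slope <- function(date, value) {
  stopifnot(length(date) == length(value))
  if (length(date) < 5L) abort("fit_slope needs >= 5 visits")
  t <- (date - date[1]) / 365.25
  if (length(unique(t)) < 2L) abort("fit_slope needs >= 2 distinct dates")
  n <- length(t)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * value) / sxx
  intercept <- mean(value) - slope * mean(t)
  resid <- value - intercept - slope * t
  rss <- sum(resid^2)
  tss <- sum((value - mean(value))^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  tibble(slope = slope, se = se,
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         n_visits = n)
}

#' Classify a fitted slope against the normative course
#'
#' One-sided test of H0: slope >= normative slope mean, combining the
#' sampling standard error of the fitted slope with the normative
#' between-subject slope SD:
#' `z = (slope - slope_mean) / sqrt(se^2 + slope_sd^2)`; progressive iff the
#' one-sided p-value `P(Z <= z)` is below `alpha`.
#'
#' @param slope,se Fitted slope (um/year) and its standard error.
#' @param slope_mean,slope_sd Normative slope mean and between-subject SD.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `z`, `p_vs_normative`, `progressive`.
#' @export
classify_trend <- function(slope, se, slope_mean, slope_sd, alpha = 0.05) {
  if (is.na(slope_mean) || is.na(slope_sd) || slope_sd <= 0) {
    abort("missing or invalid normative entry")
  }
  z <- (slope - slope_mean) / sqrt(se^2 + slope_sd^2)
  p <- pnorm(z)
  tibble(z = z, p_vs_normative = p,
         progressive = (p < alpha) & (slope < slope_mean))
}

#' Per-eye, per-region trend analysis
#'
#' Fits OLS slopes of region-mean thickness on time for every eligible eye
#' (>= 5 visits spanning >= 2 years), every base region (average, hemifields,
#' assigned clock sectors) and layer; classifies each against the normative
#' reference; and resolves the per-eye selections `faster_hemifield`,
#' `fastest_sector` (most negative clock-sector slope) and `fastest_overall`
#' (most negative among hemifields and clock sectors). Selection ties break
#' toward the lower clock hour (hemifields: superior first).
#'
#' @param cohort An `oct_cohort`.
#' @param sector_map An `oct_sector_map` covering the analysed layers.
#' @param normative A [normative_reference()] table.
#' @param layers Layers to analyse (default both).
#' @param alpha Significance level for the normative comparison.
#' @return An object of class `oct_trend`; `tidy()` returns the per-eye
#'   region table (`eye_id`, `layer`, `region`, `selected_from`, `slope`,
#'   `se`, `r_squared`, `n_visits`, `z`, `p_vs_normative`, `progressive`),
#'   `glance()` a per-layer-region cohort summary.
#' @export
trend_analysis <- function(cohort, sector_map, normative = normative_reference(),
                           layers = LAYERS, alpha = 0.05) {
  stopifnot(inherits(cohort, "oct_cohort"))
  keep <- eligible_eyes(cohort)
  fits <- dplyr::bind_rows(lapply(layers, function(lay) {
    region_series(cohort, lay, sector_map) |>
      dplyr::filter(.data$eye_id %in% keep) |>
      dplyr::group_by(.data$eye_id, .data$region) |>
      dplyr::arrange(.data$date, .by_group = TRUE) |>
      dplyr::reframe(fit_slope(.data$date, .data$value)) |>
      dplyr::mutate(layer = lay)
  }))

  fits <- dplyr::bind_rows(fits, select_extreme_regions(fits))
  fits <- fits |>
    dplyr::left_join(normative[c("layer", "region", "slope_mean", "slope_sd")],
                     by = c("layer", "region")) |>
    dplyr::rowwise() |>
    dplyr::mutate(classify_trend(.data$slope, .data$se, .data$slope_mean,
                                 .data$slope_sd, alpha = alpha)) |>
    dplyr::ungroup() |>
    dplyr::select("eye_id", "layer", "region", dplyr::any_of("selected_from"),
                  "slope", "se", "r_squared", "n_visits", "z",
                  "p_vs_normative", "progressive") |>
    dplyr::arrange(.data$eye_id, .data$layer,
                   factor(.data$region, levels = REGIONS))
  structure(list(results = fits, alpha = alpha), class = "oct_trend")
}

#' Resolve per-eye extreme-region slopes
#'
#' From a per-eye table of base-region slopes, selects for each eye and layer
#' the faster (more negative) hemifield, the fastest clock sector, and the
#' fastest overall region (clock sectors and hemifields pooled). No
#' selection-bias correction is applied: slopes are reported as estimated.
#'
#' @param fits Tibble with `eye_id`, `layer`, `region`, `slope` (+ fit
#'   columns) covering the base regions.
#' @return Tibble of the selected rows, with `region` renamed to the
#'   selection id and the source region kept in `selected_from`.
#' @export
select_extreme_regions <- function(fits) {
  pick_min <- function(df, regions, id) {
    sub <- df[df$region %in% regions, ]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(sub$slope, match(sub$region, regions)), ]
    out <- sub[1, ]
    out$selected_from <- out$region
    out$region <- id
    out
  }
  fits |>
    dplyr::group_by(.data$eye_id, .data$layer) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_rows(
        pick_min(df, c("superior", "inferior"), "faster_hemifield"),
        pick_min(df, paste0("clock", 7:11), "fastest_sector"),
        pick_min(df, c(paste0("clock", 7:11), "superior", "inferior"),
                 "fastest_overall"))
    }) |>
    dplyr::ungroup()
}

#' @export
print.oct_trend <- function(x, ...) {
  cat(sprintf("<oct_trend> %d eyes, %d layer(s); alpha = %g\n",
              dplyr::n_distinct(x$results$eye_id),
              dplyr::n_distinct(x$results$layer), x$alpha))
  print(glance(x))
  invisible(x)
}

#' @rdname trend_analysis
#' @param x An `oct_trend` object.
#' @param ... Unused.
#' @method tidy oct_trend
#' @export
tidy.oct_trend <- function(x, ...) x$results

#' @rdname trend_analysis
#' @method glance oct_trend
#' @export
glance.oct_trend <- function(x, ...) {
  avg <- x$results |>
    dplyr::filter(.data$region == "average") |>
    dplyr::select("eye_id", "layer", avg_slope = "slope")
  x$results |>
    dplyr::left_join(avg, by = c("eye_id", "layer")) |>
    dplyr::group_by(.data$layer, .data$region) |>
    dplyr::summarise(
      n_eyes = dplyr::n(),
      mean_slope = mean(.data$slope),
      sd_slope = sd(.data$slope),
      prop_progressive = mean(.data$progressive),
      p_vs_average = if (dplyr::first(.data$region) == "average") NA_real_ else
        tryCatch(wilcox.test(.data$slope, .data$avg_slope,
                             paired = TRUE)$p.value,
                 error = function(e) NA_real_),
      .groups = "drop") |>
    dplyr::arrange(.data$layer, factor(.data$region, levels = REGIONS))
}
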