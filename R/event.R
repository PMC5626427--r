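# Event analysis: confirmed drop below a two-exam baseline minus a
# test-retest fluctuation margin.

#' Two-exam baseline of a region-mean series
#'
#' @param values Region-mean thickness per visit, in date order.
#' @return Mean of the first two values.
#' @export
event_baseline <- function(values) {
  if (length(values) < 2L) abort("event baseline needs >= 2 visits")
  mean(values[1:2])
}

#' Detect a confirmed event in a region-mean series
#'
#' A visit (from the third on) is flagged when its value falls below
#' `baseline - k * fluct_sd * sqrt(1.5)`; the `sqrt(1.5)` term accounts for
#' comparing a single exam against the mean of two baseline exams
#' (`Var(x - (b1 + b2)/2) = sigma^2 (1 + 1/2)`). The region has progressed
#' when a flagged visit is followed by at least `confirm` consecutive flagged
#' visits; the onset is the first exam of the confirmed run. By default the
#' last visit cannot confirm itself (`confirm_at_end = FALSE`).
#'
#' @param values Region-mean thickness per visit, date order.
#' @param fluct_sd Test-retest fluctuation SD (um) of a single exam,
#'   > 0.
#' @param k Multiplier on the fluctuation margin (default 2).
#' @param confirm Number of subsequent consecutive flagged visits required
#'   (default 1).
#' @param confirm_at_end If `TRUE`, a flagged run truncated by the end of the
#'   series counts as confirmed.
#' @return One-row tibble: `progressed`, `onset_visit` (1-based index of the
#'   first exam of the confirmed run, `NA` if none), `baseline`, `threshold`.
#' @examples
#' detect_event(c(30, 30, 30, 20, 20), fluct_sd = 1)
#' @export
detect_event <- function(values, fluct_sd, k = 2, confirm = 1L,
                         confirm_at_end = FALSE) {
  if (fluct_sd <= 0) abort("fluct_sd must be > 0")
  baseline <- event_baseline(values)
  threshold <- baseline - k * fluct_sd * sqrt(1.5)
  n <- length(values)
  flagged <- values < threshold
  flagged[1:2] <- FALSE               # baseline exams are never events
  onset <- NA_integer_
  if (n >= 3L) {
    for (i in 3:n) {
      if (!flagged[i]) next
      run <- i
      while (run < n && flagged[run + 1L]) run <- run + 1L
      len <- run - i + 1L
      if (len >= confirm + 1L || (confirm_at_end && run == n)) {
        onset <- i
        break
      }
      # skip past this unconfirmed run
    }
  }
  tibble(progressed = !is.na(onset), onset_visit = onset,
         baseline = baseline, threshold = threshold)
}

#' Per-eye, per-region event analysis
#'
#' Runs [detect_event()] on every eligible eye (>= 5 visits over >= 2 years),
#' base region and layer, taking each region's fluctuation SD from the
#' normative reference.
#'
#' @inheritParams trend_analysis
#' @param k,confirm,confirm_at_end Event rule parameters (see
#'   [detect_event()]).
#' @return An object of class `oct_events`; `tidy()` returns the per-eye
#'   table, `glance()` the per-region counts with the `any_hemifield` /
#'   `any_sector` rollups (see [summarize_events()]).
#' @export
event_analysis <- function(cohort, sector_map, normative = normative_reference(),
                           layers = LAYERS, k = 2, confirm = 1L,
                           confirm_at_end = FALSE) {
  stopifnot(inherits(cohort, "oct_cohort"))
  keep <- eligible_eyes(cohort)
  res <- dplyr::bind_rows(lapply(layers, function(lay) {
    region_series(cohort, lay, sector_map) |>
      dplyr::filter(.data$eye_id %in% keep) |>
      dplyr::left_join(
        normative[normative$layer == lay, c("region", "fluctuation_sd")],
        by = "region") |>
      dplyr::group_by(.data$eye_id, .data$region) |>
      dplyr::arrange(.data$date, .by_group = TRUE) |>
      dplyr::reframe(detect_event(.data$value,
                                  fluct_sd = .data$fluctuation_sd[1],
                                  k = k, confirm = confirm,
                                  confirm_at_end = confirm_at_end)) |>
      dplyr::mutate(layer = lay)
  })) |>
    dplyr::select("eye_id", "layer", "region", "progressed", "onset_visit",
                  "baseline", "threshold")
  structure(list(results = res, k = k, confirm = confirm),
            class = "oct_events")
}

#' Summarise event counts per region with union rollups
#'
#' @param events An `oct_events` object (or its tidy table).
#' @return Tibble per layer and region: `n_eyes`, `n_progressed`,
#'   `pct_progressed`, including `any_hemifield` (progression in superior or
#'   inferior) and `any_sector` (progression in any clock sector) rollup rows.
#' @export
summarize_events <- function(events) {
  res <- if (inherits(events, "oct_events")) events$results else events
  roll <- function(df, regions, id) {
    df |>
      dplyr::filter(.data$region %in% regions) |>
      dplyr::group_by(.data$eye_id, .data$layer) |>
      dplyr::summarise(progressed = any(.data$progressed), .groups = "drop") |>
      dplyr::mutate(region = id)
  }
  base <- res[c("eye_id", "layer", "region", "progressed")]
  all_rows <- dplyr::bind_rows(
    base,
    roll(base, c("superior", "inferior"), "any_hemifield"),
    roll(base, paste0("clock", 7:11), "any_sector"))
  all_rows |>
    dplyr::group_by(.data$layer, .data$region) |>
    dplyr::summarise(n_eyes = dplyr::n(),
                     n_progressed = sum(.data$progressed),
                     pct_progressed = 100 * mean(.data$progressed),
                     .groups = "drop") |>
    dplyr::arrange(.data$layer,
                   factor(.data$region,
                          levels = c(BASE_REGIONS, "any_hemifield",
                                     "any_sector")))
}

#' @export
print.oct_events <- function(x, ...) {
  cat(sprintf("<oct_events> k = %g, confirm = %d\n", x$k, x$confirm))
  print(summarize_events(x))
  invisible(x)
}

#' @rdname event_analysis
#' @param x An `oct_events` object.
#' @param ... Unused.
#' @method tidy oct_events
#' @export
tidy.oct_events <- function(x, ...) x$results

#' @rdname event_analysis
#' @method glance oct_events
#' @export
glance.oct_events <- function(x, ...) summarize_events(x)
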