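# Cohort container and tabular I/O.
#
# An `oct_cohort` holds tidy per-visit tables, always in the right-eye frame:
#   eyes    : eye_id, patient_id, laterality
#   visits  : eye_id, date (days since first visit), quality
#   macular : eye_id, date, layer, row, col, thickness (um)
#   cprnfl  : eye_id, date, clock_hour (1-12), thickness (um)
#   vf      : eye_id, date, row, col (central 4x4), sensitivity, total_deviation (dB)
#
# On disk the cohort is a single long CSV in the eye's *native* orientation
# (OS eyes mirrored); `read_cohort()` mirrors OS eyes into the right-eye frame
# and `write_cohort()` mirrors them back, so write(read(f)) round-trips all
# numeric fields exactly.

new_oct_cohort <- function(eyes, visits, macular, cprnfl, vf,
                           dropped_visits = 0L) {
  structure(
    list(eyes = as_tibble(eyes), visits = as_tibble(visits),
         macular = as_tibble(macular), cprnfl = as_tibble(cprnfl),
         vf = as_tibble(vf)),
    dropped_visits = dropped_visits,
    class = "oct_cohort"
  )
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf(
    "<oct_cohort> %d eyes (%d patients), %d visits; %d macular rows, %s VF exams\n",
    nrow(x$eyes), dplyr::n_distinct(x$eyes$patient_id), nrow(x$visits),
    nrow(x$macular),
    if (nrow(x$vf)) as.character(dplyr::n_distinct(x$vf[c("eye_id", "date")]))
    else "no"))
  invisible(x)
}

#' Validate cohort invariants
#'
#' Checks that every (eye, visit, layer) macular scan has exactly 100 grid
#' values in 0-200 um, every circumpapillary profile has 12 non-negative
#' clock-hour values, and visit dates are non-negative and strictly increasing
#' within each eye.
#'
#' @param cohort An `oct_cohort`.
#' @return `cohort`, invisibly; aborts on violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "oct_cohort"))
  m <- cohort$macular
  counts <- dplyr::count(m, .data$eye_id, .data$date, .data$layer)
  if (any(counts$n != 100L)) abort("macular scans must have exactly 100 grid points")
  if (any(m$thickness < 0 | m$thickness > 200)) {
    abort("macular thickness out of range [0, 200] um")
  }
  cp <- dplyr::count(cohort$cprnfl, .data$eye_id, .data$date)
  if (any(cp$n != 12L)) abort("cpRNFL profiles must have 12 clock-hour entries")
  if (any(cohort$cprnfl$thickness < 0)) abort("cpRNFL thickness must be >= 0")
  bad_dates <- cohort$visits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(ok = all(.data$date >= 0) &&
                       all(diff(sort(.data$date)) > 0) &&
                       !anyDuplicated(.data$date)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad_dates)) {
    abort(paste("non-increasing or negative visit dates for eye(s):",
                paste(bad_dates$eye_id, collapse = ", ")))
  }
  invisible(cohort)
}

# internal: eyes with >= min_visits and span >= min_span_days; others dropped
# with a warning. Unit of progression analysis.
eligible_eyes <- function(cohort, min_visits = 5L, min_span_days = 730) {
  spans <- cohort$visits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(n = dplyr::n(), span = max(.data$date) - min(.data$date))
  bad <- spans$eye_id[spans$n < min_visits | spans$span < min_span_days]
  if (length(bad)) {
    warn(sprintf(
      "%d eye(s) excluded from progression analysis (< %d visits or span < %d days)",
      length(bad), min_visits, min_span_days))
  }
  setdiff(spans$eye_id, bad)
}

# internal: mirror all laterality-dependent coordinates of the given eyes
mirror_eyes <- function(cohort, eye_ids) {
  if (!length(eye_ids)) return(cohort)
  i <- cohort$macular$eye_id %in% eye_ids
  cohort$macular$col[i] <- mirror_col(cohort$macular$col[i])
  j <- cohort$cprnfl$eye_id %in% eye_ids
  cohort$cprnfl$clock_hour[j] <- mirror_clock_hour(cohort$cprnfl$clock_hour[j])
  if (nrow(cohort$vf)) {
    k <- cohort$vf$eye_id %in% eye_ids
    cohort$vf$col[k] <- mirror_vf_col(cohort$vf$col[k])
  }
  cohort
}

cohort_csv_columns <- c(
  "patient_id", "eye_id", "laterality", "date", "block", "quality", "layer",
  "clock_hour", "row", "col", "thickness", "sensitivity", "total_deviation")

#' Read a cohort from a long-format CSV
#'
#' The file holds one row per measured value, tagged by `block`:
#' `"macular"` rows carry `layer`, `row`, `col`, `thickness`, `quality`;
#' `"cprnfl"` rows carry `clock_hour`, `thickness`; `"vf"` rows carry `row`,
#' `col`, `sensitivity`, `total_deviation`. Coordinates are in the eye's
#' native orientation; left (OS) eyes are mirrored into the right-eye frame on
#' ingest. Visits whose macular image quality is not above `quality_min` are
#' dropped (and counted in the `dropped_visits` attribute).
#'
#' @param path CSV file path.
#' @param quality_min Minimum acceptable image quality; visits with
#'   `quality <= quality_min` are dropped. Default 40 (the inclusion-criterion
#'   threshold); use 70 for the stricter per-scan rule.
#' @return An `oct_cohort` (visits sorted by date within eye).
#' @export
read_cohort <- function(path, quality_min = 40) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(cohort_csv_columns, names(raw))
  if (length(missing_cols)) {
    abort(paste("cohort file is missing mandatory column(s):",
                paste(missing_cols, collapse = ", ")))
  }

  mac <- raw[raw$block == "macular", ]
  dup <- anyDuplicated(mac[c("eye_id", "date", "layer", "row", "col")])
  if (dup) abort("duplicate (eye, date, layer, row, col) macular rows")

  eyes <- dplyr::distinct(raw, .data$eye_id, .data$patient_id, .data$laterality)
  if (anyDuplicated(eyes$eye_id)) {
    abort("inconsistent patient_id/laterality within an eye_id")
  }
  if (!all(eyes$laterality %in% c("OD", "OS"))) {
    abort("laterality must be 'OD' or 'OS'")
  }

  # quality filter: drop whole visits measured at or below threshold
  vq <- mac |>
    dplyr::group_by(.data$eye_id, .data$date) |>
    dplyr::summarise(quality = min(.data$quality), .groups = "drop")
  bad_visits <- vq[vq$quality <= quality_min, c("eye_id", "date")]
  dropped <- nrow(bad_visits)
  if (dropped) {
    raw <- dplyr::anti_join(raw, bad_visits, by = c("eye_id", "date"))
    mac <- raw[raw$block == "macular", ]
    vq <- dplyr::semi_join(vq, raw, by = c("eye_id", "date"))
  }

  visits <- dplyr::arrange(vq, .data$eye_id, .data$date)
  cohort <- new_oct_cohort(
    eyes = dplyr::arrange(eyes, .data$eye_id),
    visits = visits,
    macular = mac[c("eye_id", "date", "layer", "row", "col", "thickness")],
    cprnfl = raw[raw$block == "cprnfl",
                 c("eye_id", "date", "clock_hour", "thickness")],
    vf = raw[raw$block == "vf",
             c("eye_id", "date", "row", "col", "sensitivity",
               "total_deviation")],
    dropped_visits = dropped
  )
  cohort <- mirror_eyes(cohort, eyes$eye_id[eyes$laterality == "OS"])
  validate_cohort(cohort)
}

#' Write a cohort to a long-format CSV
#'
#' Inverse of [read_cohort()]: OS eyes are mirrored back to their native
#' orientation before writing.
#'
#' @param cohort An `oct_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "oct_cohort"))
  cohort <- mirror_eyes(
    cohort, cohort$eyes$eye_id[cohort$eyes$laterality == "OS"])
  meta <- cohort$eyes
  qual <- cohort$visits

  mac <- cohort$macular |>
    dplyr::left_join(qual, by = c("eye_id", "date")) |>
    dplyr::mutate(block = "macular", clock_hour = NA_integer_,
                  sensitivity = NA_real_, total_deviation = NA_real_)
  cp <- cohort$cprnfl |>
    dplyr::mutate(block = "cprnfl", quality = NA_real_, layer = NA_character_,
                  row = NA_integer_, col = NA_integer_,
                  sensitivity = NA_real_, total_deviation = NA_real_)
  vf <- cohort$vf
  if (nrow(vf)) {
    vf <- vf |>
      dplyr::mutate(block = "vf", quality = NA_real_, layer = NA_character_,
                    clock_hour = NA_integer_, thickness = NA_real_)
  } else {
    vf <- NULL
  }
  out <- dplyr::bind_rows(mac, cp, vf) |>
    dplyr::left_join(meta, by = "eye_id") |>
    dplyr::select(dplyr::all_of(cohort_csv_columns)) |>
    dplyr::arrange(.data$eye_id, .data$date, .data$block, .data$layer,
                   .data$clock_hour, .data$row, .data$col)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
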