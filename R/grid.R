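# Grid conventions
#
# All in-memory macular grids use the right-eye (OD) frame:
#   row 1 = anatomically superior retina, row 10 = inferior;
#   col 1 = temporal, col 10 = nasal (optic-disc side).
# Left (OS) eyes are mirrored horizontally on ingest so a single sector map
# serves both eyes; clock hours are mirrored accordingly (e.g. OS 5 -> 7).

#' All 100 macular grid points
#'
#' @return A tibble with integer columns `row` and `col`, rows 1-10
#'   (1 = superior) and cols 1-10 (1 = temporal), in row-major order.
#' @export
grid_points <- function() {
  tidyr::expand_grid(row = 1:10, col = 1:10)
}

#' Hemifield membership on the macular grid
#'
#' The horizontal raphe splits the 10x10 grid between rows 5 and 6:
#' the superior hemifield is rows 1-5, the inferior rows 6-10.
#'
#' @param which `"superior"` or `"inferior"`.
#' @return A tibble of `row`, `col` grid points (50 each; the two masks are
#'   disjoint and jointly exhaustive).
#' @examples
#' nrow(hemifield_mask("superior")) # 50
#' @export
hemifield_mask <- function(which = c("superior", "inferior")) {
  which <- match.arg(which)
  rows <- if (which == "superior") 1:5 else 6:10
  tidyr::expand_grid(row = rows, col = 1:10)
}

#' Mirror a column index between OD and OS orientation
#' @param col Integer column index in 1..10.
#' @return The horizontally mirrored index (`11 - col`). Involutive.
#' @export
mirror_col <- function(col) {
  stopifnot(all(col %in% 1:10))
  11L - as.integer(col)
}

#' Mirror a clock hour between OD and OS orientation
#'
#' Mirrors across the vertical meridian: 3 <-> 9, 1 <-> 11, 12 and 6 fixed.
#' Under this map the OS temporal hours 1-5 land on the right-eye temporal
#' hours 11-7.
#'
#' @param hour Integer clock hour in 1..12.
#' @return Mirrored clock hour. Involutive.
#' @export
mirror_clock_hour <- function(hour) {
  stopifnot(all(hour %in% 1:12))
  h <- (12L - as.integer(hour)) %% 12L
  ifelse(h == 0L, 12L, h)
}

#' Mirror a visual-field column index (central 4x4 block)
#' @param col Integer column in 1..4.
#' @return `5 - col`.
#' @export
mirror_vf_col <- function(col) {
  stopifnot(all(col %in% 1:4))
  5L - as.integer(col)
}

#' Central-16 visual-field test points
#'
#' The 16 central points of the 24-2 pattern form a 4x4 block; they cover the
#' visual field projected from the macular cube. Row 1 is the most superior
#' field row (which images the *inferior* retina), col 1 the most temporal.
#'
#' @return Tibble of `row`, `col` in 1..4 (16 rows).
#' @export
central16_points <- function() {
  tidyr::expand_grid(row = 1:4, col = 1:4)
}

#' Map a central-16 visual-field point to its macular grid point
#'
#' The field is inverted on the retina: superior field rows image inferior
#' retinal rows. The central 4x4 block covers the middle of the macular cube.
#'
#' @param row,col Visual-field point indices in 1..4.
#' @return Tibble with `ret_row`, `ret_col` macular grid indices.
#' @export
vf_to_macula <- function(row, col) {
  stopifnot(all(row %in% 1:4), all(col %in% 1:4))
  tibble(ret_row = 8L - as.integer(row), ret_col = as.integer(col) + 3L)
}

#' Grid points belonging to a region
#'
#' @param region One of `"average"`, `"superior"`, `"inferior"`, or
#'   `"clock7"` ... `"clock11"`. Per-eye selections (`faster_hemifield`,
#'   `fastest_sector`, `fastest_overall`) are resolved from fitted slopes, not
#'   from a fixed mask.
#' @param sector_map For clock regions, a sector map tibble for one layer with
#'   columns `row`, `col`, `sector` (see [assign_sectors()]).
#' @return Tibble of `row`, `col`.
#' @export
region_points <- function(region, sector_map = NULL) {
  if (region == "average") return(grid_points())
  if (region %in% c("superior", "inferior")) return(hemifield_mask(region))
  if (grepl("^clock(7|8|9|10|11)$", region)) {
    if (is.null(sector_map)) {
      abort("clock regions require a `sector_map`")
    }
    s <- as.integer(sub("^clock", "", region))
    pts <- sector_map[!is.na(sector_map$sector) & sector_map$sector == s,
                      c("row", "col")]
    if (nrow(pts) == 0L) {
      abort(paste0("region '", region, "' has no assigned grid points"))
    }
    return(as_tibble(pts))
  }
  abort(paste0("unknown or non-maskable region: '", region, "'"))
}

# internal: long grid tibble from a 10x10 matrix
grid_to_tibble <- function(m, value_name = "thickness") {
  stopifnot(is.matrix(m), all(dim(m) == c(10L, 10L)))
  out <- grid_points()
  out[[value_name]] <- m[cbind(out$row, out$col)]
  out
}

# internal: 10x10 matrix from long tibble (row, col, value)
tibble_to_grid <- function(df, value_col = "thickness") {
  m <- matrix(NA_real_, 10, 10)
  m[cbind(df$row, df$col)] <- df[[value_col]]
  m
}
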