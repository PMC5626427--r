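# Parametric model of retinal nerve fiber bundle trajectories.
#
# Fibers from the macula enter the optic disc at the temporal clock hours
# 7-11 (right-eye convention): the papillomacular bundle (9 o'clock) serves a
# horizontal band around the raphe; superior fibers arc into 10 then 11 as
# they originate further from the raphe and further temporally; inferior
# fibers mirror into 8 then 7. Fibers never cross the horizontal raphe.
#
# The model scores each grid point by an "entry height"
#   h = y * (1 + curvature * d_t)
# where y is the signed distance above the raphe (rows) and d_t in (0, 1] the
# normalized temporal distance from the disc; thresholds on |h| split the
# grid into arc-shaped sectors. The curvature term bends iso-sector contours
# temporally, reproducing the arcuate geometry.

#' Arcuate nerve-fiber-bundle trajectory model
#'
#' @param superior_curvature,inferior_curvature Dimensionless arc curvature
#'   per hemifield (larger = stronger temporal bending). Defaults 0.8.
#' @param raphe_row Row coordinate of the horizontal raphe; default 5.5
#'   (between grid rows 5 and 6).
#' @param pmb_halfwidth Half-width of the papillomacular (9 o'clock) band on
#'   the entry-height scale; default 1.2 (covers the two rows flanking the
#'   raphe).
#' @param split_superior,split_inferior Entry-height threshold separating
#'   sector 10 from 11 (superior) and 8 from 7 (inferior); default 4.6.
#' @return An object of class `bundle_model`.
#' @seealso [trajectory_map()]
#' @export
bundle_model <- function(superior_curvature = 0.8,
                         inferior_curvature = 0.8,
                         raphe_row = 5.5,
                         pmb_halfwidth = 1.2,
                         split_superior = 4.6,
                         split_inferior = 4.6) {
  stopifnot(superior_curvature >= 0, inferior_curvature >= 0,
            raphe_row > 1, raphe_row < 10, pmb_halfwidth > 0)
  structure(
    list(superior_curvature = superior_curvature,
         inferior_curvature = inferior_curvature,
         raphe_row = raphe_row,
         pmb_halfwidth = pmb_halfwidth,
         split_superior = split_superior,
         split_inferior = split_inferior),
    class = "bundle_model"
  )
}

#' @export
print.bundle_model <- function(x, ...) {
  cat("<bundle_model> arcuate trajectories:",
      sprintf("curvature sup/inf = %.2f/%.2f, raphe row = %.1f",
              x$superior_curvature, x$inferior_curvature, x$raphe_row),
      "\n")
  invisible(x)
}

#' Entry clock sector for each macular grid point
#'
#' Deterministically maps every grid point to the temporal clock hour (7-11)
#' at which its nerve fiber bundle enters the optic disc.
#'
#' @param bundle A [bundle_model()].
#' @return Tibble with `row`, `col`, `sector` (integer 7-11) for all 100
#'   points. Points above the raphe map only to 9-11, points below only to
#'   7-9.
#' @examples
#' table(trajectory_map(bundle_model())$sector)
#' @export
trajectory_map <- function(bundle = bundle_model()) {
  pts <- grid_points()
  y <- bundle$raphe_row - pts$row          # > 0 superior
  d_t <- (11 - pts$col) / 10               # 1 = most temporal, 0.1 = nasal edge
  curv <- ifelse(y >= 0, bundle$superior_curvature, bundle$inferior_curvature)
  h <- y * (1 + curv * d_t)
  sector <- integer(nrow(pts))
  sup <- h > 0
  sector[abs(h) <= bundle$pmb_halfwidth] <- 9L
  sector[sup & h > bundle$pmb_halfwidth] <-
    ifelse(h[sup & h > bundle$pmb_halfwidth] <= bundle$split_superior, 10L, 11L)
  sector[!sup & -h > bundle$pmb_halfwidth] <-
    ifelse(-h[!sup & -h > bundle$pmb_halfwidth] <= bundle$split_inferior, 8L, 7L)
  pts$sector <- sector
  pts
}

# internal: sector lookup matrix (10x10 integer) for fast indexing
trajectory_matrix <- function(bundle = bundle_model()) {
  tm <- trajectory_map(bundle)
  m <- matrix(NA_integer_, 10, 10)
  m[cbind(tm$row, tm$col)] <- tm$sector
  m
}

# internal: hemifield of a sector label: +1 superior (10,11), -1 inferior
# (7,8), 0 for the papillomacular 9.
sector_hemifield <- function(sector) {
  out <- integer(length(sector))
  out[sector %in% c(10L, 11L)] <- 1L
  out[sector %in% c(7L, 8L)] <- -1L
  out
}
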