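# Smooth healthy (normal-eye) thickness templates.

#' Healthy macular thickness template
#'
#' Builds a smooth 10x10 template (um, right-eye frame) for one layer. Each
#' bundle sector is anchored at its configured healthy target mean, a smooth
#' within-sector shape is added (an annulus peaking at ~2.5 grid units from
#' the fovea for mGCIPL, thin at fovea and periphery; a nasal-increasing
#' gradient toward the disc for mRNFL), and a single per-layer offset makes
#' the overall 100-point average match the configured average target exactly.
#'
#' The sector targets jointly over-determine the average, so individual
#' sector means sit at `target + offset` with a small common offset
#' (about +2 um for mRNFL, -0.7 um for mGCIPL under the default geometry);
#' the relative ordering of sector means is always preserved.
#'
#' @param layer `"mRNFL"` or `"mGCIPL"`.
#' @param bundle [bundle_model()] defining the sector geometry.
#' @param targets Healthy region targets as in [normative_reference()]
#'   (columns `layer`, `region`, `healthy_mean`).
#' @return A 10x10 numeric matrix (row 1 superior, col 1 temporal) with
#'   attribute `layer`. Deterministic: identical inputs give identical output.
#' @examples
#' mean(healthy_template("mGCIPL")) # 67.96
#' @export
healthy_template <- function(layer = c("mRNFL", "mGCIPL"),
                             bundle = bundle_model(),
                             targets = healthy_region_targets()) {
  layer <- match.arg(layer)
  tm <- trajectory_matrix(bundle)
  tg <- targets[targets$layer == layer, ]
  sector_target <- setNames(tg$healthy_mean[match(paste0("clock", 7:11),
                                                  tg$region)],
                            as.character(7:11))
  avg_target <- tg$healthy_mean[tg$region == "average"]

  base <- matrix(sector_target[as.character(tm)], 10, 10)

  rr <- matrix(1:10, 10, 10)
  cc <- matrix(1:10, 10, 10, byrow = TRUE)
  if (layer == "mGCIPL") {
    r <- sqrt((rr - 5.5)^2 + (cc - 5.5)^2)
    shape <- 6 * exp(-(r - 2.5)^2 / (2 * 1.5^2))
  } else {
    # RNFL thickens toward the disc (nasal) and along the arcades
    shape <- 5 * (cc - 5.5) / 4.5 + 2 * exp(-((abs(rr - 5.5) - 3)^2) / 4)
  }
  # re-center the shape within each sector so sector means stay on target
  for (s in 7:11) {
    idx <- tm == s
    shape[idx] <- shape[idx] - mean(shape[idx])
  }
  tmpl <- base + shape
  tmpl <- tmpl + (avg_target - mean(tmpl))
  tmpl <- pmax(tmpl, 1)
  attr(tmpl, "layer") <- layer
  tmpl
}
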