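# Derivation of axonal-tract-dependent macular sectors: per-grid-point
# Spearman correlation against the five temporal cpRNFL clock sectors,
# thresholded argmax assignment, then anatomical cleanup.

#' Correlate every macular grid point with the temporal cpRNFL sectors
#'
#' Cross-sectional analysis: one visit per eye (default the first), Spearman
#' rank correlation between each grid point's thickness and each temporal
#' clock sector's circumpapillary thickness across eyes.
#'
#' @param cohort An `oct_cohort`.
#' @param layer `"mRNFL"` or `"mGCIPL"`.
#' @param visit_policy `"first"` (default) or `"last"`: which visit represents
#'   each eye. Pooling multiple visits per eye is deliberately not offered
#'   (it would pseudo-replicate eyes).
#' @return A tibble of class `oct_cor_maps` with one row per grid point and
#'   sector: `layer`, `row`, `col`, `sector`, `rho`, `p_value`, `n`.
#'   Undefined correlations (constant input) have `NA` rho.
#' @export
correlate_grid <- function(cohort, layer = c("mRNFL", "mGCIPL"),
                           visit_policy = c("first", "last")) {
  stopifnot(inherits(cohort, "oct_cohort"))
  layer <- match.arg(layer)
  visit_policy <- match.arg(visit_policy)

  pick <- cohort$visits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(date = if (visit_policy == "first") min(.data$date)
                     else max(.data$date))
  n <- nrow(pick)
  if (n < 3L) abort("correlate_grid needs at least 3 eyes")
  if (n < 20L) {
    warn(sprintf("only %d eyes: sector correlations will be unstable", n))
  }

  mac <- cohort$macular |>
    dplyr::filter(.data$layer == !!layer) |>
    dplyr::inner_join(pick, by = c("eye_id", "date")) |>
    dplyr::arrange(.data$eye_id, .data$row, .data$col)
  X <- matrix(mac$thickness, nrow = n, byrow = TRUE)  # eyes x 100 (row-major pts)
  stopifnot(ncol(X) == 100L)

  cp <- cohort$cprnfl |>
    dplyr::filter(.data$clock_hour %in% TEMPORAL_SECTORS) |>
    dplyr::inner_join(pick, by = c("eye_id", "date")) |>
    dplyr::arrange(.data$eye_id, .data$clock_hour)
  Y <- matrix(cp$thickness, nrow = n, byrow = TRUE)   # eyes x 5 (hours 7..11)

  res <- spearman_matrix(X, Y)
  pts <- grid_points()
  out <- tidyr::expand_grid(idx = seq_len(100L), sector = TEMPORAL_SECTORS)
  out <- tibble(
    layer = layer,
    row = pts$row[out$idx], col = pts$col[out$idx], sector = out$sector,
    rho = as.vector(t(res$rho))[seq_len(nrow(out))],
    p_value = as.vector(t(res$p))[seq_len(nrow(out))],
    n = n)
  class(out) <- c("oct_cor_maps", class(out))
  out
}

#' Assign grid points to clock sectors by thresholded argmax correlation
#'
#' A point is assigned to the sector with the highest rho, provided that
#' maximum rho is at least `r_min` and its p-value is below `alpha`;
#' otherwise it stays unassigned (`NA`). Ties are broken toward the sector
#' predicted by the trajectory model, then toward the lower clock hour.
#'
#' @param maps Output of [correlate_grid()].
#' @param r_min Minimum correlation (default 0.4).
#' @param alpha Significance level for the winning correlation (default 0.05,
#'   uncorrected). Set `adjust = "BH"` for a Benjamini-Hochberg-adjusted
#'   variant.
#' @param bundle [bundle_model()] used only for tie-breaking.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A sector-map tibble of class `oct_sector_map`: `layer`, `row`,
#'   `col`, `sector` (integer 7-11 or `NA`), plus `rho` of the winning sector.
#' @export
assign_sectors <- function(maps, r_min = 0.4, alpha = 0.05,
                           bundle = bundle_model(),
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  maps <- as_tibble(maps)
  if (adjust == "BH") {
    maps <- maps |>
      dplyr::group_by(.data$layer) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  tmat <- trajectory_matrix(bundle)
  out <- maps |>
    dplyr::group_by(.data$layer, .data$row, .data$col) |>
    dplyr::group_modify(function(df, key) {
      df <- df[!is.na(df$rho), ]
      if (!nrow(df)) return(tibble(sector = NA_integer_, rho = NA_real_))
      top <- max(df$rho)
      cand <- df[df$rho == top, ]
      traj_sector <- tmat[key$row, key$col]
      pick <- if (traj_sector %in% cand$sector) traj_sector else min(cand$sector)
      win <- cand[cand$sector == pick, ]
      ok <- top >= r_min && win$p_value < alpha
      tibble(sector = if (ok) as.integer(pick) else NA_integer_, rho = top)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("layer", "row", "col", "sector", "rho") |>
    dplyr::arrange(.data$layer, .data$row, .data$col)
  class(out) <- c("oct_sector_map", class(out))
  out
}

# internal: 4-neighbour offsets
neighbours4 <- function(row, col) {
  nb <- cbind(row + c(-1L, 1L, 0L, 0L), col + c(0L, 0L, -1L, 1L))
  nb[nb[, 1] >= 1 & nb[, 1] <= 10 & nb[, 2] >= 1 & nb[, 2] <= 10, , drop = FALSE]
}

# internal: is every assigned label's point set 4-connected?
all_labels_connected <- function(m) {
  for (s in unique(m[!is.na(m)])) {
    idx <- which(m == s, arr.ind = TRUE)
    if (nrow(idx) <= 1L) next
    seen <- matrix(FALSE, 10, 10)
    stack <- list(idx[1, ])
    seen[idx[1, 1], idx[1, 2]] <- TRUE
    count <- 1L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      nb <- neighbours4(p[1], p[2])
      for (k in seq_len(nrow(nb))) {
        r <- nb[k, 1]; c <- nb[k, 2]
        if (!seen[r, c] && !is.na(m[r, c]) && m[r, c] == s) {
          seen[r, c] <- TRUE
          count <- count + 1L
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    if (count < nrow(idx)) return(FALSE)
  }
  TRUE
}

# internal: raphe consistency: a point whose trajectory is inferior (7/8) may
# not carry a superior label (10/11) and vice versa.
raphe_violations <- function(m, tmat) {
  viol <- !is.na(m) &
    ((sector_hemifield(tmat) == -1L & matrix(m %in% c(10L, 11L), 10, 10)) |
       (sector_hemifield(tmat) == 1L & matrix(m %in% c(7L, 8L), 10, 10)))
  viol
}

#' Anatomical correction of a raw sector map
#'
#' Iteratively relabels points by majority vote over their 4-neighbourhoods,
#' with candidate labels restricted to the neighbour labels plus the point's
#' trajectory label, and hemifield (raphe) consistency enforced: no point with
#' an inferior trajectory may carry a superior label or vice versa.
#' Unassigned points are filled with their trajectory label only when at
#' least 3 assigned neighbours share it; conversely, a disconnected island
#' that cannot take any hemifield-consistent label is demoted to unassigned. Iteration stops when every assigned
#' sector's point set is 4-connected, no raphe violation remains, and the map
#' is a fixed point of the relabeling sweep.
#'
#' @param raw An `oct_sector_map` from [assign_sectors()].
#' @param bundle [bundle_model()] supplying the anatomical trajectories.
#'   To avoid circularity in recovery experiments this may (and in tests does)
#'   differ from the generating model.
#' @param max_iter Maximum sweeps before aborting (default 100).
#' @return A corrected `oct_sector_map` (same columns as the input). On
#'   non-convergence, aborts with the diagnostic map attached to the
#'   condition.
#' @export
anatomical_correction <- function(raw, bundle = bundle_model(),
                                  max_iter = 100L) {
  stopifnot(inherits(raw, "oct_sector_map"))
  tmat <- trajectory_matrix(bundle)
  out <- list()
  for (lay in unique(raw$layer)) {
    sub <- raw[raw$layer == lay, ]
    m <- matrix(NA_integer_, 10, 10)
    m[cbind(sub$row, sub$col)] <- sub$sector
    m <- correct_label_matrix(m, tmat, max_iter, lay)
    sub$sector <- m[cbind(sub$row, sub$col)]
    out[[lay]] <- sub
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("oct_sector_map", class(tibble()))
  res
}

# internal: one layer's correction on a 10x10 label matrix.
# Conservative sweeps: (a) raphe violations take their trajectory label;
# (b) points with no same-label neighbour are absorbed by the majority
# hemifield-consistent neighbour label; (c) non-largest components of a label
# are relabeled (trajectory label, or neighbour majority when the trajectory
# label coincides with the island's own); (d) unassigned points are filled by
# their trajectory label when >= 3 assigned neighbours share it. A map that is
# already 4-connected and raphe-consistent is a fixed point.
correct_label_matrix <- function(m, tmat, max_iter, layer) {
  hemi_ok <- function(label, r, c) {
    th <- sector_hemifield(tmat[r, c])
    lh <- sector_hemifield(label)
    th == 0L || lh == 0L || th == lh
  }
  majority_label <- function(r, c, exclude = NA_integer_) {
    nb <- neighbours4(r, c)
    nb_lab <- m[nb]
    nb_lab <- nb_lab[!is.na(nb_lab)]
    nb_lab <- nb_lab[is.na(exclude) | nb_lab != exclude]
    nb_lab <- nb_lab[vapply(nb_lab, hemi_ok, logical(1), r = r, c = c)]
    if (!length(nb_lab)) return(NA_integer_)
    tab <- table(nb_lab)
    best <- as.integer(names(tab)[tab == max(tab)])
    if (tmat[r, c] %in% best) tmat[r, c] else min(best)
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE

    # (a) raphe violations -> trajectory label
    viol <- raphe_violations(m, tmat)
    if (any(viol)) {
      m[viol] <- tmat[viol]
      changed <- TRUE
    }

    # (b) isolated points (no same-label neighbour) -> neighbour majority
    for (r in 1:10) for (c in 1:10) {
      cur <- m[r, c]
      if (is.na(cur)) next
      nb_lab <- m[neighbours4(r, c)]
      if (any(!is.na(nb_lab) & nb_lab == cur)) next
      new <- majority_label(r, c, exclude = cur)
      if (!is.na(new) && new != cur) {
        m[r, c] <- new
        changed <- TRUE
      }
    }

    # (c) absorb non-largest components of each label
    m2 <- absorb_islands(m, tmat, hemi_ok)
    if (!identical(m2, m)) {
      m <- m2
      changed <- TRUE
    }

    # (d) fill unassigned from a trajectory-label consensus
    for (r in 1:10) for (c in 1:10) {
      if (!is.na(m[r, c])) next
      tl <- tmat[r, c]
      nb_lab <- m[neighbours4(r, c)]
      if (sum(!is.na(nb_lab) & nb_lab == tl) >= 3L) {
        m[r, c] <- tl
        changed <- TRUE
      }
    }

    if (!changed) break
  }
  if (all_labels_connected(m) && !any(raphe_violations(m, tmat))) return(m)
  abort(sprintf("anatomical correction did not converge for layer %s", layer),
        diagnostic_map = m)
}

# internal: relabel all but the largest 4-connected component of each label;
# island points take their trajectory label, or the neighbour majority when
# the trajectory label equals the island's own label.
absorb_islands <- function(m, tmat, hemi_ok) {
  comp <- matrix(0L, 10, 10)
  ncomp <- 0L
  for (r in 1:10) for (c in 1:10) {
    if (is.na(m[r, c]) || comp[r, c] > 0L) next
    ncomp <- ncomp + 1L
    s <- m[r, c]
    stack <- list(c(r, c)); comp[r, c] <- ncomp
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      nb <- neighbours4(p[1], p[2])
      for (k in seq_len(nrow(nb))) {
        rr <- nb[k, 1]; cc <- nb[k, 2]
        if (comp[rr, cc] == 0L && !is.na(m[rr, cc]) && m[rr, cc] == s) {
          comp[rr, cc] <- ncomp
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  if (ncomp == 0L) return(m)
  sizes <- tabulate(comp, ncomp)
  lab_of_comp <- vapply(seq_len(ncomp),
                        function(k) m[which(comp == k)[1]], integer(1))
  out <- m
  for (s in unique(lab_of_comp)) {
    comps <- which(lab_of_comp == s)
    if (length(comps) <= 1L) next
    keep <- comps[sizes[comps] == max(sizes[comps])][1]
    for (k in setdiff(comps, keep)) {
      idx <- which(comp == k, arr.ind = TRUE)
      for (j in seq_len(nrow(idx))) {
        r <- idx[j, 1]; c <- idx[j, 2]
        tl <- tmat[r, c]
        if (tl != s) {
          out[r, c] <- tl
        } else {
          nb_lab <- m[neighbours4(r, c)]
          nb_lab <- nb_lab[!is.na(nb_lab) & nb_lab != s]
          nb_lab <- nb_lab[vapply(nb_lab, hemi_ok, logical(1), r = r, c = c)]
          if (length(nb_lab)) {
            tab <- table(nb_lab)
            out[r, c] <- as.integer(names(tab)[tab == max(tab)])[1]
          } else {
            # no consistent label reachable: leave the point unassigned
            out[r, c] <- NA_integer_
          }
        }
      }
    }
  }
  out
}

#' Derive corrected sector maps for one or both layers
#'
#' Convenience wrapper: [correlate_grid()] then [assign_sectors()] then
#' [anatomical_correction()], independently per layer (the two layers' maps
#' may legitimately differ).
#'
#' @inheritParams correlate_grid
#' @inheritParams assign_sectors
#' @param layers Layers to derive (default both).
#' @param correct Apply anatomical correction (default `TRUE`).
#' @return An `oct_sector_map` tibble covering the requested layers.
#' @export
derive_sector_map <- function(cohort, layers = LAYERS, r_min = 0.4,
                              alpha = 0.05, bundle = bundle_model(),
                              visit_policy = "first", correct = TRUE) {
  maps <- dplyr::bind_rows(lapply(layers, function(l) {
    correlate_grid(cohort, l, visit_policy)
  }))
  raw <- assign_sectors(maps, r_min = r_min, alpha = alpha, bundle = bundle)
  if (!correct) return(raw)
  anatomical_correction(raw, bundle = bundle)
}

#' @export
print.oct_sector_map <- function(x, ...) {
  for (lay in unique(x$layer)) {
    sub <- x[x$layer == lay, ]
    m <- matrix(".", 10, 10)
    m[cbind(sub$row, sub$col)] <- ifelse(is.na(sub$sector), ".",
                                         as.character(sub$sector %% 10))
    cat(lay, "sector map (T left, S top; '.' unassigned):\n")
    for (r in 1:10) cat(" ", paste(m[r, ], collapse = " "), "\n")
  }
  invisible(x)
}
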