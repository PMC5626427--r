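# Synthetic longitudinal cohort generator.
#
# Generative model, per eye:
#   * each of the five temporal bundles b gets a baseline damage severity
#     sev_b in [0,1] (Beta draw, mixing an eye-level common component with a
#     bundle-specific one) and a true mRNFL slope (um/year); progressor eyes
#     get 1-2 fast bundles;
#   * grid point p with trajectory sector b:
#       thickness_l(p, t) = template_l(p) * (1 - susceptibility_l * sev_b)
#                           + slope_{b,l} * t + visit offset + iid noise
#   * circumpapillary temporal sector b:
#       cp(b, t) = cp_template(b) * (1 - cp_susceptibility * sev_b)
#                  + 1.5 * slope_b * t + noise
#     (non-temporal hours use the eye-mean severity and no trend);
#   * central-16 VF point mapped to grid point p:
#       sensitivity(t) = normal - vf_link * gcipl_loss(p, t) + noise,
#       total deviation = sensitivity - normal.
# Thicknesses are clipped at `thickness_floor` (and 200 um above).

CP_SLOPE_FACTOR <- 1.5  # um/year of temporal cpRNFL loss per um/year of mRNFL loss

#' Generate a synthetic cohort with ground truth
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical `config` + `seed` give an identical
#'   cohort.
#' @return A list of class `oct_sim` with elements
#'   \describe{
#'     \item{cohort}{an `oct_cohort` ready for the analysis functions}
#'     \item{truth}{list with `bundles` (per eye x bundle: `severity`,
#'       `slope_mRNFL`, `slope_mGCIPL`), `sector_map` (the generating
#'       trajectory map), `eyes` (per-eye `structural_progressor` and
#'       `vf_progressor` labels), and `templates`}
#'   }
#' @examples
#' sim <- generate_cohort(cohort_config(n_eyes = 10), seed = 1)
#' sim$cohort
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config

  tmpl <- lapply(setNames(LAYERS, LAYERS), healthy_template, bundle = cfg$bundle)
  cp_tmpl <- healthy_cprnfl_template()
  traj <- trajectory_map(cfg$bundle)
  sector_of_point <- traj$sector                      # length 100, row-major
  pts <- traj[c("row", "col")]

  n <- cfg$n_eyes
  eye_id <- sprintf("eye%03d", seq_len(n))
  # ~half of patients contribute both eyes
  patient <- character(n); lat <- character(n)
  pid <- 0L; i <- 1L
  while (i <= n) {
    pid <- pid + 1L
    both <- i < n && runif(1) < 0.5
    if (both) {
      patient[i:(i + 1L)] <- sprintf("pt%03d", pid)
      lat[i:(i + 1L)] <- c("OD", "OS")
      i <- i + 2L
    } else {
      patient[i] <- sprintf("pt%03d", pid)
      lat[i] <- sample(c("OD", "OS"), 1)
      i <- i + 1L
    }
  }

  sev_common <- rbeta(n, cfg$severity_shape1, cfg$severity_shape2)
  sev_bundle <- matrix(rbeta(5L * n, cfg$severity_shape1, cfg$severity_shape2),
                       nrow = n)
  w <- cfg$severity_common_weight
  severity <- pmin(pmax(w * sev_common + (1 - w) * sev_bundle, 0), 1)
  colnames(severity) <- as.character(TEMPORAL_SECTORS)

  is_prog <- runif(n) < cfg$fraction_progressors
  slope <- matrix(rnorm(5L * n, cfg$slope_background_mean,
                        cfg$slope_background_sd), nrow = n)
  for (e in which(is_prog)) {
    nb <- sample(1:2, 1)
    bsel <- sample(5L, nb)
    slope[e, bsel] <- pmin(rnorm(nb, cfg$slope_progressor_mean,
                                 cfg$slope_progressor_sd), 0)
  }
  colnames(slope) <- as.character(TEMPORAL_SECTORS)

  vf_map <- central16_points()
  vf_map <- dplyr::bind_cols(vf_map, vf_to_macula(vf_map$row, vf_map$col))
  tmat <- trajectory_matrix(cfg$bundle)
  vf_map$sector <- tmat[cbind(vf_map$ret_row, vf_map$ret_col)]
  gcipl_tmpl_at_vf <- tmpl$mGCIPL[cbind(vf_map$ret_row, vf_map$ret_col)]

  mac_l <- list(); cp_l <- list(); vf_l <- list(); vis_l <- list()
  V <- cfg$n_visits
  for (e in seq_len(n)) {
    d0 <- round((seq_len(V) - 1L) * cfg$visit_interval_days +
                  c(0, runif(V - 1L, -cfg$visit_jitter_days,
                             cfg$visit_jitter_days)))
    dates <- c(0, cumsum(pmax(diff(d0), 1)))   # strictly increasing from day 0
    t_yr <- dates / 365.25
    offs <- rnorm(V, 0, cfg$visit_offset_sd)

    sev_p <- severity[e, as.character(sector_of_point)]   # length 100
    for (layer in LAYERS) {
      slope_p <- slope[e, as.character(sector_of_point)] *
        if (layer == "mGCIPL") cfg$gcipl_slope_factor else 1
      base_p <- tmpl[[layer]][cbind(pts$row, pts$col)] *
        (1 - cfg$susceptibility[[layer]] * sev_p)
      ex <- outer(base_p, rep(1, V)) + outer(slope_p, t_yr)
      val <- ex + rep(offs, each = 100) +
        rnorm(100L * V, 0, cfg$noise_sd_macular)
      val <- pmin(pmax(val, cfg$thickness_floor), 200)
      mac_l[[length(mac_l) + 1L]] <- tibble(
        eye_id = eye_id[e], date = rep(dates, each = 100),
        layer = layer, row = rep(pts$row, V), col = rep(pts$col, V),
        thickness = as.vector(val))
    }

    sev_mean <- mean(severity[e, ])
    cp_base <- cp_tmpl
    cp_slope <- numeric(12)
    for (s in TEMPORAL_SECTORS) {
      cp_base[as.character(s)] <- cp_tmpl[as.character(s)] *
        (1 - cfg$cprnfl_susceptibility * severity[e, as.character(s)])
      cp_slope[s] <- CP_SLOPE_FACTOR * slope[e, as.character(s)]
    }
    nt <- setdiff(1:12, TEMPORAL_SECTORS)
    cp_base[as.character(nt)] <- cp_tmpl[as.character(nt)] *
      (1 - cfg$cprnfl_susceptibility * sev_mean)
    cp_val <- outer(cp_base, rep(1, V)) + outer(cp_slope, t_yr) +
      rnorm(12L * V, 0, cfg$noise_sd_cprnfl)
    cp_val <- pmax(cp_val, 0)
    cp_l[[length(cp_l) + 1L]] <- tibble(
      eye_id = eye_id[e], date = rep(dates, each = 12),
      clock_hour = rep(1:12, V), thickness = as.vector(cp_val))

    # VF: sensitivity loss proportional to cumulative mGCIPL loss at the
    # structurally mapped grid point
    gcipl_loss0 <- gcipl_tmpl_at_vf * cfg$susceptibility[["mGCIPL"]] *
      severity[e, as.character(vf_map$sector)]
    gcipl_rate <- -slope[e, as.character(vf_map$sector)] *
      cfg$gcipl_slope_factor                     # um lost per year (>= 0 if thinning)
    loss <- outer(gcipl_loss0, rep(1, V)) + outer(gcipl_rate, t_yr)
    sens <- cfg$vf_normal_sensitivity - cfg$vf_link * loss +
      rnorm(16L * V, 0, cfg$vf_noise_sd)
    vf_l[[length(vf_l) + 1L]] <- tibble(
      eye_id = eye_id[e], date = rep(dates, each = 16),
      row = rep(vf_map$row, V), col = rep(vf_map$col, V),
      sensitivity = as.vector(sens),
      total_deviation = as.vector(sens) - cfg$vf_normal_sensitivity)

    vis_l[[length(vis_l) + 1L]] <- tibble(
      eye_id = eye_id[e], date = dates,
      quality = round(runif(V, cfg$quality_range[1], cfg$quality_range[2]), 1))
  }

  cohort <- new_oct_cohort(
    eyes = tibble(eye_id = eye_id, patient_id = patient, laterality = lat),
    visits = dplyr::bind_rows(vis_l),
    macular = dplyr::bind_rows(mac_l),
    cprnfl = dplyr::bind_rows(cp_l),
    vf = dplyr::bind_rows(vf_l))
  validate_cohort(cohort)

  bundles <- tidyr::expand_grid(eye_id = eye_id, sector = TEMPORAL_SECTORS) |>
    dplyr::mutate(
      severity = as.vector(t(severity)),
      slope_mRNFL = as.vector(t(slope)),
      slope_mGCIPL = as.vector(t(slope)) * cfg$gcipl_slope_factor)

  # noise-free VF progressor label under the literal cluster rule
  vf_true <- vapply(seq_len(n), function(e) {
    sl <- cfg$vf_link * cfg$gcipl_slope_factor *
      slope[e, as.character(vf_map$sector)]   # true dB/year at each VF point
    prog <- sl < -1
    has_cluster(vf_map$row, vf_map$col, prog, min_points = 3L)
  }, logical(1))

  truth <- list(
    bundles = bundles,
    sector_map = dplyr::bind_rows(
      lapply(setNames(LAYERS, LAYERS), function(l) traj), .id = "layer"),
    eyes = tibble(eye_id = eye_id, structural_progressor = is_prog,
                  vf_progressor = vf_true),
    templates = tmpl,
    vf_point_map = vf_map
  )
  structure(list(cohort = cohort, truth = truth, config = cfg, seed = seed),
            class = "oct_sim")
}

#' @export
print.oct_sim <- function(x, ...) {
  cat(sprintf("<oct_sim> seed %d: ", x$seed))
  print(x$cohort)
  invisible(x)
}
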