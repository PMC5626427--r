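# Simulation and analysis configuration.

# Table of healthy (normal-eye) region means, per layer (um). Used as targets
# when building the smooth healthy template and as normative healthy means.
healthy_region_targets <- function() {
  tibble::tribble(
    ~layer,    ~region,    ~healthy_mean, ~healthy_sd,
    "mRNFL",   "average",  35.06, 3.82,
    "mRNFL",   "superior", 34.15, 3.45,
    "mRNFL",   "inferior", 35.97, 4.99,
    "mRNFL",   "clock7",   37.47, 5.92,
    "mRNFL",   "clock8",   37.41, 6.15,
    "mRNFL",   "clock9",   29.71, 4.61,
    "mRNFL",   "clock10",  37.18, 3.78,
    "mRNFL",   "clock11",  21.02, 2.40,
    "mGCIPL",  "average",  67.96, 3.56,
    "mGCIPL",  "superior", 69.24, 3.42,
    "mGCIPL",  "inferior", 66.67, 4.00,
    "mGCIPL",  "clock7",   61.00, 4.13,
    "mGCIPL",  "clock8",   77.06, 4.55,
    "mGCIPL",  "clock9",   76.65, 6.44,
    "mGCIPL",  "clock10",  71.07, 3.38,
    "mGCIPL",  "clock11",  52.43, 3.66
  )
}

# Healthy circumpapillary RNFL thickness per clock hour (um, right-eye
# convention): thick superior/inferior arcades, thin temporally (9 o'clock,
# papillomacular bundle) and nasally. Average ~110 um.
healthy_cprnfl_template <- function() {
  setNames(
    c(115, 95, 80, 85, 115, 140, 145, 110, 75, 100, 135, 130),
    as.character(1:12)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the analysis expects: 122 eyes, 8 visits
#' per eye at ~115-day intervals (span ~2.2 years), glaucomatous baseline
#' damage at the scale of the normal-vs-glaucoma thickness gap, per-eye
#' bundle-wise progression slopes at the -0.2 to -1.5 um/year scale, and
#' visual-field series linearly linked to cumulative mGCIPL loss.
#'
#' @param n_eyes Number of eyes.
#' @param n_visits Visits per eye (>= 5).
#' @param visit_interval_days Nominal days between visits;
#'   `n_visits * visit_interval_days` should span >= 730 days when emulating
#'   the study design.
#' @param visit_jitter_days Uniform jitter (+/- days) on each non-baseline
#'   visit date.
#' @param noise_sd_macular Per-grid-point, per-visit Gaussian measurement
#'   noise SD (um).
#' @param noise_sd_cprnfl Per-clock-hour, per-visit noise SD (um).
#' @param visit_offset_sd SD (um) of a per-visit common offset shared by all
#'   grid points of a scan (scan-alignment term); set 0 for pure i.i.d. noise.
#' @param severity_shape1,severity_shape2 Beta parameters of the baseline
#'   damage severity (in `[0, 1]`) drawn per bundle and per eye.
#' @param severity_common_weight Weight of an eye-level common severity
#'   component shared across bundles (0 = independent bundles).
#' @param susceptibility Named per-layer multiplier translating bundle
#'   severity into fractional thickness loss.
#' @param cprnfl_susceptibility Same multiplier for circumpapillary sectors.
#' @param fraction_progressors Fraction of eyes given 1-2 fast-progressing
#'   bundles.
#' @param slope_background_mean,slope_background_sd Background (stable-bundle)
#'   mRNFL slope distribution, um/year.
#' @param slope_progressor_mean,slope_progressor_sd Fast-bundle mRNFL slope
#'   distribution, um/year (draws truncated at 0 from above).
#' @param gcipl_slope_factor mGCIPL slope = factor x mRNFL slope.
#' @param vf_link dB of visual-field sensitivity lost per um of mGCIPL loss at
#'   the structurally mapped point.
#' @param vf_noise_sd Per-point, per-exam visual-field noise SD (dB).
#' @param vf_normal_sensitivity Normal sensitivity (dB) at central points;
#'   total deviation = sensitivity - this value.
#' @param thickness_floor Lower clip (um) applied to generated thicknesses.
#' @param quality_range Range of simulated image-quality scores.
#' @param bundle The generating [bundle_model()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_eyes = 122L,
                          n_visits = 8L,
                          visit_interval_days = 115L,
                          visit_jitter_days = 7L,
                          noise_sd_macular = 2.0,
                          noise_sd_cprnfl = 4.0,
                          visit_offset_sd = 0.5,
                          severity_shape1 = 2.0,
                          severity_shape2 = 2.45,
                          severity_common_weight = 0.3,
                          susceptibility = c(mRNFL = 0.92, mGCIPL = 0.40),
                          cprnfl_susceptibility = 0.55,
                          fraction_progressors = 0.30,
                          slope_background_mean = -0.10,
                          slope_background_sd = 0.20,
                          slope_progressor_mean = -1.5,
                          slope_progressor_sd = 0.6,
                          gcipl_slope_factor = 1.3,
                          vf_link = 0.8,
                          vf_noise_sd = 1.5,
                          vf_normal_sensitivity = 30,
                          thickness_floor = 0,
                          quality_range = c(75, 100),
                          bundle = bundle_model()) {
  if (n_visits < 5L) abort("n_visits must be >= 5")
  if (noise_sd_macular < 0 || noise_sd_cprnfl < 0 || visit_offset_sd < 0 ||
      vf_noise_sd < 0) {
    abort("noise SDs must be non-negative")
  }
  if (severity_shape1 <= 0 || severity_shape2 <= 0) {
    abort("severity Beta shapes must be positive")
  }
  stopifnot(all(LAYERS %in% names(susceptibility)))
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d eyes x %d visits every %d d; macular noise %.1f um; %d%% progressors\n",
    x$n_eyes, x$n_visits, x$visit_interval_days, x$noise_sd_macular,
    round(100 * x$fraction_progressors)))
  invisible(x)
}

#' Build a cohort configuration from a YAML file
#'
#' Reads a flat YAML mapping of [cohort_config()] argument names to values.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  rlang::check_installed("yaml")
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(cohort_config)))
  if ("susceptibility" %in% names(vals)) {
    vals$susceptibility <- unlist(vals$susceptibility)
  }
  do.call(cohort_config, vals[keep])
}

#' Normative reference for progression analyses
#'
#' Stands in for a device normative database: per region and layer, the
#' distribution of age-related slopes (mean and between-subject SD, um/year)
#' and the test-retest fluctuation SD of the region mean (um), plus healthy
#' region means/SDs. The slope defaults (-0.1 +/- 0.3 um/year) are synthetic
#' placeholders, not values from any published normative dataset; replace them
#' when a real reference is available.
#'
#' @param slope_mean,slope_sd Normative slope mean and between-subject SD
#'   (um/year), recycled across regions and layers.
#' @param fluctuation_sd Named vector of test-retest SDs (um) by region class:
#'   `average`, `hemifield`, `sector`.
#' @return Tibble with columns `layer`, `region`, `slope_mean`, `slope_sd`,
#'   `fluctuation_sd`, `healthy_mean`, `healthy_sd`.
#' @export
normative_reference <- function(slope_mean = -0.1,
                                slope_sd = 0.3,
                                fluctuation_sd = c(average = 0.6,
                                                   hemifield = 0.65,
                                                   sector = 0.8)) {
  if (slope_sd <= 0 || any(fluctuation_sd <= 0)) {
    abort("normative SDs must be positive")
  }
  cls <- function(region) {
    dplyr::case_when(
      region == "average" ~ "average",
      region %in% c("superior", "inferior", "faster_hemifield") ~ "hemifield",
      TRUE ~ "sector"
    )
  }
  out <- tidyr::expand_grid(layer = LAYERS, region = REGIONS)
  out$slope_mean <- slope_mean
  out$slope_sd <- slope_sd
  out$fluctuation_sd <- unname(fluctuation_sd[cls(out$region)])
  out <- dplyr::left_join(out, healthy_region_targets(),
                          by = c("layer", "region"))
  out
}
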