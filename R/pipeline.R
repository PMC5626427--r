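# End-to-end pipeline: simulate -> derive sectors -> trend -> event -> VF ->
# report, with all outputs as tidy CSV plus a JSON run manifest.

#' Baseline (first-visit) region means per eye
#'
#' @param cohort An `oct_cohort`.
#' @param sector_map An `oct_sector_map`.
#' @param layers Layers to summarise.
#' @return Tibble `eye_id`, `layer`, `region`, `baseline` (um).
#' @export
baseline_region_means <- function(cohort, sector_map, layers = LAYERS) {
  first <- cohort$visits |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(date = min(.data$date))
  dplyr::bind_rows(lapply(layers, function(lay) {
    region_series(cohort, lay, sector_map) |>
      dplyr::semi_join(first, by = c("eye_id", "date")) |>
      dplyr::mutate(layer = lay)
  })) |>
    dplyr::select("eye_id", "layer", "region", baseline = "value")
}

#' Progressor-vs-non-progressor report
#'
#' Builds the cohort-level summary tables: per-region slope summaries with
#' paired comparisons against the average region, baseline-thickness and
#' slope comparisons between VF progressors and non-progressors, event
#' counts, and VF/OCT agreement counts.
#'
#' @param cohort An `oct_cohort`.
#' @param sector_map An `oct_sector_map`.
#' @param trend An `oct_trend` from [trend_analysis()].
#' @param events An `oct_events` from [event_analysis()].
#' @param vf Per-eye table from [vf_analysis()].
#' @return Named list of tibbles: `slope_summary`, `baseline_by_group`,
#'   `slope_by_group`, `event_summary`, `agreement`.
#' @export
progression_report <- function(cohort, sector_map, trend, events, vf) {
  slope_summary <- glance(trend)

  vf_lab <- vf[c("eye_id", "vf_progressor")]

  # group comparisons need >= 2 eyes per group; small simulated cohorts may
  # not produce enough VF progressors, in which case the comparison columns
  # are reported as NA rather than failing the whole report
  safe_compare <- function(data, vars) {
    tryCatch(
      compare_progressor_groups(data, "vf_progressor", vars),
      rlang_error = function(e) {
        tibble(variable = vars, non_progressors = NA_character_,
               progressors = NA_character_,
               test = "skipped: group too small", p_value = NA_real_)
      })
  }

  base_wide <- baseline_region_means(cohort, sector_map) |>
    dplyr::mutate(var = paste(.data$layer, .data$region, sep = "_")) |>
    dplyr::select("eye_id", "var", "baseline") |>
    tidyr::pivot_wider(names_from = "var", values_from = "baseline") |>
    dplyr::inner_join(vf_lab, by = "eye_id")
  baseline_by_group <- safe_compare(
    base_wide, setdiff(names(base_wide), c("eye_id", "vf_progressor")))

  slope_wide <- tidy(trend) |>
    dplyr::mutate(var = paste(.data$layer, .data$region, "slope", sep = "_")) |>
    dplyr::select("eye_id", "var", "slope") |>
    tidyr::pivot_wider(names_from = "var", values_from = "slope") |>
    dplyr::inner_join(vf_lab, by = "eye_id")
  slope_by_group <- safe_compare(
    slope_wide, setdiff(names(slope_wide), c("eye_id", "vf_progressor")))

  list(
    slope_summary = slope_summary,
    baseline_by_group = baseline_by_group,
    slope_by_group = slope_by_group,
    event_summary = summarize_events(events),
    agreement = agreement(vf_lab, event_labels(events)))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort, derives the sector maps, runs trend, event and VF
#' progression analyses and the cohort report, and writes every result as a
#' tidy CSV plus a JSON run manifest (seed, configuration hash, row counts).
#' Identical `config` + `seed` produce byte-identical outputs.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing). `NULL` to skip
#'   writing.
#' @param normative A [normative_reference()].
#' @param correction_bundle [bundle_model()] used for sector assignment and
#'   anatomical correction (kept separate from the generator's model so the
#'   derivation is not circular by construction).
#' @return Invisibly, a list with `sim`, `sectors`, `trend`, `events`, `vf`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         out_dir = NULL,
                         normative = normative_reference(),
                         correction_bundle = bundle_model()) {
  sim <- generate_cohort(config, seed = seed)
  cohort <- sim$cohort
  sectors <- derive_sector_map(cohort, bundle = correction_bundle)
  trend <- trend_analysis(cohort, sectors, normative)
  events <- event_analysis(cohort, sectors, normative)
  vf <- vf_analysis(cohort)
  report <- progression_report(cohort, sectors, trend, events, vf)

  manifest <- list(
    package = "octsector",
    version = as.character(utils::packageVersion("octsector")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_eyes = nrow(cohort$eyes),
    n_visits = nrow(cohort$visits),
    dropped_visits = attr(cohort, "dropped_visits") %||% 0L)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    w(sim$truth$bundles, "truth_bundles")
    w(sim$truth$eyes, "truth_eyes")
    w(sectors, "sectors")
    w(tidy(trend), "trend")
    w(glance(trend), "trend_summary")
    w(tidy(events), "events")
    w(report$event_summary, "event_summary")
    w(vf, "vf")
    w(report$baseline_by_group, "baseline_by_group")
    w(report$slope_by_group, "slope_by_group")
    w(report$agreement, "agreement")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(sim = sim, sectors = sectors, trend = trend, events = events,
                 vf = vf, report = report, manifest = manifest))
}
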