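# Cohort-level group comparisons and structure-function agreement.

#' Compare variables between progressors and non-progressors
#'
#' Continuous variables use the rank-based Mann-Whitney/Wilcoxon two-group
#' test (with two groups this is equivalent to Kruskal-Wallis); logical or
#' two-level categorical variables use Fisher's exact test. P-values are
#' reported uncorrected (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param data Tibble with one row per eye.
#' @param label Name of the logical progressor column in `data`.
#' @param variables Character vector of columns to compare.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble per variable: group means (+/- SD) or counts, `test`,
#'   `p_value`.
#' @export
compare_progressor_groups <- function(data, label = "vf_progressor",
                                      variables,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  lab <- data[[label]]
  if (is.null(lab)) abort(sprintf("no column '%s' in data", label))
  lab <- as.logical(lab)
  if (length(unique(lab)) < 2L || min(table(lab)) < 2L) {
    abort("need >= 2 eyes in each group")
  }
  out <- purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(sprintf("no column '%s' in data", v))
    if (is.numeric(x)) {
      # exact when samples are small and untied; tie-corrected normal
      # approximation without continuity correction otherwise (the latter is
      # identical to a two-group Kruskal-Wallis)
      tst <- suppressWarnings(wilcox.test(x[!lab], x[lab], correct = FALSE))
      tibble(
        variable = v,
        non_progressors = sprintf("%.2f ± %.2f",
                                  mean(x[!lab], na.rm = TRUE),
                                  sd(x[!lab], na.rm = TRUE)),
        progressors = sprintf("%.2f ± %.2f",
                              mean(x[lab], na.rm = TRUE),
                              sd(x[lab], na.rm = TRUE)),
        test = "Mann-Whitney", p_value = tst$p.value)
    } else {
      tab <- table(factor(x), factor(lab, levels = c(FALSE, TRUE)))
      tst <- fisher.test(tab)
      tibble(
        variable = v,
        non_progressors = paste(tab[, 1], collapse = " / "),
        progressors = paste(tab[, 2], collapse = " / "),
        test = "Fisher exact", p_value = tst$p.value)
    }
  })
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Structure-function agreement counts
#'
#' Cross-tabulates the visual-field progressor labels against one or more
#' OCT progression criteria (e.g. event-analysis labels per region rollup),
#' producing the counts behind a Venn/agreement diagram.
#'
#' @param vf_labels Tibble with `eye_id` and logical `vf_progressor`.
#' @param oct_labels Tibble with `eye_id`, `criterion` (character), and
#'   logical `progressed`. Must cover exactly the same eyes.
#' @return Tibble per criterion: `both`, `vf_only`, `oct_only`, `neither`
#'   (summing to the cohort size), plus `n`.
#' @export
agreement <- function(vf_labels, oct_labels) {
  eyes <- sort(unique(vf_labels$eye_id))
  out <- oct_labels |>
    dplyr::group_by(.data$criterion) |>
    dplyr::group_modify(function(df, key) {
      if (!setequal(df$eye_id, eyes) || anyDuplicated(df$eye_id)) {
        abort(sprintf("criterion '%s' does not cover the same eye set",
                      key$criterion))
      }
      j <- dplyr::inner_join(df, vf_labels, by = "eye_id")
      tibble(
        both = sum(j$progressed & j$vf_progressor),
        vf_only = sum(!j$progressed & j$vf_progressor),
        oct_only = sum(j$progressed & !j$vf_progressor),
        neither = sum(!j$progressed & !j$vf_progressor),
        n = nrow(j))
    }) |>
    dplyr::ungroup()
  out
}

#' Event-analysis progression labels per agreement criterion
#'
#' Builds the per-eye OCT progression labels used by [agreement()]:
#' for each layer, `average`, `any_hemifield` and `any_sector`.
#'
#' @param events An `oct_events` object.
#' @return Tibble `eye_id`, `criterion`, `progressed`.
#' @export
event_labels <- function(events) {
  res <- tidy(events)
  avg <- res |>
    dplyr::filter(.data$region == "average") |>
    dplyr::transmute(.data$eye_id,
                     criterion = paste0(.data$layer, "_average"),
                     progressed = .data$progressed)
  hemi <- res |>
    dplyr::filter(.data$region %in% c("superior", "inferior")) |>
    dplyr::group_by(.data$eye_id, .data$layer) |>
    dplyr::summarise(progressed = any(.data$progressed), .groups = "drop") |>
    dplyr::transmute(.data$eye_id,
                     criterion = paste0(.data$layer, "_any_hemifield"),
                     .data$progressed)
  sect <- res |>
    dplyr::filter(grepl("^clock", .data$region)) |>
    dplyr::group_by(.data$eye_id, .data$layer) |>
    dplyr::summarise(progressed = any(.data$progressed), .groups = "drop") |>
    dplyr::transmute(.data$eye_id,
                     criterion = paste0(.data$layer, "_any_sector"),
                     .data$progressed)
  dplyr::bind_rows(avg, hemi, sect)
}
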