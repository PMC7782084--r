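#' Run the full analysis on a gallery or feature table
#'
#' One-call pipeline: measure every marked event (when images are supplied),
#' run the selection cascade, build the per-event morphometry table, the
#' per-cohort summaries and the planned cohort comparisons.
#'
#' @param x A gallery tibble ([read_gallery()] / [render_cohort()]) or an
#'   already-measured feature tibble ([measure_events()] /
#'   [read_feature_table()]).
#' @param config A [ctc_config()].
#' @param plan A [comparison_plan()], or `NULL` to skip comparisons.
#' @return A list of class `ctc_analysis` with elements `records`
#'   (flagged features), `counts` ([tabulate_counts()]), `morphometry`,
#'   `summary` ([summarize_cohorts()]) and `comparisons` (or `NULL`).
#' @export
analyze_events <- function(x, config = ctc_config(), plan = comparison_plan()) {
  x <- as_tibble(x)
  records <- if (all(CHANNELS %in% names(x))) {
    measure_events(x, min_component_px = config$min_component_px,
                   median_filter = config$median_filter)
  } else {
    x
  }
  bins <- p2a_bins(config$p2a_edges)
  records <- flag_events(records, bins)
  morph <- morphometry_table(records, method = config$ncr_method)
  cmp <- NULL
  if (!is.null(plan) && nrow(morph) > 0) {
    cmp <- withCallingHandlers(
      run_comparisons(morph, .data$cell_area, plan = plan),
      warning = function(w) invokeRestart("muffleWarning")  # absent cohorts are fine
    )
    if (nrow(cmp) == 0L) cmp <- NULL
  }
  structure(list(records = records,
                 counts = tabulate_counts(records),
                 morphometry = morph,
                 summary = summarize_cohorts(morph),
                 comparisons = cmp),
            class = "ctc_analysis")
}

#' @export
print.ctc_analysis <- function(x, ...) {
  cat(sprintf("<ctc_analysis> %d events, %d cohorts, %d size-eligible, %d NCR-eligible\n",
              nrow(x$records), nrow(x$summary),
              sum(x$records$size_eligible, na.rm = TRUE),
              sum(x$records$ncr_eligible, na.rm = TRUE)))
  if (!is.null(x$comparisons)) {
    cat(sprintf("  %d cohort comparisons (min p = %.3g)\n",
                nrow(x$comparisons), min(x$comparisons$p_value, na.rm = TRUE)))
  }
  invisible(x)
}
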