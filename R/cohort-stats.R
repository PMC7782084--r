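# Cohort summaries (median / IQR / computed diameter) and the nonparametric
# comparison battery: Kruskal-Wallis across tumor types, pairwise
# Mann-Whitney U, and the independent-samples median test.

#' Summarize one cohort's size distribution
#'
#' Median and interquartile width of a set of areas plus the computed
#' diameter of the median. Quantiles use linear interpolation (type 7); the
#' IQR is reported as the single width Q3 - Q1, matching the "(IQR 104.9)"
#' reporting style of cohort tables.
#'
#' @param values Numeric vector of areas (um^2), nonnegative.
#' @param label Optional cohort label stored in the `group` column.
#' @return One-row tibble: `group`, `n`, `median_area`, `iqr_area`, `cd`.
#'   An empty input yields `n = 0` and undefined (`NA`) statistics.
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  if (any(values < 0)) {
    abort("Areas must be nonnegative.", class = "ctcmorph_validation_error")
  }
  if (length(values) == 0L) {
    return(tibble(group = label, n = 0L, median_area = NA_real_,
                  iqr_area = NA_real_, cd = NA_real_))
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(group = label, n = length(values), median_area = q[2],
         iqr_area = q[3] - q[1], cd = equivalent_diameter(q[2]))
}

#' Summarize all cohorts of a morphometry table
#'
#' Per `(group, material, signal)` cohort: event count, median cell area and
#' IQR width, computed diameter of the median area, and -- where nucleus
#' measurements exist -- the median nucleus area, its IQR and diameter, and
#' the cohort NCR under both conventions: the ratio of the two cohort
#' medians (`ncr_ratio_of_medians`, the convention behind published per-
#' cohort values) and the median of the per-event ratios
#' (`ncr_median_of_ratios`).
#'
#' @param morph Morphometry tibble from [morphometry_table()].
#' @return A tibble of class `ctc_cohort_summary`, one row per cohort.
#' @export
summarize_cohorts <- function(morph) {
  morph <- as_tibble(morph)
  q <- function(x, p) if (sum(!is.na(x)) == 0L) NA_real_ else
    quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)
  out <- morph |>
    group_by(.data$group, .data$material, .data$signal) |>
    summarise(
      n = dplyr::n(),
      median_area = q(.data$cell_area, 0.5),
      iqr_area = q(.data$cell_area, 0.75) - q(.data$cell_area, 0.25),
      cd = equivalent_diameter(q(.data$cell_area, 0.5)),
      n_nucleus = sum(!is.na(.data$nucleus_area)),
      median_nucleus_area = q(.data$nucleus_area, 0.5),
      iqr_nucleus_area = q(.data$nucleus_area, 0.75) - q(.data$nucleus_area, 0.25),
      nucleus_cd = equivalent_diameter(q(.data$nucleus_area, 0.5)),
      ncr_ratio_of_medians = .data$median_nucleus_area / .data$median_area,
      ncr_median_of_ratios = q(.data$ncr, 0.5),
      .groups = "drop"
    )
  class(out) <- c("ctc_cohort_summary", class(out))
  out
}

new_test_result <- function(test, groups, statistic, df = NA_real_, p_value,
                            n_per_group, note = NA_character_) {
  tibble(test = test, groups = paste(groups, collapse = " vs "),
         statistic = statistic, df = df, p_value = p_value,
         n_per_group = list(n_per_group), note = note)
}

split_cohort_values <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  split(v[keep], as.character(g[keep]))
}

#' Kruskal-Wallis rank test across cohorts
#'
#' Tie-corrected H statistic with a chi-square approximation on k - 1
#' degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param data A data frame.
#' @param value,group Columns (data-masked) holding the measured value and
#'   the cohort label.
#' @return One-row result tibble: `test`, `groups`, `statistic`, `df`,
#'   `p_value`, `n_per_group` (list-column), `note`.
#' @examples
#' d <- data.frame(a = c(1, 2, 3, 14, 15, 16, 7, 8, 9),
#'                 g = rep(c("x", "y", "z"), each = 3))
#' kruskal_wallis(d, a, g)
#' @export
kruskal_wallis <- function(data, value, group) {
  vals <- split_cohort_values(data, {{ value }}, {{ group }})
  vals <- vals[lengths(vals) > 0]
  if (length(vals) < 2L) {
    abort("Kruskal-Wallis needs at least two non-empty groups.",
          class = "ctcmorph_validation_error")
  }
  ht <- stats::kruskal.test(unname(vals))
  new_test_result("kruskal_wallis", names(vals),
                  statistic = unname(ht$statistic), df = unname(ht$parameter),
                  p_value = ht$p.value, n_per_group = lengths(vals))
}

#' Mann-Whitney U test for two cohorts
#'
#' Two-sided rank-sum test. The p-value is exact (permutation null of the U
#' statistic) when the smaller sample has at most 8 observations and there
#' are no ties; otherwise the tie-corrected normal approximation without
#' continuity correction is used (the convention of mainstream statistics
#' suites). The reported statistic is U for the first sample.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max Largest `min(n)` for which the exact null is enumerated
#'   (default 8).
#' @return One-row result tibble (see [kruskal_wallis()]); `statistic` is U.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.", class = "ctcmorph_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  new_test_result("mann_whitney_u", c("x", "y"),
                  statistic = unname(ht$statistic), p_value = min(ht$p.value, 1),
                  n_per_group = c(x = length(x), y = length(y)),
                  note = if (exact) "exact" else "normal approximation")
}

#' Independent-samples median test
#'
#' Classifies every value as above vs not-above the pooled median and tests
#' the resulting group-by-side contingency table with a Pearson chi-square
#' (no continuity correction). When the pooled classification is degenerate
#' (e.g. all values equal), the result is reported as undefined rather than
#' raising an error.
#'
#' @inheritParams kruskal_wallis
#' @return One-row result tibble (see [kruskal_wallis()]).
#' @export
median_test <- function(data, value, group) {
  vals <- split_cohort_values(data, {{ value }}, {{ group }})
  vals <- vals[lengths(vals) > 0]
  if (length(vals) < 2L) {
    abort("The median test needs at least two non-empty groups.",
          class = "ctcmorph_validation_error")
  }
  pooled <- unlist(vals, use.names = FALSE)
  m <- median(pooled)
  above <- lapply(vals, function(v) sum(v > m))
  tot <- lengths(vals)
  tab <- rbind(above = unlist(above), not_above = tot - unlist(above))
  if (all(tab["above", ] == 0) || all(tab["not_above", ] == 0)) {
    return(new_test_result("median_test", names(vals), statistic = NA_real_,
                           p_value = NA_real_, n_per_group = tot,
                           note = "degenerate pooled classification"))
  }
  if (all(colSums(tab) > 0) && identical_proportions(tab)) {
    # identical compositions: chi-square statistic is exactly 0
    return(new_test_result("median_test", names(vals), statistic = 0,
                           df = length(vals) - 1, p_value = 1, n_per_group = tot))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result("median_test", names(vals), statistic = unname(ht$statistic),
                  df = unname(ht$parameter), p_value = ht$p.value,
                  n_per_group = tot)
}

identical_proportions <- function(tab) {
  p <- tab["above", ] / colSums(tab)
  max(p) - min(p) < .Machine$double.eps^0.5
}

#' Build the study comparison plan
#'
#' Describes which cohorts are compared and how, mirroring the published
#' analysis: one Kruskal-Wallis (and one median test) across the blood-
#' derived tumor-type cohorts, all pairwise Mann-Whitney U tests between
#' them, blood vs liquor within the group that has liquor samples,
#' patient-derived CTCs vs the matching cultured cell line, and leukocytes
#' vs each tumor type. Cohorts are keyed as `"group/material"`.
#'
#' @param tumor_groups Character vector of tumor-type group labels (blood
#'   material).
#' @param liquor_group Group with an additional liquor cohort (`NULL` to
#'   skip).
#' @param cell_line_map Named character vector mapping a tumor group to its
#'   cell-line group label.
#' @param leukocyte_group Group label of the leukocyte reference cohort
#'   (`NULL` to skip).
#' @return A plan object (list of comparison descriptors) of class
#'   `ctc_comparison_plan`.
#' @export
comparison_plan <- function(tumor_groups = c("breast", "prostate", "colorectal", "bladder"),
                            liquor_group = "breast",
                            cell_line_map = c(breast = "breast_cell_line",
                                              prostate = "prostate_cell_line"),
                            leukocyte_group = "leukocyte") {
  key <- function(group, material = "blood") paste(group, material, sep = "/")
  plan <- list()
  tumor_keys <- key(tumor_groups)
  plan[[length(plan) + 1L]] <- list(test = "kruskal_wallis", label = "tumor types (KW)",
                                    cohorts = tumor_keys)
  plan[[length(plan) + 1L]] <- list(test = "median_test", label = "tumor types (median test)",
                                    cohorts = tumor_keys)
  if (length(tumor_keys) >= 2L) {
    for (pr in utils::combn(tumor_keys, 2L, simplify = FALSE)) {
      plan[[length(plan) + 1L]] <- list(test = "mann_whitney_u",
                                        label = sprintf("%s vs %s", pr[1], pr[2]),
                                        cohorts = pr)
    }
  }
  if (!is.null(liquor_group)) {
    plan[[length(plan) + 1L]] <- list(
      test = "mann_whitney_u", label = sprintf("%s blood vs liquor", liquor_group),
      cohorts = c(key(liquor_group), key(liquor_group, "liquor")))
  }
  for (g in names(cell_line_map)) {
    plan[[length(plan) + 1L]] <- list(
      test = "mann_whitney_u", label = sprintf("%s CTC vs cell line", g),
      cohorts = c(key(g), key(cell_line_map[[g]])))
  }
  if (!is.null(leukocyte_group)) {
    for (g in tumor_groups) {
      plan[[length(plan) + 1L]] <- list(
        test = "mann_whitney_u", label = sprintf("leukocytes vs %s", g),
        cohorts = c(key(leukocyte_group), key(g)))
    }
  }
  structure(plan, class = "ctc_comparison_plan")
}

#' Run the planned cohort comparisons
#'
#' Executes every comparison of the plan on a morphometry table (or any
#' data frame with `group`, `material` and the value column). Cohorts named
#' in the plan but absent from the data are skipped with a warning; pass
#' `strict = TRUE` to turn a missing cohort into an error listing it. No
#' multiple-testing correction is applied by default, mirroring the
#' published pairwise usage; `adjust = "bonferroni"` adds an adjusted
#' column.
#'
#' @param data Morphometry tibble ([morphometry_table()]) or compatible.
#' @param value Data-masked column to compare (e.g. `cell_area`,
#'   `nucleus_area`, `ncr`).
#' @param plan A [comparison_plan()].
#' @param strict Error (instead of warn + skip) on missing cohorts.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A tibble of class `ctc_comparisons`, one row per executed test:
#'   `label`, `test`, `groups`, `statistic`, `df`, `p_value`
#'   (and `p_adjusted` when requested), `n_per_group`, `note`.
#' @export
run_comparisons <- function(data, value, plan = comparison_plan(),
                            strict = FALSE, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  data <- as_tibble(data)
  data$.cohort <- paste(data$group, data$material, sep = "/")
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  data$.value <- v
  have <- unique(data$.cohort[!is.na(data$.value)])
  rows <- list()
  for (cmp in plan) {
    missing <- setdiff(cmp$cohorts, have)
    if (length(missing)) {
      msg <- sprintf("Comparison '%s' skipped: missing cohort(s) %s.",
                     cmp$label, paste(missing, collapse = ", "))
      if (strict) abort(msg, class = "ctcmorph_validation_error")
      warn(msg)
      next
    }
    sub <- data |> filter(.data$.cohort %in% cmp$cohorts)
    res <- switch(cmp$test,
      kruskal_wallis = kruskal_wallis(sub, .data$.value, .data$.cohort),
      median_test = median_test(sub, .data$.value, .data$.cohort),
      mann_whitney_u = {
        a <- sub$.value[sub$.cohort == cmp$cohorts[1]]
        b <- sub$.value[sub$.cohort == cmp$cohorts[2]]
        r <- mann_whitney_u(a, b)
        r$groups <- paste(cmp$cohorts, collapse = " vs ")
        r$n_per_group <- list(setNames(c(length(a[!is.na(a)]), length(b[!is.na(b)])),
                                       cmp$cohorts))
        r
      },
      abort(sprintf("Unknown test '%s' in plan.", cmp$test))
    )
    res$label <- cmp$label
    rows[[length(rows) + 1L]] <- res
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    out <- out[, c("label", setdiff(names(out), "label"))]
    if (adjust == "bonferroni") {
      mwu <- out$test == "mann_whitney_u"
      out$p_adjusted <- out$p_value
      out$p_adjusted[mwu] <- p.adjust(out$p_value[mwu], method = "bonferroni")
    }
  }
  class(out) <- c("ctc_comparisons", class(out))
  out
}

#' Format p-values for reporting
#'
#' `"< 0.001"` below one-tenth of a percent, otherwise three decimals --
#' the presentation convention of the cohort tables.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  if_else(is.na(p), NA_character_,
          if_else(p < 0.001, "< 0.001", sprintf("%.3f", p)))
}
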