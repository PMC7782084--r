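# Singularity classification by the P2A shape ratio and the nested
# single-CTC / intact-nucleus / leukocyte selection cascade.

P2A_CLASSES <- c("single", "doublet", "small_cluster", "large_cluster")

#' P2A class bin edges
#'
#' Three ascending thresholds `(t1, t2, t3)` partition the P2A axis into four
#' half-open classes: single `[0, t1)`, doublet `[t1, t2)`, small cluster
#' `[t2, t3)`, large cluster `[t3, Inf)`. The defaults 1.5 / 2.5 / 4 are the
#' published bin edges for CellSearch event galleries; they are configurable
#' because the underlying shape-ratio definition has appeared with other
#' normalizations.
#'
#' @param edges Numeric vector of three strictly increasing positive values.
#' @return The validated numeric edge vector, classed `p2a_bins`.
#' @export
p2a_bins <- function(edges = c(1.5, 2.5, 4)) {
  if (inherits(edges, "p2a_bins")) return(edges)
  if (length(edges) != 3L || anyNA(edges) || any(edges <= 0) ||
      any(diff(edges) <= 0)) {
    abort("`edges` must be three ascending positive thresholds (t1 < t2 < t3).",
          class = "ctcmorph_validation_error")
  }
  structure(as.numeric(edges), class = "p2a_bins")
}

#' Classify event singularity from a P2A value
#'
#' @param p2a Numeric vector of P2A values (`NA` = undefined, e.g. an empty
#'   channel).
#' @param bins Bin edges, see [p2a_bins()].
#' @return A factor with levels `single`, `doublet`, `small_cluster`,
#'   `large_cluster`; `NA` where `p2a` is undefined (never an error).
#' @examples
#' classify_singularity(c(1.0, 1.5, 2.7, 4.0, NA))
#' @export
classify_singularity <- function(p2a, bins = p2a_bins()) {
  bins <- p2a_bins(bins)
  if (any(p2a < 0, na.rm = TRUE)) {
    abort("P2A values must be nonnegative.", class = "ctcmorph_validation_error")
  }
  idx <- findInterval(p2a, c(0, unclass(bins)))  # lower-closed, upper-open
  factor(P2A_CLASSES[idx], levels = P2A_CLASSES)
}

#' Selection cascade: flag size-eligible single CTCs
#'
#' Fills `singularity_class` from the CK-channel P2A (undefined for
#' CK-negative events, which are excluded from all classes) and flags
#' `size_eligible` events: CK positive *and* classified single. Only these
#' events enter the size analysis; marked coordinates can contain several
#' touching CTCs, and the P2A bins separate those doublets/clusters out.
#'
#' @param records Feature tibble from [measure_events()] or
#'   [read_feature_table()].
#' @param bins P2A bin edges ([p2a_bins()]).
#' @return `records` with `singularity_class` and `size_eligible` filled.
#' @export
select_ctc_events <- function(records, bins = p2a_bins()) {
  records <- as_tibble(records)
  records$singularity_class <- classify_singularity(
    ifelse(records$ck_positive, records$ck_p2a, NA_real_), bins)
  records$size_eligible <- records$ck_positive &
    !is.na(records$singularity_class) & records$singularity_class == "single"
  records
}

#' Selection cascade: flag nucleus-evaluable events
#'
#' Among size-eligible events, flags `dapi_evaluable` when the nuclear signal
#' is positive (DAPI area > 0 um^2) and intact (DAPI area strictly smaller
#' than the CK area), and `ncr_eligible` when additionally the DAPI signal is
#' itself classified single by the same P2A bins. Fills
#' `dapi_singularity_class` for all DAPI-positive events.
#'
#' @inheritParams select_ctc_events
#' @return `records` with `dapi_singularity_class`, `dapi_evaluable` and
#'   `ncr_eligible` filled.
#' @export
select_nucleus_evaluable <- function(records, bins = p2a_bins()) {
  records <- as_tibble(records)
  if (!"size_eligible" %in% names(records) ||
      (nrow(records) > 0 && all(is.na(records$size_eligible)))) {
    abort("`size_eligible` must be set first; call select_ctc_events().",
          class = "ctcmorph_validation_error")
  }
  records$dapi_singularity_class <- classify_singularity(
    ifelse(records$dapi_positive, records$dapi_p2a, NA_real_), bins)
  records$dapi_evaluable <- records$size_eligible &
    !is.na(records$dapi_area) & records$dapi_area > 0 &
    records$dapi_area < records$ck_area
  records$ncr_eligible <- records$dapi_evaluable &
    !is.na(records$dapi_singularity_class) &
    records$dapi_singularity_class == "single"
  records
}

#' Selection cascade: flag leukocyte events
#'
#' Leukocytes are CD45+/DAPI+/CK- events whose CD45 signal is classified
#' single by the same P2A bins that the CK channel uses for CTCs.
#'
#' @inheritParams select_ctc_events
#' @return `records` with the `leukocyte` flag filled.
#' @export
select_leukocytes <- function(records, bins = p2a_bins()) {
  records <- as_tibble(records)
  cd45_class <- classify_singularity(
    ifelse(records$cd45_positive, records$cd45_p2a, NA_real_), bins)
  records$leukocyte <- records$cd45_positive & records$dapi_positive &
    !records$ck_positive & !is.na(cd45_class) & cd45_class == "single"
  records
}

#' Run the full selection cascade
#'
#' Applies [select_ctc_events()], [select_nucleus_evaluable()] and
#' [select_leukocytes()] in order.
#'
#' @inheritParams select_ctc_events
#' @return The fully flagged feature tibble.
#' @export
flag_events <- function(records, bins = p2a_bins()) {
  records |>
    select_ctc_events(bins) |>
    select_nucleus_evaluable(bins) |>
    select_leukocytes(bins)
}

#' Tabulate selection counts per cohort
#'
#' Counts events per `(group, material)` cohort at each stage of the
#' cascade: all detected events, CK-positive events, the four singularity
#' classes (which partition the CK-positive events), DAPI-evaluable events,
#' and the nucleus categories single / double / clustered (the doublet bin
#' of the DAPI P2A maps to "double", both cluster bins to "clustered").
#'
#' @param records Fully flagged feature tibble ([flag_events()]).
#' @param total Append a grand-total row (`group = "(all)"`)? Default `FALSE`.
#' @return A tibble with one row per cohort and columns `detected`,
#'   `ck_positive`, `single`, `doublet`, `small_cluster`, `large_cluster`,
#'   `dapi_evaluable`, `dapi_single`, `dapi_double`, `dapi_clustered`.
#' @export
tabulate_counts <- function(records, total = FALSE) {
  records <- as_tibble(records)
  if (all(is.na(records$size_eligible)) && nrow(records) > 0) {
    abort("Flags are not set; call flag_events() first.",
          class = "ctcmorph_validation_error")
  }
  cls <- records$singularity_class
  dcls <- records$dapi_singularity_class
  counts <- records |>
    mutate(.cls = cls, .dcls = dcls,
           .ev = !is.na(.data$dapi_evaluable) & .data$dapi_evaluable) |>
    group_by(.data$group, .data$material) |>
    summarise(
      detected = dplyr::n(),
      ck_positive = sum(.data$ck_positive, na.rm = TRUE),
      single = sum(.data$.cls == "single", na.rm = TRUE),
      doublet = sum(.data$.cls == "doublet", na.rm = TRUE),
      small_cluster = sum(.data$.cls == "small_cluster", na.rm = TRUE),
      large_cluster = sum(.data$.cls == "large_cluster", na.rm = TRUE),
      dapi_evaluable = sum(.data$.ev),
      dapi_single = sum(.data$.ev & .data$.dcls == "single", na.rm = TRUE),
      dapi_double = sum(.data$.ev & .data$.dcls == "doublet", na.rm = TRUE),
      dapi_clustered = sum(.data$.ev &
                             .data$.dcls %in% c("small_cluster", "large_cluster"),
                           na.rm = TRUE),
      .groups = "drop"
    )
  if (total && nrow(counts) > 0) {
    tot <- counts |>
      summarise(group = "(all)", material = "(all)",
                across(all_of(setdiff(names(counts), c("group", "material"))), sum))
    counts <- bind_rows(counts, tot)
  }
  counts
}

#' Compare re-detected event counts to expert counts
#'
#' For each cartridge, the number of events the pipeline measured is divided
#' by the platform-reported (expert) CTC count from the manifest. The ratio
#' is undefined (`NA`) when the expert count is zero.
#'
#' @param records Feature tibble (flags not required).
#' @param manifest Manifest tibble ([read_manifest()]) covering every
#'   cartridge present in `records`.
#' @return A tibble with one row per cartridge: `cartridge_id`, `group`,
#'   `material`, `detected`, `expert_ctc_count`, `ratio`.
#' @export
compare_to_expert_counts <- function(records, manifest) {
  records <- as_tibble(records)
  missing <- setdiff(unique(records$cartridge_id), manifest$cartridge_id)
  if (length(missing)) {
    abort(sprintf("Cartridge(s) absent from manifest: %s",
                  paste(missing, collapse = ", ")),
          class = "ctcmorph_validation_error")
  }
  detected <- records |> count(.data$cartridge_id, name = "detected")
  manifest |>
    left_join(detected, by = "cartridge_id") |>
    mutate(detected = if_else(is.na(.data$detected), 0L, .data$detected),
           ratio = if_else(!is.na(.data$expert_ctc_count) & .data$expert_ctc_count > 0,
                           .data$detected / .data$expert_ctc_count, NA_real_)) |>
    select(all_of(c("cartridge_id", "group", "material", "detected",
                    "expert_ctc_count", "ratio")))
}
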