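# Equivalent-circle diameters and nucleus/cytoplasm ratios.

#' Equivalent-circle diameter of a measured area
#'
#' Diameter (um) of the circle with the same area as the segmented signal:
#' `2 * sqrt(area / pi)`. Strictly increasing in area; quadrupling the area
#' exactly doubles the diameter; an area of 0 maps to 0.
#'
#' @param area Numeric vector of areas in um^2 (>= 0).
#' @return Numeric vector of diameters in um.
#' @examples
#' equivalent_diameter(120.4)  # 12.4 um to one decimal
#' equivalent_diameter(pi)     # 2 um
#' @export
equivalent_diameter <- function(area) {
  if (any(area < 0, na.rm = TRUE)) {
    abort("Areas must be nonnegative.", class = "ctcmorph_validation_error")
  }
  2 * sqrt(area / pi)
}

#' Nucleus/cytoplasm ratio
#'
#' Ratio of the nuclear (DAPI) to cytoplasmic (CK) signal of one cell. The
#' default convention is the **area** ratio `dapi_area / ck_area`, which lies
#' in (0, 1) for an intact nucleus enclosed in its cytoplasm. The diameter
#' convention (`method = "diameter"`, the square root of the area ratio) is
#' available for comparison with reports that quote diameter ratios.
#'
#' @param dapi_area,ck_area Paired numeric vectors of areas in um^2 with
#'   `0 < dapi_area < ck_area` elementwise.
#' @param method `"area"` (default) or `"diameter"`.
#' @return Numeric vector of ratios in (0, 1).
#' @examples
#' nucleus_cytoplasm_ratio(52.0, 83.6)  # 0.62
#' @export
nucleus_cytoplasm_ratio <- function(dapi_area, ck_area,
                                    method = c("area", "diameter")) {
  method <- match.arg(method)
  bad <- !is.na(dapi_area) & !is.na(ck_area) &
    (dapi_area <= 0 | ck_area <= 0 | dapi_area >= ck_area)
  if (any(bad)) {
    abort(sprintf("NCR requires 0 < dapi_area < ck_area; violated for %d value(s).",
                  sum(bad)),
          class = "ctcmorph_validation_error")
  }
  r <- dapi_area / ck_area
  if (method == "diameter") sqrt(r) else r
}

#' Per-event morphometry table
#'
#' Converts flagged event records into one morphometry row per event that
#' enters the size analysis: size-eligible single CTCs (cell signal = CK
#' channel) and, when present, flagged leukocytes (cell signal = CD45
#' channel, mirroring the application of the CK selection criteria to CD45).
#' Nucleus fields and the NCR are populated only for `ncr_eligible` events.
#'
#' @param records Fully flagged feature tibble ([flag_events()]).
#' @param method NCR convention, see [nucleus_cytoplasm_ratio()].
#' @param include_leukocytes Include leukocyte-flagged events (default
#'   `TRUE`).
#' @return A tibble with columns `event_id`, `cartridge_id`, `group`,
#'   `material`, `signal` (`"ck"` or `"cd45"`), `cell_area` (um^2),
#'   `cell_diameter` (um), `nucleus_area`, `nucleus_diameter`, `ncr`.
#' @export
morphometry_table <- function(records, method = c("area", "diameter"),
                              include_leukocytes = TRUE) {
  method <- match.arg(method)
  records <- as_tibble(records)
  if (!"ncr_eligible" %in% names(records) ||
      (nrow(records) > 0 && all(is.na(records$size_eligible)))) {
    abort("Flags are not set; call flag_events() first.",
          class = "ctcmorph_validation_error")
  }
  ids <- c("event_id", "cartridge_id", "group", "material")
  ctc <- records |> filter(.data$size_eligible)
  ctc_tab <- tibble(
    ctc[, ids],
    signal = rep("ck", nrow(ctc)),
    cell_area = ctc$ck_area,
    nucleus_area = if_else(ctc$ncr_eligible, ctc$dapi_area, NA_real_)
  )
  out <- ctc_tab
  if (include_leukocytes && "leukocyte" %in% names(records)) {
    leu <- records |> filter(!is.na(.data$leukocyte) & .data$leukocyte)
    if (nrow(leu) > 0) {
      out <- bind_rows(out, tibble(
        leu[, ids],
        signal = rep("cd45", nrow(leu)),
        cell_area = leu$cd45_area,
        nucleus_area = NA_real_
      ))
    }
  }
  out |>
    mutate(
      cell_diameter = equivalent_diameter(.data$cell_area),
      nucleus_diameter = if_else(is.na(.data$nucleus_area), NA_real_,
                                 equivalent_diameter(.data$nucleus_area)),
      ncr = if_else(is.na(.data$nucleus_area), NA_real_,
                    .data$nucleus_area / .data$cell_area)
    ) |>
    mutate(ncr = if (method == "diameter") sqrt(.data$ncr) else .data$ncr) |>
    select(all_of(c(ids, "signal", "cell_area", "cell_diameter",
                    "nucleus_area", "nucleus_diameter", "ncr")))
}
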