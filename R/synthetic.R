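# Synthetic cartridge generator: cohorts with known ground truth, rendered
# as multichannel thumbnail galleries that the whole pipeline can consume.

z75 <- qnorm(0.75)

#' Solve lognormal parameters from a target median and IQR
#'
#' Areas are generated from a two-parameter lognormal, the minimal
#' right-skewed positive family that can match both a target median and a
#' target interquartile width. The solution is closed form:
#' `mu = log(median)` and, because Q3 - Q1 = 2 median sinh(z75 sigma),
#' `sigma = asinh(iqr / (2 median)) / z75` with `z75` the 0.75 standard
#' normal quantile. Any positive (median, IQR) pair is attainable.
#'
#' @param median_area Target median (um^2), > 0.
#' @param iqr_area Target Q3 - Q1 width (um^2), > 0.
#' @return Named list with `meanlog` and `sdlog`.
#' @examples
#' p <- lognormal_from_median_iqr(83.6, 63.5)
#' qlnorm(0.5, p$meanlog, p$sdlog)  # 83.6
#' @export
lognormal_from_median_iqr <- function(median_area, iqr_area) {
  if (!is.finite(median_area) || median_area <= 0 ||
      !is.finite(iqr_area) || iqr_area <= 0) {
    abort("Target median and IQR must be finite and > 0.",
          class = "ctcmorph_validation_error")
  }
  list(meanlog = log(median_area),
       sdlog = asinh(iqr_area / (2 * median_area)) / z75)
}

# Beta parameters with a fixed concentration whose median approximates the
# target (median ~ (a - 1/3) / (a + b - 2/3) for a, b > 1).
beta_from_median <- function(median_ncr, concentration = 24) {
  if (!is.finite(median_ncr) || median_ncr <= 0 || median_ncr >= 1) {
    abort("Target NCR median must lie in (0, 1).", class = "ctcmorph_validation_error")
  }
  a <- median_ncr * (concentration - 2 / 3) + 1 / 3
  list(shape1 = a, shape2 = concentration - a)
}

#' Specify a synthetic cohort
#'
#' Bundles the generative parameters of one cohort: how many events, the
#' area distribution (lognormal matched to a target median and IQR), the
#' singularity class mix, the NCR distribution (beta on (0, 1) matched to a
#' target median), the fraction of leukocyte events, nucleus detection
#' failure and double-nucleus rates, and the imaging noise.
#'
#' @param group,material Cohort labels.
#' @param n_events Number of events to generate.
#' @param area_median,area_iqr Target median and IQR of the cell-signal area
#'   (um^2): the CK signal for CTC events, the CD45 signal for leukocytes.
#' @param class_mix Probabilities over
#'   `c(single, doublet, small_cluster, large_cluster)`, summing to 1.
#' @param ncr_median Target median of the per-event nucleus/cytoplasm area
#'   ratio, in (0, 1).
#' @param ncr_concentration Beta concentration (a + b); larger = tighter.
#' @param dapi_missing_rate Fraction of events whose nuclear signal goes
#'   undetected (DAPI channel left at background).
#' @param dapi_double_rate Fraction of single-cell events rendered with a
#'   double (two-lobed) nuclear signal.
#' @param leukocyte_fraction Fraction of events that are leukocytes
#'   (CD45+/DAPI+/CK-).
#' @param noise_background,noise_sd Background level and Gaussian sigma on
#'   the 0-1 intensity scale.
#' @param foreground_level Mean foreground intensity on the 0-1 scale.
#' @param pixel_size um per pixel edge.
#' @param seed Integer seed; all sampling and rendering for the cohort is a
#'   deterministic function of it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group, material = "blood", n_events,
                        area_median, area_iqr,
                        class_mix = c(single = 1, doublet = 0,
                                      small_cluster = 0, large_cluster = 0),
                        ncr_median = 0.55, ncr_concentration = 24,
                        dapi_missing_rate = 0, dapi_double_rate = 0,
                        leukocyte_fraction = 0,
                        noise_background = 0.06, noise_sd = 0.02,
                        foreground_level = 0.55, pixel_size = 0.64,
                        seed = 20201004L) {
  lognormal_from_median_iqr(area_median, area_iqr)  # validates targets
  class_mix <- as.numeric(class_mix)
  if (length(class_mix) != 4L || anyNA(class_mix) || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    abort("`class_mix` must be 4 nonnegative probabilities summing to 1.",
          class = "ctcmorph_validation_error")
  }
  for (p in c(dapi_missing_rate, dapi_double_rate, leukocyte_fraction)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      abort("Rates must lie in [0, 1].", class = "ctcmorph_validation_error")
    }
  }
  beta_from_median(ncr_median, ncr_concentration)  # validates target
  structure(list(
    group = group, material = material, n_events = as.integer(n_events),
    area_median = area_median, area_iqr = area_iqr,
    class_mix = setNames(class_mix, P2A_CLASSES),
    ncr_median = ncr_median, ncr_concentration = ncr_concentration,
    dapi_missing_rate = dapi_missing_rate, dapi_double_rate = dapi_double_rate,
    leukocyte_fraction = leukocyte_fraction,
    noise_background = noise_background, noise_sd = noise_sd,
    foreground_level = foreground_level, pixel_size = pixel_size,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample a cohort's ground truth
#'
#' Draws the true per-event quantities of a synthetic cohort: singularity
#' class from the class mix, cell-signal area from the matched lognormal,
#' per-event NCR from the matched beta, and the derived nuclear area
#' (NCR x cell area, so the nucleus is always strictly enclosed). Leukocyte
#' events carry their area on the CD45 channel and none on CK. Sampling is
#' deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param cartridge_size Events per synthetic cartridge (galleries hold at
#'   most 175 thumbnails per sample, the default).
#' @return A ground-truth tibble: `event_id`, `cartridge_id`, `group`,
#'   `material`, `is_leukocyte`, `true_class`, `true_ck_area`,
#'   `true_cd45_area`, `true_dapi_area` (0 when the nuclear signal is
#'   missing), `true_dapi_lobes`, `true_ncr` (`NA` when undefined).
#' @export
sample_cohort <- function(spec, cartridge_size = 175L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_events
  ln <- lognormal_from_median_iqr(spec$area_median, spec$area_iqr)
  bt <- beta_from_median(spec$ncr_median, spec$ncr_concentration)
  with_local_seed(spec$seed, {
    is_leu <- runif(n) < spec$leukocyte_fraction
    cls <- sample(P2A_CLASSES, n, replace = TRUE, prob = spec$class_mix)
    cls[is_leu] <- "single"
    area <- rlnorm(n, ln$meanlog, ln$sdlog)
    ncr <- rbeta(n, bt$shape1, bt$shape2)
    dapi_missing <- runif(n) < spec$dapi_missing_rate
    lobes <- ifelse(!dapi_missing & cls == "single" &
                      runif(n) < spec$dapi_double_rate, 2L, 1L)
    dapi <- ifelse(dapi_missing, 0, ncr * area)
    tibble(
      event_id = sprintf("%s_%s_e%05d", spec$group, substr(spec$material, 1, 1),
                         seq_len(n)),
      cartridge_id = sprintf("%s_%s_c%03d", spec$group, substr(spec$material, 1, 1),
                             (seq_len(n) - 1L) %/% cartridge_size + 1L),
      group = spec$group, material = spec$material,
      is_leukocyte = is_leu, true_class = factor(cls, levels = P2A_CLASSES),
      true_ck_area = ifelse(is_leu, 0, area),
      true_cd45_area = ifelse(is_leu, area, 0),
      true_dapi_area = dapi, true_dapi_lobes = lobes,
      true_ncr = ifelse(dapi > 0, ncr, NA_real_)
    )
  })
}

# Add k near-tangent disks of equal area (total `area_px2` px^2) along a
# chain at angle `theta`, anchored at (cy, cx). A small inter-lobe gap
# (default 2 px) keeps the rasterized lobes from fusing under the median
# denoise, so the union area stays exactly k * pi * r^2 and the analytic
# P2A of the chain stays k (perimeters and areas of the lobes both add).
disk_chain <- function(k, area_px2, cy, cx, theta, gap_px = 2) {
  r <- sqrt(area_px2 / (k * pi))
  offs <- (seq_len(k) - (k + 1) / 2) * (2 * r + gap_px)
  list(r = r,
       cy = cy + offs * sin(theta),
       cx = cx + offs * cos(theta))
}

paint_disks <- function(frame, chain) {
  yy <- matrix(seq_len(frame), frame, frame)
  xx <- t(yy)
  m <- matrix(FALSE, frame, frame)
  for (i in seq_along(chain$cy)) {
    m <- m | ((yy - chain$cy[i])^2 + (xx - chain$cx[i])^2 <= chain$r^2)
  }
  m
}

CLASS_LOBES <- c(single = 1L, doublet = 2L, small_cluster = 3L, large_cluster = 5L)

#' Render one ground-truth event as a multichannel thumbnail
#'
#' Draws the event geometry the P2A classifier presumes: the cell signal as
#' `k` tangent equal disks whose union area equals the true area, with
#' `k` = 1 (single), 2 (doublet), 3 (small cluster) or 5 (large cluster) --
#' tangent chains of k disks have an analytic P2A of exactly k, placing each
#' class mid-bin. The nuclear signal uses the same chain geometry scaled to
#' the true DAPI area, so nuclei sit inside their cytoplasm; leukocytes are
#' drawn on CD45 + DAPI with the CK channel left at background. Gaussian
#' background noise is added per the spec; disk centers carry subpixel
#' jitter so measurements are not tied to lattice-aligned placements.
#'
#' @param truth One row of a [sample_cohort()] tibble (as a list or one-row
#'   data frame).
#' @param spec The [cohort_spec()] providing noise, intensity and pixel
#'   size (individual values can be overridden via `...` arguments of
#'   [cohort_spec()] when constructing it).
#' @param frame Thumbnail edge length in pixels, or `NULL` (default) to
#'   auto-size generously around the geometry. When an explicit frame is too
#'   small for the event, a validation error is raised.
#' @return Named list with [channel_image()] elements `dapi`, `ck`, `cd45`.
#' @export
render_event <- function(truth, spec, frame = NULL) {
  truth <- as.list(as_tibble(truth)[1, ])
  ps <- spec$pixel_size
  k <- CLASS_LOBES[[as.character(truth$true_class)]]
  cell_area <- if (isTRUE(truth$is_leukocyte)) truth$true_cd45_area else truth$true_ck_area
  area_px2 <- cell_area / ps^2
  r <- sqrt(area_px2 / (k * pi))
  extent <- (2 * r + 2) * k + 2 * r  # chain length plus margin for jitter
  needed <- ceiling(extent + 12)
  if (is.null(frame)) {
    frame <- max(56L, as.integer(needed))
  } else if (frame < needed) {
    abort(sprintf("Event %s: area %.1f um^2 does not fit a %d px frame (needs %d).",
                  truth$event_id, cell_area, frame, as.integer(needed)),
          class = "ctcmorph_validation_error")
  }
  cy <- (frame + 1) / 2 + runif(1) - 0.5
  cx <- (frame + 1) / 2 + runif(1) - 0.5
  theta <- runif(1, 0, pi)
  cell_mask <- paint_disks(frame, disk_chain(k, area_px2, cy, cx, theta))
  dapi_mask <- matrix(FALSE, frame, frame)
  if (truth$true_dapi_area > 0) {
    kd <- max(k, truth$true_dapi_lobes)
    dapi_mask <- paint_disks(frame,
                             disk_chain(kd, truth$true_dapi_area / ps^2, cy, cx, theta))
  }
  noisy <- function(mask) {
    px <- spec$noise_background + rnorm(frame * frame, 0, spec$noise_sd)
    px[mask] <- spec$foreground_level + rnorm(sum(mask), 0, spec$noise_sd)
    matrix(pmin(pmax(px, 0), 1), frame, frame)
  }
  blank <- function() {
    matrix(pmin(pmax(spec$noise_background + rnorm(frame * frame, 0, spec$noise_sd),
                     0), 1), frame, frame)
  }
  if (isTRUE(truth$is_leukocyte)) {
    ck_px <- blank(); cd45_px <- noisy(cell_mask)
  } else {
    ck_px <- noisy(cell_mask); cd45_px <- blank()
  }
  dapi_px <- if (truth$true_dapi_area > 0) noisy(dapi_mask) else blank()
  list(dapi = channel_image(dapi_px, ps, "dapi"),
       ck = channel_image(ck_px, ps, "ck"),
       cd45 = channel_image(cd45_px, ps, "cd45"))
}

#' Render a sampled cohort into a gallery tibble
#'
#' Renders every ground-truth event (deterministically, from the spec seed)
#' and returns the same gallery shape that [read_gallery()] produces, so the
#' rendered cohort feeds directly into [measure_events()].
#'
#' @param truth Ground-truth tibble from [sample_cohort()].
#' @param spec The matching [cohort_spec()].
#' @param frame Optional fixed thumbnail edge (px); `NULL` auto-sizes.
#' @return A gallery tibble with list-columns `dapi`, `ck`, `cd45`.
#' @export
render_cohort <- function(truth, spec, frame = NULL) {
  with_local_seed(spec$seed + 1L, {
    imgs <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      imgs[[i]] <- render_event(truth[i, ], spec, frame = frame)
    }
    tibble(
      event_id = truth$event_id, cartridge_id = truth$cartridge_id,
      group = truth$group, material = truth$material,
      row = sample.int(1000L, nrow(truth), replace = TRUE),
      col = sample.int(1000L, nrow(truth), replace = TRUE),
      dapi = purrr::map(imgs, "dapi"),
      ck = purrr::map(imgs, "ck"),
      cd45 = purrr::map(imgs, "cd45")
    )
  })
}

#' Export a synthetic gallery to disk
#'
#' Writes the cohort in the cartridge gallery layout that [read_gallery()]
#' reads: `manifest.csv` at the root, one subdirectory per cartridge with a
#' `markers.xml` marker file and one 8-bit grayscale TIFF per event and
#' channel, plus `ground_truth.csv` alongside.
#'
#' @param gallery Gallery tibble from [render_cohort()].
#' @param truth Matching ground-truth tibble ([sample_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_synthetic_gallery <- function(gallery, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expert <- truth |> count(.data$cartridge_id, name = "expert_ctc_count")
  manifest <- gallery |>
    dplyr::distinct(.data$cartridge_id, .data$group, .data$material) |>
    left_join(expert, by = "cartridge_id")
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"), progress = FALSE)
  for (cid in unique(gallery$cartridge_id)) {
    cdir <- file.path(dir, cid)
    dir.create(cdir, showWarnings = FALSE)
    sub <- gallery |> filter(.data$cartridge_id == cid)
    write_marker_file(sub[, c("event_id", "row", "col")],
                      file.path(cdir, "markers.xml"), cartridge_id = cid)
    for (i in seq_len(nrow(sub))) {
      for (ch in CHANNELS) {
        tiff::writeTIFF(sub[[ch]][[i]]$pixels,
                        file.path(cdir, sprintf("%s_%s.tif", sub$event_id[[i]], ch)),
                        bits.per.sample = 8L)
      }
    }
  }
  invisible(dir)
}

#' Cohort presets mirroring the published study conditions
#'
#' One [cohort_spec()] per cohort of the study, calibrated to the published
#' per-cohort medians and IQRs of the cell and nucleus signals, the
#' singularity class mixes of the per-tumor-type count table, the observed
#' nucleus detection/doubling rates, and the published cohort sizes (scaled
#' by `scale` for desk-sized runs). The targets are read from the bundled
#' `published_cohort_summaries.csv` and `published_selection_counts.csv`.
#'
#' @param scale Multiplier on the published cohort sizes (default 0.1;
#'   `scale = 1` reproduces the full published n per cohort).
#' @param seed Base seed; cohort i uses `seed + i`.
#' @return Named list of [cohort_spec()] objects.
#' @export
ctc_study_presets <- function(scale = 0.1, seed = 20201004L) {
  summaries <- published_cohort_summaries()
  counts <- published_selection_counts()
  nuc <- published_nucleus_counts()
  specs <- list()
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    cnt <- counts |> filter(.data$group == s$group, .data$material == s$material)
    mix <- if (nrow(cnt) == 1L) {
      m <- c(cnt$single, cnt$doublet, cnt$small_cluster, cnt$large_cluster)
      m / sum(m)
    } else c(1, 0, 0, 0)
    nr <- nuc |> filter(.data$group == s$group)
    dapi_missing <- if (nrow(nr) == 1L) 1 - nr$dapi_evaluable / nr$n_single_ctc else 0
    dapi_double <- if (nrow(nr) == 1L) nr$dapi_double / nr$dapi_evaluable else 0
    key <- paste(s$group, s$material, sep = "/")
    specs[[key]] <- cohort_spec(
      group = s$group, material = s$material,
      n_events = max(10L, as.integer(round(s$n_single * scale))),
      area_median = s$median_area, area_iqr = s$iqr_area,
      class_mix = mix,
      ncr_median = if (!is.na(s$printed_ncr)) s$printed_ncr else 0.7,
      dapi_missing_rate = dapi_missing, dapi_double_rate = dapi_double,
      leukocyte_fraction = if (s$group == "leukocyte") 1 else 0,
      seed = seed + i
    )
  }
  specs
}

#' Published per-cohort summaries and selection counts
#'
#' The printed per-cohort medians, IQRs, computed diameters, NCRs and event
#' counts of the source study, bundled as plain CSV. These are inputs: they
#' calibrate the synthetic generator and anchor the worked-arithmetic
#' checks.
#'
#' @return A tibble.
#' @export
published_cohort_summaries <- function() {
  readr::read_csv(system.file("extdata", "published_cohort_summaries.csv",
                              package = "ctcmorph", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_cohort_summaries
#' @export
published_selection_counts <- function() {
  readr::read_csv(system.file("extdata", "published_selection_counts.csv",
                              package = "ctcmorph", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_cohort_summaries
#' @export
published_nucleus_counts <- function() {
  readr::read_csv(system.file("extdata", "published_nucleus_counts.csv",
                              package = "ctcmorph", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_cohort_summaries
#' @export
published_diameter_pairs <- function() {
  readr::read_csv(system.file("extdata", "published_diameter_pairs.csv",
                              package = "ctcmorph", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_cohort_summaries
#' @export
published_ncr_triples <- function() {
  readr::read_csv(system.file("extdata", "published_ncr_triples.csv",
                              package = "ctcmorph", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}
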