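# The ground-truth generator and renderer.

test_that("lognormal parameters solved from median/IQR hit both targets", {
  p <- lognormal_from_median_iqr(83.6, 63.5)
  expect_equal(qlnorm(0.5, p$meanlog, p$sdlog), 83.6)
  expect_equal(qlnorm(0.75, p$meanlog, p$sdlog) - qlnorm(0.25, p$meanlog, p$sdlog),
               63.5)
  expect_error(lognormal_from_median_iqr(-1, 10), class = "ctcmorph_validation_error")
  expect_error(lognormal_from_median_iqr(10, 0), class = "ctcmorph_validation_error")
})

test_that("sampling is deterministic and respects the class mix", {
  spec <- cohort_spec("prostate", n_events = 50, area_median = 83.6,
                      area_iqr = 63.5, seed = 5)
  expect_identical(sample_cohort(spec), sample_cohort(spec))

  singles <- cohort_spec("x", n_events = 40, area_median = 100, area_iqr = 50,
                         class_mix = c(1, 0, 0, 0), seed = 6)
  expect_true(all(sample_cohort(singles)$true_class == "single"))

  expect_error(cohort_spec("x", n_events = 5, area_median = 100, area_iqr = 50,
                           class_mix = c(0.5, 0.5, 0.5, 0)),
               class = "ctcmorph_validation_error")
})

test_that("large samples match the target median and IQR", {
  spec <- cohort_spec("big", n_events = 20000, area_median = 83.6,
                      area_iqr = 63.5, seed = 8)
  a <- sample_cohort(spec)$true_ck_area
  expect_lt(abs(median(a) - 83.6) / 83.6, 0.02)
  iqr <- diff(quantile(a, c(0.25, 0.75), names = FALSE))
  expect_lt(abs(iqr - 63.5) / 63.5, 0.05)
})

test_that("ground truth satisfies its own invariants", {
  spec <- cohort_spec("breast", n_events = 300, area_median = 120.4,
                      area_iqr = 104.9, ncr_median = 0.47,
                      class_mix = c(0.9, 0.08, 0.015, 0.005),
                      dapi_missing_rate = 0.2, leukocyte_fraction = 0.1, seed = 9)
  tr <- sample_cohort(spec)
  ctc <- tr[!tr$is_leukocyte & tr$true_dapi_area > 0, ]
  expect_true(all(ctc$true_dapi_area < ctc$true_ck_area))
  expect_equal(ctc$true_ncr, ctc$true_dapi_area / ctc$true_ck_area)
  leu <- tr[tr$is_leukocyte, ]
  expect_true(all(leu$true_ck_area == 0))
  expect_true(all(leu$true_cd45_area > 0))
})

test_that("rendered singles and doublets measure into their P2A bins", {
  spec <- cohort_spec("x", n_events = 1, area_median = 120, area_iqr = 50,
                      noise_background = 0, noise_sd = 0, seed = 11)
  single <- tibble::tibble(event_id = "s", is_leukocyte = FALSE,
                           true_class = factor("single", levels = levels(sample_cohort(spec)$true_class)),
                           true_ck_area = 120, true_cd45_area = 0,
                           true_dapi_area = 55, true_dapi_lobes = 1L)
  imgs <- withr::with_seed(1, render_event(single, spec))
  rec <- measure_event(c(list(event_id = "s"), imgs))
  expect_lt(abs(rec$ck_area - 120) / 120, 0.05)
  expect_lt(rec$ck_p2a, 1.5)

  doublet <- single
  doublet$true_class <- factor("doublet", levels = levels(single$true_class))
  imgs_d <- withr::with_seed(2, render_event(doublet, spec))
  rec_d <- measure_event(c(list(event_id = "d"), imgs_d))
  expect_gte(rec_d$ck_p2a, 1.5)
  expect_lt(rec_d$ck_p2a, 2.5)
  expect_lt(abs(rec_d$ck_area - 120) / 120, 0.08)

  leu <- single
  leu$is_leukocyte <- TRUE
  leu$true_ck_area <- 0; leu$true_cd45_area <- 70; leu$true_dapi_area <- 40
  imgs_l <- withr::with_seed(3, render_event(leu, spec))
  expect_equal(max(imgs_l$ck$pixels), 0)  # CK channel pure background
  rec_l <- measure_event(c(list(event_id = "l"), imgs_l))
  expect_false(rec_l$ck_positive)
  expect_true(rec_l$cd45_positive)

  expect_error(render_event(single, spec, frame = 10),
               class = "ctcmorph_validation_error")
})

test_that("the cascade rejects rendered events whose nucleus engulfs the cell", {
  spec <- cohort_spec("x", n_events = 1, area_median = 100, area_iqr = 40,
                      noise_background = 0, noise_sd = 0, seed = 12)
  lv <- c("single", "doublet", "small_cluster", "large_cluster")
  bad <- tibble::tibble(event_id = sprintf("b%d", 1:6), cartridge_id = "c1",
                        group = "x", material = "blood", is_leukocyte = FALSE,
                        true_class = factor("single", levels = lv),
                        true_ck_area = 80,
                        true_cd45_area = 0,
                        true_dapi_area = c(80, 90, 100, 120, 150, 200),
                        true_dapi_lobes = 1L)
  recs <- withr::with_seed(4, {
    purrr::map_dfr(seq_len(nrow(bad)), function(i) {
      measure_event(c(list(event_id = bad$event_id[[i]]),
                      render_event(bad[i, ], spec)))
    })
  })
  flagged <- flag_events(recs)
  expect_true(all(!flagged$ncr_eligible))  # 100% specificity at zero noise
})

test_that("exported galleries drive the full pipeline back to the truth", {
  spec <- cohort_spec("prostate", n_events = 80, area_median = 83.6,
                      area_iqr = 63.5, ncr_median = 0.62,
                      class_mix = c(0.9, 0.07, 0.02, 0.01), seed = 13)
  truth <- sample_cohort(spec)
  gal <- render_cohort(truth, spec)
  dir <- withr::local_tempdir()
  export_synthetic_gallery(gal, truth, dir)

  back <- read_gallery(dir, default_pixel_size = spec$pixel_size)
  expect_equal(nrow(back), nrow(truth))
  recs <- flag_events(measure_events(back))
  joined <- dplyr::inner_join(recs, truth, by = "event_id")
  singles <- joined[joined$true_class == "single" & !joined$is_leukocyte, ]
  acc <- mean(as.character(singles$singularity_class) == "single")
  expect_gte(acc, 0.95)
  doublets <- joined[joined$true_class == "doublet", ]
  if (nrow(doublets) >= 4) {
    expect_gte(mean(as.character(doublets$singularity_class) == "doublet"), 0.75)
  }
})

test_that("study presets mirror the published cohort structure", {
  presets <- ctc_study_presets(scale = 0.01)
  expect_named(presets, c("breast/blood", "breast/liquor", "prostate/blood",
                          "colorectal/blood", "bladder/blood",
                          "breast_cell_line/blood", "prostate_cell_line/blood",
                          "leukocyte/blood"))
  pc <- presets[["prostate/blood"]]
  expect_equal(pc$area_median, 83.6)
  expect_equal(pc$ncr_median, 0.62)
  expect_equal(unname(pc$class_mix[1]), 19117 / 20100, tolerance = 1e-9)
  expect_equal(presets[["leukocyte/blood"]]$leukocyte_fraction, 1)
  expect_gt(pc$dapi_missing_rate, 0.25)  # 1 - 13356/19117
})
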