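# Shared fixtures: analytic shapes rasterized into channel images, canonical
# feature records, and the enumeration oracle for the exact Mann-Whitney U
# null distribution.

# Logical disk mask: pixels whose center lies within `r` of the disk center.
# `offset` shifts the center off the integer lattice (generic placement).
disk_mask <- function(r, frame = ceiling(2 * r + 9), offset = c(0, 0),
                      center = NULL) {
  if (is.null(center)) center <- c((frame + 1) / 2, (frame + 1) / 2)
  cy <- center[1] + offset[1]; cx <- center[2] + offset[2]
  yy <- matrix(seq_len(frame), frame, frame)
  xx <- t(yy)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# Channel image with foreground `fg` on `mask`, flat background `bg`.
mask_image <- function(mask, fg = 0.8, bg = 0, pixel_size = 0.64,
                       channel = "ck") {
  px <- matrix(bg, nrow(mask), ncol(mask))
  px[mask] <- fg
  channel_image(px, pixel_size = pixel_size, channel = channel)
}

disk_image <- function(r, frame = ceiling(2 * r + 9), offset = c(0, 0),
                       fg = 0.8, bg = 0, pixel_size = 0.64, channel = "ck") {
  mask_image(disk_mask(r, frame, offset), fg = fg, bg = bg,
             pixel_size = pixel_size, channel = channel)
}

blank_image <- function(frame = 31, pixel_size = 0.64, channel = "cd45") {
  channel_image(matrix(0, frame, frame), pixel_size = pixel_size,
                channel = channel)
}

# One canonical feature record with overridable fields; defaults are a
# well-formed CK+/DAPI+ single CTC.
make_record <- function(...) {
  rec <- tibble::tibble(
    event_id = "e1", cartridge_id = "c1", group = "breast", material = "blood",
    dapi_area = 50, dapi_perimeter = 26, dapi_p2a = 1.08,
    dapi_mean_intensity = 0.5, dapi_positive = TRUE,
    ck_area = 120, ck_perimeter = 40, ck_p2a = 1.1,
    ck_mean_intensity = 0.6, ck_positive = TRUE,
    cd45_area = 0, cd45_perimeter = 0, cd45_p2a = NA_real_,
    cd45_mean_intensity = NA_real_, cd45_positive = FALSE,
    singularity_class = NA_character_, dapi_singularity_class = NA_character_,
    size_eligible = NA, dapi_evaluable = NA, ncr_eligible = NA, leukocyte = NA
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Random cohort of canonical records (no images) for cascade property tests.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    recs <- purrr::map_dfr(seq_len(n), function(i) {
      ck_pos <- runif(1) < 0.85
      dapi_pos <- runif(1) < 0.8
      cd45_pos <- runif(1) < 0.3
      ck_area <- if (ck_pos) runif(1, 10, 400) else 0
      dapi_area <- if (dapi_pos) runif(1, 5, 300) else 0
      cd45_area <- if (cd45_pos) runif(1, 20, 150) else 0
      make_record(
        event_id = sprintf("e%04d", i),
        group = sample(c("breast", "prostate"), 1),
        ck_area = ck_area, ck_positive = ck_pos,
        ck_p2a = if (ck_pos) runif(1, 0.9, 6) else NA_real_,
        dapi_area = dapi_area, dapi_positive = dapi_pos,
        dapi_p2a = if (dapi_pos) runif(1, 0.9, 6) else NA_real_,
        cd45_area = cd45_area, cd45_positive = cd45_pos,
        cd45_p2a = if (cd45_pos) runif(1, 0.9, 6) else NA_real_
      )
    })
    recs
  })
}

# Exact two-sided Mann-Whitney p by full enumeration of the C(n1+n2, n1)
# group assignments; mirrors the doubled-tail convention of the test proper
# but is computed from first principles, independent of stats::wilcox.test.
mwu_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- if (u_obs > mu) {
    2 * mean(us >= u_obs)
  } else if (u_obs < mu) {
    2 * mean(us <= u_obs)
  } else 1
  list(u = u_obs, p = min(p, 1))
}
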