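#' Single-channel fluorescence thumbnail
#'
#' Lightweight container for one channel of an event thumbnail: a grayscale
#' pixel matrix plus the physical pixel size. Intensities are arbitrary
#' nonnegative units (TIFF galleries are read onto a 0--1 scale).
#'
#' @param pixels Numeric matrix of nonnegative intensities (rows x cols).
#' @param pixel_size Micrometers per pixel edge; finite and > 0. The default
#'   0.64 um/px matches CellSearch-style thumbnails (a 6.4 um scale bar
#'   spanning 10 px) and should be overridden when the acquisition differs.
#' @param channel One of `"dapi"`, `"ck"`, `"cd45"`.
#'
#' @return An object of class `channel_image`.
#' @examples
#' img <- channel_image(matrix(0, 20, 20), pixel_size = 0.64, channel = "ck")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, pixel_size = 0.64, channel = c("dapi", "ck", "cd45")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "ctcmorph_validation_error")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("`pixels` must have at least one row and one column.",
          class = "ctcmorph_validation_error")
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    abort("Channel intensities must be nonnegative and non-missing.",
          class = "ctcmorph_validation_error")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a single finite value > 0 (um/px).",
          class = "ctcmorph_validation_error")
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size), channel = channel),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %.3g um/px, intensity range [%.3g, %.3g]\n",
              toupper(x$channel), nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_channel_image <- function(x) inherits(x, "channel_image")

# Check that the three thumbnails of one event are mutually consistent.
validate_event_channels <- function(dapi, ck, cd45, event_id = "<event>") {
  imgs <- list(dapi = dapi, ck = ck, cd45 = cd45)
  for (ch in names(imgs)) {
    if (!is_channel_image(imgs[[ch]])) {
      abort(sprintf("Event %s: `%s` is not a channel_image.", event_id, ch),
            class = "ctcmorph_validation_error")
    }
  }
  dims <- vapply(imgs, function(i) dim(i$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort(sprintf("Event %s: channel thumbnails differ in dimensions.", event_id),
          class = "ctcmorph_validation_error")
  }
  ps <- vapply(imgs, function(i) i$pixel_size, numeric(1))
  if (max(ps) - min(ps) > 1e-9) {
    abort(sprintf("Event %s: channel thumbnails differ in pixel_size.", event_id),
          class = "ctcmorph_validation_error")
  }
  invisible(TRUE)
}
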