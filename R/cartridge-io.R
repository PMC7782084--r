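#' Read a marker-coordinate file
#'
#' Reads the coordinates of expert-marked events for one cartridge. Two
#' dialects are supported and chosen by file extension:
#'
#' * **XML** (`.xml`): one `<event>` element per marked event inside a
#'   `<markers>` root, with `id`, `row` and `col` attributes, e.g.
#'   `<event id="e1" row="120" col="340"/>`. This open dialect stands in for
#'   the proprietary vendor schema, which is not publicly documented.
#' * **Delimited fallback** (`.csv`/`.txt`): header `event_id,row,col`.
#'
#' Coordinates are 0-based `(row, col)` pixel positions of the event center
#' in the cartridge frame.
#'
#' @param path Path to the marker file.
#' @return A tibble with columns `event_id` (character), `row`, `col`
#'   (integers), one row per marked event in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("event_id,row,col", "e1,10,12"), f)
#' read_marker_file(f)
#' @export
read_marker_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Marker file not found: %s", path), class = "ctcmorph_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "xml") read_marker_xml(path) else read_marker_csv(path)
}

read_marker_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("Cannot parse XML marker file %s: %s", path, conditionMessage(e)),
          class = "ctcmorph_parse_error")
  })
  events <- xml2::xml_find_all(doc, ".//event")
  if (length(events) == 0L) {
    return(tibble(event_id = character(), row = integer(), col = integer()))
  }
  parse_one <- function(node, i) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id) || !nzchar(id)) id <- sprintf("event%03d", i)
    coords <- vapply(c("row", "col"), function(a) {
      v <- xml2::xml_attr(node, a)
      if (is.na(v) || !grepl("^-?[0-9]+$", trimws(v))) {
        abort(sprintf("Marker file %s, element %d (id '%s'): attribute '%s' is not an integer (got '%s').",
                      path, i, id, a, if (is.na(v)) "<missing>" else v),
              class = "ctcmorph_parse_error")
      }
      as.integer(trimws(v))
    }, integer(1))
    tibble(event_id = id, row = coords[["row"]], col = coords[["col"]])
  }
  purrr::imap_dfr(as.list(events), parse_one)
}

read_marker_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    return(tibble(event_id = character(), row = integer(), col = integer()))
  }
  header <- trimws(strsplit(lines[[1]], ",")[[1]])
  need <- c("event_id", "row", "col")
  idx <- match(need, header)
  if (anyNA(idx)) {
    abort(sprintf("Marker file %s: header must contain %s.",
                  path, paste(need, collapse = ", ")),
          class = "ctcmorph_parse_error")
  }
  purrr::imap_dfr(lines[-1], function(line, i) {
    fields <- trimws(strsplit(line, ",")[[1]])
    if (length(fields) < max(idx)) {
      abort(sprintf("Marker file %s, line %d: expected %d fields, got %d.",
                    path, i + 1L, max(idx), length(fields)),
            class = "ctcmorph_parse_error")
    }
    rc <- fields[idx[2:3]]
    bad <- !grepl("^-?[0-9]+$", rc)
    if (any(bad)) {
      abort(sprintf("Marker file %s, line %d (id '%s'): non-integer coordinate '%s'.",
                    path, i + 1L, fields[idx[1]], rc[bad][1]),
            class = "ctcmorph_parse_error")
    }
    tibble(event_id = fields[idx[1]], row = as.integer(rc[1]), col = as.integer(rc[2]))
  })
}

#' Write a marker-coordinate file (XML dialect)
#'
#' @param markers Tibble with columns `event_id`, `row`, `col`.
#' @param path Output path (`.xml`).
#' @param cartridge_id Cartridge identifier stored on the root element.
#' @return `path`, invisibly.
#' @export
write_marker_file <- function(markers, path, cartridge_id = "cartridge") {
  root <- xml2::xml_new_root("markers", cartridge = cartridge_id)
  for (i in seq_len(nrow(markers))) {
    xml2::xml_add_child(root, "event",
                        id = as.character(markers$event_id[[i]]),
                        row = as.character(as.integer(markers$row[[i]])),
                        col = as.character(as.integer(markers$col[[i]])))
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read or write a cohort manifest
#'
#' The manifest lists one row per cartridge: `cartridge_id`, `group` (cohort
#' label, e.g. tumor type), `material` (`"blood"` or `"liquor"`; defaults to
#' `"blood"` when the column is absent or empty) and `expert_ctc_count` (the
#' platform-reported CTC count, a nonnegative integer).
#'
#' @param path CSV path.
#' @return `read_manifest()`: a tibble; `write_manifest()`: `path`, invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Manifest not found: %s", path), class = "ctcmorph_io_error")
  }
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"cartridge_id" %in% names(m)) {
    abort("Manifest must have a `cartridge_id` column.", class = "ctcmorph_parse_error")
  }
  m$cartridge_id <- as.character(m$cartridge_id)
  if (anyDuplicated(m$cartridge_id)) {
    abort("Manifest cartridge_ids must be unique.", class = "ctcmorph_validation_error")
  }
  if (!"group" %in% names(m)) m$group <- NA_character_
  if (!"material" %in% names(m)) m$material <- "blood"
  m$material[is.na(m$material) | !nzchar(m$material)] <- "blood"
  if (!"expert_ctc_count" %in% names(m)) m$expert_ctc_count <- NA_integer_
  if (any(!is.na(m$expert_ctc_count) & m$expert_ctc_count < 0)) {
    abort("expert_ctc_count must be nonnegative.", class = "ctcmorph_validation_error")
  }
  as_tibble(m[, c("cartridge_id", "group", "material", "expert_ctc_count")])
}

#' @rdname read_manifest
#' @param manifest Tibble as returned by [read_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a cartridge image gallery
#'
#' Reads the per-event, per-channel thumbnail rasters of one or more
#' cartridges into a gallery tibble. The expected layout under `dir` is one
#' subdirectory per cartridge (named by `cartridge_id`), each containing a
#' marker file (`markers.xml` or `markers.csv`) and one grayscale TIFF per
#' event and channel named `<event_id>_<channel>.tif` with channel one of
#' `dapi`, `ck`, `cd45`.
#'
#' Events with a missing or unreadable channel raster are skipped with a
#' warning naming the event; they are never silently dropped. Channel rasters
#' of one event must agree in dimensions. Physical pixel size is taken from
#' the TIFF `x.resolution` tag when present (pixels per um), otherwise from
#' `default_pixel_size`.
#'
#' @param dir Gallery root directory.
#' @param manifest Optional manifest tibble ([read_manifest()]); when `NULL`,
#'   `dir/manifest.csv` is read if present, else all subdirectories are used
#'   with unknown group and blood material.
#' @param default_pixel_size Fallback um/px when the raster carries no
#'   resolution metadata.
#' @return A gallery tibble with columns `event_id`, `cartridge_id`, `group`,
#'   `material`, `row`, `col`, and list-columns `dapi`, `ck`, `cd45` of
#'   [channel_image()] objects. At most one row per marker-file entry.
#' @export
read_gallery <- function(dir, manifest = NULL, default_pixel_size = 0.64) {
  if (!dir.exists(dir)) {
    abort(sprintf("Gallery directory not found: %s", dir), class = "ctcmorph_io_error")
  }
  if (is.null(manifest)) {
    mf <- file.path(dir, "manifest.csv")
    manifest <- if (file.exists(mf)) {
      read_manifest(mf)
    } else {
      ids <- basename(list.dirs(dir, recursive = FALSE))
      tibble(cartridge_id = ids, group = NA_character_, material = "blood",
             expert_ctc_count = NA_integer_)
    }
  }
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    read_cartridge(file.path(dir, manifest$cartridge_id[[i]]),
                   cartridge_id = manifest$cartridge_id[[i]],
                   group = manifest$group[[i]],
                   material = manifest$material[[i]],
                   default_pixel_size = default_pixel_size)
  })
}

read_cartridge <- function(cdir, cartridge_id, group, material, default_pixel_size) {
  if (!dir.exists(cdir)) {
    abort(sprintf("Cartridge directory not found: %s", cdir), class = "ctcmorph_io_error")
  }
  mpath <- file.path(cdir, "markers.xml")
  if (!file.exists(mpath)) mpath <- file.path(cdir, "markers.csv")
  markers <- read_marker_file(mpath)
  purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    eid <- markers$event_id[[i]]
    paths <- file.path(cdir, sprintf("%s_%s.tif", eid, CHANNELS))
    if (!all(file.exists(paths))) {
      missing <- CHANNELS[!file.exists(paths)]
      warn(sprintf("Cartridge %s, event %s: missing %s raster(s); event skipped.",
                   cartridge_id, eid, paste(missing, collapse = "/")))
      return(tibble())
    }
    imgs <- purrr::map(seq_along(CHANNELS), function(k) {
      read_channel_tiff(paths[[k]], CHANNELS[[k]], default_pixel_size)
    })
    names(imgs) <- CHANNELS
    validate_event_channels(imgs$dapi, imgs$ck, imgs$cd45, event_id = eid)
    tibble(event_id = eid, cartridge_id = cartridge_id,
           group = group, material = material,
           row = markers$row[[i]], col = markers$col[[i]],
           dapi = list(imgs$dapi), ck = list(imgs$ck), cd45 = list(imgs$cd45))
  })
}

read_channel_tiff <- function(path, channel, default_pixel_size) {
  px <- tryCatch(tiff::readTIFF(path, info = TRUE), error = function(e) {
    abort(sprintf("Cannot read TIFF %s: %s", path, conditionMessage(e)),
          class = "ctcmorph_io_error")
  })
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse any extra planes
  res <- attr(px, "x.resolution")
  pixel_size <- if (!is.null(res) && is.finite(res) && res > 0) 1 / res else default_pixel_size
  channel_image(unclass(as.matrix(px)), pixel_size = pixel_size, channel = channel)
}

# Canonical feature-table schema: identifiers, per-channel measurements in
# fixed channel order, then classification labels and cascade flags.
feature_table_columns <- function() {
  meas <- c("area", "perimeter", "p2a", "mean_intensity", "positive")
  c("event_id", "cartridge_id", "group", "material",
    paste0(rep(CHANNELS, each = length(meas)), "_", meas),
    "singularity_class", "dapi_singularity_class",
    "size_eligible", "dapi_evaluable", "ncr_eligible", "leukocyte")
}

feature_col_types <- function() {
  readr::cols(
    dapi_positive = readr::col_logical(),
    ck_positive = readr::col_logical(),
    cd45_positive = readr::col_logical(),
    event_id = readr::col_character(),
    cartridge_id = readr::col_character(),
    group = readr::col_character(),
    material = readr::col_character(),
    singularity_class = readr::col_character(),
    dapi_singularity_class = readr::col_character(),
    size_eligible = readr::col_logical(),
    dapi_evaluable = readr::col_logical(),
    ncr_eligible = readr::col_logical(),
    leukocyte = readr::col_logical(),
    .default = readr::col_double()
  )
}

#' Write or read a per-event feature table
#'
#' Serializes event records as CSV in a fixed, documented column order:
#' identifiers (`event_id`, `cartridge_id`, `group`, `material`), then per
#' channel (dapi, ck, cd45) `area` (um^2), `perimeter` (um), `p2a`,
#' `mean_intensity`, `positive`, then `singularity_class`,
#' `dapi_singularity_class` and the cascade flags. Undefined numeric values
#' (e.g. the P2A of an empty channel) are serialized as empty cells and
#' restored as `NA`. Columns absent from `records` are filled with `NA` so
#' that tables written before and after flagging share one schema.
#'
#' @param records Tibble of event records (possibly zero rows).
#' @param path CSV path.
#' @return `write_feature_table()`: `path`, invisibly;
#'   `read_feature_table()`: the records tibble.
#' @export
write_feature_table <- function(records, path) {
  cols <- feature_table_columns()
  records <- as_tibble(records)
  for (cn in setdiff(cols, names(records))) {
    records[[cn]] <- if (cn %in% c("size_eligible", "dapi_evaluable",
                                   "ncr_eligible", "leukocyte")) {
      NA
    } else if (cn %in% c("singularity_class", "dapi_singularity_class",
                         "event_id", "cartridge_id", "group", "material")) {
      NA_character_
    } else NA_real_
  }
  out <- records[, cols]
  # factors (class labels) serialize as their character labels
  out <- dplyr::mutate(out, across(all_of(c("singularity_class", "dapi_singularity_class")),
                                   as.character))
  tryCatch(readr::write_csv(out, path, na = "", progress = FALSE),
           error = function(e) abort(sprintf("Cannot write feature table %s: %s",
                                             path, conditionMessage(e)),
                                     class = "ctcmorph_io_error"))
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Feature table not found: %s", path), class = "ctcmorph_io_error")
  }
  tb <- readr::read_csv(path, col_types = feature_col_types(), na = "",
                        progress = FALSE)
  missing <- setdiff(feature_table_columns(), names(tb))
  if (length(missing)) {
    abort(sprintf("Feature table %s lacks column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "ctcmorph_parse_error")
  }
  tb[, feature_table_columns()]
}

#' Run configuration
#'
#' `ctc_config()` builds the configuration list that parameterizes the
#' pipeline; `write_run_config()`/`read_run_config()` persist it as YAML.
#'
#' @param pixel_size Micrometers per pixel edge (default 0.64).
#' @param p2a_edges Ascending P2A bin edges `(t1, t2, t3)`; defaults
#'   `c(1.5, 2.5, 4)`.
#' @param min_component_px Minimum connected-component size (pixels) kept by
#'   segmentation; default 4.
#' @param median_filter Logical; apply a 3x3 median denoise before
#'   thresholding (default `TRUE`).
#' @param ncr_method `"area"` (default) or `"diameter"`.
#' @param seed Integer seed for synthetic generation.
#' @return A named list of class `ctc_config`.
#' @export
ctc_config <- function(pixel_size = 0.64, p2a_edges = c(1.5, 2.5, 4),
                       min_component_px = 4L, median_filter = TRUE,
                       ncr_method = c("area", "diameter"), seed = 20201004L) {
  ncr_method <- match.arg(ncr_method)
  p2a_bins(p2a_edges)  # validate edges
  structure(list(pixel_size = pixel_size, p2a_edges = as.numeric(p2a_edges),
                 min_component_px = as.integer(min_component_px),
                 median_filter = isTRUE(median_filter),
                 ncr_method = ncr_method, seed = as.integer(seed)),
            class = "ctc_config")
}

#' @rdname ctc_config
#' @param config A `ctc_config` list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname ctc_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config not found: %s", path), class = "ctcmorph_io_error")
  }
  raw <- yaml::read_yaml(path)
  do.call(ctc_config, raw)
}
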