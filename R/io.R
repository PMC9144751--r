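series_schema <- c("plant_id", "treatment", "concentration", "condition",
                   "time_days", "area_px", "mean_R", "mean_G", "mean_B")
trait_schema <- c("plant_id", "treatment", "concentration", "condition",
                  "gc_slope", "auc", "rgr", "fg", "gli")
metabolite_schema <- c("sample_id", "treatment", "concentration", "condition",
                       "metabolite", "class", "value")

check_schema <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop_invalid(what, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Read and write the pipeline's CSV tables
#'
#' Thin wrappers around readr with explicit schema validation: long-format
#' time series, per-plant trait tables and long metabolite tables. All
#' files are UTF-8 with '.' as the decimal mark.
#'
#' @param df Table to write.
#' @param path File path.
#' @return The table (readers), or `path` invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_series_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, series_schema, "series CSV")
  df
}

#' @rdname table_io
#' @export
write_series_csv <- function(df, path) {
  check_schema(df, series_schema, "series CSV")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_trait_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, trait_schema, "trait CSV")
  if ("flag" %in% names(df)) {
    df$flag <- dplyr::coalesce(as.character(df$flag), "")
  }
  df
}

#' @rdname table_io
#' @export
write_trait_csv <- function(df, path) {
  check_schema(df, trait_schema, "trait CSV")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_metabolite_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, metabolite_schema, "metabolite CSV")
  df
}

#' @rdname table_io
#' @export
write_metabolite_csv <- function(df, path) {
  check_schema(df, metabolite_schema, "metabolite CSV")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read and write label masks and scene images
#'
#' Label masks are written as single-channel 16-bit TIFF so integer well
#' labels round-trip losslessly; scene images are written as 8-bit RGB PNG.
#'
#' @param mask Integer label matrix.
#' @param scene A plate scene.
#' @param path,image_path,mask_path File paths.
#' @param layout Layout to attach to a read scene.
#' @param time Acquisition time to attach to a read scene.
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535) stop_invalid("mask", "labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "LZW")
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

#' @rdname image_io
#' @export
write_scene <- function(scene, image_path, mask_path = NULL) {
  png::writePNG(scene$image / 255, image_path)
  if (!is.null(mask_path) && !is.null(scene$truth_mask)) {
    write_mask(scene$truth_mask, mask_path)
  }
  invisible(image_path)
}

#' @rdname image_io
#' @export
read_scene <- function(path, layout, time = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid("scene", sprintf("unsupported image format '%s'", ext))
  )
  if (length(dim(raw)) == 3 && dim(raw)[3] > 3) raw <- raw[, , 1:3]
  img <- array(as.integer(round(raw * 255)), dim = dim(raw))
  structure(list(image = img, truth_mask = NULL, layout = layout, time = time),
            class = "plate_scene")
}

#' Read and write a plate layout as JSON
#'
#' @param layout A [plate_layout()].
#' @param path File path.
#' @name layout_io
NULL

#' @rdname layout_io
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(
      n_rows = layout$n_rows, n_cols = layout$n_cols,
      well_centers = layout$well_centers,
      well_diameter_px = layout$well_diameter_px,
      image_shape = as.list(layout$image_shape),
      mm_per_px = layout$mm_per_px
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname layout_io
#' @export
read_layout_json <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("plate_layout", sprintf("layout file not found: %s", path))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- structure(
    list(
      n_rows = as.integer(j$n_rows), n_cols = as.integer(j$n_cols),
      well_centers = tibble::as_tibble(j$well_centers),
      well_diameter_px = j$well_diameter_px,
      image_shape = c(height = as.integer(j$image_shape$height),
                      width = as.integer(j$image_shape$width)),
      mm_per_px = j$mm_per_px
    ),
    class = "plate_layout"
  )
  validate_plate_layout(lay)
  lay
}
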