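# Image and manifest I/O. Images live in memory as 8-bit RGB arrays with
# (row, col) 0-based coordinates, row 0 at top, regardless of on-disk layout.

#' Construct a fluorescence image object
#'
#' An `fl_image` is an H x W x 3 integer array of 8-bit channel intensities in
#' RGB order, the canonical in-memory representation for every stage of the
#' pipeline. Pixel coordinates are (row, col), 0-based, row 0 at the top.
#'
#' @param pixels Numeric or integer array, `H x W x 3`, values in 0-255.
#' @return An `fl_image` object.
#' @export
fl_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_afpheno("`pixels` must be an H x W x 3 array", "validation_error")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop_afpheno("image must have height >= 1 and width >= 1", "validation_error")
  }
  px <- as.numeric(pixels)
  if (anyNA(px) || any(px < 0) || any(px > 255)) {
    stop_afpheno("channel intensities must lie in [0, 255]", "validation_error")
  }
  out <- array(as.integer(round(pixels)), dim = dim(pixels))
  class(out) <- c("fl_image", "array")
  out
}

#' @export
print.fl_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fl_image> %d x %d px, 3-channel 8-bit RGB (range %d-%d)\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' @rdname fl_image
#' @param x Object to test.
#' @export
is_fl_image <- function(x) inherits(x, "fl_image")

#' Read an autofluorescence image
#'
#' Reads a PNG or TIFF file into the canonical 8-bit, 3-channel RGB
#' representation. 16-bit inputs are rescaled to 8-bit by integer division
#' (v %/% 257); grayscale images are replicated to 3 channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An [fl_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop_afpheno(paste0("image file not found: ", path), "not_found_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = list(x = png::readPNG(path), bits = 8L),
      tif = ,
      tiff = {
        img <- tiff::readTIFF(path, info = TRUE)
        list(x = img, bits = attr(img, "bits.per.sample") %||% 8L)
      },
      stop_afpheno(paste0("unsupported image format '", ext, "': ", path),
                   "format_error")
    ),
    error = function(e) {
      if (inherits(e, "afpheno_error")) stop(e)
      stop_afpheno(paste0("cannot read image ", path, ": ", conditionMessage(e)),
                   "format_error")
    }
  )
  x <- raw$x
  if (raw$bits >= 16L) {
    v <- round(x * 65535)
    v <- v %/% 257
  } else {
    v <- round(x * 255)
  }
  if (length(dim(v)) == 2L) v <- array(v, dim = c(dim(v), 1L))
  nc <- dim(v)[3]
  px <- if (nc == 1L) {
    array(v[, , 1L], dim = c(dim(v)[1:2], 3L))
  } else if (nc >= 3L) {
    v[, , 1:3, drop = FALSE]
  } else {
    stop_afpheno(paste0("image has ", nc, " channels, expected 1, 3 or 4: ", path),
                 "format_error")
  }
  fl_image(px)
}

#' Write an image as lossless 8-bit RGB PNG
#'
#' `load_image(save_image(x, path))` reproduces `x` bit for bit.
#'
#' @param image An [fl_image()].
#' @param path Output path; parent directories are created as needed.
#' @return The path, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(is_fl_image(image))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch(
    {
      png::writePNG(unclass(image) / 255, target = path)
      TRUE
    },
    error = function(e) {
      stop_afpheno(paste0("cannot write image ", path, ": ", conditionMessage(e)),
                   "io_error")
    }
  )
  invisible(path)
}

manifest_columns <- c("plant_id", "genotype", "dag", "stress_onset_day", "image_path")

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `plant_id, genotype, dag, stress_onset_day,
#' image_path` listing one image per plant and day after germination (DAG).
#' `stress_onset_day = 0` encodes "never stressed". Records are returned sorted
#' by `plant_id` then `dag`; duplicate `(plant_id, dag)` pairs are rejected.
#'
#' @param path Path to the manifest CSV.
#' @param root Dataset root that `image_path` entries resolve under; defaults to
#'   the manifest's directory.
#' @param check_paths If `TRUE`, error when a referenced image is missing.
#' @return A tibble with the manifest columns plus a `root` attribute.
#' @export
load_manifest <- function(path, root = dirname(path), check_paths = FALSE) {
  if (!file.exists(path)) {
    stop_afpheno(paste0("manifest not found: ", path), "not_found_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(manifest_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop_afpheno(paste0("manifest is missing column(s): ",
                        paste(missing_cols, collapse = ", ")), "schema_error")
  }
  validate_manifest_tbl(raw, source = path)
}

# Shared validation for manifests read from disk or built in memory.
validate_manifest_tbl <- function(tbl, source = "manifest") {
  parse_int <- function(col) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad) > 0) {
      stop_afpheno(sprintf("%s: column '%s' must be a non-negative integer (row %d: '%s')",
                           source, col, bad[1], tbl[[col]][bad[1]]), "parse_error")
    }
    as.integer(v)
  }
  out <- tibble::tibble(
    plant_id = as.character(tbl$plant_id),
    genotype = as.character(tbl$genotype),
    dag = parse_int("dag"),
    stress_onset_day = parse_int("stress_onset_day"),
    image_path = as.character(tbl$image_path)
  )
  key <- paste(out$plant_id, out$dag, sep = "\r")
  if (anyDuplicated(key) > 0) {
    d <- key[duplicated(key)][1]
    stop_afpheno(paste0(source, ": duplicate (plant_id, dag) record: ",
                        gsub("\r", " / dag ", d)), "validation_error")
  }
  dplyr::arrange(out, .data$plant_id, .data$dag)
}

#' @rdname load_manifest
#' @param manifest A manifest tibble (see [load_manifest()]).
#' @export
save_manifest <- function(manifest, path) {
  manifest <- validate_manifest_tbl(manifest)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(manifest[manifest_columns], path, progress = FALSE)
  invisible(path)
}

# Resolve manifest image paths under a root directory.
resolve_image_path <- function(root, image_path) {
  p <- file.path(root, image_path)
  if (!file.exists(p)) {
    stop_afpheno(paste0("manifest image not found: ", p), "not_found_error")
  }
  p
}
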