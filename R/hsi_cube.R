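#' Hyperspectral reflectance cube
#'
#' Constructs and validates an `hs_cube` object: a calibrated reflectance
#' image cube indexed `(row, col, band)` with ascending band-centre
#' wavelengths in nanometres. The nominal acquisition grid of the
#' intraoperative HSI camera is 500-995 nm at 5 nm spacing (100 bands,
#' 640 x 480 pixels), but any strictly increasing grid is accepted.
#'
#' Reflectance values must be finite and non-negative; values above 1 are
#' allowed because specular glare can exceed the calibration range.
#'
#' @param data numeric array `(rows, cols, bands)` of reflectance values.
#' @param wavelengths_nm strictly increasing numeric vector of band centres,
#'   one per band of `data`.
#' @param acquisition_tag one of `"pre"`, `"intra"`, `"post"`: acquisition
#'   relative to ICG administration (before, at estimated maximum
#'   fluorescence, after the washout observation).
#' @param meta named list of free-form character metadata (e.g. measurement
#'   distance `"50 cm"`, ICG dose `"0.1 mg/kg"`).
#' @return an object of class `hs_cube` with fields `data`,
#'   `wavelengths_nm`, `width`, `height`, `acquisition_tag`, `meta`.
#' @export
hs_cube <- function(data, wavelengths_nm, acquisition_tag = "pre", meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    validation_error("cube data must be a 3-d array (rows, cols, bands)")
  d <- dim(data)
  if (d[3] < 1L) validation_error("cube must have at least one band")
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) != d[3])
    validation_error(sprintf("band count mismatch: %d bands in data, %d wavelengths",
                             d[3], length(wavelengths_nm)))
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0))
    validation_error("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(data)))
    validation_error("reflectance values must be finite")
  if (any(data < 0))
    validation_error("negative reflectance values are not allowed")
  if (!acquisition_tag %in% c("pre", "intra", "post"))
    validation_error("acquisition_tag must be one of 'pre', 'intra', 'post'")
  structure(list(
    data = data,
    wavelengths_nm = wavelengths_nm,
    width = d[2],
    height = d[1],
    acquisition_tag = acquisition_tag,
    meta = meta
  ), class = "hs_cube")
}

#' @export
print.hs_cube <- function(x, ...) {
  cat(sprintf("<hs_cube> %d x %d px, %d bands (%.1f-%.1f nm), tag '%s'\n",
              x$height, x$width, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm), x$acquisition_tag))
  invisible(x)
}

#' Circular region of interest
#'
#' A circular ROI on the image plane, placed at anatomically meaningful
#' positions along the bowel segment and labelled with its perfusion class.
#' Coordinates are 1-based with `x` the column and `y` the row; pixel
#' membership of the disc is `dx^2 + dy^2 <= r^2` evaluated at pixel
#' centres. The interchange JSON annotation format stores 0-based
#' coordinates (see [read_annotations()]), which are shifted on read.
#'
#' @param x,y centre coordinates (1-based, x = column, y = row).
#' @param r radius in pixels (>= 1).
#' @param label free-text label.
#' @param perfusion_class one of `"perfused"`, `"transition"`, `"ischemic"`.
#' @return an object of class `circular_roi`.
#' @export
circular_roi <- function(x, y, r, label = "", perfusion_class = "perfused") {
  if (!is_scalar_number(x) || !is_scalar_number(y) || !is_scalar_number(r))
    validation_error("ROI centre and radius must be finite scalars")
  if (r < 1) validation_error("ROI radius must be >= 1 pixel")
  if (!perfusion_class %in% c("perfused", "transition", "ischemic"))
    validation_error("perfusion_class must be 'perfused', 'transition' or 'ischemic'")
  structure(list(x = x, y = y, r = r, label = label,
                 perfusion_class = perfusion_class),
            class = "circular_roi")
}

roi_check_inside <- function(roi, nrow, ncol, what = "image") {
  if (roi$x - roi$r < 1 || roi$x + roi$r > ncol ||
      roi$y - roi$r < 1 || roi$y + roi$r > nrow)
    validation_error(sprintf(
      "ROI disc (centre %.1f,%.1f radius %.1f) not fully inside %s bounds %d x %d",
      roi$x, roi$y, roi$r, what, nrow, ncol))
  invisible(TRUE)
}

#' Index of the band nearest a wavelength
#'
#' Returns the 1-based index of the band centre closest to `wavelength_nm`;
#' ties are broken toward the lower wavelength.
#'
#' @param cube an [hs_cube()].
#' @param wavelength_nm query wavelength in nm; must lie within the grid
#'   range.
#' @return integer band index (1-based).
#' @export
band_index <- function(cube, wavelength_nm) {
  wl <- cube$wavelengths_nm
  if (wavelength_nm < wl[1] || wavelength_nm > wl[length(wl)])
    range_error(sprintf("wavelength %.1f nm outside grid range [%.1f, %.1f]",
                        wavelength_nm, wl[1], wl[length(wl)]))
  which.min(abs(wl - wavelength_nm))
}

#' Mean reflectance spectrum over a circular ROI
#'
#' Arithmetic per-band mean over all pixels whose centres lie within the
#' ROI disc (inclusive boundary). The ROI must lie fully inside the image.
#'
#' @param cube an [hs_cube()].
#' @param roi a [circular_roi()].
#' @return numeric vector, one mean reflectance per band.
#' @export
extract_mean_spectrum <- function(cube, roi) {
  roi_check_inside(roi, cube$height, cube$width)
  idx <- disc_indices(roi$x, roi$y, roi$r, cube$height, cube$width)
  m <- matrix(cube$data, cube$height * cube$width, length(cube$wavelengths_nm))
  colMeans(m[idx, , drop = FALSE])
}

# ---- ENVI-style I/O ---------------------------------------------------------

# data type codes used: 4 = 32-bit float, 5 = 64-bit float
envi_sizes <- c(`4` = 4L, `5` = 8L)

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", lines[1]))
    format_error(sprintf("'%s' is not an ENVI header (missing ENVI magic)", hdr_path))
  txt <- paste(lines[-1], collapse = "\n")
  # fold { ... } blocks onto single logical entries
  fields <- list()
  pos <- 1L
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt)[[1]]
  if (pat[1] != -1) {
    starts <- pat
    lens <- attr(pat, "match.length")
    for (i in seq_along(starts)) {
      entry <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      key <- trimws(sub("=.*$", "", entry))
      val <- trimws(sub("^[^=]*=", "", entry))
      val <- trimws(gsub("[{}]", "", val))
      fields[[tolower(key)]] <- val
    }
  }
  need <- function(key) {
    v <- fields[[key]]
    if (is.null(v) || !nzchar(v))
      format_error(sprintf("ENVI header '%s' missing required field '%s'", hdr_path, key))
    v
  }
  num <- function(key) {
    v <- suppressWarnings(as.numeric(need(key)))
    if (is.na(v)) format_error(sprintf("ENVI header field '%s' is not numeric", key))
    v
  }
  wl <- fields[["wavelength"]]
  if (is.null(wl)) format_error(sprintf("ENVI header '%s' missing required field 'wavelength'", hdr_path))
  wl <- suppressWarnings(as.numeric(trimws(strsplit(wl, ",")[[1]])))
  if (any(is.na(wl))) format_error("ENVI header field 'wavelength' contains non-numeric entries")
  meta <- list()
  for (key in names(fields)) {
    if (startsWith(key, "meta ")) meta[[substring(key, 6L)]] <- fields[[key]]
  }
  list(
    samples = as.integer(num("samples")),
    lines = as.integer(num("lines")),
    bands = as.integer(num("bands")),
    data_type = as.integer(num("data type")),
    interleave = tolower(need("interleave")),
    byte_order = as.integer(num("byte order")),
    header_offset = if (is.null(fields[["header offset"]])) 0L else as.integer(num("header offset")),
    wavelength = wl,
    acquisition_tag = if (is.null(fields[["acquisition tag"]])) "pre" else fields[["acquisition tag"]],
    meta = meta
  )
}

# reorder a flat vector read in the given interleave into (rows, cols, bands)
interleave_to_array <- function(v, h, w, b, interleave) {
  switch(interleave,
    bsq = aperm(array(v, c(w, h, b)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(w, b, h)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(b, w, h)), c(3L, 2L, 1L)),
    format_error(sprintf("unsupported interleave '%s' (expected bsq, bil or bip)", interleave))
  )
}

array_to_interleave <- function(arr, interleave) {
  switch(interleave,
    bsq = as.vector(aperm(arr, c(2L, 1L, 3L))),
    bil = as.vector(aperm(arr, c(2L, 3L, 1L))),
    bip = as.vector(aperm(arr, c(3L, 2L, 1L))),
    format_error(sprintf("unsupported interleave '%s' (expected bsq, bil or bip)", interleave))
  )
}

read_binary_cube <- function(data_path, h, w, b, data_type, byte_order_big, interleave,
                             offset = 0L) {
  size <- envi_sizes[[as.character(data_type)]]
  if (is.null(size))
    format_error(sprintf("unsupported data type code %d (expected 4 or 5)", data_type))
  n <- as.numeric(h) * w * b
  expected <- n * size + offset
  actual <- file.info(data_path)$size
  if (is.na(actual) || actual != expected)
    shape_error(sprintf(
      "'%s': %s bytes on disk, %s expected for %d x %d x %d (type %d, offset %d)",
      data_path, format(actual, scientific = FALSE),
      format(expected, scientific = FALSE), h, w, b, data_type, offset))
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  v <- readBin(con, "double", n = n, size = size,
               endian = if (byte_order_big) "big" else "little")
  interleave_to_array(v, h, w, b, interleave)
}

#' Read a hyperspectral cube
#'
#' Reads an `hs_cube` either from an ENVI header/binary pair or from a raw
#' float32 cube whose layout is supplied explicitly (the vendor's native
#' binary layout is not standardised, so the raw reader is fully
#' configuration-driven).
#'
#' @param path for `layout = "envi"` the `.hdr` file (or its basename); for
#'   `raw_float32` the binary file itself.
#' @param layout either the string `"envi"` (default) or a list
#'   `list(format = "raw_float32", height =, width =, bands =,
#'   interleave = "bsq"|"bil"|"bip", byte_order = "little"|"big",
#'   wavelengths = <vector> | list(start =, step =))`.
#' @return an [hs_cube()].
#' @export
read_cube <- function(path, layout = "envi") {
  if (identical(layout, "envi") || (is.list(layout) && identical(layout$format, "envi"))) {
    hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
    if (!file.exists(hdr_path)) format_error(sprintf("ENVI header '%s' not found", hdr_path))
    hdr <- parse_envi_header(hdr_path)
    if (length(hdr$wavelength) != hdr$bands)
      format_error(sprintf("ENVI header declares %d bands but lists %d wavelengths",
                           hdr$bands, length(hdr$wavelength)))
    if (any(diff(hdr$wavelength) <= 0))
      validation_error("ENVI wavelengths are not strictly increasing")
    data_path <- sub("\\.hdr$", ".raw", hdr_path)
    if (!file.exists(data_path)) {
      alt <- sub("\\.hdr$", "", hdr_path)
      if (file.exists(alt)) data_path <- alt
      else format_error(sprintf("ENVI data file for '%s' not found", hdr_path))
    }
    arr <- read_binary_cube(data_path, hdr$lines, hdr$samples, hdr$bands,
                            hdr$data_type, hdr$byte_order == 1L, hdr$interleave,
                            hdr$header_offset)
    hs_cube(arr, hdr$wavelength, hdr$acquisition_tag, hdr$meta)
  } else if (is.list(layout) && identical(layout$format, "raw_float32")) {
    for (f in c("height", "width", "bands", "interleave", "byte_order", "wavelengths"))
      if (is.null(layout[[f]]))
        config_error(sprintf("raw_float32 layout missing field '%s'", f))
    wl <- layout$wavelengths
    if (is.list(wl)) wl <- wl$start + wl$step * (seq_len(layout$bands) - 1L)
    wl <- as.numeric(wl)
    if (length(wl) != layout$bands)
      config_error("raw_float32 layout: wavelength count does not match bands")
    if (any(diff(wl) <= 0))
      validation_error("raw_float32 layout wavelengths are not strictly increasing")
    if (!file.exists(path)) format_error(sprintf("raw cube '%s' not found", path))
    arr <- read_binary_cube(path, layout$height, layout$width, layout$bands,
                            4L, identical(layout$byte_order, "big"),
                            tolower(layout$interleave))
    tag <- if (is.null(layout$acquisition_tag)) "pre" else layout$acquisition_tag
    hs_cube(arr, wl, tag, if (is.null(layout$meta)) list() else layout$meta)
  } else {
    config_error("layout must be 'envi' or a raw_float32 layout list")
  }
}

#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' Writes `<path>.hdr` and `<path>.raw`. The default on-disk sample type is
#' 64-bit float (ENVI data type 5) so that [read_cube()] inverts the write
#' bit-exactly; pass `data_type = 4` for interoperable 32-bit output.
#'
#' @param cube an [hs_cube()].
#' @param path output basename (any `.hdr`/`.raw` extension is stripped).
#' @param interleave `"bsq"` (default), `"bil"` or `"bip"`.
#' @param data_type ENVI data type code: 5 (float64, default) or 4 (float32).
#' @return the header path, invisibly.
#' @export
write_cube <- function(cube, path, interleave = "bsq", data_type = 5L) {
  if (!inherits(cube, "hs_cube")) validation_error("cube must be an hs_cube")
  if (!data_type %in% c(4L, 5L)) config_error("data_type must be 4 or 5")
  base <- sub("\\.(hdr|raw)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  raw_path <- paste0(base, ".raw")
  wl <- format(cube$wavelengths_nm, digits = 17, trim = TRUE, scientific = FALSE)
  hdr <- c(
    "ENVI",
    "description = {icgperf hyperspectral reflectance cube}",
    sprintf("samples = %d", cube$width),
    sprintf("lines = %d", cube$height),
    sprintf("bands = %d", length(cube$wavelengths_nm)),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("acquisition tag = %s", cube$acquisition_tag))
  for (key in names(cube$meta))
    hdr <- c(hdr, sprintf("meta %s = {%s}", key, cube$meta[[key]]))
  hdr <- c(hdr, sprintf("wavelength = {%s}", paste(wl, collapse = ", ")))
  ok <- tryCatch({ writeLines(hdr, hdr_path); TRUE }, error = function(e) FALSE)
  if (!ok) abort(sprintf("cannot write ENVI header '%s'", hdr_path), "icgperf_io_error")
  v <- array_to_interleave(cube$data, interleave)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = envi_sizes[[as.character(data_type)]], endian = "little")
  invisible(hdr_path)
}
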