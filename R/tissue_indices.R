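# Configurable band-ratio engine for HSI tissue parameter maps. The camera
# vendor's exact index formulas are proprietary; the shipped defaults are
# documented approximations on the published physiological absorption
# windows and must not be read as validated clinical formulas.

#' Tissue index definition
#'
#' Defines a band-ratio tissue index: per pixel, the mean of a transform of
#' reflectance over a numerator wavelength window is divided by the mean
#' over a denominator window, and the ratio is mapped to the 0-100 display
#' scale by an affine transform with clipping.
#'
#' @param name index name (`"StO2"`, `"NIR_PI"`, `"OHI"`, `"TWI"` or custom).
#' @param numerator_window_nm,denominator_window_nm closed `[lo, hi]`
#'   wavelength windows in nm (`lo < hi`).
#' @param transform `"reflectance"` (ratio of mean R) or `"absorbance"`
#'   (ratio of mean `-log(R)`; reflectance is floored at 1e-6 before the
#'   logarithm).
#' @param gain,offset affine map `clip(gain * ratio + offset, 0, 100)`;
#'   `gain` must be non-zero.
#' @return an object of class `index_definition`.
#' @export
index_definition <- function(name, numerator_window_nm, denominator_window_nm,
                             transform = c("reflectance", "absorbance"),
                             gain = 100, offset = 0) {
  transform <- match.arg(transform)
  for (w in list(numerator_window_nm, denominator_window_nm)) {
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
      validation_error(sprintf("index '%s': window must be [lo, hi] with lo < hi", name))
  }
  if (!is_scalar_number(gain) || gain == 0)
    validation_error(sprintf("index '%s': gain must be a non-zero scalar", name))
  structure(list(name = name,
                 numerator_window_nm = as.numeric(numerator_window_nm),
                 denominator_window_nm = as.numeric(denominator_window_nm),
                 transform = transform, gain = gain, offset = offset),
            class = "index_definition")
}

#' Default tissue index definitions
#'
#' Approximate definitions for the four camera parameters, chosen from
#' standard chromophore absorption windows: StO2 (superficial tissue
#' oxygenation), NIR_PI (near-infrared perfusion index), OHI (organ
#' haemoglobin index) and TWI (tissue water index), each on the 0-100
#' scale. These are non-authoritative stand-ins for the vendor's
#' unpublished formulas; the engine is fully configuration-driven so real
#' definitions can be supplied via [read_index_config()].
#'
#' @return named list of [index_definition()] objects, ordered by name.
#' @export
default_index_definitions <- function() {
  defs <- list(
    index_definition("StO2",   c(570, 590), c(740, 780), "absorbance", gain = 40, offset = 0),
    index_definition("NIR_PI", c(655, 735), c(825, 925), "absorbance", gain = 60, offset = 0),
    index_definition("OHI",    c(530, 590), c(785, 825), "absorbance", gain = 25, offset = 0),
    index_definition("TWI",    c(880, 900), c(955, 980), "absorbance", gain = 70, offset = 0)
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs[order(names(defs))]
}

window_band_mask <- function(cube, window_nm, name) {
  wl <- cube$wavelengths_nm
  if (window_nm[1] < wl[1] || window_nm[2] > wl[length(wl)])
    range_error(sprintf("index '%s': window [%.0f, %.0f] nm outside cube grid [%.0f, %.0f]",
                        name, window_nm[1], window_nm[2], wl[1], wl[length(wl)]))
  mask <- wl >= window_nm[1] & wl <= window_nm[2]
  if (!any(mask))
    range_error(sprintf("index '%s': no band centres inside window [%.0f, %.0f] nm",
                        name, window_nm[1], window_nm[2]))
  mask
}

#' Compute one tissue parameter map
#'
#' Per pixel: `ratio = mean(transform(R), numerator window) /
#' mean(transform(R), denominator window)` and
#' `value = clip(gain * ratio + offset, 0, 100)`. Pixels whose denominator
#' mean has magnitude <= 1e-12 get value 0; their count is attached as the
#' `n_degenerate` attribute and reported via a warning.
#'
#' @param cube an [hs_cube()].
#' @param definition an [index_definition()].
#' @return an object of class `parameter_map` with `values` (matrix in
#'   `[0, 100]`), `name`, `acquisition_tag`.
#' @export
compute_index_map <- function(cube, definition) {
  num_mask <- window_band_mask(cube, definition$numerator_window_nm, definition$name)
  den_mask <- window_band_mask(cube, definition$denominator_window_nm, definition$name)
  b <- length(cube$wavelengths_nm)
  m <- matrix(cube$data, cube$height * cube$width, b)
  if (definition$transform == "absorbance") m <- -log(pmax(m, 1e-6))
  num <- rowMeans(m[, num_mask, drop = FALSE])
  den <- rowMeans(m[, den_mask, drop = FALSE])
  bad <- abs(den) <= 1e-12
  ratio <- ifelse(bad, 0, num / ifelse(bad, 1, den))
  vals <- clip(definition$gain * ratio + definition$offset, 0, 100)
  vals[bad] <- 0
  if (any(bad))
    warning(sprintf("index '%s': %d pixels with degenerate denominator set to 0",
                    definition$name, sum(bad)))
  structure(list(values = matrix(vals, cube$height, cube$width),
                 name = definition$name,
                 acquisition_tag = cube$acquisition_tag,
                 n_degenerate = sum(bad)),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s (%s): %d x %d, range [%.1f, %.1f]\n",
              x$name, x$acquisition_tag, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Compute all configured tissue parameter maps
#'
#' @param cube an [hs_cube()].
#' @param definitions named list of [index_definition()]s (default
#'   [default_index_definitions()]); names must be unique.
#' @return named list of `parameter_map`s, ordered by name.
#' @export
compute_all_indices <- function(cube, definitions = default_index_definitions()) {
  if (length(definitions) == 0L) return(list())
  nms <- vapply(definitions, `[[`, "", "name")
  if (anyDuplicated(nms)) config_error("duplicate index names in definitions")
  out <- lapply(definitions[order(nms)], function(d) compute_index_map(cube, d))
  names(out) <- sort(nms)
  out
}

#' Read tissue index definitions from a YAML config
#'
#' The YAML file holds a list `indices:` of entries mirroring
#' [index_definition()] fields (`name`, `numerator_window_nm`,
#' `denominator_window_nm`, `transform`, `gain`, `offset`).
#'
#' @param path YAML file path.
#' @return named list of [index_definition()]s.
#' @export
read_index_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indices)) config_error(sprintf("'%s' has no 'indices' list", path))
  defs <- lapply(cfg$indices, function(e) {
    index_definition(e$name, unlist(e$numerator_window_nm),
                     unlist(e$denominator_window_nm),
                     if (is.null(e$transform)) "reflectance" else e$transform,
                     if (is.null(e$gain)) 100 else e$gain,
                     if (is.null(e$offset)) 0 else e$offset)
  })
  nms <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(nms)) config_error("duplicate index names in config")
  names(defs) <- nms
  defs
}
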