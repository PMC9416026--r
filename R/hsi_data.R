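#' Spectral axis of a hyperspectral cube
#'
#' A strictly increasing sequence of band-center wavelengths in nanometres.
#' The default axis models a visible/near-infrared snapshot camera covering
#' 450--950 nm in 125 bands on a linear grid.
#'
#' @param wavelengths_nm Numeric vector of band centers (nm), strictly
#'   increasing, all in (300, 1100).
#' @return An object of class `spectral_axis` with fields `wavelengths_nm`
#'   and `band_count`.
#' @examples
#' ax <- default_axis()
#' ax$band_count
#' @export
spectral_axis <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 1L || anyNA(w))
    stop_config("wavelengths_nm must be a non-empty numeric vector")
  if (any(diff(w) <= 0))
    stop_config("wavelengths_nm must be strictly increasing")
  if (any(w <= 300) || any(w >= 1100))
    stop_config("wavelengths_nm must lie in (300, 1100) nm")
  structure(list(wavelengths_nm = w, band_count = length(w)),
            class = "spectral_axis")
}

#' @rdname spectral_axis
#' @param bands Number of bands.
#' @param from,to Wavelength range endpoints (nm).
#' @export
default_axis <- function(bands = 125L, from = 450, to = 950) {
  spectral_axis(seq(from, to, length.out = bands))
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d bands, %.1f-%.1f nm\n",
              x$band_count, min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Hyperspectral reflectance cube
#'
#' The package's central container: a height x width x bands reflectance
#' array with its wavelength axis, an optional binary lesion mask
#' (1 = lesion) and an optional class label.
#'
#' @param data 3-D numeric array, height x width x bands, finite values.
#' @param axis A [spectral_axis()]; its band count must match `dim(data)[3]`.
#' @param mask Optional binary height x width matrix (values in \{0, 1\}).
#' @param label Optional class, `"benign"` or `"malignant"`.
#' @param id Character identifier.
#' @return An object of class `hsi_cube`.
#' @examples
#' cube <- hsi_cube(array(0.5, c(4, 4, 5)), default_axis(5))
#' dim(cube$data)
#' @export
hsi_cube <- function(data, axis, mask = NULL, label = NULL, id = "cube") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_dimension("data must be a 3-D array (height x width x bands)")
  if (!inherits(axis, "spectral_axis")) stop_config("axis must be a spectral_axis")
  d <- dim(data)
  if (d[3] != axis$band_count)
    stop_dimension(sprintf("band dimension %d does not match axis band_count %d",
                           d[3], axis$band_count))
  if (anyNA(data) || any(!is.finite(data)))
    stop_numeric("cube data contains NaN/Inf")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == d[1:2]))
      stop_dimension("mask shape does not match spatial dimensions")
    if (!all(mask %in% c(0, 1)))
      stop_data("mask must contain only 0/1")
    storage.mode(mask) <- "double"
  }
  if (!is.null(label)) label <- match.arg(label, c("benign", "malignant"))
  structure(list(data = data, axis = axis, mask = mask, label = label,
                 id = as.character(id)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> '%s' %dx%dx%d%s%s\n", x$id, d[1], d[2], d[3],
              if (is.null(x$label)) "" else paste0(", label=", x$label),
              if (is.null(x$mask)) "" else
                sprintf(", mask (%.1f%% lesion)", 100 * mean(x$mask))))
  invisible(x)
}

#' White/dark reference calibration
#'
#' Converts raw sensor counts to reflectance by the standard flat-field
#' rule `(raw - dark) / (white - dark)`, where `white` is an acquisition of
#' a reflectance standard and `dark` one with the shutter closed.  Values
#' are clipped to \[0, 2\] to bound specular artifacts.
#'
#' @param raw,white,dark 3-D count arrays of identical shape.
#' @param axis A [spectral_axis()] for the band dimension.
#' @param id Identifier for the resulting cube.
#' @return An [hsi_cube()] of reflectances.
#' @examples
#' ax <- default_axis(4)
#' raw <- array(5, c(2, 2, 4)); dk <- array(1, c(2, 2, 4))
#' wt <- array(9, c(2, 2, 4))
#' range(calibrate(raw, wt, dk, ax)$data)  # (5-1)/(9-1) = 0.5
#' @export
calibrate <- function(raw, white, dark, axis, id = "calibrated") {
  for (nm in c("raw", "white", "dark")) {
    v <- get(nm)
    if (!is.array(v) || length(dim(v)) != 3L)
      stop_dimension(sprintf("%s must be a 3-D array", nm))
  }
  if (!all(dim(raw) == dim(white)) || !all(dim(raw) == dim(dark)))
    stop_dimension("raw, white and dark must share the same shape")
  den <- white - dark
  if (any(den == 0)) {
    idx <- arrayInd(which(den == 0)[1], dim(den))
    stop_hsigan(sprintf(
      "degenerate references: white - dark is zero at voxel (%d, %d, band %d)",
      idx[1], idx[2], idx[3]), "hsigan_degenerate_reference_error")
  }
  refl <- clip((raw - dark) / den, 0, 2)
  hsi_cube(refl, axis, id = id)
}

#' Remove noisy edge bands
#'
#' Drops the first `head` and last `tail` spectral bands, which typically
#' carry high sensor noise at the edges of the camera's range, slicing the
#' wavelength axis consistently.  Defaults reduce a 125-band cube to 116.
#'
#' @param cube An [hsi_cube()].
#' @param head,tail Number of leading/trailing bands to drop.
#' @return The trimmed [hsi_cube()].
#' @examples
#' cube <- hsi_cube(array(0.5, c(2, 2, 125)), default_axis())
#' trim_bands(cube)$axis$band_count  # 116
#' @export
trim_bands <- function(cube, head = 5L, tail = 4L) {
  if (!inherits(cube, "hsi_cube")) stop_config("cube must be an hsi_cube")
  if (!is_count(head) || !is_count(tail) || head < 0 || tail < 0)
    stop_config("head and tail must be nonnegative integers")
  b <- cube$axis$band_count
  if (head + tail >= b)
    stop_hsigan(sprintf("trimming %d + %d bands would empty a %d-band cube",
                        head, tail, b), "hsigan_empty_cube_error")
  keep <- seq.int(head + 1L, b - tail)
  hsi_cube(cube$data[, , keep, drop = FALSE],
           spectral_axis(cube$axis$wavelengths_nm[keep]),
           mask = cube$mask, label = cube$label, id = cube$id)
}

#' Smoothed class label
#'
#' One-hot class encodings make an adversarial discriminator overconfident;
#' the package instead encodes `malignant` as a uniform draw in \[0.7, 1\]
#' and `benign` as a uniform draw in \[0, 0.3\].
#'
#' @param class `"benign"` or `"malignant"` (vectorized).
#' @param rng_seed Optional integer seed for a reproducible draw; when
#'   `NULL` the ambient RNG stream is used.
#' @return An object of class `smoothed_label` with fields `value` and
#'   `class_of_origin` (both vectorized).
#' @examples
#' smooth_label("malignant", rng_seed = 7)$value  # in [0.7, 1]
#' @export
smooth_label <- function(class, rng_seed = NULL) {
  if (length(class) < 1L || !all(class %in% c("benign", "malignant")))
    stop_hsigan("class must be 'benign' or 'malignant'", "hsigan_value_error")
  value <- with_seed(rng_seed, {
    u <- runif(length(class))
    ifelse(class == "malignant", 0.7 + 0.3 * u, 0.3 * u)
  })
  structure(list(value = value, class_of_origin = class),
            class = "smoothed_label")
}

#' @export
print.smoothed_label <- function(x, ...) {
  cat("<smoothed_label>", paste0(sprintf("%s=%.3f", x$class_of_origin, x$value),
                                 collapse = ", "), "\n")
  invisible(x)
}

# numeric smoothed values from a class vector, ambient RNG
smooth_values <- function(classes) smooth_label(classes)$value

#' Pseudo-RGB rendering of a hyperspectral cube
#'
#' Renders the cube as a 3-channel image by picking, per channel, the band
#' nearest the requested red/green/blue wavelength, then min-max scaling
#' the three planes jointly to \[0, 1\].  Requests up to 25 nm beyond the
#' axis ends snap to the nearest edge band (a trimmed axis often starts
#' just above the nominal blue wavelength); farther requests error.
#'
#' @param cube An [hsi_cube()].
#' @param rgb_wavelengths_nm Length-3 numeric, target wavelengths (nm) for
#'   the red, green and blue channels.
#' @return A height x width x 3 array in \[0, 1\].
#' @examples
#' cube <- hsi_cube(array(runif(4 * 4 * 116), c(4, 4, 116)),
#'                  trim_bands(hsi_cube(array(0, c(1, 1, 125)), default_axis()))$axis)
#' dim(pseudo_rgb(cube))
#' @export
pseudo_rgb <- function(cube, rgb_wavelengths_nm = c(630, 532, 465)) {
  if (!inherits(cube, "hsi_cube")) stop_config("cube must be an hsi_cube")
  w <- cube$axis$wavelengths_nm
  req <- as.numeric(rgb_wavelengths_nm)
  if (length(req) != 3L) stop_config("rgb_wavelengths_nm must have length 3")
  tol <- 25
  if (any(req < min(w) - tol) || any(req > max(w) + tol))
    stop_range(sprintf(
      "requested wavelength outside axis range %.1f-%.1f nm (+/- %g nm)",
      min(w), max(w), tol))
  bands <- vapply(req, function(r) which.min(abs(w - r)), integer(1))
  img <- cube$data[, , bands, drop = FALSE]
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  else img[] <- 0.5
  img
}
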