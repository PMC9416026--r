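# Synthetic lesion-phantom generator.
#
# The real clinical material this package targets (dermoscopic
# hyperspectral cubes of benign/malignant skin lesions) is not publicly
# available, so every test and example runs on parametric phantoms with
# known ground truth: a smooth skin background spectrum, a blob-shaped
# lesion whose spectrum follows a class-specific smooth signature,
# per-image illumination jitter, band noise and spatial smoothing.

#' Class spectral-signature model
#'
#' A smooth reflectance curve defined by control points and interpolated
#' with a monotone-segment (Fritsch--Carlson) spline, plus a per-image
#' multiplicative amplitude jitter modelling illumination variability.
#' The default signatures are in-house fixtures chosen to qualitatively
#' resemble dermoscopic tissue spectra (lesions darker than skin below
#' 600 nm, the malignant class with a deeper 540--580 nm trough); they are
#' not digitized from any measured dataset.
#'
#' @param class `"skin"`, `"benign"` or `"malignant"`.
#' @param control_points Two-column matrix-like (wavelength nm,
#'   reflectance in \[0, 1\]), at least 4 rows, wavelengths increasing.
#' @param amplitude_jitter_sd Standard deviation (log scale) of the
#'   mean-one log-normal per-image amplitude factor.
#' @param notes Free-text provenance note.
#' @return An object of class `signature_model`.
#' @examples
#' sig <- default_signatures()$skin
#' head(eval_signature(sig, default_axis(10, 470, 930)))
#' @export
signature_model <- function(class, control_points, amplitude_jitter_sd = 0.05,
                            notes = "") {
  class <- match.arg(class, c("skin", "benign", "malignant"))
  cp <- as.matrix(control_points)
  if (ncol(cp) != 2L || nrow(cp) < 4L)
    stop_config("control_points must have >= 4 rows of (wavelength, reflectance)")
  if (any(diff(cp[, 1]) <= 0))
    stop_config("control wavelengths must be strictly increasing")
  if (any(cp[, 2] < 0) || any(cp[, 2] > 1))
    stop_config("control reflectances must lie in [0, 1]")
  if (amplitude_jitter_sd < 0) stop_config("amplitude_jitter_sd must be >= 0")
  structure(list(class = class, control_points = unname(cp),
                 amplitude_jitter_sd = amplitude_jitter_sd, notes = notes),
            class = "signature_model")
}

#' @rdname signature_model
#' @param amplitude_jitter_sd Passed to each default model.
#' @export
default_signatures <- function(amplitude_jitter_sd = 0.05) {
  cp <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    skin = signature_model("skin", cp(
      440, 0.30, 500, 0.35, 550, 0.38, 600, 0.48,
      650, 0.55, 700, 0.60, 800, 0.65, 960, 0.68),
      amplitude_jitter_sd, "synthetic fixture"),
    benign = signature_model("benign", cp(
      440, 0.18, 500, 0.20, 540, 0.22, 580, 0.24,
      620, 0.32, 700, 0.42, 800, 0.48, 960, 0.52),
      amplitude_jitter_sd, "synthetic fixture"),
    malignant = signature_model("malignant", cp(
      440, 0.15, 500, 0.15, 540, 0.10, 560, 0.09,
      580, 0.11, 620, 0.22, 700, 0.34, 800, 0.42, 960, 0.47),
      amplitude_jitter_sd, "synthetic fixture"))
}

#' Evaluate a signature model on a spectral axis
#'
#' @param model A [signature_model()].
#' @param axis A [spectral_axis()] whose span is covered by the model's
#'   control wavelengths.
#' @return Per-band reflectance vector in \[0, 1\].
#' @examples
#' m <- signature_model("skin", cbind(c(470, 600, 800, 930), rep(0.5, 4)))
#' eval_signature(m, default_axis(5, 470, 930))
#' @export
eval_signature <- function(model, axis) {
  if (!inherits(model, "signature_model"))
    stop_config("model must be a signature_model")
  if (!inherits(axis, "spectral_axis")) stop_config("axis must be a spectral_axis")
  cp <- model$control_points
  w <- axis$wavelengths_nm
  if (min(w) < cp[1, 1] || max(w) > cp[nrow(cp), 1])
    stop_range(sprintf(
      "axis %.1f-%.1f nm extends beyond control span %.1f-%.1f nm",
      min(w), max(w), cp[1, 1], cp[nrow(cp), 1]))
  f <- splinefun(cp[, 1], cp[, 2], method = "monoH.FC")
  f(w)
}

#' Parameters of the lesion-phantom generator
#'
#' Defaults emulate the study conditions the package's networks assume:
#' 50 x 50 pixel cubes with 116 bands on the trimmed ~470--934 nm axis,
#' blob-shaped lesions covering roughly 6--30% of the frame, mild band
#' noise and sub-pixel spatial smoothing.
#'
#' @param height,width,bands Cube geometry.
#' @param axis Optional [spectral_axis()]; default is a linear grid over
#'   the trimmed camera range 470.2--933.9 nm.
#' @param signatures Named list with `skin`, `benign`, `malignant`
#'   [signature_model()]s.
#' @param lesion_radius_range Min/max mean lesion radius in pixels;
#'   default scales with the frame (16--30% of the shorter side).
#' @param lesion_eccentricity_range Min/max ellipse eccentricity in \[0, 1).
#' @param noise_sd Standard deviation of i.i.d. Gaussian band noise.
#' @param smoothness_sigma_px Sigma (pixels) of the spatial Gaussian blur.
#' @param boundary_jitter_sd SD of the low-order Fourier boundary
#'   perturbation of the lesion outline (relative radius units).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `phantom_params`.
#' @examples
#' p <- phantom_params(height = 16, width = 16, bands = 16, seed = 1)
#' p$axis$band_count
#' @export
phantom_params <- function(height = 50L, width = 50L, bands = 116L,
                           axis = NULL, signatures = default_signatures(),
                           lesion_radius_range = NULL,
                           lesion_eccentricity_range = c(0, 0.6),
                           noise_sd = 0.02, smoothness_sigma_px = 0.8,
                           boundary_jitter_sd = 0.06, seed = 1L) {
  if (!is_count(height) || !is_count(width) || !is_count(bands) ||
      height < 4 || width < 4 || bands < 1)
    stop_config("height, width and bands must be positive integers (>= 4 px)")
  if (is.null(axis)) {
    # trimmed 125-band 450-950 nm grid: indices 5..120 span ~470.2-933.9
    lo <- 450 + 5 * 500 / 124; hi <- 450 + 120 * 500 / 124
    axis <- spectral_axis(seq(lo, hi, length.out = bands))
  }
  if (axis$band_count != bands) stop_config("axis band count must equal bands")
  need <- c("skin", "benign", "malignant")
  if (!all(need %in% names(signatures)))
    stop_config("signatures must name skin, benign and malignant models")
  if (is.null(lesion_radius_range))
    lesion_radius_range <- c(0.16, 0.30) * min(height, width)
  rr <- as.numeric(lesion_radius_range)
  if (length(rr) != 2L || rr[1] <= 0 || rr[2] < rr[1])
    stop_config("lesion_radius_range must be increasing and positive")
  if (rr[2] >= min(height, width) / 2)
    stop_config("max lesion radius must be < min(height, width) / 2")
  ee <- as.numeric(lesion_eccentricity_range)
  if (length(ee) != 2L || ee[1] < 0 || ee[2] >= 1 || ee[2] < ee[1])
    stop_config("lesion_eccentricity_range must lie in [0, 1) and increase")
  if (noise_sd < 0 || noise_sd >= 0.5)
    stop_config("noise_sd must lie in [0, 0.5)")
  if (smoothness_sigma_px < 0) stop_config("smoothness_sigma_px must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 bands = as.integer(bands), axis = axis,
                 signatures = signatures[need],
                 lesion_radius_range = rr, lesion_eccentricity_range = ee,
                 noise_sd = noise_sd, smoothness_sigma_px = smoothness_sigma_px,
                 boundary_jitter_sd = boundary_jitter_sd,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# single elliptical blob with Fourier boundary perturbation, drawn from
# the ambient RNG stream
draw_mask <- function(params) {
  h <- params$height; w <- params$width
  for (try in 1:25) {
    cy <- runif(1, h / 3, 2 * h / 3)
    cx <- runif(1, w / 3, 2 * w / 3)
    r <- runif(1, params$lesion_radius_range[1], params$lesion_radius_range[2])
    e <- runif(1, params$lesion_eccentricity_range[1],
               params$lesion_eccentricity_range[2])
    th <- runif(1, 0, 2 * pi)
    amp <- rnorm(3, 0, params$boundary_jitter_sd)  # harmonics k = 2, 3, 4
    ph <- runif(3, 0, 2 * pi)
    a <- r; b <- r * sqrt(1 - e^2)
    dy <- matrix(seq_len(h) - cy, h, w)
    dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    rho <- sqrt(u^2 + v^2)
    phi <- atan2(v, u)
    edge <- 1 + amp[1] * cos(2 * phi + ph[1]) + amp[2] * cos(3 * phi + ph[2]) +
      amp[3] * cos(4 * phi + ph[3])
    mask <- (rho <= edge) * 1
    frac <- mean(mask)
    if (frac >= 0.05 && frac <= 0.6) return(mask)
  }
  stop_numeric("could not draw a lesion mask with fraction in [0.05, 0.6]")
}

#' Draw a lesion mask
#'
#' Samples a single connected, boundary-perturbed elliptical lesion blob
#' centered within the middle third of the frame, with lesion fraction
#' constrained to \[0.05, 0.6\] of the pixels.
#'
#' @param params A [phantom_params()].
#' @param seed Optional seed; `NULL` draws from the ambient RNG.
#' @return Binary height x width matrix (1 = lesion).
#' @examples
#' m <- make_mask(phantom_params(height = 16, width = 16, bands = 4), seed = 1)
#' mean(m)
#' @export
make_mask <- function(params, seed = NULL) {
  if (!inherits(params, "phantom_params"))
    stop_config("params must be phantom_params")
  with_seed(seed, draw_mask(params))
}

# separable Gaussian blur (per band), boundary-renormalized so constants
# are preserved
gaussian_blur_bands <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  smat <- function(n) {
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) dnorm(i - j, sd = sigma))
    K / rowSums(K)
  }
  Kh <- smat(d[1]); Kw <- smat(d[2])
  y <- array(Kh %*% matrix(x, d[1]), d)            # rows
  y <- aperm(array(Kw %*% matrix(aperm(y, c(2, 1, 3)), d[2]),
                   c(d[2], d[1], d[3])), c(2, 1, 3)) # columns
  y
}

#' Generate one labeled phantom cube
#'
#' Pixel spectra follow `mask * lesion_signature + (1 - mask) *
#' skin_signature`, each component scaled by a mean-one log-normal
#' per-image amplitude factor, plus i.i.d. Gaussian band noise, then
#' spatial Gaussian smoothing, clipped to \[0, 1\].  Mask and class label
#' are attached to the result.
#'
#' @param params A [phantom_params()].
#' @param class `"benign"` or `"malignant"`.
#' @param seed Optional seed; `NULL` draws from the ambient RNG.
#' @param id Cube identifier.
#' @return An [hsi_cube()] with mask and label.
#' @examples
#' cube <- make_cube(phantom_params(height = 16, width = 16, bands = 8),
#'                   "malignant", seed = 3)
#' cube$label
#' @export
make_cube <- function(params, class, seed = NULL, id = NULL) {
  if (!inherits(params, "phantom_params"))
    stop_config("params must be phantom_params")
  class <- match.arg(class, c("benign", "malignant"))
  id <- id %||% paste0("phantom_", class)
  with_seed(seed, {
    mask <- draw_mask(params)
    sig_lesion <- eval_signature(params$signatures[[class]], params$axis)
    sig_skin <- eval_signature(params$signatures$skin, params$axis)
    jsd_l <- params$signatures[[class]]$amplitude_jitter_sd
    jsd_s <- params$signatures$skin$amplitude_jitter_sd
    jit_l <- exp(rnorm(1, -jsd_l^2 / 2, jsd_l))  # mean-one log-normal
    jit_s <- exp(rnorm(1, -jsd_s^2 / 2, jsd_s))
    h <- params$height; w <- params$width; b <- params$bands
    x <- outer(mask, jit_l * sig_lesion) + outer(1 - mask, jit_s * sig_skin)
    if (params$noise_sd > 0)
      x <- x + array(rnorm(h * w * b, 0, params$noise_sd), c(h, w, b))
    x <- gaussian_blur_bands(x, params$smoothness_sigma_px)
    hsi_cube(clip(x, 0, 1), params$axis, mask = mask, label = class, id = id)
  })
}

#' Generate a labeled phantom dataset
#'
#' Default counts (40 benign, 36 malignant) emulate a small clinical
#' lesion collection.  Every cube gets its own child seed derived from
#' `params$seed` via [stream_seed()], so the dataset is fully reproducible
#' and individual cubes can be regenerated in isolation.
#'
#' @param params A [phantom_params()].
#' @param n_benign,n_malignant Cube counts per class.
#' @return List of [hsi_cube()] with unique ids.
#' @examples
#' cubes <- make_phantom_dataset(
#'   phantom_params(height = 16, width = 16, bands = 8), 3, 2)
#' table(vapply(cubes, function(x) x$label, character(1)))
#' @export
make_phantom_dataset <- function(params, n_benign = 40L, n_malignant = 36L) {
  if (!is_count(n_benign) || !is_count(n_malignant) ||
      n_benign < 0 || n_malignant < 0)
    stop_config("cube counts must be nonnegative integers")
  classes <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  ids <- c(sprintf("phantom_benign_%04d", seq_len(n_benign)),
           sprintf("phantom_malignant_%04d", seq_len(n_malignant)))
  mapply(function(cls, id) {
    make_cube(params, cls, seed = stream_seed(params$seed, id), id = id)
  }, classes, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
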