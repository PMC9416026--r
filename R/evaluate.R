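# Evaluation suite: feature embeddings, Frechet distance between
# Gaussian moment fits, confusion-matrix metrics, Jensen-Shannon
# spectral divergence, spectral-signature envelopes, and the
# train-on-synthetic / test-on-real fidelity protocol.

#' Embed cubes as feature vectors
#'
#' The default `deterministic_stats` embedding is a fixed-length,
#' bit-reproducible descriptor requiring no pretrained weights: per band,
#' the spatial mean, the spatial standard deviation, and the
#' lesion/background contrast (difference of region means; 0 when no
#' mask or an empty region).  The `cnn` embedding uses the penultimate
#' activations of a fitted [fit_lesion_classifier()].  Frechet distances
#' computed on either embedding are not comparable to published
#' Inception-feature values.
#'
#' @param cubes List of [hsi_cube()] of identical shape.
#' @param extractor `"deterministic_stats"` or `"cnn"`.
#' @param classifier A fitted `lesion_classifier` (required for `cnn`).
#' @return Numeric matrix, one row per cube (3 x bands columns for
#'   `deterministic_stats`).
#' @examples
#' cubes <- make_phantom_dataset(
#'   phantom_params(height = 12, width = 12, bands = 6, seed = 1), 2, 2)
#' dim(embed_cubes(cubes))  # 4 x 18
#' @export
embed_cubes <- function(cubes, extractor = c("deterministic_stats", "cnn"),
                        classifier = NULL) {
  extractor <- match.arg(extractor)
  if (!length(cubes)) stop_data("no cubes to embed")
  d <- dim(cubes[[1]]$data)
  same <- vapply(cubes, function(cb) all(dim(cb$data) == d), logical(1))
  if (!all(same)) stop_dimension("all cubes must share the same shape")
  if (extractor == "cnn") {
    if (is.null(classifier)) stop_usage("cnn embedding requires a classifier")
    return(predict(classifier, cubes, type = "features"))
  }
  B <- d[3]
  t(vapply(cubes, function(cb) {
    m <- matrix(cb$data, d[1] * d[2], B)
    mu <- colMeans(m)
    sd_b <- sqrt(pmax(0, colMeans(m * m) - mu^2))
    contrast <- rep(0, B)
    if (!is.null(cb$mask)) {
      les <- as.vector(cb$mask) == 1
      if (any(les) && any(!les))
        contrast <- colMeans(m[les, , drop = FALSE]) -
          colMeans(m[!les, , drop = FALSE])
    }
    c(mu, sd_b, contrast)
  }, numeric(3L * B)))
}

#' Gaussian moments of an embedded image set
#'
#' @param features Feature matrix (rows = images), e.g. from
#'   [embed_cubes()].
#' @return An object of class `feature_moments`: mean vector `mu`,
#'   covariance `sigma`, count `n`.
#' @export
feature_moments <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop_data("need at least 2 samples for moments")
  structure(list(mu = colMeans(features), sigma = cov(features),
                 n = nrow(features)),
            class = "feature_moments")
}

sym_sqrt <- function(S, tol = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ev <- e$values
  if (min(ev) < -tol)
    stop_numeric(sprintf(
      "matrix is not positive semi-definite (min eigenvalue %.3e)", min(ev)))
  ev <- pmax(ev, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Frechet distance between two Gaussian moment fits
#'
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^(1/2))`, the distance
#' underlying the standard GAN image-quality score.  The matrix square
#' root is taken through the symmetric eigendecomposition of
#' `sqrt(S1) S2 sqrt(S1)`; eigenvalues above `-1e-8` are clipped to zero
#' and anything more negative raises a numerical error.
#'
#' @param a,b `feature_moments` objects (or feature matrices, which are
#'   converted via [feature_moments()]).
#' @return Nonnegative scalar.
#' @examples
#' x <- matrix(rnorm(300), 100)
#' fid(feature_moments(x), feature_moments(x))  # 0
#' @export
fid <- function(a, b) {
  if (!inherits(a, "feature_moments")) a <- feature_moments(a)
  if (!inherits(b, "feature_moments")) b <- feature_moments(b)
  if (length(a$mu) != length(b$mu))
    stop_dimension("feature dimensions differ")
  S1h <- sym_sqrt(a$sigma)
  M <- S1h %*% b$sigma %*% S1h
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_numeric(sprintf(
      "cross-covariance product not PSD (min eigenvalue %.3e)", min(ev)))
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  max(0, sum((a$mu - b$mu)^2) + sum(diag(a$sigma)) + sum(diag(b$sigma)) -
        2 * tr_sqrt)
}

#' Confusion matrix
#'
#' @param tp,tn,fp,fn Nonnegative counts (malignant = positive class).
#' @return An object of class `confusion_matrix`.
#' @examples
#' confusion_matrix(tp = 31, tn = 33, fp = 7, fn = 5)
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != as.integer(counts)))
    stop_config("confusion counts must be nonnegative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param truth,predicted Class vectors (`"benign"`/`"malignant"`).
#' @param positive The positive class.
#' @export
confusion_from_predictions <- function(truth, predicted,
                                       positive = "malignant") {
  if (length(truth) != length(predicted))
    stop_dimension("truth and predicted must have equal length")
  confusion_matrix(tp = sum(truth == positive & predicted == positive),
                   tn = sum(truth != positive & predicted != positive),
                   fp = sum(truth != positive & predicted == positive),
                   fn = sum(truth == positive & predicted != positive))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d tn=%d fp=%d fn=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and the F1 score (harmonic mean of precision and
#' recall), reported in percent rounded to two decimals.  A metric with
#' a zero denominator is returned as `NA` (flagged, not an error).
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `classification_metrics` (named list
#'   `accuracy`, `precision`, `recall`, `f1`, percents).
#' @examples
#' classification_metrics(confusion_matrix(31, 33, 7, 5))
#' @export
classification_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop_config("cm must be a confusion_matrix")
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop_data("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- ratio(cm$tp + cm$tn, total)
  prec <- ratio(cm$tp, cm$tp + cm$fp)
  rec <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
  else 2 * prec * rec / (prec + rec)
  structure(lapply(list(accuracy = acc, precision = prec, recall = rec,
                        f1 = f1),
                   function(v) if (is.na(v)) v else round(100 * v, 2)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-9s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.2f%%", x[[nm]])))
  invisible(x)
}

#' Normalize a spectrum into a distribution
#'
#' Spectral signatures are not probability vectors; before divergence
#' comparison they are L1-normalized to sum to one.
#'
#' @param values Nonnegative per-band vector with positive sum.
#' @return An object of class `spectral_distribution`.
#' @export
spectral_distribution <- function(values) {
  v <- as.numeric(values)
  if (any(v < 0) || !any(v > 0) || anyNA(v))
    stop_data("values must be nonnegative with a positive sum")
  structure(list(values = v / sum(v)), class = "spectral_distribution")
}

#' Jensen-Shannon divergence between spectral distributions
#'
#' `0.5 * sum_i (v_i log2 v_i + w_i log2 w_i - (v_i + w_i)
#' log2((v_i + w_i)/2))` with `0 log 0 := 0`.  Base-2 logarithms bound
#' the divergence by 1 (attained on disjoint supports); it is 0 iff the
#' distributions coincide.
#'
#' @param v,w [spectral_distribution()] objects, or numeric vectors
#'   already summing to one (checked to 1e-9).
#' @return Scalar in \[0, 1\].
#' @examples
#' js_divergence(c(1, 0), c(0, 1))  # 1
#' @export
js_divergence <- function(v, w) {
  vv <- if (inherits(v, "spectral_distribution")) v$values else as.numeric(v)
  ww <- if (inherits(w, "spectral_distribution")) w$values else as.numeric(w)
  if (length(vv) != length(ww)) stop_dimension("distributions differ in length")
  if (any(vv < 0) || any(ww < 0) ||
      abs(sum(vv) - 1) > 1e-9 || abs(sum(ww) - 1) > 1e-9)
    stop_hsigan("inputs must be normalized distributions (sum 1, nonnegative)",
                "hsigan_normalization_error")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  0.5 * sum(xlx(vv) + xlx(ww) - (vv + ww) * log2(pmax((vv + ww) / 2,
                                                      .Machine$double.xmin)) *
              ((vv + ww) > 0))
}

#' Pooled spectral signature of a region
#'
#' Pixel-pooled per-band mean and standard deviation over the lesion or
#' skin region of a (optionally class-filtered) cube set, with
#' mean +/- 2 sd envelopes.
#'
#' @param cubes List of [hsi_cube()] with masks.
#' @param region `"lesion"` or `"skin"`.
#' @param class_filter Optional class (`"benign"`/`"malignant"`) to
#'   restrict the cube set.
#' @return An object of class `spectral_signature`: `wavelengths_nm`,
#'   `mean`, `sd`, `lower`, `upper`, `n_pixels`.
#' @export
spectral_signature <- function(cubes, region = c("lesion", "skin"),
                               class_filter = NULL) {
  region <- match.arg(region)
  if (!is.null(class_filter))
    cubes <- Filter(function(cb) identical(cb$label, class_filter), cubes)
  if (!length(cubes)) stop_data("no cubes selected")
  B <- cubes[[1]]$axis$band_count
  s1 <- numeric(B); s2 <- numeric(B); npx <- 0
  for (cb in cubes) {
    if (is.null(cb$mask))
      stop_data(sprintf("cube '%s' has no mask; region pooling needs one",
                        cb$id))
    sel <- if (region == "lesion") as.vector(cb$mask) == 1
    else as.vector(cb$mask) == 0
    if (!any(sel)) next
    m <- matrix(cb$data, ncol = B)[sel, , drop = FALSE]
    s1 <- s1 + colSums(m)
    s2 <- s2 + colSums(m * m)
    npx <- npx + nrow(m)
  }
  if (npx == 0) stop_data(sprintf("empty %s region selection", region))
  mu <- s1 / npx
  sd_b <- sqrt(pmax(0, s2 / npx - mu^2))
  structure(list(wavelengths_nm = cubes[[1]]$axis$wavelengths_nm, mean = mu,
                 sd = sd_b, lower = mu - 2 * sd_b, upper = mu + 2 * sd_b,
                 n_pixels = npx, region = region,
                 class_filter = class_filter),
            class = "spectral_signature")
}

#' @export
plot.spectral_signature <- function(x, col = "steelblue", add = FALSE, ...) {
  if (!add)
    graphics::plot(x$wavelengths_nm, x$mean, type = "n",
                   ylim = range(c(x$lower, x$upper)),
                   xlab = "wavelength (nm)", ylab = "reflectance", ...)
  graphics::lines(x$wavelengths_nm, x$mean, col = col, lwd = 2)
  graphics::lines(x$wavelengths_nm, x$lower, col = col, lty = 2)
  graphics::lines(x$wavelengths_nm, x$upper, col = col, lty = 2)
  invisible(x)
}

#' Train-on-synthetic / test-on-real fidelity protocol
#'
#' Trains the compact residual classifier exclusively on the synthetic
#' set, then scores it on the real set, which never touches
#' optimization.  Deliberate overfitting of the synthetic set combined
#' with good real-set metrics indicates that the synthetic distribution
#' overlaps the real one.
#'
#' @param synthetic_train,real_test Labeled [hsi_cube()] lists of
#'   identical shape.
#' @param classifier_config A [classifier_config()].
#' @return An object of class `fidelity_protocol`: `train_accuracy`
#'   (percent), `confusion` ([confusion_matrix()] on the real set),
#'   `metrics` ([classification_metrics()]), and the fitted `classifier`.
#' @export
fidelity_protocol <- function(synthetic_train, real_test,
                              classifier_config = classifier_config()) {
  for (set in list(synthetic_train, real_test)) {
    labs <- vapply(set, function(cb) cb$label %||% NA_character_, character(1))
    if (anyNA(labs) || length(unique(labs)) < 2L)
      stop_data("both classes must be labeled in both sets")
  }
  clf <- fit_lesion_classifier(synthetic_train, config = classifier_config)
  pred <- predict(clf, real_test, type = "class")
  truth <- vapply(real_test, function(cb) cb$label, character(1))
  cmat <- confusion_from_predictions(truth, pred)
  structure(list(train_accuracy = clf$train_accuracy, confusion = cmat,
                 metrics = classification_metrics(cmat), classifier = clf),
            class = "fidelity_protocol")
}

#' @export
print.fidelity_protocol <- function(x, ...) {
  cat(sprintf("Fidelity protocol: train accuracy %.2f%% (synthetic)\n",
              x$train_accuracy))
  cat("Real-set performance:\n")
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}
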