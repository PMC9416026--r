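# Generator and discriminator architectures.
#
# The generator maps a standard-normal latent vector (plus, in the
# conditional variant, a smoothed class label) through exactly seven
# transposed-convolution stages -- stages 1-6 followed by batch
# normalization and ReLU, stage 7 by tanh -- to a cube in [-1, 1].
# Spatial sizes grow from 4x4 by stride-2 doublings to the smallest
# power-of-two frame covering the target, with stride-1 filler stages
# keeping the stage count at seven, and a final center crop reaching
# frames (such as 50x50) that stride-2 arithmetic cannot hit exactly.
# The discriminator mirrors this with six convolution stages: leaky ReLU
# (slope 0.2) on the first, batchnorm + leaky ReLU on stages 2-5, and a
# sigmoid on the last, which reduces to a single real/fake score.

#' Generator architecture description
#'
#' @param out_height,out_width Spatial size of generated cubes (4--128).
#' @param out_channels Number of output channels (spectral bands, plus one
#'   when the segmentation-mask channel is enabled).
#' @param latent_dim Length of the latent input vector.
#' @param base_width Channel count of the first 4x4 stage; halved at each
#'   spatial doubling (floor 16).
#' @param conditional If `TRUE` the generator takes a smoothed class label
#'   as an extra scalar input alongside the latent vector.
#' @param equalized Enable the equalized learning-rate reparameterization
#'   ([equalized_scale()]) on all stages.
#' @return An object of class `generator_spec` with a seven-stage plan.
#' @examples
#' gs <- generator_spec(16, 16, 9, base_width = 32)
#' length(gs$stages)  # 7
#' @export
generator_spec <- function(out_height, out_width, out_channels,
                           latent_dim = 100L, base_width = 512L,
                           conditional = FALSE, equalized = FALSE) {
  if (!is_count(out_height) || !is_count(out_width) || !is_count(out_channels) ||
      out_height < 4 || out_width < 4 || out_channels < 1)
    stop_hsigan("output shape must be at least 4x4x1", "hsigan_spec_error")
  if (!is_count(latent_dim) || latent_dim < 1)
    stop_hsigan("latent_dim must be a positive integer", "hsigan_spec_error")
  S <- 4L; n_up <- 0L
  while (S < max(out_height, out_width)) { S <- S * 2L; n_up <- n_up + 1L }
  if (n_up > 5L)
    stop_hsigan(sprintf(
      "spatial path cannot reach %dx%d within 7 stages (max 128)",
      out_height, out_width), "hsigan_spec_error")
  n_fill <- 5L - n_up
  ch <- max(16L, as.integer(base_width))
  stages <- list(list(k = 4L, stride = 1L, pad = 0L, Cout = ch,
                      bn = TRUE, act = "relu"))      # 1x1 -> 4x4
  for (i in seq_len(n_up)) {
    ch <- max(16L, ch %/% 2L)
    stages[[length(stages) + 1L]] <-
      list(k = 4L, stride = 2L, pad = 1L, Cout = ch, bn = TRUE, act = "relu")
  }
  for (i in seq_len(n_fill))
    stages[[length(stages) + 1L]] <-
      list(k = 3L, stride = 1L, pad = 1L, Cout = ch, bn = TRUE, act = "relu")
  stages[[7L]] <- list(k = 3L, stride = 1L, pad = 1L,
                       Cout = as.integer(out_channels), bn = FALSE,
                       act = "tanh")
  # verify stage arithmetic lands on a frame we can crop to the target
  H <- 1L
  for (st in stages) H <- tconv_out_size(H, st$k, st$stride, st$pad)
  if (H < out_height || H < out_width)
    stop_hsigan("stage arithmetic cannot reach the requested output size",
                "hsigan_spec_error")
  structure(list(latent_dim = as.integer(latent_dim),
                 out_height = as.integer(out_height),
                 out_width = as.integer(out_width),
                 out_channels = as.integer(out_channels),
                 conditional = isTRUE(conditional),
                 equalized = isTRUE(equalized),
                 base_width = as.integer(base_width),
                 grid = H, stages = stages),
            class = "generator_spec")
}

#' Discriminator architecture description
#'
#' @param in_height,in_width,in_channels Input cube shape (the label plane
#'   of a conditional discriminator is added internally).
#' @param base_width Channel count of the first stage; doubled at each
#'   spatial halving (cap 512).
#' @param conditional If `TRUE` the smoothed class label is broadcast as
#'   an extra input plane.
#' @param equalized Enable equalized learning-rate scaling.
#' @param leaky_slope Negative slope of the leaky ReLU activations.
#' @return An object of class `discriminator_spec` with a six-stage plan.
#' @examples
#' ds <- discriminator_spec(16, 16, 9)
#' length(ds$stages)  # 6
#' @export
discriminator_spec <- function(in_height, in_width, in_channels,
                               base_width = 64L, conditional = FALSE,
                               equalized = FALSE, leaky_slope = 0.2) {
  if (!is_count(in_height) || !is_count(in_width) || !is_count(in_channels) ||
      in_height < 4 || in_width < 4 || in_channels < 1)
    stop_hsigan("input shape must be at least 4x4x1", "hsigan_spec_error")
  H <- as.integer(in_height); W <- as.integer(in_width)
  ch <- max(8L, as.integer(base_width))
  stages <- list()
  while (max(H, W) > 4L) {
    stages[[length(stages) + 1L]] <-
      list(k = 4L, stride = 2L, pad = 1L, Cout = ch)
    H <- conv_out_size(H, 4L, 2L, 1L); W <- conv_out_size(W, 4L, 2L, 1L)
    ch <- min(512L, ch * 2L)
    if (min(H, W) < 1L)
      stop_hsigan(sprintf(
        "input %dx%d is too elongated for the six-stage plan",
        in_height, in_width), "hsigan_spec_error")
    if (length(stages) > 5L)
      stop_hsigan(sprintf("input %dx%d too large for 6 stages (max 128)",
                          in_height, in_width), "hsigan_spec_error")
  }
  while (length(stages) < 5L)
    stages[[length(stages) + 1L]] <-
      list(k = 3L, stride = 1L, pad = 1L, Cout = ch)
  stages[[6L]] <- list(k = c(H, W), stride = 1L, pad = 0L, Cout = 1L)
  structure(list(in_height = as.integer(in_height),
                 in_width = as.integer(in_width),
                 in_channels = as.integer(in_channels),
                 conditional = isTRUE(conditional),
                 equalized = isTRUE(equalized),
                 base_width = as.integer(base_width),
                 leaky_slope = leaky_slope, stages = stages),
            class = "discriminator_spec")
}

#' Build the generator network
#'
#' @param spec A [generator_spec()].
#' @param rng_seed Seed for reproducible parameter initialization.
#' @return An object of class `hsi_generator`.
#' @examples
#' G <- build_generator(generator_spec(16, 16, 5, base_width = 32), 1)
#' dim(generator_forward(G, sample_latent(2, 100, seed = 1)))
#' @export
build_generator <- function(spec, rng_seed = 1L) {
  if (!inherits(spec, "generator_spec"))
    stop_config("spec must be a generator_spec")
  in_dim <- spec$latent_dim + as.integer(spec$conditional)
  net <- with_seed(rng_seed, {
    net <- list(layer_reshape(c(1L, 1L, in_dim)))
    Cin <- in_dim
    for (i in seq_along(spec$stages)) {
      st <- spec$stages[[i]]
      net[[length(net) + 1L]] <- layer_tconv(Cin, st$Cout, st$k, st$stride,
                                             st$pad, spec$equalized)
      if (st$bn) net[[length(net) + 1L]] <- layer_bn(st$Cout)
      net[[length(net) + 1L]] <- layer_act(st$act)
      Cin <- st$Cout
    }
    net[[length(net) + 1L]] <- layer_crop(spec$out_height, spec$out_width)
    net
  })
  structure(list(spec = spec, net = net, seed = as.integer(rng_seed)),
            class = "hsi_generator")
}

#' Build the discriminator network
#'
#' @param spec A [discriminator_spec()].
#' @param rng_seed Seed for reproducible parameter initialization.
#' @return An object of class `hsi_discriminator`.
#' @examples
#' D <- build_discriminator(discriminator_spec(16, 16, 5), 1)
#' x <- array(runif(16 * 16 * 5 * 2, -1, 1), c(16, 16, 5, 2))
#' discriminator_forward(D, x)
#' @export
build_discriminator <- function(spec, rng_seed = 1L) {
  if (!inherits(spec, "discriminator_spec"))
    stop_config("spec must be a discriminator_spec")
  Cin <- spec$in_channels + as.integer(spec$conditional)
  net <- with_seed(rng_seed, {
    net <- list()
    for (i in seq_along(spec$stages)) {
      st <- spec$stages[[i]]
      net[[length(net) + 1L]] <- layer_conv(Cin, st$Cout, st$k, st$stride,
                                            st$pad, spec$equalized)
      if (i >= 2L && i <= 5L) net[[length(net) + 1L]] <- layer_bn(st$Cout)
      if (i < 6L)
        net[[length(net) + 1L]] <- layer_act("lrelu", spec$leaky_slope)
      Cin <- st$Cout
    }
    net[[length(net) + 1L]] <- layer_flatten()
    net[[length(net) + 1L]] <- layer_act("sigmoid")
    net
  })
  structure(list(spec = spec, net = net, seed = as.integer(rng_seed)),
            class = "hsi_discriminator")
}

#' Draw latent vectors
#'
#' @param n Number of vectors.
#' @param latent_dim Vector length.
#' @param seed Optional seed; `NULL` draws from the ambient RNG.
#' @return `latent_dim` x `n` matrix of i.i.d. standard normals (one
#'   latent vector per column).
#' @examples
#' z <- sample_latent(3, 100, seed = 1)
#' dim(z)
#' @export
sample_latent <- function(n, latent_dim = 100L, seed = NULL) {
  if (!is_count(n) || n < 1 || !is_count(latent_dim) || latent_dim < 1)
    stop_config("n and latent_dim must be positive integers")
  with_seed(seed, matrix(rnorm(latent_dim * n), latent_dim, n))
}

#' Condition a latent input on a smoothed class label
#'
#' Concatenates the smoothed label value as one extra coordinate of the
#' latent vector, the conditioning route of the conditional generator.
#'
#' @param z Latent matrix (`latent_dim` x n) or single vector.
#' @param label A [smooth_label()] object or numeric value(s) in \[0, 1\]
#'   (length 1 or n).
#' @return A (`latent_dim` + 1) x n matrix.
#' @examples
#' z <- sample_latent(2, 10, seed = 1)
#' dim(condition_inject(z, smooth_label(c("benign", "malignant"), 1)))
#' @export
condition_inject <- function(z, label) {
  if (!is.matrix(z)) z <- matrix(z, ncol = 1)
  value <- if (inherits(label, "smoothed_label")) label$value else
    as.numeric(label)
  if (anyNA(value) || any(value < 0) || any(value > 1))
    stop_hsigan("label values must lie in [0, 1]", "hsigan_value_error")
  if (length(value) == 1L) value <- rep(value, ncol(z))
  if (length(value) != ncol(z))
    stop_dimension("one label per latent vector required")
  # affinely mapped to the tanh range so the two class ranges sit
  # symmetrically around zero, matching the scale of the latent input
  rbind(z, 2 * value - 1, deparse.level = 0)
}

#' Run the generator
#'
#' @param G An `hsi_generator` from [build_generator()].
#' @param z Latent matrix, `latent_dim` x n.
#' @param labels Smoothed label values (required iff the spec is
#'   conditional).
#' @param training Use batch statistics (`TRUE`) or running statistics in
#'   the normalization layers.
#' @return Array `out_height` x `out_width` x `out_channels` x n in
#'   \[-1, 1\].
#' @export
generator_forward <- function(G, z, labels = NULL, training = FALSE) {
  if (!inherits(G, "hsi_generator")) stop_config("G must be an hsi_generator")
  if (!is.matrix(z)) z <- matrix(z, ncol = 1)
  if (nrow(z) != G$spec$latent_dim)
    stop_dimension(sprintf("latent vectors must have length %d",
                           G$spec$latent_dim))
  if (G$spec$conditional) {
    if (is.null(labels))
      stop_usage("conditional generator requires smoothed labels")
    z <- condition_inject(z, labels)
  } else if (!is.null(labels)) {
    stop_usage("labels supplied to a non-conditional generator")
  }
  net_forward(G$net, z, training)
}

#' Run the discriminator
#'
#' @param D An `hsi_discriminator` from [build_discriminator()].
#' @param x Input array H x W x C x n scaled to \[-1, 1\] (a single cube
#'   H x W x C is promoted to a batch of one).
#' @param labels Smoothed label values, broadcast as an extra input plane
#'   (required iff the spec is conditional).
#' @param training Batch vs running normalization statistics.
#' @return Numeric vector of n real/fake scores in (0, 1).
#' @export
discriminator_forward <- function(D, x, labels = NULL, training = FALSE) {
  if (!inherits(D, "hsi_discriminator"))
    stop_config("D must be an hsi_discriminator")
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  sp <- D$spec
  if (length(d) != 4L || d[1] != sp$in_height || d[2] != sp$in_width ||
      d[3] != sp$in_channels)
    stop_dimension(sprintf("discriminator expects %dx%dx%d input, got %s",
                           sp$in_height, sp$in_width, sp$in_channels,
                           paste(d, collapse = "x")))
  if (sp$conditional) {
    if (is.null(labels))
      stop_usage("conditional discriminator requires smoothed labels")
    value <- if (inherits(labels, "smoothed_label")) labels$value else
      as.numeric(labels)
    if (length(value) == 1L) value <- rep(value, d[4])
    if (length(value) != d[4]) stop_dimension("one label per sample required")
    # broadcast on the tanh scale, like the image channels
    plane <- array(rep(2 * value - 1, each = d[1] * d[2]),
                   c(d[1], d[2], 1L, d[4]))
    x2 <- array(0, c(d[1], d[2], d[3] + 1L, d[4]))
    x2[, , seq_len(d[3]), ] <- x
    x2[, , d[3] + 1L, ] <- plane
    x <- x2
  } else if (!is.null(labels)) {
    stop_usage("labels supplied to a non-conditional discriminator")
  }
  as.vector(net_forward(D$net, x, training))
}

#' Convert generator output to reflectance cubes
#'
#' Maps tanh-scaled band channels from \[-1, 1\] to reflectance \[0, 1\].
#' When the sample carries one channel more than the spectral axis, that
#' extra channel is the generated segmentation mask: it is binarized at
#' the tanh midpoint (strictly positive -> lesion).
#'
#' @param sample Array H x W x C (one sample) or H x W x C x n.
#' @param axis A [spectral_axis()]; `C` must equal `band_count` or
#'   `band_count + 1`.
#' @param labels Optional class labels (length n) attached to the cubes.
#' @param ids Optional cube identifiers.
#' @return An [hsi_cube()] (single sample) or list of them.
#' @examples
#' ax <- default_axis(4)
#' s <- array(0.2, c(5, 5, 5))  # 4 bands + mask channel
#' cube <- to_reflectance(s, ax)
#' mean(cube$mask)  # 1: mask channel is positive everywhere
#' @export
to_reflectance <- function(sample, axis, labels = NULL, ids = NULL) {
  single <- length(dim(sample)) == 3L
  if (single) dim(sample) <- c(dim(sample), 1L)
  d <- dim(sample)
  b <- axis$band_count
  if (!d[3] %in% c(b, b + 1L))
    stop_dimension(sprintf("sample has %d channels; axis expects %d or %d",
                           d[3], b, b + 1L))
  has_mask <- d[3] == b + 1L
  n <- d[4]
  if (!is.null(labels) && length(labels) == 1L) labels <- rep(labels, n)
  cubes <- lapply(seq_len(n), function(i) {
    refl <- clip((sample[, , seq_len(b), i, drop = FALSE] + 1) / 2, 0, 1)
    dim(refl) <- c(d[1], d[2], b)
    mask <- if (has_mask) (sample[, , b + 1L, i] > 0) * 1 else NULL
    hsi_cube(refl, axis, mask = mask,
             label = if (!is.null(labels)) labels[[i]] else NULL,
             id = if (!is.null(ids)) ids[[i]] else sprintf("generated_%04d", i))
  })
  if (single) cubes[[1]] else cubes
}
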