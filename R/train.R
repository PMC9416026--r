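# Adversarial training.
#
# Two phases: (1) RGB pretraining of an unconditional GAN on 50x50 RGB
# images, (2) conditional hyperspectral training initialized by
# channel-mapped weight transfer.  Stabilization follows small-dataset
# GAN practice: smoothed real/fake targets, a small fraction of swapped
# targets, two time-scale learning rates, equalized learning-rate
# scaling, and L2 weight decay.

#' Training configuration
#'
#' Phase-dependent defaults: RGB pretraining runs 100 epochs at batch 128
#' with Adam learning rate 2e-4 for both networks; hyperspectral
#' conditional training runs 200 epochs at batch 2 with two time-scale
#' rates (generator 1e-4, discriminator 4e-4) and equalized
#' learning-rate scaling enabled.
#'
#' @param phase `"hs_cgan"` or `"rgb_pretrain"`.
#' @param epochs,batch_size,lr_g,lr_d Override the phase defaults.
#' @param beta1,beta2 Adam moment coefficients.
#' @param label_swap_fraction Probability that a real/fake target is
#'   flipped during the discriminator update (in \[0, 0.5)).
#' @param l2_coeff L2 weight-decay coefficient on convolution weights.
#' @param label_smoothing Draw real targets from \[0.7, 1\] and fake
#'   targets from \[0, 0.3\] instead of hard 1/0.
#' @param equalized_lr Enable [equalized_scale()] weight scaling
#'   (default: on for the hyperspectral phase only).
#' @param fid_every Record a deterministic-embedding Frechet distance
#'   against the training set every this many epochs (0 = never).
#' @param mask_aux_loss Add a per-pixel binary cross-entropy term tying
#'   the generated mask channel to the real masks (off by default; the
#'   mask channel is otherwise judged adversarially with the bands).
#' @param mask_aux_weight Weight of that auxiliary term.
#' @param seed Global seed for every stochastic component of the run.
#' @param verbose Print a log line per epoch.
#' @return An object of class `train_config`.
#' @examples
#' train_config("hs_cgan", epochs = 30)$lr_d
#' @export
train_config <- function(phase = c("hs_cgan", "rgb_pretrain"), epochs = NULL,
                         batch_size = NULL, lr_g = NULL, lr_d = NULL,
                         beta1 = 0.5, beta2 = 0.999,
                         label_swap_fraction = 0.05, l2_coeff = 1e-5,
                         label_smoothing = TRUE, equalized_lr = NULL,
                         fid_every = 10L, mask_aux_loss = FALSE,
                         mask_aux_weight = 1, seed = 1L, verbose = FALSE) {
  phase <- match.arg(phase)
  defaults <- if (phase == "rgb_pretrain")
    list(epochs = 100L, batch_size = 128L, lr_g = 2e-4, lr_d = 2e-4,
         equalized_lr = FALSE)
  else
    list(epochs = 200L, batch_size = 2L, lr_g = 1e-4, lr_d = 4e-4,
         equalized_lr = TRUE)
  epochs <- as.integer(epochs %||% defaults$epochs)
  batch_size <- as.integer(batch_size %||% defaults$batch_size)
  lr_g <- lr_g %||% defaults$lr_g
  lr_d <- lr_d %||% defaults$lr_d
  equalized_lr <- equalized_lr %||% defaults$equalized_lr
  if (epochs < 0 || batch_size < 1) stop_config("invalid epochs/batch_size")
  if (lr_g < 0 || lr_d < 0) stop_config("learning rates must be >= 0")
  if (label_swap_fraction < 0 || label_swap_fraction >= 0.5)
    stop_config("label_swap_fraction must lie in [0, 0.5)")
  structure(list(phase = phase, epochs = epochs, batch_size = batch_size,
                 lr_g = lr_g, lr_d = lr_d, beta1 = beta1, beta2 = beta2,
                 label_swap_fraction = label_swap_fraction,
                 l2_coeff = l2_coeff, label_smoothing = isTRUE(label_smoothing),
                 equalized_lr = isTRUE(equalized_lr),
                 fid_every = as.integer(fid_every),
                 mask_aux_loss = isTRUE(mask_aux_loss),
                 mask_aux_weight = mask_aux_weight,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Randomly swap real/fake training targets
#'
#' Flips each target (real <-> fake role, i.e. `t -> 1 - t`) independently
#' with the given probability, a deliberate injection of label noise that
#' slows discriminator dominance.
#'
#' @param targets Numeric vector of targets in \[0, 1\].
#' @param fraction Flip probability (in \[0, 0.5)).
#' @param seed Optional seed; `NULL` draws from the ambient RNG.
#' @return The targets with a random subset flipped.
#' @examples
#' swap_labels(rep(1, 10), fraction = 0.5 - 1e-9, seed = 1)
#' @export
swap_labels <- function(targets, fraction = 0.05, seed = NULL) {
  if (fraction < 0 || fraction >= 0.5)
    stop_config("fraction must lie in [0, 0.5)")
  if (fraction == 0) return(targets)
  with_seed(seed, {
    flip <- runif(length(targets)) < fraction
    targets[flip] <- 1 - targets[flip]
    targets
  })
}

# model step counters live beside the nets; the counter env is attached
# to the first layer so it survives the model list being copied
model_state <- function(model) {
  l1 <- model$net[[1]]
  if (!exists("opt_state", envir = l1, inherits = FALSE)) {
    st <- new.env(parent = emptyenv()); st$t <- 0L
    l1$opt_state <- st
  }
  l1$opt_state
}

draw_targets <- function(n, real, smoothing) {
  if (!smoothing) return(rep(if (real) 1 else 0, n))
  if (real) runif(n, 0.7, 1) else runif(n, 0, 0.3)
}

# inject d(mean BCE)/d(logit) below the final sigmoid and backpropagate
d_backward_bce <- function(D, p, targets) {
  n <- length(p)
  net_backward(D$net[-length(D$net)], matrix((p - targets) / n, 1L, n))
}

#' One adversarial update
#'
#' Performs one discriminator update on a real batch plus a generated
#' batch (smoothed and randomly swapped targets), then one generator
#' update with the non-saturating cross-entropy loss, honoring the two
#' learning rates and L2 weight decay of `config`.  All randomness (latent
#' draws, target smoothing, swaps) comes from the ambient RNG stream.
#'
#' @param G,D Models from [build_generator()] / [build_discriminator()].
#' @param real_batch Array H x W x C x n scaled to \[-1, 1\].
#' @param config A [train_config()].
#' @param real_labels,fake_labels Smoothed condition values for the real
#'   batch and for the generated batch (conditional models only).
#' @param real_masks Optional H x W x n array of \{0,1\} lesion masks,
#'   used only when `config$mask_aux_loss` is enabled and the generator
#'   emits a mask channel.
#' @param update Apply the Adam updates (set `FALSE` to inspect losses
#'   and gradients without changing parameters).
#' @return Named numeric `c(loss_d, loss_g)`; when `update = FALSE` the
#'   per-network gradient lists are attached as attributes `d_grads` and
#'   `g_grads`.
#' @export
adversarial_step <- function(G, D, real_batch, config, real_labels = NULL,
                             fake_labels = NULL, real_masks = NULL,
                             update = TRUE) {
  n <- dim(real_batch)[4]
  latent <- G$spec$latent_dim
  conditional <- isTRUE(G$spec$conditional)
  if (conditional && (is.null(real_labels) || is.null(fake_labels)))
    stop_data("conditional training requires smoothed labels for both batches")
  d_cond <- function(v) if (isTRUE(D$spec$conditional)) v else NULL

  ## --- discriminator update ---
  net_zero_grads(D$net)
  z1 <- matrix(rnorm(latent * n), latent, n)
  fake1 <- generator_forward(G, z1, if (conditional) fake_labels, training = TRUE)
  t_real <- draw_targets(n, TRUE, config$label_smoothing)
  t_fake <- draw_targets(n, FALSE, config$label_smoothing)
  swapped <- swap_labels(c(t_real, t_fake), config$label_swap_fraction)
  t_real <- swapped[seq_len(n)]; t_fake <- swapped[n + seq_len(n)]

  p_real <- discriminator_forward(D, real_batch, d_cond(real_labels),
                                  training = TRUE)
  d_backward_bce(D, p_real, t_real)
  p_fake <- discriminator_forward(D, fake1, d_cond(fake_labels),
                                  training = TRUE)
  d_backward_bce(D, p_fake, t_fake)
  loss_d <- binary_cross_entropy(p_real, t_real) +
    binary_cross_entropy(p_fake, t_fake)
  d_grads <- if (!update) net_grads(D$net)
  if (update) {
    st <- model_state(D); st$t <- st$t + 1L
    adam_step(D$net, config$lr_d, st$t, config$beta1, config$beta2,
              l2 = config$l2_coeff)
  }

  ## --- generator update ---
  net_zero_grads(G$net); net_zero_grads(D$net)
  z2 <- matrix(rnorm(latent * n), latent, n)
  fake2 <- generator_forward(G, z2, if (conditional) fake_labels, training = TRUE)
  p2 <- discriminator_forward(D, fake2, d_cond(fake_labels), training = TRUE)
  gx <- d_backward_bce(D, p2, rep(1, n))  # non-saturating: push toward "real"
  C <- dim(fake2)[3]
  if (isTRUE(D$spec$conditional)) gx <- gx[, , seq_len(C), , drop = FALSE]
  loss_g <- binary_cross_entropy(p2, rep(1, n))
  if (config$mask_aux_loss && !is.null(real_masks) &&
      C == G$spec$out_channels && G$spec$out_channels > 1) {
    # per-pixel BCE of the mask channel (tanh output mapped to (0,1))
    mch <- G$spec$out_channels
    pm <- clip((fake2[, , mch, , drop = FALSE] + 1) / 2, 1e-6, 1 - 1e-6)
    tm <- array(real_masks, dim(pm))
    npx <- length(pm)
    loss_m <- -mean(tm * log(pm) + (1 - tm) * log(1 - pm))
    aux <- config$mask_aux_weight * (pm - tm) / (2 * npx)
    gx[, , mch, ] <- gx[, , mch, ] + array(aux, dim(aux)[c(1, 2, 4)])
    loss_g <- loss_g + config$mask_aux_weight * loss_m
  }
  net_backward(G$net, gx)
  g_grads <- if (!update) net_grads(G$net)
  if (update) {
    st <- model_state(G); st$t <- st$t + 1L
    adam_step(G$net, config$lr_g, st$t, config$beta1, config$beta2,
              l2 = config$l2_coeff)
  }
  if (!is.finite(loss_d) || !is.finite(loss_g))
    stop_numeric("training diverged: non-finite adversarial loss")
  out <- c(loss_d = loss_d, loss_g = loss_g)
  if (!update) {
    attr(out, "d_grads") <- d_grads
    attr(out, "g_grads") <- g_grads
  }
  out
}

# stack cubes into the [-1,1]-scaled training array, with optional mask
# plane as last channel
stack_cubes <- function(cubes, mask_channel) {
  d <- dim(cubes[[1]]$data)
  n <- length(cubes)
  C <- d[3] + as.integer(mask_channel)
  X <- array(0, c(d[1], d[2], C, n))
  for (i in seq_len(n)) {
    if (!all(dim(cubes[[i]]$data) == d))
      stop_dimension("all cubes must share the same shape")
    X[, , seq_len(d[3]), i] <- 2 * cubes[[i]]$data - 1
    if (mask_channel) {
      if (is.null(cubes[[i]]$mask))
        stop_data(sprintf("cube '%s' has no mask but the mask channel is enabled",
                          cubes[[i]]$id))
      X[, , C, i] <- 2 * cubes[[i]]$mask - 1
    }
  }
  X
}

#' Train the conditional hyperspectral GAN
#'
#' The inner training loop: per epoch, class condition values are
#' re-smoothed, the data order reshuffled, and one [adversarial_step()]
#' run per batch.  Every `config$fid_every` epochs a Frechet distance
#' between the deterministic embeddings of the training set and an
#' equally sized generated set is logged (also once before training, as
#' the untrained baseline).
#'
#' @param dataset List of labeled [hsi_cube()] of identical shape.
#' @param config A [train_config()] with `phase = "hs_cgan"`.
#' @param G,D Models from [build_generator()]/[build_discriminator()],
#'   e.g. initialized by [transfer_weights()].
#' @return An object of class `hsi_cgan`; see [hsi_cgan()].
#' @export
train_hs <- function(dataset, config, G, D) {
  if (!inherits(config, "train_config") || config$phase != "hs_cgan")
    stop_usage("config must be a train_config with phase 'hs_cgan'")
  if (!length(dataset)) stop_data("empty dataset")
  conditional <- isTRUE(G$spec$conditional)
  classes <- vapply(dataset, function(cb) cb$label %||% NA_character_,
                    character(1))
  if (conditional && anyNA(classes))
    stop_data("conditional training requires a class label on every cube")
  b <- dataset[[1]]$axis$band_count
  mask_channel <- G$spec$out_channels == b + 1L
  X <- stack_cubes(dataset, mask_channel)
  masks <- if (mask_channel && config$mask_aux_loss)
    vapply(dataset, function(cb) cb$mask, matrix(0, dim(X)[1], dim(X)[2]))
  n <- length(dataset)
  log <- data.frame(epoch = integer(), loss_d = numeric(), loss_g = numeric(),
                    fid = numeric())
  model <- structure(list(G = G, D = D, config = config,
                          axis = dataset[[1]]$axis,
                          mask_channel = mask_channel,
                          classes = sort(unique(classes[!is.na(classes)])),
                          log = NULL),
                     class = "hsi_cgan")
  real_feats <- embed_cubes(dataset, "deterministic_stats")
  eval_fid <- function() {
    fakes <- generate_from_model(model, n,
                                 classes = if (conditional)
                                   sample(classes, n, replace = TRUE))
    fid(feature_moments(real_feats),
        feature_moments(embed_cubes(fakes, "deterministic_stats")))
  }
  with_seed(stream_seed(config$seed, "train_hs"), {
    fid0 <- if (config$fid_every > 0) eval_fid() else NA_real_
    log <- rbind(log, data.frame(epoch = 0L, loss_d = NA_real_,
                                 loss_g = NA_real_, fid = fid0))
    for (ep in seq_len(config$epochs)) {
      cond_values <- if (conditional) smooth_values(classes)
      perm <- sample.int(n)
      steps <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ld <- lg <- 0
      for (idx in steps) {
        fake_classes <- if (conditional)
          sample(model$classes, length(idx), replace = TRUE)
        losses <- adversarial_step(
          G, D, X[, , , idx, drop = FALSE], config,
          real_labels = if (conditional) cond_values[idx],
          fake_labels = if (conditional) smooth_values(fake_classes),
          real_masks = if (!is.null(masks)) masks[, , idx, drop = FALSE])
        ld <- ld + losses[["loss_d"]]; lg <- lg + losses[["loss_g"]]
      }
      fid_e <- if (config$fid_every > 0 && (ep %% config$fid_every == 0 ||
                                            ep == config$epochs))
        eval_fid() else NA_real_
      log <- rbind(log, data.frame(epoch = ep, loss_d = ld / length(steps),
                                   loss_g = lg / length(steps), fid = fid_e))
      if (config$verbose)
        message(sprintf("epoch %3d  loss_d %.4f  loss_g %.4f  fid %s",
                        ep, ld / length(steps), lg / length(steps),
                        if (is.na(fid_e)) "-" else sprintf("%.3f", fid_e)))
    }
  })
  model$log <- log
  model
}

#' Fit a conditional GAN to a hyperspectral lesion dataset
#'
#' The package's main fitting function: infers the cube geometry, builds
#' the seven-stage generator and six-stage discriminator (conditional on
#' the smoothed class label, with a segmentation-mask output channel when
#' the cubes carry masks), and runs the adversarial training loop.
#' Returns a classed model with `print`, `summary`, `plot` (loss and
#' Frechet-distance trajectories) and `simulate` (cube generation)
#' methods.
#'
#' @param dataset List of labeled [hsi_cube()] of identical shape.
#' @param config A [train_config()] (phase `"hs_cgan"`).
#' @param latent_dim Latent vector length.
#' @param base_width_g,base_width_d First-stage channel widths.
#' @param conditional Condition both networks on the smoothed label.
#' @param mask_channel Emit a segmentation-mask channel (default: yes iff
#'   every cube has a mask).
#' @param init Optional `list(G =, D =)` initial models, e.g. from
#'   [transfer_weights()]; overrides the architecture arguments.
#' @return An object of class `hsi_cgan` with elements `G`, `D`,
#'   `config`, `log` (per-epoch losses and Frechet distances), `axis`,
#'   `classes` and `mask_channel`.
#' @examples
#' \donttest{
#' cubes <- make_phantom_dataset(
#'   phantom_params(height = 16, width = 16, bands = 8, seed = 1), 6, 6)
#' fit <- hsi_cgan(cubes, train_config("hs_cgan", epochs = 2, fid_every = 0,
#'                                     seed = 1),
#'                 base_width_g = 32, base_width_d = 16)
#' cubes_new <- simulate(fit, nsim = 2, seed = 1)
#' }
#' @export
hsi_cgan <- function(dataset, config = train_config("hs_cgan"),
                     latent_dim = 100L, base_width_g = 512L,
                     base_width_d = 64L, conditional = TRUE,
                     mask_channel = NULL, init = NULL) {
  if (!length(dataset)) stop_data("empty dataset")
  d <- dim(dataset[[1]]$data)
  if (is.null(mask_channel))
    mask_channel <- all(!vapply(dataset, function(cb) is.null(cb$mask),
                                logical(1)))
  if (is.null(init)) {
    gs <- generator_spec(d[1], d[2], d[3] + as.integer(mask_channel),
                         latent_dim = latent_dim, base_width = base_width_g,
                         conditional = conditional,
                         equalized = config$equalized_lr)
    ds <- discriminator_spec(d[1], d[2], d[3] + as.integer(mask_channel),
                             base_width = base_width_d,
                             conditional = conditional,
                             equalized = config$equalized_lr)
    G <- build_generator(gs, stream_seed(config$seed, "init_g"))
    D <- build_discriminator(ds, stream_seed(config$seed, "init_d"))
  } else {
    G <- init$G; D <- init$D
  }
  train_hs(dataset, config, G, D)
}

#' @export
print.hsi_cgan <- function(x, ...) {
  sp <- x$G$spec
  cat(sprintf(
    "<hsi_cgan> %dx%dx%d generator (latent %d%s%s), trained %d epochs\n",
    sp$out_height, sp$out_width, sp$out_channels, sp$latent_dim,
    if (sp$conditional) ", conditional" else "",
    if (x$mask_channel) ", mask channel" else "",
    max(x$log$epoch)))
  invisible(x)
}

#' @export
summary.hsi_cgan <- function(object, ...) {
  tr <- object$log[object$log$epoch > 0, ]
  fids <- object$log$fid[!is.na(object$log$fid)]
  cat("Conditional hyperspectral GAN\n")
  print(object)
  if (nrow(tr))
    cat(sprintf("final losses: D %.4f, G %.4f\n",
                tr$loss_d[nrow(tr)], tr$loss_g[nrow(tr)]))
  if (length(fids))
    cat(sprintf("Frechet distance (deterministic embedding): %.3f -> %.3f\n",
                fids[1], fids[length(fids)]))
  invisible(object)
}

#' @export
plot.hsi_cgan <- function(x, ...) {
  tr <- x$log[x$log$epoch > 0, ]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tr$epoch, cbind(tr$loss_d, tr$loss_g), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", main = "adversarial losses")
  graphics::legend("topright", c("D", "G"), lty = 1, bty = "n",
                   col = c("firebrick", "steelblue"))
  fl <- x$log[!is.na(x$log$fid), ]
  if (nrow(fl))
    graphics::plot(fl$epoch, fl$fid, type = "b", xlab = "epoch",
                   ylab = "Frechet distance", main = "embedding distance")
  invisible(x)
}

# batched generation shared by simulate() and generate_cubes().  The
# normalization layers use the statistics of the generation batch itself
# (without updating the running averages), the standard choice for
# batch-normalized GAN generators.
generate_from_model <- function(model, n, classes = NULL, seed = NULL,
                                batch = 64L) {
  if (n == 0) return(list())
  G <- model$G
  conditional <- isTRUE(G$spec$conditional)
  with_seed(seed, {
    if (conditional && is.null(classes))
      classes <- sample(model$classes, n, replace = TRUE)
    values <- if (conditional) smooth_values(classes)
    cubes <- vector("list", n)
    for (start in seq(1L, n, by = batch)) {
      idx <- start:min(n, start + batch - 1L)
      z <- matrix(rnorm(G$spec$latent_dim * length(idx)), G$spec$latent_dim)
      out <- generator_forward(G, z, if (conditional) values[idx],
                               training = "batch")
      cubes[idx] <- to_reflectance(
        out, model$axis,
        labels = if (conditional) classes[idx],
        ids = sprintf("generated_%04d", idx))
    }
    cubes
  })
}

#' Simulate cubes from a fitted conditional GAN
#'
#' @param object An `hsi_cgan` fit.
#' @param nsim Number of cubes.
#' @param seed Seed for the latent draws and condition smoothing.
#' @param classes Optional class vector (length `nsim`); default draws
#'   `floor(nsim * class_balance)` benign and the rest malignant.
#' @param class_balance Benign fraction used when `classes` is `NULL`.
#' @param ... Unused.
#' @return List of [hsi_cube()] with condition labels (and masks when the
#'   model has a mask channel).
#' @export
simulate.hsi_cgan <- function(object, nsim = 1L, seed = NULL, classes = NULL,
                              class_balance = 0.5, ...) {
  if (is.null(classes) && isTRUE(object$G$spec$conditional)) {
    nb <- floor(nsim * class_balance)
    classes <- c(rep("benign", nb), rep("malignant", nsim - nb))
  }
  generate_from_model(object, nsim, classes = classes, seed = seed)
}

#' Pretrain an unconditional GAN on RGB images
#'
#' Transfer-learning phase one: a 3-channel version of the same
#' architecture is trained on a folder of RGB images (e.g. dermoscopic
#' photographs) resized to the hyperspectral frame, so that its interior
#' weights can seed the hyperspectral model via [transfer_weights()].
#'
#' @param image_folder Directory of PNG images.
#' @param config A [train_config()] with `phase = "rgb_pretrain"`.
#' @param out_size Target frame, default 50 x 50.
#' @param latent_dim,base_width_g,base_width_d Architecture knobs.
#' @param checkpoint Optional path; when given the result is saved there
#'   with [save_checkpoint()].
#' @return An object of class `hsi_gan_pretrain` (`G`, `D`, `log`).
#' @export
pretrain_rgb <- function(image_folder, config, out_size = c(50L, 50L),
                         latent_dim = 100L, base_width_g = 512L,
                         base_width_d = 64L, checkpoint = NULL) {
  if (!inherits(config, "train_config") || config$phase != "rgb_pretrain")
    stop_usage("config must be a train_config with phase 'rgb_pretrain'")
  files <- sort(list.files(image_folder, pattern = "\\.png$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop_data(sprintf("no PNG images in %s", image_folder))
  h <- out_size[1]; w <- out_size[2]
  X <- array(0, c(h, w, 3L, length(files)))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    img <- img[, , 1:3, drop = FALSE]
    X[, , , i] <- resize_nearest(img, h, w)
  }
  X <- 2 * X - 1
  gs <- generator_spec(h, w, 3L, latent_dim = latent_dim,
                       base_width = base_width_g, conditional = FALSE,
                       equalized = config$equalized_lr)
  ds <- discriminator_spec(h, w, 3L, base_width = base_width_d,
                           conditional = FALSE,
                           equalized = config$equalized_lr)
  G <- build_generator(gs, stream_seed(config$seed, "init_g_rgb"))
  D <- build_discriminator(ds, stream_seed(config$seed, "init_d_rgb"))
  n <- dim(X)[4]
  log <- data.frame(epoch = integer(), loss_d = numeric(), loss_g = numeric())
  with_seed(stream_seed(config$seed, "pretrain_rgb"), {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      steps <- split(perm, ceiling(seq_along(perm) /
                                     min(config$batch_size, n)))
      ld <- lg <- 0
      for (idx in steps) {
        losses <- adversarial_step(G, D, X[, , , idx, drop = FALSE], config)
        ld <- ld + losses[["loss_d"]]; lg <- lg + losses[["loss_g"]]
      }
      log <- rbind(log, data.frame(epoch = ep, loss_d = ld / length(steps),
                                   loss_g = lg / length(steps)))
      if (config$verbose)
        message(sprintf("pretrain epoch %3d  loss_d %.4f  loss_g %.4f",
                        ep, ld / length(steps), lg / length(steps)))
    }
  })
  out <- structure(list(G = G, D = D, config = config, log = log),
                   class = "hsi_gan_pretrain")
  if (!is.null(checkpoint)) save_checkpoint(out, checkpoint)
  out
}

resize_nearest <- function(img, h, w) {
  d <- dim(img)
  ri <- pmin(d[1], pmax(1L, round((seq_len(h) - 0.5) * d[1] / h + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(w) - 0.5) * d[2] / w + 0.5)))
  img[ri, ci, , drop = FALSE]
}

#' Map RGB channels to hyperspectral bands
#'
#' @param axis A [spectral_axis()].
#' @param wavelengths_nm Red, green and blue target wavelengths.
#' @return A `band_map`: list with band indices `red`, `green`, `blue`.
#' @examples
#' default_band_map(default_axis(116, 470, 934))
#' @export
default_band_map <- function(axis, wavelengths_nm = c(red = 630, green = 532,
                                                      blue = 465)) {
  w <- axis$wavelengths_nm
  idx <- vapply(wavelengths_nm, function(t) which.min(abs(w - t)), integer(1))
  bm <- list(red = idx[[1]], green = idx[[2]], blue = idx[[3]])
  if (length(unique(unlist(bm))) != 3L)
    stop_config("band map must select three distinct bands")
  structure(bm, class = "band_map")
}

# copy every parameter of src layer into dst layer, verbatim
copy_layer_params <- function(dst, src, where) {
  for (p in c(dst$pnames, dst$snames)) {
    if (!identical(dim(src[[p]]), dim(dst[[p]])) ||
        length(src[[p]]) != length(dst[[p]]))
      stop_hsigan(sprintf("spec mismatch beyond the channel layers (%s, %s)",
                          where, p), "hsigan_transfer_error")
    dst[[p]] <- src[[p]]
  }
}

#' Transfer RGB-pretrained weights to the hyperspectral model
#'
#' Interior layers are copied verbatim.  In the generator's output stage,
#' the parameter slices that produce the three bands mapped to red, green
#' and blue are copied from the RGB model's corresponding output slices;
#' in the discriminator's input stage, the slices consuming those bands
#' are copied likewise.  All other new-channel parameters (remaining
#' bands, the mask channel, the conditional label input/plane) keep their
#' seeded pseudorandom initialization.
#'
#' @param G_rgb,D_rgb Models from [pretrain_rgb()] (or an
#'   `hsi_gan_pretrain` object passed as `G_rgb` with `D_rgb = NULL`).
#' @param g_spec,d_spec Hyperspectral [generator_spec()] /
#'   [discriminator_spec()]; must match the RGB specs except for the
#'   generator output / discriminator input channel counts (and the
#'   conditional inputs).
#' @param band_map A [default_band_map()] into the target axis.
#' @param rng_seed Seed for the new-channel initialization.
#' @return `list(G =, D =)` hyperspectral models.
#' @export
transfer_weights <- function(G_rgb, D_rgb, g_spec, d_spec, band_map,
                             rng_seed = 1L) {
  if (inherits(G_rgb, "hsi_gan_pretrain")) {
    D_rgb <- G_rgb$D; G_rgb <- G_rgb$G
  }
  if (!inherits(band_map, "band_map")) stop_config("band_map required")
  G_hs <- build_generator(g_spec, stream_seed(rng_seed, "transfer_g"))
  D_hs <- build_discriminator(d_spec, stream_seed(rng_seed, "transfer_d"))
  bands <- c(band_map$red, band_map$green, band_map$blue)

  ## generator: stage-1 tconv consumes the latent (copy latent slices;
  ## a conditional model's label coordinate stays random); stage-7 tconv
  ## produces the channels (copy mapped band slices); rest verbatim
  src_l <- G_rgb$net; dst_l <- G_hs$net
  if (length(src_l) != length(dst_l))
    stop_hsigan("generator stage structure differs", "hsigan_transfer_error")
  tconv_seen <- 0L
  n_tconv <- sum(vapply(dst_l, function(l) l$type == "tconv", logical(1)))
  for (i in seq_along(dst_l)) {
    dst <- dst_l[[i]]; src <- src_l[[i]]
    if (dst$type != src$type)
      stop_hsigan("generator stage structure differs", "hsigan_transfer_error")
    if (!length(dst$pnames) && !length(dst$snames)) next
    if (dst$type == "tconv") {
      tconv_seen <- tconv_seen + 1L
      if (tconv_seen == 1L && dst$Cin != src$Cin) {
        # conditional HS generator: one extra latent coordinate
        if (dst$Cin != src$Cin + 1L || dst$Cout != src$Cout)
          stop_hsigan("generator latent stage mismatch", "hsigan_transfer_error")
        dst$W[, , , seq_len(src$Cin)] <- src$W
        dst$b <- src$b
        next
      }
      if (tconv_seen == n_tconv) {
        if (dst$Cin != src$Cin || src$Cout != 3L)
          stop_hsigan("generator output stage mismatch", "hsigan_transfer_error")
        for (ch in 1:3) dst$W[, , bands[ch], ] <- src$W[, , ch, ]
        dst$b[bands] <- src$b
        next
      }
    }
    copy_layer_params(dst, src, sprintf("generator layer %d", i))
  }

  ## discriminator: stage-1 conv consumes the channels (copy mapped band
  ## slices; the conditional label plane stays random); rest verbatim
  src_l <- D_rgb$net; dst_l <- D_hs$net
  if (length(src_l) != length(dst_l))
    stop_hsigan("discriminator stage structure differs", "hsigan_transfer_error")
  first_conv <- TRUE
  for (i in seq_along(dst_l)) {
    dst <- dst_l[[i]]; src <- src_l[[i]]
    if (dst$type != src$type)
      stop_hsigan("discriminator stage structure differs",
                  "hsigan_transfer_error")
    if (!length(dst$pnames) && !length(dst$snames)) next
    if (dst$type == "conv" && first_conv) {
      first_conv <- FALSE
      if (src$Cin != 3L + as.integer(isTRUE(D_rgb$spec$conditional)) ||
          dst$Cout != src$Cout)
        stop_hsigan("discriminator input stage mismatch",
                    "hsigan_transfer_error")
      for (ch in 1:3) dst$W[, , bands[ch], ] <- src$W[, , ch, ]
      dst$b <- src$b
      next
    }
    copy_layer_params(dst, src, sprintf("discriminator layer %d", i))
  }
  list(G = G_hs, D = D_hs)
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single-file archive holding a versioned magic
#' string, the architecture specs, and a flat named list of parameter
#' arrays; [load_checkpoint()] rebuilds the networks and restores the
#' parameters.
#'
#' @param object An `hsi_cgan`, `hsi_gan_pretrain`, `hsi_generator` or
#'   `lesion_classifier` object.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored object.
#' @export
save_checkpoint <- function(object, path) {
  payload <- if (inherits(object, "hsi_cgan")) {
    list(kind = "hsi_cgan", g_spec = object$G$spec, d_spec = object$D$spec,
         params_g = net_params(object$G$net), params_d = net_params(object$D$net),
         config = object$config, log = object$log, axis = object$axis,
         classes = object$classes, mask_channel = object$mask_channel)
  } else if (inherits(object, "hsi_gan_pretrain")) {
    list(kind = "hsi_gan_pretrain", g_spec = object$G$spec,
         d_spec = object$D$spec, params_g = net_params(object$G$net),
         params_d = net_params(object$D$net), config = object$config,
         log = object$log)
  } else if (inherits(object, "hsi_generator")) {
    list(kind = "hsi_generator", g_spec = object$spec,
         params_g = net_params(object$net))
  } else if (inherits(object, "lesion_classifier")) {
    list(kind = "lesion_classifier", config = object$config,
         input_dim = object$input_dim, params = net_params(object$net),
         classes = object$classes, history = object$history,
         train_accuracy = object$train_accuracy)
  } else stop_config("unsupported object for checkpointing")
  saveRDS(c(list(magic = "hsigan-checkpoint-v1"), payload), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_hsigan(sprintf("%s: no such checkpoint", path),
                                      "hsigan_checkpoint_error")
  ck <- tryCatch(readRDS(path), error = function(e)
    stop_hsigan(sprintf("%s: unreadable checkpoint (%s)", path,
                        conditionMessage(e)), "hsigan_checkpoint_error"))
  if (!is.list(ck) || !identical(ck$magic, "hsigan-checkpoint-v1"))
    stop_hsigan(sprintf("%s: not an hsigan checkpoint", path),
                "hsigan_checkpoint_error")
  switch(ck$kind,
    hsi_cgan = {
      G <- build_generator(ck$g_spec, 1L)
      D <- build_discriminator(ck$d_spec, 1L)
      net_set_params(G$net, ck$params_g)
      net_set_params(D$net, ck$params_d)
      structure(list(G = G, D = D, config = ck$config, axis = ck$axis,
                     mask_channel = ck$mask_channel, classes = ck$classes,
                     log = ck$log),
                class = "hsi_cgan")
    },
    hsi_gan_pretrain = {
      G <- build_generator(ck$g_spec, 1L)
      D <- build_discriminator(ck$d_spec, 1L)
      net_set_params(G$net, ck$params_g)
      net_set_params(D$net, ck$params_d)
      structure(list(G = G, D = D, config = ck$config, log = ck$log),
                class = "hsi_gan_pretrain")
    },
    hsi_generator = {
      G <- build_generator(ck$g_spec, 1L)
      net_set_params(G$net, ck$params_g)
      G
    },
    lesion_classifier = rebuild_classifier(ck),
    stop_hsigan(sprintf("%s: unknown checkpoint kind '%s'", path, ck$kind),
                "hsigan_checkpoint_error"))
}
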