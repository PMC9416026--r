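# Toy two-parameter networks with closed-form gradients, plus the
# stabilization tricks of the adversarial recipe.

toy_gan <- function(theta_g = 0.6, a = 0.8, c = -0.2) {
  Gnet <- list(hsigan:::layer_dense(1, 1), hsigan:::layer_reshape(c(1, 1, 1)))
  Gnet[[1]]$W <- matrix(theta_g); Gnet[[1]]$b <- 0
  G <- structure(list(spec = list(latent_dim = 1L, conditional = FALSE,
                                  out_channels = 1L),
                      net = Gnet), class = "hsi_generator")
  Dnet <- list(hsigan:::layer_conv(1, 1, 1), hsigan:::layer_flatten(),
               hsigan:::layer_act("sigmoid"))
  Dnet[[1]]$W <- array(a, c(1, 1, 1, 1)); Dnet[[1]]$b <- c
  D <- structure(list(spec = list(in_height = 1L, in_width = 1L,
                                  in_channels = 1L, conditional = FALSE),
                      net = Dnet), class = "hsi_discriminator")
  list(G = G, D = D)
}

test_that("the adversarial step reduces to the textbook update", {
  # no smoothing, no swapping: gradients must equal the hand-derived
  # BCE/minimax expressions for a scalar G(z) = theta z, D(x) = sigm(ax+c)
  toy <- toy_gan()
  cfg <- train_config("hs_cgan", label_smoothing = FALSE,
                      label_swap_fraction = 0, epochs = 1)
  x_real <- array(0.5, c(1, 1, 1, 1))
  set.seed(123)
  losses <- adversarial_step(toy$G, toy$D, x_real, cfg, update = FALSE)

  # replay the same latent draws
  set.seed(123)
  z1 <- rnorm(1); z2 <- rnorm(1)
  sigm <- function(t) 1 / (1 + exp(-t))
  a <- 0.8; cc <- -0.2; th <- 0.6
  p_r <- sigm(a * 0.5 + cc)
  xf1 <- th * z1
  p_f <- sigm(a * xf1 + cc)
  expect_equal(unname(losses["loss_d"]), -log(p_r) - log(1 - p_f),
               tolerance = 1e-10)
  dW_d <- (p_r - 1) * 0.5 + p_f * xf1
  db_d <- (p_r - 1) + p_f
  dg <- attr(losses, "d_grads")
  expect_equal(as.vector(dg[["L001.W"]]), dW_d, tolerance = 1e-10)
  expect_equal(as.vector(dg[["L001.b"]]), db_d, tolerance = 1e-10)

  xf2 <- th * z2
  p2 <- sigm(a * xf2 + cc)
  expect_equal(unname(losses["loss_g"]), -log(p2), tolerance = 1e-10)
  gg <- attr(losses, "g_grads")
  expect_equal(as.vector(gg[["L001.W"]]), (p2 - 1) * a * z2,
               tolerance = 1e-10)
})

test_that("label swapping flips the configured fraction", {
  t0 <- runif(1000)
  expect_identical(swap_labels(t0, 0), t0)
  expect_identical(swap_labels(t0, 0.05, seed = 4),
                   swap_labels(t0, 0.05, seed = 4))
  big <- rep(1, 100000)
  sw <- swap_labels(big, 0.05, seed = 9)
  flipped <- sum(sw == 0)
  expect_lt(abs(flipped - 5000), 3 * sqrt(100000 * 0.05 * 0.95))
  expect_error(swap_labels(t0, 0.6), class = "hsigan_config_error")
})

test_that("one adversarial step moves both networks unless rates are zero", {
  set.seed(20)
  G <- build_generator(generator_spec(8, 8, 3, base_width = 16), 1)
  D <- build_discriminator(discriminator_spec(8, 8, 3, base_width = 8), 2)
  real <- array(runif(8 * 8 * 3 * 4, -1, 1), c(8, 8, 3, 4))
  pg0 <- hsigan:::net_params(G$net, include_state = FALSE)
  pd0 <- hsigan:::net_params(D$net, include_state = FALSE)

  frozen <- train_config("hs_cgan", lr_g = 0, lr_d = 0, equalized_lr = FALSE)
  losses <- adversarial_step(G, D, real, frozen)
  expect_true(all(is.finite(losses)))
  expect_identical(hsigan:::net_params(G$net, include_state = FALSE), pg0)
  expect_identical(hsigan:::net_params(D$net, include_state = FALSE), pd0)

  cfg <- train_config("hs_cgan", equalized_lr = FALSE)
  adversarial_step(G, D, real, cfg)
  expect_false(identical(hsigan:::net_params(G$net, include_state = FALSE),
                         pg0))
  expect_false(identical(hsigan:::net_params(D$net, include_state = FALSE),
                         pd0))
})

test_that("an untrained discriminator scores at the random-guessing level", {
  set.seed(31)
  G <- build_generator(generator_spec(8, 8, 3, base_width = 16), 5)
  D <- build_discriminator(discriminator_spec(8, 8, 3, base_width = 8), 6)
  real <- array(runif(8 * 8 * 3 * 16, -1, 1), c(8, 8, 3, 16))
  cfg <- train_config("hs_cgan", lr_g = 0, lr_d = 0,
                      label_smoothing = FALSE, label_swap_fraction = 0)
  losses <- adversarial_step(G, D, real, cfg)
  # -2 ln(0.5) = 1.386 per real/fake pair at D == 1/2
  expect_lt(abs(losses[["loss_d"]] - 2 * log(2)), 0.35)
})

test_that("two time-scale updates scale with the configured rates", {
  set.seed(77)
  G <- build_generator(generator_spec(8, 8, 3, base_width = 16), 3)
  D <- build_discriminator(discriminator_spec(8, 8, 3, base_width = 8), 4)
  real <- array(runif(8 * 8 * 3 * 4, -1, 1), c(8, 8, 3, 4))
  pg0 <- hsigan:::net_params(G$net, include_state = FALSE)
  pd0 <- hsigan:::net_params(D$net, include_state = FALSE)
  cfg <- train_config("hs_cgan", lr_g = 1e-4, lr_d = 4e-4)
  set.seed(5); adversarial_step(G, D, real, cfg)
  dG <- mean(abs(unlist(hsigan:::net_params(G$net, include_state = FALSE)) -
                   unlist(pg0)))
  dD <- mean(abs(unlist(hsigan:::net_params(D$net, include_state = FALSE)) -
                   unlist(pd0)))
  # Adam's first step magnitude is ~lr per coordinate: ratio tracks lr_d/lr_g
  expect_gt(dD / dG, 2.5)
  expect_lt(dD / dG, 6)
})

write_blob_pngs <- function(dir, n = 12) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(99)
  for (i in seq_len(n)) {
    img <- array(runif(1, 0.3, 0.9), c(50, 50, 3))
    cy <- runif(1, 15, 35); cx <- runif(1, 15, 35); r <- runif(1, 6, 12)
    blob <- (outer(1:50 - cy, rep(1, 50))^2 +
               outer(rep(1, 50), 1:50 - cx)^2) <= r^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[blob] <- runif(1, 0, 0.4)
      img[, , ch] <- plane
    }
    png::writePNG(img, file.path(dir, sprintf("blob_%02d.png", i)))
  }
  dir
}

test_that("RGB pretraining produces a working 3-channel generator", {
  dir <- write_blob_pngs(file.path(tempdir(), "rgb_blobs"))
  cfg <- train_config("rgb_pretrain", epochs = 2, batch_size = 6, seed = 3)
  ck <- file.path(tempdir(), "rgb.ckpt")
  pre <- pretrain_rgb(dir, cfg, base_width_g = 16, base_width_d = 8,
                      checkpoint = ck)
  expect_s3_class(pre, "hsi_gan_pretrain")
  out <- generator_forward(pre$G, sample_latent(2, 100, seed = 1))
  expect_equal(dim(out), c(50, 50, 3, 2))
  expect_true(all(out >= -1 & out <= 1))
  restored <- load_checkpoint(ck)
  expect_equal(generator_forward(restored$G, sample_latent(2, 100, seed = 1)),
               out)

  expect_error(pretrain_rgb(dir, train_config("hs_cgan")),
               class = "hsigan_usage_error")
  expect_error(pretrain_rgb(file.path(tempdir(), "no_such_dir_x"), cfg),
               class = "hsigan_data_error")

  pre2 <- pretrain_rgb(dir, cfg, base_width_g = 16, base_width_d = 8)
  expect_identical(pre$log, pre2$log)
})

test_that("weight transfer copies interiors verbatim and maps RGB slices", {
  set.seed(50)
  g_rgb_spec <- generator_spec(16, 16, 3, base_width = 16)
  d_rgb_spec <- discriminator_spec(16, 16, 3, base_width = 8)
  G_rgb <- build_generator(g_rgb_spec, 7)
  D_rgb <- build_discriminator(d_rgb_spec, 8)

  ax <- spectral_axis(seq(470, 934, length.out = 8))
  bm <- default_band_map(ax)
  g_hs_spec <- generator_spec(16, 16, 9, base_width = 16, conditional = TRUE)
  d_hs_spec <- discriminator_spec(16, 16, 9, base_width = 8,
                                  conditional = TRUE)
  hs <- transfer_weights(G_rgb, D_rgb, g_hs_spec, d_hs_spec, bm, rng_seed = 1)

  tg_rgb <- Filter(function(l) l$type == "tconv", G_rgb$net)
  tg_hs <- Filter(function(l) l$type == "tconv", hs$G$net)
  for (i in 2:6) expect_identical(tg_hs[[i]]$W, tg_rgb[[i]]$W)
  expect_identical(tg_hs[[1]]$W[, , , 1:100], tg_rgb[[1]]$W)
  bands <- c(bm$red, bm$green, bm$blue)
  for (ch in 1:3)
    expect_identical(tg_hs[[7]]$W[, , bands[ch], ], tg_rgb[[7]]$W[, , ch, ])

  cd_rgb <- Filter(function(l) l$type == "conv", D_rgb$net)
  cd_hs <- Filter(function(l) l$type == "conv", hs$D$net)
  for (i in 2:6) expect_identical(cd_hs[[i]]$W, cd_rgb[[i]]$W)
  for (ch in 1:3)
    expect_identical(cd_hs[[1]]$W[, , bands[ch], ], cd_rgb[[1]]$W[, , ch, ])

  # different transfer seeds touch only the non-mapped parameters
  hs2 <- transfer_weights(G_rgb, D_rgb, g_hs_spec, d_hs_spec, bm,
                          rng_seed = 2)
  tg_hs2 <- Filter(function(l) l$type == "tconv", hs2$G$net)
  for (ch in 1:3)
    expect_identical(tg_hs2[[7]]$W[, , bands[ch], ],
                     tg_hs[[7]]$W[, , bands[ch], ])
  other <- setdiff(seq_len(9), bands)
  expect_false(identical(tg_hs2[[7]]$W[, , other, ],
                         tg_hs[[7]]$W[, , other, ]))

  # interior mismatch is a transfer error
  bad_spec <- generator_spec(16, 16, 9, base_width = 32, conditional = TRUE)
  expect_error(transfer_weights(G_rgb, D_rgb, bad_spec, d_hs_spec, bm, 1),
               class = "hsigan_transfer_error")
})

test_that("conditional training demands labels and masks", {
  p <- tiny_params(bands = 4, height = 8, width = 8)
  cubes <- make_phantom_dataset(p, 2, 2)
  cubes[[1]]$label <- NULL
  cfg <- train_config("hs_cgan", epochs = 1, fid_every = 0)
  expect_error(hsi_cgan(cubes, cfg, base_width_g = 16, base_width_d = 8),
               class = "hsigan_data_error")
  expect_error(train_hs(list(), cfg, NULL, NULL),
               class = "hsigan_data_error")
})

test_that("short conditional training runs are reproducible and logged", {
  p <- tiny_params(bands = 4, height = 8, width = 8)
  cubes <- make_phantom_dataset(p, 3, 3)
  cfg <- train_config("hs_cgan", epochs = 2, fid_every = 1, seed = 6)
  f1 <- hsi_cgan(cubes, cfg, base_width_g = 16, base_width_d = 8)
  f2 <- hsi_cgan(cubes, cfg, base_width_g = 16, base_width_d = 8)
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 3) # epoch 0 baseline + 2 epochs
  expect_true(all(is.finite(f1$log$fid)))
  # batch size 2 honored: ceil(6/2) optimizer steps per epoch
  expect_identical(simulate(f1, 3, seed = 1), simulate(f2, 3, seed = 1))
})
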