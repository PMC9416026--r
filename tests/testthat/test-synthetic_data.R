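test_that("signature evaluation interpolates the control points", {
  ax <- default_axis(9, 470, 930)
  flat <- signature_model("skin", cbind(c(460, 600, 800, 940), 0.5))
  expect_equal(eval_signature(flat, ax), rep(0.5, 9))

  cp <- cbind(c(460, 600, 800, 940), c(0.2, 0.4, 0.3, 0.6))
  m <- signature_model("benign", cp)
  at_controls <- eval_signature(m, spectral_axis(cp[, 1]))
  expect_equal(at_controls, cp[, 2])

  # monotone spline degenerates to the chord on a two-segment straight line
  lin <- signature_model("skin", cbind(c(470, 700, 800, 930),
                                       c(0.2, 0.4, 0.48695652173913, 0.6)))
  got <- eval_signature(lin, spectral_axis(585))
  expect_equal(got, 0.2 + (585 - 470) / (930 - 470) * 0.4, tolerance = 1e-6)

  expect_error(eval_signature(m, default_axis(5, 400, 900)),
               class = "hsigan_range_error")
})

test_that("signature models validate their control points", {
  expect_error(signature_model("skin", cbind(c(1, 2, 3), c(0, 0, 0))),
               class = "hsigan_config_error")
  expect_error(signature_model("skin", cbind(c(500, 480, 600, 700), 0.5)),
               class = "hsigan_config_error")
  expect_error(signature_model("skin", cbind(c(460, 600, 800, 940),
                                             c(0.5, 1.2, 0.5, 0.5))),
               class = "hsigan_config_error")
})

test_that("a collapsed mask draw is a discrete ellipse", {
  p <- tiny_params(bands = 4, height = 21, width = 21,
                   lesion_radius_range = c(5, 5 + 1e-9),
                   lesion_eccentricity_range = c(0, 0),
                   boundary_jitter_sd = 0)
  m <- make_mask(p, seed = 3)
  # replicate the centre draw and compare against the exact discrete disk
  set.seed(3)
  cy <- runif(1, 7, 14); cx <- runif(1, 7, 14)
  disk <- (outer(seq_len(21) - cy, rep(1, 21))^2 +
             outer(rep(1, 21), seq_len(21) - cx)^2) <= 25 * (1 + 1e-7)
  expect_equal(m, disk * 1)
  # centre lies in the middle third of the frame
  expect_true(cy >= 7 && cy <= 14 && cx >= 7 && cx <= 14)
  expect_identical(make_mask(p, seed = 11), make_mask(p, seed = 11))
})

test_that("mask lesion fractions stay within the stated bounds", {
  p <- tiny_params(bands = 4, height = 50, width = 50)
  fracs <- vapply(1:300, function(i) mean(make_mask(p, seed = i)),
                  numeric(1))
  expect_gte(min(fracs), 0.05)
  expect_lte(max(fracs), 0.6)
})

test_that("noise-free cubes reproduce the class signature exactly", {
  p <- tiny_params(bands = 10, noise_sd = 0, smoothness_sigma_px = 0,
                   signatures = default_signatures(amplitude_jitter_sd = 0))
  cube <- make_cube(p, "malignant", seed = 2)
  sig <- eval_signature(p$signatures$malignant, p$axis)
  les <- which(cube$mask == 1, arr.ind = TRUE)
  for (i in seq_len(min(5, nrow(les))))
    expect_equal(cube$data[les[i, 1], les[i, 2], ], sig)
  skin <- which(cube$mask == 0, arr.ind = TRUE)[1, ]
  expect_equal(cube$data[skin[1], skin[2], ],
               eval_signature(p$signatures$skin, p$axis))
  expect_identical(make_cube(p, "benign", seed = 9),
                   make_cube(p, "benign", seed = 9))
})

test_that("lesion means concentrate on the class signature", {
  p <- tiny_params(bands = 8, seed = 10, smoothness_sigma_px = 0)
  cubes <- lapply(1:200, function(i) make_cube(p, "benign", seed = i))
  sig <- eval_signature(p$signatures$benign, p$axis)
  pool <- do.call(rbind, lapply(cubes, function(cb) {
    matrix(cb$data, ncol = 8)[as.vector(cb$mask) == 1, , drop = FALSE]
  }))
  # per-image amplitude jitter makes lesion pixels within an image
  # correlated; bound the error with the between-image variability
  per_image <- t(vapply(cubes, function(cb)
    colMeans(matrix(cb$data, ncol = 8)[as.vector(cb$mask) == 1, ,
                                       drop = FALSE]), numeric(8)))
  se <- apply(per_image, 2, sd) / sqrt(nrow(per_image))
  expect_true(all(abs(colMeans(pool) - sig) < 4 * se + 1e-3))
})

test_that("phantom datasets have the requested composition", {
  p <- tiny_params(bands = 4)
  cubes <- make_phantom_dataset(p, 5, 3)
  labs <- vapply(cubes, `[[`, "", "label")
  expect_equal(sum(labs == "benign"), 5)
  expect_equal(sum(labs == "malignant"), 3)
  ids <- vapply(cubes, `[[`, "", "id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(make_phantom_dataset(p, 2, 2),
                   make_phantom_dataset(p, 2, 2))
  expect_length(make_phantom_dataset(p, 0, 0), 0)
})

test_that("generated class-mean signatures recover the ground truth", {
  p <- tiny_params(bands = 12, seed = 3)
  for (cls in c("benign", "malignant")) {
    cubes <- lapply(1:200, function(i)
      make_cube(p, cls, seed = 1000 + i))
    got <- spectral_signature(cubes, "lesion")$mean
    truth <- eval_signature(p$signatures[[cls]], p$axis)
    js <- js_divergence(spectral_distribution(got),
                        spectral_distribution(truth))
    expect_lt(js, 0.01)
  }
})

test_that("default phantom classes are linearly separable", {
  p <- tiny_params(bands = 12, seed = 5, height = 20, width = 20)
  train <- make_phantom_dataset(p, 50, 50)
  p2 <- tiny_params(bands = 12, seed = 77, height = 20, width = 20)
  test <- make_phantom_dataset(p2, 100, 100)
  mean_spec <- function(cb)
    colMeans(matrix(cb$data, ncol = 12)[as.vector(cb$mask) == 1, ,
                                        drop = FALSE])
  Xtr <- t(vapply(train, mean_spec, numeric(12)))
  ytr <- vapply(train, `[[`, "", "label")
  Xte <- t(vapply(test, mean_spec, numeric(12)))
  yte <- vapply(test, `[[`, "", "label")
  # nearest-centroid rule: linear decision boundary
  cb_ <- colMeans(Xtr[ytr == "benign", ]); cm_ <- colMeans(Xtr[ytr == "malignant", ])
  pred <- ifelse(rowSums((Xte - rep(cm_, each = nrow(Xte)))^2) <
                   rowSums((Xte - rep(cb_, each = nrow(Xte)))^2),
                 "malignant", "benign")
  expect_gte(mean(pred == yte), 0.95)
})
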