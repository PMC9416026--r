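test_that("deterministic embeddings are reproducible summaries", {
  p <- tiny_params(bands = 6, height = 10, width = 10)
  cubes <- make_phantom_dataset(p, 2, 2)
  F1 <- embed_cubes(cubes)
  F2 <- embed_cubes(cubes)
  expect_identical(F1, F2)
  expect_equal(dim(F1), c(4, 18))
  expect_identical(F1[1, ], embed_cubes(cubes[c(1, 1)])[2, ])

  uni <- hsi_cube(array(0.37, c(5, 5, 6)), p$axis)
  fu <- embed_cubes(list(uni, uni))
  expect_equal(fu[1, 1:6], rep(0.37, 6), ignore_attr = TRUE)
  expect_equal(fu[1, 7:12], rep(0, 6), ignore_attr = TRUE)
  expect_equal(fu[1, 13:18], rep(0, 6), ignore_attr = TRUE) # no mask

  expect_error(embed_cubes(list(uni, hsi_cube(array(0, c(4, 4, 6)),
                                              p$axis))),
               class = "hsigan_dimension_error")
})

test_that("the Frechet distance matches analytic and brute-force oracles", {
  set.seed(2)
  X <- matrix(rnorm(500), 100, 5)
  expect_lt(fid(feature_moments(X), feature_moments(X)), 1e-6)

  # univariate Gaussians: (mu1-mu2)^2 + (sd1-sd2)^2
  a <- moments(0, 1); b <- moments(3, 4)
  expect_equal(fid(a, b), (0 - 3)^2 + (1 - 2)^2, tolerance = 1e-9)

  # diagonal covariances: closed form and brute-force matrix square root
  s1 <- c(0.5, 2, 1.3); s2 <- c(1.1, 0.4, 2.2)
  mu1 <- c(0, 1, -1); mu2 <- c(0.5, 0, 2)
  da <- moments(mu1, diag(s1)); db <- moments(mu2, diag(s2))
  closed <- sum((mu1 - mu2)^2) + sum((sqrt(s1) - sqrt(s2))^2)
  expect_equal(fid(da, db), closed, tolerance = 1e-9)
  expect_equal(fid(da, db), fid_oracle(mu1, diag(s1), mu2, diag(s2)),
               tolerance = 1e-8)

  # dense PSD covariances against the brute-force oracle; symmetry
  for (i in 1:3) {
    set.seed(i)
    S1 <- random_psd(4); S2 <- random_psd(4)
    m1 <- rnorm(4); m2 <- rnorm(4)
    expect_equal(fid(moments(m1, S1), moments(m2, S2)),
                 fid_oracle(m1, S1, m2, S2), tolerance = 1e-6)
    expect_equal(fid(moments(m1, S1), moments(m2, S2)),
                 fid(moments(m2, S2), moments(m1, S1)), tolerance = 1e-8)
  }

  bad <- moments(c(0, 0), matrix(c(1, 0, 0, -1), 2))
  expect_error(fid(bad, moments(c(0, 0), diag(2))),
               class = "hsigan_numeric_error")
})

test_that("confusion-matrix metrics follow the percent formulas", {
  m <- classification_metrics(confusion_matrix(tp = 31, tn = 33, fp = 7,
                                               fn = 5))
  expect_equal(m$accuracy, 84.21)
  expect_equal(m$precision, 81.58)
  expect_equal(m$recall, 86.11)
  expect_equal(m$f1, 83.78)

  all_tp <- classification_metrics(confusion_matrix(12, 0, 0, 0))
  expect_true(all(unlist(all_tp) == 100))
  sym <- classification_metrics(confusion_matrix(1, 1, 1, 1))
  expect_true(all(unlist(sym) == 50))

  und <- classification_metrics(confusion_matrix(0, 5, 0, 0))
  expect_true(is.na(und$precision))
  expect_true(is.na(und$recall))
  expect_equal(und$accuracy, 100)
})

test_that("metrics agree with a direct recount of predictions", {
  set.seed(8)
  for (i in 1:5) {
    truth <- sample(c("benign", "malignant"), 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.3,
                   ifelse(truth == "benign", "malignant", "benign"), truth)
    cm <- confusion_from_predictions(truth, pred)
    m <- classification_metrics(cm)
    tp <- sum(truth == "malignant" & pred == "malignant")
    fp <- sum(truth == "benign" & pred == "malignant")
    fn <- sum(truth == "malignant" & pred == "benign")
    expect_equal(m$accuracy, round(100 * mean(truth == pred), 2))
    expect_equal(m$precision, round(100 * tp / (tp + fp), 2))
    expect_equal(m$recall, round(100 * tp / (tp + fn), 2))
  }
})

test_that("Jensen-Shannon divergence matches the mixture-form identity", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)

  kl2 <- function(p, q) sum(ifelse(p > 0, p * (log2(p) - log2(q)), 0))
  set.seed(4)
  for (i in 1:10) {
    v <- spectral_distribution(runif(8))$values
    w <- spectral_distribution(runif(8))$values
    m <- (v + w) / 2
    expect_equal(js_divergence(v, w), 0.5 * kl2(v, m) + 0.5 * kl2(w, m),
                 tolerance = 1e-12)
    expect_equal(js_divergence(v, w), js_divergence(w, v))
    expect_gte(js_divergence(v, w), 0)
    expect_lte(js_divergence(v, w), 1)
  }
  expect_equal(js_divergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * kl2(c(0.5, 0.5), c(0.7, 0.3)) +
                 0.5 * kl2(c(0.9, 0.1), c(0.7, 0.3)), tolerance = 1e-12)

  expect_error(js_divergence(c(0.5, 0.6), c(0.5, 0.5)),
               class = "hsigan_normalization_error")
  expect_error(js_divergence(c(0.5, 0.5), c(0.5, 0.4, 0.1)),
               class = "hsigan_dimension_error")
})

test_that("spectral signatures pool regions correctly", {
  p <- tiny_params(bands = 6, height = 10, width = 10)
  ax <- p$axis
  uni <- hsi_cube(array(0.4, c(10, 10, 6)), ax,
                  mask = matrix(rep(c(0, 1), 50), 10), label = "benign")
  sg <- spectral_signature(list(uni), "lesion")
  expect_equal(sg$sd, rep(0, 6))
  expect_equal(sg$mean, rep(0.4, 6))
  expect_equal(sg$lower, sg$mean)

  # no spatial smoothing here: boundary pixels would mix skin into the
  # lesion pool and bias the comparison against the pure signature
  p <- tiny_params(bands = 6, height = 10, width = 10,
                   smoothness_sigma_px = 0)
  cubes <- make_phantom_dataset(p, 6, 6)
  les <- spectral_signature(cubes, "lesion", class_filter = "malignant")
  skn <- spectral_signature(cubes, "skin")
  truth_skin <- eval_signature(p$signatures$skin, ax)
  truth_mal <- eval_signature(p$signatures$malignant, ax)
  expect_lt(max(abs(skn$mean - truth_skin)), 0.05)
  expect_lt(max(abs(les$mean - truth_mal)), 0.05)
  expect_gt(max(abs(les$mean - skn$mean)), 0.1)

  nomask <- hsi_cube(array(0.4, c(10, 10, 6)), ax)
  expect_error(spectral_signature(list(nomask), "lesion"),
               class = "hsigan_data_error")
  expect_error(spectral_signature(cubes, "lesion", class_filter = "weird"),
               class = "hsigan_data_error")
})

test_that("the fidelity protocol never trains on the test set", {
  p <- tiny_params(bands = 8, height = 16, width = 16, seed = 21)
  synth <- make_phantom_dataset(p, 30, 30)
  cfg <- classifier_config(width = 8, blocks = 3, epochs = 8,
                           batch_size = 16, seed = 2)

  # leakage sanity: scoring the training set itself reproduces the
  # training accuracy
  res_leak <- fidelity_protocol(synth, synth, cfg)
  expect_equal(res_leak$metrics$accuracy, round(res_leak$train_accuracy, 2))

  # a shifted-seed phantom set stands in for the real data
  p2 <- tiny_params(bands = 8, height = 16, width = 16, seed = 1234)
  real <- make_phantom_dataset(p2, 20, 18)
  res <- fidelity_protocol(synth, real, cfg)
  expect_s3_class(res$confusion, "confusion_matrix")
  with(res$confusion, expect_equal(tp + tn + fp + fn, 38))
  expect_gt(res$metrics$accuracy, 60)

  single <- synth[vapply(synth, `[[`, "", "label") == "benign"]
  expect_error(fidelity_protocol(single, real, cfg),
               class = "hsigan_data_error")
})

test_that("the learned embedding reuses the classifier trunk", {
  p <- tiny_params(bands = 6, height = 8, width = 8, seed = 3)
  cubes <- make_phantom_dataset(p, 6, 6)
  clf <- fit_lesion_classifier(cubes, config = classifier_config(
    width = 8, blocks = 2, epochs = 2, seed = 1))
  F <- embed_cubes(cubes, "cnn", classifier = clf)
  expect_equal(nrow(F), 12)
  expect_equal(ncol(F), 16) # width 8, blocks 2 -> 2*width channels
  expect_error(embed_cubes(cubes, "cnn"), class = "hsigan_usage_error")
})
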