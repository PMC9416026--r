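test_that("white/dark calibration follows the flat-field identity", {
  ax <- default_axis(6)
  dk <- array(runif(2 * 3 * 6, 0, 10), c(2, 3, 6))
  wt <- dk + array(runif(2 * 3 * 6, 5, 20), c(2, 3, 6))

  expect_equal(calibrate(wt, wt, dk, ax)$data, array(1, c(2, 3, 6)))
  expect_equal(calibrate(dk, wt, dk, ax)$data, array(0, c(2, 3, 6)))
  raw <- dk + 0.25 * (wt - dk)
  expect_equal(calibrate(raw, wt, dk, ax)$data, array(0.25, c(2, 3, 6)))
})

test_that("calibration clips speculars and flags degenerate references", {
  ax <- default_axis(2)
  dk <- array(0, c(2, 2, 2)); wt <- array(1, c(2, 2, 2))
  hot <- array(5, c(2, 2, 2))
  expect_equal(max(calibrate(hot, wt, dk, ax)$data), 2)

  expect_error(calibrate(array(1, c(2, 2, 3)), wt, dk, ax),
               class = "hsigan_dimension_error")
  bad <- wt; bad[2, 1, 2] <- 0
  err <- tryCatch(calibrate(hot, bad, dk, ax), condition = identity)
  expect_s3_class(err, "hsigan_degenerate_reference_error")
  expect_match(conditionMessage(err), "(2, 1, band 2)", fixed = TRUE)
})

test_that("band trimming drops noisy edges and keeps the axis aligned", {
  cube <- hsi_cube(array(runif(4 * 4 * 125), c(4, 4, 125)), default_axis())
  trimmed <- trim_bands(cube)
  expect_equal(trimmed$axis$band_count, 116L)
  expect_equal(trimmed$axis$wavelengths_nm,
               cube$axis$wavelengths_nm[6:121])
  expect_equal(trimmed$data, cube$data[, , 6:121])

  expect_equal(trim_bands(cube, 0, 0), cube)

  ten <- hsi_cube(array(runif(2 * 2 * 10), c(2, 2, 10)), default_axis(10))
  mid <- trim_bands(ten, 3, 3)
  expect_equal(mid$axis$wavelengths_nm, ten$axis$wavelengths_nm[4:7])
  expect_equal(mid$data, ten$data[, , 4:7])
  expect_error(trim_bands(ten, 5, 5), class = "hsigan_empty_cube_error")
})

test_that("label smoothing lands in the class interval, reproducibly", {
  for (seed in c(1, 7, 123)) {
    expect_true(smooth_label("malignant", seed)$value >= 0.7)
    expect_true(smooth_label("malignant", seed)$value <= 1.0)
    expect_true(smooth_label("benign", seed)$value >= 0)
    expect_true(smooth_label("benign", seed)$value <= 0.3)
  }
  expect_identical(smooth_label("benign", 42), smooth_label("benign", 42))
  expect_error(smooth_label("weird"), class = "hsigan_value_error")
})

test_that("smoothed-label draws match the uniform model", {
  n <- 10000
  se <- (0.3 / sqrt(12)) / sqrt(n) # uniform width 0.3
  for (cls in c("benign", "malignant")) {
    v <- smooth_label(rep(cls, n), rng_seed = 5)$value
    lo <- if (cls == "benign") 0 else 0.7
    expect_true(min(v) >= lo && max(v) <= lo + 0.3)
    expect_lt(abs(mean(v) - (lo + 0.15)), 3 * se)
  }
})

test_that("pseudo-RGB picks nearest bands and scales jointly", {
  ax <- trim_bands(hsi_cube(array(0.5, c(2, 2, 125)), default_axis()))$axis

  uni <- hsi_cube(array(0.4, c(4, 4, ax$band_count)), ax)
  expect_equal(pseudo_rgb(uni), array(0.5, c(4, 4, 3)))

  dat <- array(0.1, c(4, 4, ax$band_count))
  red_band <- which.min(abs(ax$wavelengths_nm - 630))
  dat[2, 3, red_band] <- 1
  img <- pseudo_rgb(hsi_cube(dat, ax))
  expect_equal(img[2, 3, 1], 1)
  expect_lt(max(img[, , 2:3]), 0.01)

  # 465 nm sits below the trimmed axis start (~470 nm): nearest edge band
  dat2 <- array(0.1, c(4, 4, ax$band_count))
  dat2[1, 1, 1] <- 1
  img2 <- pseudo_rgb(hsi_cube(dat2, ax))
  expect_equal(img2[1, 1, 3], 1)

  expect_error(pseudo_rgb(uni, c(630, 532, 300)),
               class = "hsigan_range_error")
})

test_that("datasets round-trip bit-identically through both formats", {
  cubes <- make_phantom_dataset(tiny_params(bands = 6), 2, 1)
  cubes[[2]]$mask <- NULL # exercise the optional-mask path

  for (fmt in c("rds", "envi")) {
    path <- file.path(tempdir(), paste0("roundtrip_", fmt,
                                        if (fmt == "rds") ".rds" else ""))
    unlink(path, recursive = TRUE)
    write_hsi_dataset(cubes, path, fmt)
    back <- read_hsi_dataset(path, fmt)
    expect_length(back, 3)
    ord <- match(vapply(cubes, `[[`, "", "id"),
                 vapply(back, `[[`, "", "id"))
    for (i in seq_along(cubes)) {
      expect_identical(back[[ord[i]]]$data, cubes[[i]]$data)
      expect_identical(back[[ord[i]]]$mask, cubes[[i]]$mask)
      expect_identical(back[[ord[i]]]$label, cubes[[i]]$label)
      expect_equal(back[[ord[i]]]$axis$wavelengths_nm,
                   cubes[[i]]$axis$wavelengths_nm)
    }
  }
})

test_that("malformed ENVI headers raise format errors naming the file", {
  cubes <- make_phantom_dataset(tiny_params(bands = 4), 1, 0)
  dir <- file.path(tempdir(), "badenvi")
  unlink(dir, recursive = TRUE)
  write_hsi_dataset(cubes, dir, "envi")
  hdr <- list.files(dir, pattern = "\\.hdr$", full.names = TRUE)[1]
  txt <- readLines(hdr)
  writeLines(sub("^bands = 4", "bands = 7", txt), hdr)
  err <- tryCatch(read_hsi_dataset(dir, "envi"), condition = identity)
  expect_s3_class(err, "hsigan_format_error")
  expect_match(conditionMessage(err), basename(hdr), fixed = TRUE)
})

test_that("calibration and band trimming commute", {
  ax <- default_axis(10)
  dk <- array(runif(40, 0, 5), c(2, 2, 10))
  wt <- dk + array(runif(40, 1, 4), c(2, 2, 10))
  raw <- dk + array(runif(40, 0, 6), c(2, 2, 10))
  a <- trim_bands(calibrate(raw, wt, dk, ax), 2, 3)
  b <- calibrate(raw[, , 3:7], wt[, , 3:7], dk[, , 3:7],
                 spectral_axis(ax$wavelengths_nm[3:7]))
  expect_equal(a$data, b$data)
  expect_equal(a$axis$wavelengths_nm, b$axis$wavelengths_nm)
})
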