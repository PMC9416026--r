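# Orchestration: cube generation from checkpoints, dataset-vs-dataset
# evaluation reports, and the simulate -> train -> generate -> evaluate
# pipeline driven by a YAML configuration.  Every stage derives its seed
# from the single global seed through stream_seed(), so adding a stage
# never perturbs the draws of earlier ones.

#' Generate labeled cubes from a trained model
#'
#' Draws `floor(n * class_balance)` benign-conditioned cubes and the rest
#' malignant-conditioned from a fitted conditional GAN (masks attached
#' from the generated mask channel), optionally writing them as a
#' dataset.
#'
#' @param model An `hsi_cgan` object or a checkpoint path.
#' @param n Number of cubes.
#' @param class_balance Benign fraction in \[0, 1\].
#' @param seed Seed for the latent draws and condition smoothing.
#' @param out Optional output path for [write_hsi_dataset()].
#' @param format Dataset format when writing.
#' @return Invisibly, the list of generated [hsi_cube()].
#' @export
generate_cubes <- function(model, n, class_balance = 0.5, seed = 1L,
                           out = NULL, format = c("rds", "envi")) {
  format <- match.arg(format)
  if (is.character(model)) model <- load_checkpoint(model)
  if (!inherits(model, "hsi_cgan"))
    stop_hsigan("model must be an hsi_cgan fit or checkpoint",
                "hsigan_checkpoint_error")
  if (!is_count(n) || n < 0) stop_config("n must be a nonnegative integer")
  if (class_balance < 0 || class_balance > 1)
    stop_config("class_balance must lie in [0, 1]")
  nb <- floor(n * class_balance)
  classes <- c(rep("benign", nb), rep("malignant", n - nb))
  cubes <- generate_from_model(model, n, classes = classes,
                               seed = stream_seed(seed, "generate"))
  if (!is.null(out)) write_hsi_dataset(cubes, out, format)
  invisible(cubes)
}

signature_or_null <- function(cubes, region, class_filter = NULL) {
  tryCatch(spectral_signature(cubes, region, class_filter),
           hsigan_data_error = function(e) NULL)
}

#' Compare a synthetic dataset against a real one
#'
#' Computes the deterministic-embedding Frechet distance, per-region
#' Jensen-Shannon divergences between L1-normalized mean spectral
#' signatures (benign lesion, malignant lesion, skin), the signature
#' envelopes, and optionally the train-on-synthetic/test-on-real
#' fidelity metrics.
#'
#' @param real,synthetic Labeled [hsi_cube()] lists of identical shape.
#' @param fidelity Run [fidelity_protocol()] as part of the report.
#' @param classifier_config Classifier settings for the protocol.
#' @param out Optional directory; writes `report.json`,
#'   `signatures.csv` and `signatures.png` there.
#' @return An `hsigan_report` list: `fid`, `js` (named per region),
#'   `signatures`, optional `fidelity`.
#' @export
evaluate_datasets <- function(real, synthetic, fidelity = FALSE,
                              classifier_config = classifier_config(),
                              out = NULL) {
  f <- fid(feature_moments(embed_cubes(real)),
           feature_moments(embed_cubes(synthetic)))
  regions <- list(benign = list("lesion", "benign"),
                  malignant = list("lesion", "malignant"),
                  skin = list("skin", NULL))
  sigs <- list(); js <- list()
  for (nm in names(regions)) {
    rs <- signature_or_null(real, regions[[nm]][[1]], regions[[nm]][[2]])
    ss <- signature_or_null(synthetic, regions[[nm]][[1]], regions[[nm]][[2]])
    sigs[[nm]] <- list(real = rs, synthetic = ss)
    js[[nm]] <- if (is.null(rs) || is.null(ss)) NA_real_
    else js_divergence(spectral_distribution(rs$mean),
                       spectral_distribution(ss$mean))
  }
  report <- structure(list(fid = f, js = js, signatures = sigs),
                      class = "hsigan_report")
  if (fidelity)
    report$fidelity <- fidelity_protocol(synthetic, real, classifier_config)
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    payload <- list(fid = f, js = js)
    if (fidelity)
      payload$fidelity <- c(list(train_accuracy = report$fidelity$train_accuracy),
                            unclass(report$fidelity$metrics),
                            unclass(report$fidelity$confusion))
    jsonlite::write_json(payload, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    rows <- do.call(rbind, lapply(names(sigs), function(nm) {
      do.call(rbind, lapply(c("real", "synthetic"), function(src) {
        sg <- sigs[[nm]][[src]]
        if (is.null(sg)) return(NULL)
        data.frame(region = nm, source = src,
                   wavelength_nm = sg$wavelengths_nm, mean = sg$mean,
                   sd = sg$sd, lower = sg$lower, upper = sg$upper)
      }))
    }))
    utils::write.csv(rows, file.path(out, "signatures.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out, "signatures.png"), width = 900,
                   height = 600)
    plot_report_signatures(sigs)
    grDevices::dev.off()
  }
  report
}

plot_report_signatures <- function(sigs) {
  op <- graphics::par(mfrow = c(1, length(sigs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(sigs)) {
    pair <- sigs[[nm]]
    if (is.null(pair$real) && is.null(pair$synthetic)) next
    first <- TRUE
    for (src in c("real", "synthetic")) {
      sg <- pair[[src]]
      if (is.null(sg)) next
      plot(sg, col = if (src == "real") "black" else "firebrick",
           add = !first, main = if (first) nm else NULL)
      first <- FALSE
    }
    graphics::legend("topleft", c("real", "synthetic"), lwd = 2, bty = "n",
                     col = c("black", "firebrick"))
  }
}

#' @export
print.hsigan_report <- function(x, ...) {
  cat(sprintf("Frechet distance (deterministic embedding): %.4f\n", x$fid))
  for (nm in names(x$js))
    cat(sprintf("JS divergence, %s: %s\n", nm,
                if (is.na(x$js[[nm]])) "unavailable"
                else sprintf("%.4f", x$js[[nm]])))
  if (!is.null(x$fidelity)) print(x$fidelity)
  invisible(x)
}

required_key <- function(cfg, key, where) {
  if (is.null(cfg[[key]]))
    stop_config(sprintf("missing config key '%s' in %s", key, where))
  cfg[[key]]
}

phantom_params_from_config <- function(cfg, seed) {
  phantom_params(
    height = required_key(cfg, "height", "phantom"),
    width = required_key(cfg, "width", "phantom"),
    bands = required_key(cfg, "bands", "phantom"),
    lesion_radius_range = cfg$lesion_radius_range,
    lesion_eccentricity_range = cfg$lesion_eccentricity_range %||% c(0, 0.6),
    noise_sd = cfg$noise_sd %||% 0.02,
    smoothness_sigma_px = cfg$smoothness_sigma_px %||% 0.8,
    seed = seed)
}

#' Run the full phantom pipeline from a YAML configuration
#'
#' Stages: `simulate` (phantom dataset), `train` (conditional GAN),
#' `generate` (synthetic dataset from the fit), `evaluate` (report
#' against the simulated "real" data).  Writes `data.rds`,
#' `checkpoint.rds`, `synthetic.rds`, `report.json` and a
#' `manifest.json` (package version, seeds, file hashes) into the output
#' directory, enabling exact reruns.
#'
#' @param config_file Path to a YAML file with blocks `seed`, `outdir`,
#'   `phantom` (geometry + counts), and optional `train`, `generate`,
#'   `evaluate` overrides.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config_file) {
  if (!file.exists(config_file))
    stop_config(sprintf("config file %s does not exist", config_file))
  cfg <- yaml::read_yaml(config_file)
  seed <- required_key(cfg, "seed", "config")
  outdir <- required_key(cfg, "outdir", "config")
  pcfg <- required_key(cfg, "phantom", "config")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  params <- phantom_params_from_config(pcfg, stream_seed(seed, "simulate"))
  cubes <- make_phantom_dataset(params, pcfg$n_benign %||% 40L,
                                pcfg$n_malignant %||% 36L)
  data_path <- file.path(outdir, "data.rds")
  write_hsi_dataset(cubes, data_path, "rds")

  tcfg <- cfg$train %||% list()
  config <- train_config("hs_cgan",
                         epochs = tcfg$epochs,
                         batch_size = tcfg$batch_size,
                         lr_g = tcfg$lr_g, lr_d = tcfg$lr_d,
                         fid_every = tcfg$fid_every %||% 0L,
                         seed = stream_seed(seed, "train"))
  fit <- hsi_cgan(cubes, config,
                  latent_dim = tcfg$latent_dim %||% 100L,
                  base_width_g = tcfg$base_width_g %||% 64L,
                  base_width_d = tcfg$base_width_d %||% 32L)
  ckpt_path <- file.path(outdir, "checkpoint.rds")
  save_checkpoint(fit, ckpt_path)

  gcfg <- cfg$generate %||% list()
  synth_path <- file.path(outdir, "synthetic.rds")
  synth <- generate_cubes(fit, gcfg$n %||% length(cubes),
                          class_balance = gcfg$class_balance %||% 0.5,
                          seed = stream_seed(seed, "generate"),
                          out = synth_path, format = "rds")

  ecfg <- cfg$evaluate %||% list()
  evaluate_datasets(cubes, synth,
                    fidelity = isTRUE(ecfg$fidelity),
                    classifier_config = classifier_config(
                      width = ecfg$classifier_width %||% 8L,
                      epochs = ecfg$classifier_epochs %||% 10L,
                      seed = stream_seed(seed, "fidelity")),
                    out = outdir)

  files <- c(data = data_path, checkpoint = ckpt_path, synthetic = synth_path,
             report = file.path(outdir, "report.json"))
  manifest <- list(
    package = "hsigan",
    version = as.character(utils::packageVersion("hsigan")),
    seed = seed,
    stage_seeds = list(simulate = stream_seed(seed, "simulate"),
                       train = stream_seed(seed, "train"),
                       generate = stream_seed(seed, "generate"),
                       fidelity = stream_seed(seed, "fidelity")),
    config = cfg,
    md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
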