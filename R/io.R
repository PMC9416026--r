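# Dataset I/O.
#
# Two on-disk layouts are supported:
#   * "envi": one ENVI pair (<id>.hdr text header + <id>.raw band-sequential
#     binary, 8-byte IEEE doubles so round trips are bit-identical) per cube
#     in a directory, with an optional <id>.msk uint8 mask sidecar; label and
#     id are carried as header metadata.
#   * "rds": the whole dataset (data, axis, masks, labels, ids) in a single
#     RDS container file.

envi_header <- function(cube, raw_name, mask_name) {
  d <- dim(cube$data)
  lines <- c(
    "ENVI",
    "description = {hsigan hyperspectral lesion cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$axis$wavelengths_nm, digits = 12), collapse = ", ")),
    sprintf("cube id = %s", cube$id))
  if (!is.null(cube$label)) lines <- c(lines, sprintf("label = %s", cube$label))
  if (!is.null(cube$mask)) lines <- c(lines, sprintf("mask file = %s", mask_name))
  lines
}

write_envi_cube <- function(cube, dir) {
  stem <- gsub("[^A-Za-z0-9_.-]", "_", cube$id)
  raw_name <- paste0(stem, ".raw")
  mask_name <- paste0(stem, ".msk")
  writeLines(envi_header(cube, raw_name, mask_name),
             file.path(dir, paste0(stem, ".hdr")))
  con <- file(file.path(dir, raw_name), "wb")
  on.exit(close(con))
  # BSQ: sample (column) fastest, then line, then band
  writeBin(as.vector(aperm(cube$data, c(2, 1, 3))), con, size = 8,
           endian = "little")
  if (!is.null(cube$mask)) {
    mcon <- file(file.path(dir, mask_name), "wb")
    writeBin(as.integer(t(cube$mask)), mcon, size = 1)
    close(mcon)
  }
  invisible(NULL)
}

parse_envi_header <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || trimws(txt[1]) != "ENVI")
    stop_format(sprintf("%s: not an ENVI header (missing magic line)",
                        basename(path)))
  body <- paste(txt[-1], collapse = "\n")
  # key = value entries; values in {...} may span lines
  keys <- list()
  pat <- "(?s)([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- trimws(substr(piece, 1, eq - 1))
    val <- trimws(substr(piece, eq + 1, nchar(piece)))
    if (startsWith(val, "{"))
      val <- trimws(gsub("[{}]", "", val))
    keys[[tolower(key)]] <- val
  }
  keys
}

read_envi_cube <- function(hdr_path) {
  keys <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(keys))
  if (length(miss))
    stop_format(sprintf("%s: malformed header, missing %s",
                        basename(hdr_path), paste(miss, collapse = ", ")))
  W <- as.integer(keys[["samples"]]); H <- as.integer(keys[["lines"]])
  B <- as.integer(keys[["bands"]])
  dtype <- as.integer(keys[["data type"]])
  if (!dtype %in% c(4L, 5L))
    stop_format(sprintf("%s: unsupported data type %d", basename(hdr_path), dtype))
  if (tolower(keys[["interleave"]]) != "bsq")
    stop_format(sprintf("%s: only bsq interleave is supported", basename(hdr_path)))
  bytes <- if (dtype == 5L) 8L else 4L
  raw_path <- sub("\\.hdr$", ".raw", hdr_path)
  if (!file.exists(raw_path))
    stop_format(sprintf("%s: missing raw file %s", basename(hdr_path),
                        basename(raw_path)))
  n <- as.numeric(H) * W * B
  if (file.size(raw_path) != n * bytes)
    stop_format(sprintf(
      "%s: header declares %d x %d x %d (%d-byte) but %s has %d bytes",
      basename(hdr_path), H, W, B, bytes, basename(raw_path),
      file.size(raw_path)))
  con <- file(raw_path, "rb")
  vals <- readBin(con, "double", n = n, size = bytes, endian = "little")
  close(con)
  data <- aperm(array(vals, c(W, H, B)), c(2, 1, 3))
  wl <- if (!is.null(keys[["wavelength"]]))
    as.numeric(strsplit(keys[["wavelength"]], ",")[[1]])
  else seq(450, 950, length.out = B)
  if (length(wl) != B)
    stop_format(sprintf("%s: %d wavelengths for %d bands", basename(hdr_path),
                        length(wl), B))
  mask <- NULL
  if (!is.null(keys[["mask file"]])) {
    mp <- file.path(dirname(hdr_path), keys[["mask file"]])
    if (file.exists(mp)) {
      mcon <- file(mp, "rb")
      mv <- readBin(mcon, "integer", n = H * W, size = 1, signed = FALSE)
      close(mcon)
      mask <- t(matrix(as.double(mv), W, H))
    }
  }
  hsi_cube(data, spectral_axis(wl), mask = mask, label = keys[["label"]],
           id = keys[["cube id"]] %||% sub("\\.hdr$", "", basename(hdr_path)))
}

#' Read and write hyperspectral lesion datasets
#'
#' `write_hsi_dataset()` stores a list of [hsi_cube()] objects either as a
#' directory of ENVI header/raw pairs (`format = "envi"`) or as a single
#' RDS container (`format = "rds"`).  `read_hsi_dataset()` reverses the
#' operation losslessly (data, wavelength axis, mask, label, id).
#'
#' @param cubes List of [hsi_cube()] sharing a spectral axis.
#' @param path Directory (`envi`) or file path (`rds`).
#' @param format `"envi"` or `"rds"`; `read_hsi_dataset()` auto-detects
#'   from the path when omitted.
#' @return `read_hsi_dataset()` returns a list of [hsi_cube()].
#' @examples
#' cubes <- list(hsi_cube(array(0.2, c(3, 3, 4)), default_axis(4), id = "a"))
#' p <- file.path(tempdir(), "demo.rds")
#' write_hsi_dataset(cubes, p, format = "rds")
#' length(read_hsi_dataset(p))
#' @export
write_hsi_dataset <- function(cubes, path, format = c("envi", "rds")) {
  format <- match.arg(format)
  if (!is.list(cubes) || (length(cubes) && !all(vapply(cubes, inherits,
                                                       logical(1), "hsi_cube"))))
    stop_config("cubes must be a list of hsi_cube objects")
  if (length(cubes) > 1) {
    ax <- cubes[[1]]$axis$wavelengths_nm
    same <- vapply(cubes, function(cb) identical(cb$axis$wavelengths_nm, ax),
                   logical(1))
    if (!all(same)) stop_config("all cubes must share the same spectral axis")
  }
  if (format == "rds") {
    saveRDS(list(container = "hsigan-dataset-v1", cubes = cubes), path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (cube in cubes) write_envi_cube(cube, path)
  }
  invisible(path)
}

#' @rdname write_hsi_dataset
#' @export
read_hsi_dataset <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (dir.exists(path)) "envi" else "rds"
  format <- match.arg(format, c("envi", "rds"))
  if (format == "rds") {
    if (!file.exists(path)) stop_format(sprintf("%s: no such file", path))
    obj <- readRDS(path)
    if (!is.list(obj) || !identical(obj$container, "hsigan-dataset-v1"))
      stop_format(sprintf("%s: not an hsigan dataset container", path))
    obj$cubes
  } else {
    if (!dir.exists(path)) stop_format(sprintf("%s: no such directory", path))
    hdrs <- sort(list.files(path, pattern = "\\.hdr$", full.names = TRUE))
    if (!length(hdrs)) stop_format(sprintf("%s: no ENVI headers found", path))
    lapply(hdrs, read_envi_cube)
  }
}
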