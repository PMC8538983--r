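# File I/O: grayscale images (TIFF/PNG), mask and measurement CSVs,
# solver config (YAML/JSON), metrics/diagnostics/manifest JSON.
#
# CSV conventions: a first comment line `# shape=R,C rate=... seed=...`
# followed by a header. Coordinates in files are 0-based (row, col),
# raster order; in-memory objects are 1-based.

.imgFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "png") "png"
  else stop("unsupported image format: .", ext)
}

#' Read a grayscale image
#'
#' Reads TIFF or PNG as a numeric matrix in \[0, 1\] (the underlying
#' readers scale integer samples by their type maximum). Multi-channel
#' images are averaged to one channel.
#'
#' @param path file path (.tif/.tiff/.png).
#' @return numeric matrix.
#' @export
readImageGray <- function(path) {
  img <- switch(.imgFormat(path),
                tiff = tiff::readTIFF(path),
                png = png::readPNG(path))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  unname(as.matrix(img))
}

#' Write a grayscale image
#'
#' Writes 16-bit TIFF or PNG. Values are clipped to \[0, 1\].
#'
#' @param image numeric matrix.
#' @param path destination (.tif/.tiff/.png).
#' @export
writeImageGray <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  switch(.imgFormat(path),
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
         png = png::writePNG(img, path))
  invisible(path)
}

.headerLine <- function(mask) {
  sprintf("# shape=%d,%d rate=%g seed=%s", mask@shape[1L], mask@shape[2L],
          mask@rate, ifelse(is.na(mask@seed), "NA", mask@seed))
}

.parseHeader <- function(line) {
  get <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", line)
  shape <- as.integer(strsplit(get("shape"), ",")[[1L]])
  list(shape = shape, rate = as.numeric(get("rate")),
       seed = suppressWarnings(as.integer(get("seed"))))
}

#' Write a mask to file
#'
#' CSV: a comment line carrying shape/rate/seed, then 0-based `row,col`
#' pairs in raster order. Alternatively a dense 0/1 indicator image when
#' `path` has an image extension.
#'
#' @param mask a [SamplingMask-class].
#' @param path .csv, .tif/.tiff or .png destination.
#' @export
writeMask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.headerLine(mask), con)
    writeLines("row,col", con)
    idx <- mask@indices - 1L
    writeLines(paste(idx[, 1L], idx[, 2L], sep = ","), con)
  } else {
    writeImageGray(maskIndicator(mask), path)
  }
  invisible(path)
}

#' Read a mask from file
#'
#' Accepts the CSV format of [writeMask()] or a dense 0/1 mask image.
#'
#' @param path mask file.
#' @return a [SamplingMask-class].
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    lines <- readLines(path)
    hdr <- .parseHeader(lines[1L])
    df <- utils::read.csv(text = lines[-1L])
    maskFromIndices(hdr$shape, cbind(df$row + 1L, df$col + 1L),
                    seed = hdr$seed)
  } else {
    ind <- readImageGray(path) > 0.5
    maskFromIndices(dim(ind), which(ind, arr.ind = TRUE))
  }
}

#' Write measurements to file
#'
#' CSV with the mask header, then 0-based `row,col,value` triples in mask
#' order.
#'
#' @param y measurement vector.
#' @param mask the [SamplingMask-class] it belongs to.
#' @param path .csv destination.
#' @export
writeMeasurements <- function(y, mask, path) {
  if (length(y) != nrow(mask@indices))
    stop("measurement length does not match the mask")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLine(mask), con)
  writeLines("row,col,value", con)
  idx <- mask@indices - 1L
  writeLines(paste(idx[, 1L], idx[, 2L],
                   formatC(y, format = "g", digits = 17), sep = ","), con)
  invisible(path)
}

#' Read measurements from file
#'
#' @param path CSV written by [writeMeasurements()].
#' @return list with `y` (numeric vector) and `mask`
#'   ([SamplingMask-class]).
#' @export
readMeasurements <- function(path) {
  lines <- readLines(path)
  hdr <- .parseHeader(lines[1L])
  df <- utils::read.csv(text = lines[-1L])
  mask <- maskFromIndices(hdr$shape, cbind(df$row + 1L, df$col + 1L),
                          seed = hdr$seed)
  # values must follow mask (raster) order
  o <- order(df$row, df$col)
  list(y = df$value[o], mask = mask)
}

#' Read a solver configuration file
#'
#' YAML or JSON with [solverConfig()] keys; missing keys fall back to the
#' defaults, unknown keys are an error.
#'
#' @param path .yaml/.yml or .json file.
#' @return a [SolverConfig-class].
#' @export
readSolverConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  configFromList(lst)
}

#' Write a solver configuration file
#'
#' @param config a [SolverConfig-class].
#' @param path .yaml/.yml or .json destination.
#' @export
writeSolverConfig <- function(config, path) {
  lst <- configAsList(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(lst, path)
  else if (ext == "json")
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported config format: .", ext)
  invisible(path)
}

#' Write a JSON record
#'
#' Shared writer for diagnostics, metrics and manifests. Non-finite
#' numbers are encoded as strings.
#'
#' @param record named list.
#' @param path .json destination.
#' @export
writeJSONRecord <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}

#' Run manifest
#'
#' Every CLI command emits one manifest recording the command, its
#' configuration echo, input/output paths, seeds and the package version,
#' so a run can be reproduced bit-for-bit (modulo the timestamp).
#'
#' @param command command name.
#' @param config config echo (named list) or NULL.
#' @param inputs,outputs named lists of paths.
#' @param seeds named list of seeds used.
#' @return named list.
#' @export
runManifest <- function(command, config = NULL, inputs = list(),
                        outputs = list(), seeds = list()) {
  list(command = command,
       version = as.character(utils::packageVersion("thzrecon")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config, inputs = inputs, outputs = outputs, seeds = seeds)
}
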