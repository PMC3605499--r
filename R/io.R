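#' Read and write phase-pattern files
#'
#' Plain-text format: header lines `#pattern_id`, `#n_units`, `#frequency_hz`
#' followed by one phase per line at full double precision (lossless
#' round-trip).
#'
#' @param pattern a [phase_pattern()].
#' @param path file path.
#' @export
write_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#pattern_id %d", pattern$pattern_id),
               sprintf("#n_units %d", pattern$n_units),
               sprintf("#frequency_hz %s",
                       format(pattern$frequency_hz, digits = 17))), con)
  writeLines(format(pattern$phases, digits = 17, scientific = FALSE,
                    trim = TRUE), con)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(name) {
    hit <- hdr[startsWith(hdr, paste0("#", name))]
    if (length(hit) != 1L) abort(sprintf("pattern file missing header `#%s`", name))
    sub(sprintf("^#%s\\s+", name), "", hit)
  }
  phases <- as.double(lines[!startsWith(lines, "#") & nzchar(lines)])
  if (anyNA(phases)) abort("pattern file contains non-numeric phase lines")
  n_units <- as.integer(get_field("n_units"))
  if (length(phases) != n_units) {
    abort(sprintf("pattern file declares %d units but has %d phases",
                  n_units, length(phases)))
  }
  phase_pattern(phases, as.double(get_field("frequency_hz")),
                as.integer(get_field("pattern_id")))
}

#' Read and write weight matrices
#'
#' Binary little-endian doubles (column-major) with a JSON sidecar
#' (`<path>.json`) recording N, dtype, contributing pattern ids and the STDP
#' window parameters. `write_weights_tsv()` additionally exports the nonzero
#' entries as gzipped TSV `(i, j, J_ij)`.
#'
#' @param J a `synaptic_matrix`.
#' @param path path of the binary file; the sidecar gets `.json` appended.
#' @param dtype `"double"` (default) or `"single"`.
#' @export
write_weights <- function(J, path, dtype = c("double", "single")) {
  dtype <- match.arg(dtype)
  size <- if (dtype == "double") 8L else 4L
  con <- file(path, "wb")
  writeBin(as.vector(J$weights), con, size = size, endian = "little")
  close(con)
  p <- J$params
  meta <- list(n_units = J$n_units, dtype = dtype,
               pattern_ids = J$pattern_ids,
               stdp = list(T_p = p$T_p, T_D = p$T_D, eta = p$eta,
                           gamma = p$gamma),
               format_version = 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), 1L)) {
    warning("weight file written by a different schema version")
  }
  N <- as.integer(meta$n_units)
  size <- if (identical(meta$dtype, "double")) 8L else 4L
  con <- file(path, "rb")
  w <- readBin(con, "double", n = N * N, size = size, endian = "little")
  close(con)
  s <- meta$stdp
  new_synaptic_matrix(matrix(w, N, N), as.integer(meta$pattern_ids),
                      stdp_params(s$T_p, s$T_D, s$eta, s$gamma))
}

#' @rdname write_weights
#' @export
write_weights_tsv <- function(J, path) {
  W <- J$weights
  idx <- which(W != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], J = W[idx])
  con <- gzfile(path, "w")
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read and write spike trains as TSV
#'
#' Columns `time_ms` (float), `unit` (0-based integer, following the on-disk
#' convention; the in-memory API is 1-based), `source` in `{cue, net}`. A JSON
#' sidecar (`<path>.json`) records `n_units`, `duration`, `dt` and the seed.
#' The reader validates time ordering, unit ranges and source labels.
#'
#' @param train a `spike_train`.
#' @param path TSV path.
#' @export
write_spike_train <- function(train, path) {
  df <- data.frame(time_ms = format(train$time_ms, digits = 17, trim = TRUE),
                   unit = as.integer(train$unit) - 1L,
                   source = train$source)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(n_units = attr(train, "n_units"),
               duration = attr(train, "duration"),
               dt = attr(train, "dt"), seed = attr(train, "seed"),
               format_version = 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("numeric", "integer", "character"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(n_units = if (nrow(df)) max(df$unit) + 1L else 0L,
         duration = if (nrow(df)) max(df$time_ms) else 0, dt = NA_real_)
  }
  if (is.unsorted(df$time_ms)) abort("spike-train file is not time-ordered")
  if (nrow(df) && (min(df$unit) < 0L || max(df$unit) >= meta$n_units)) {
    abort("spike-train file has unit indices out of range")
  }
  if (!all(df$source %in% c("cue", "net"))) {
    abort("spike-train file has invalid source labels")
  }
  new_spike_train(tibble::tibble(time_ms = df$time_ms,
                                 unit = df$unit + 1L,
                                 source = df$source),
                  n_units = as.integer(meta$n_units),
                  duration = as.double(meta$duration),
                  dt = as.double(meta$dt), seed = meta$seed)
}

#' Write a run manifest
#'
#' JSON record sufficient to re-run an experiment bit-identically: the
#' configuration snapshot, the seeds, the package version and an md5 checksum
#' per output file.
#'
#' @param path manifest path.
#' @param config named list of configuration values.
#' @param seeds named list/vector of seeds per stream.
#' @param files character vector of output files to checksum.
#' @export
write_manifest <- function(path, config, seeds, files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "phasereplay",
    version = as.character(packageVersion("phasereplay")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = seeds,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
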