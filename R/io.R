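# Minimal RIFF/WAVE I/O for IEEE float32 mono traces. Only the dialect this
# package writes (and the common PCM16 variant) is read; anything else is
# rejected with a descriptive error rather than guessed at.

write_wav_float32 <- function(samples, sample_rate_hz, path) {
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * n
  # RIFF size: 4 ("WAVE") + (8+16) fmt + (8+4) fact + (8+data)
  riff_size <- 4L + 24L + 12L + 8L + data_bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riff_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # 3 = IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(sample_rate_hz)), con, size = 4, endian = "little")
  writeBin(as.integer(round(sample_rate_hz) * 4L), con, size = 4,
           endian = "little")                      # byte rate
  writeBin(4L, con, size = 2, endian = "little")   # block align
  writeBin(32L, con, size = 2, endian = "little")  # bits per sample
  writeChar("fact", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "RIFF")) stop(sprintf("not a RIFF file: %s", path))
  readBin(con, "integer", 1L, size = 4, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE")) {
    stop(sprintf("not a WAVE file: %s", path))
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", 1L, size = 2, endian = "little",
                       signed = FALSE),
        channels = readBin(con, "integer", 1L, size = 2, endian = "little"),
        rate = readBin(con, "integer", 1L, size = 4, endian = "little"))
      readBin(con, "raw", size - 8L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt")
      if (fmt$channels != 1L) {
        stop(sprintf("only mono WAV is supported; file has %d channels",
                     fmt$channels))
      }
      if (fmt$code == 3L) {
        samples <- readBin(con, "numeric", size %/% 4L, size = 4,
                           endian = "little")
      } else if (fmt$code == 1L) {
        samples <- readBin(con, "integer", size %/% 2L, size = 2,
                           endian = "little") / 32768
      } else {
        stop(sprintf("unsupported WAV format code %d (want 3 = IEEE float)",
                     fmt$code))
      }
      break
    } else {
      readBin(con, "raw", size + size %% 2L)  # chunks are word-aligned
    }
  }
  if (is.null(samples)) stop(sprintf("no data chunk found in %s", path))
  list(samples = samples, sample_rate_hz = fmt$rate)
}

sidecar_path <- function(wav_path) paste0(tools::file_path_sans_ext(wav_path),
                                          ".json")

#' Read a recording from a WAV file
#'
#' Reads a mono WAV trace, divides the raw values by the calibration factor
#' to obtain acceleration in m/s^2 (calibration defaults to 1), and attaches
#' metadata. Metadata is taken from, in increasing precedence, the sidecar
#' JSON written by \code{\link{write_recording}} (if present) and the
#' \code{meta} argument.
#'
#' @param wav_path path to a mono WAV file (IEEE float32 or PCM16)
#' @param meta optional \code{\link{recording_meta}}; fields set here
#'   override the sidecar
#' @return a \code{\link{recording}}
#' @export
read_recording <- function(wav_path, meta = NULL) {
  wav <- read_wav(wav_path)
  if (!all(is.finite(wav$samples))) {
    stop(sprintf("non-finite samples in %s", wav_path))
  }
  sc <- sidecar_path(wav_path)
  base <- if (file.exists(sc)) {
    fields <- jsonlite::fromJSON(sc)
    do.call(recording_meta, fields[!vapply(fields, is.null, logical(1))])
  } else {
    recording_meta()
  }
  if (!is.null(meta)) {
    stopifnot(inherits(meta, "recording_meta"))
    for (nm in names(meta)) {
      supplied <- meta[[nm]]
      if (!(length(supplied) == 1L && is.na(supplied))) base[[nm]] <- supplied
    }
  }
  base$source_path <- wav_path
  cal <- base$calibration
  if (is.na(cal)) cal <- 1
  recording(wav$samples / cal, wav$sample_rate_hz, base)
}

#' Write a recording to a WAV file with a JSON sidecar
#'
#' Writes a 32-bit IEEE float mono WAV at the recording's sample rate, plus
#' a sidecar JSON (same path, \code{.json} extension) holding every
#' metadata field.
#'
#' @param rec a \code{\link{recording}}
#' @param wav_path destination path
#' @return the path, invisibly
#' @export
write_recording <- function(rec, wav_path) {
  stopifnot(inherits(rec, "recording"))
  write_wav_float32(rec$samples, rec$sample_rate_hz, wav_path)
  meta <- rec$meta
  meta$spec <- NULL  # nested spec objects stay in-memory only
  jsonlite::write_json(unclass(meta), sidecar_path(wav_path),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(wav_path)
}

#' Write a cohort manifest CSV
#'
#' One row per recording mirroring the metadata fields, with the WAV path.
#'
#' @param recordings list of \code{\link{recording}} objects
#' @param dir output directory (created if needed); WAVs are written there
#' @return path of the manifest CSV, invisibly
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(rec) {
    p <- file.path(dir, paste0(rec$meta$recording_id, ".wav"))
    write_recording(rec, p)
    data.frame(recording_id = rec$meta$recording_id, group = rec$meta$group,
               clutch_id = rec$meta$clutch_id,
               excitation_type = rec$meta$excitation_type,
               replicate = rec$meta$replicate,
               distance_cm = rec$meta$distance_cm,
               calibration = rec$meta$calibration,
               wav_path = p, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
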