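#' Construct an audio recording
#'
#' Container for a mono auscultation signal: amplitude samples (roughly in
#' \[-1, 1\]), sampling rate in Hz, and patient / record identifiers used for
#' patient-wise cross-validation grouping.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling frequency in Hz (> 0).
#' @param patient_id,record_id Opaque identifier strings (may be empty).
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, rate, patient_id = "", record_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  structure(
    list(samples = samples, rate = rate,
         patient_id = as.character(patient_id),
         record_id = as.character(record_id)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  if (nzchar(x$patient_id)) cat(sprintf("  patient %s", x$patient_id))
  cat("\n")
  invisible(x)
}

# ---- WAV (RIFF) reading and writing -----------------------------------------
# Minimal RIFF/WAVE codec: PCM 8/16/24/32-bit and IEEE float32/64, chunk walk,
# first channel only. No R package for WAV is available in the dependency set.

.read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(id = id, size = size)
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 8/16/24/32-bit or IEEE float) and returns the
#' first channel as floating-point amplitudes in \[-1, 1\] at the file's native
#' rate. The patient identifier is parsed from the ICBHI filename convention:
#' the first underscore-separated token of the base name (e.g.
#' `"101_1b1_Al_sc_Meditron.wav"` gives patient `"101"`).
#'
#' @param path Path to a readable WAV file.
#' @return An [audio_recording].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- tryCatch(.read_chunk_header(con), error = function(e) NULL)
  if (is.null(riff) || !identical(riff$id, "RIFF"))
    stop("not a RIFF/WAVE file: ", path)
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; samples <- NULL
  repeat {
    hdr <- tryCatch(.read_chunk_header(con), error = function(e) NULL)
    if (is.null(hdr) || length(hdr$size) == 0L || !nzchar(hdr$id)) break
    if (identical(hdr$id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", hdr$size)
      u16 <- function(i) sum(as.integer(raw_fmt[i + 0:1]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(raw_fmt[i + 0:3]) * 256^(0:3))
      fmt <- list(format = u16(1L), channels = u16(3L),
                  rate = u32(5L), bits = u16(15L))
    } else if (identical(hdr$id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      bytes_per <- fmt$bits / 8
      n_total <- floor(hdr$size / bytes_per)
      if (fmt$format == 1L) {                       # integer PCM
        if (fmt$bits == 8L) {
          v <- readBin(con, "integer", n_total, size = 1L, signed = FALSE)
          x <- (v - 128) / 128
        } else if (fmt$bits == 16L) {
          v <- readBin(con, "integer", n_total, size = 2L,
                       signed = TRUE, endian = "little")
          x <- v / 32768
        } else if (fmt$bits == 24L) {
          raw <- readBin(con, "raw", n_total * 3L)
          b <- matrix(as.integer(raw), nrow = 3L)
          v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
          v <- ifelse(v >= 2^23, v - 2^24, v)
          x <- v / 2^23
        } else if (fmt$bits == 32L) {
          v <- readBin(con, "integer", n_total, size = 4L, endian = "little")
          x <- v / 2^31
        } else stop("unsupported PCM bit depth: ", fmt$bits)
      } else if (fmt$format == 3L) {                # IEEE float
        x <- readBin(con, "numeric", n_total, size = bytes_per,
                     endian = "little")
      } else stop("unsupported WAV audio format code: ", fmt$format)
      if (fmt$channels > 1L)
        x <- x[seq(1L, length(x), by = fmt$channels)]  # channel 0 only
      samples <- x
    } else {
      if (hdr$size < 0) stop("malformed WAV chunk in ", path)
      seek(con, hdr$size + hdr$size %% 2, origin = "current")
    }
    if (!is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples) || length(samples) == 0L)
    stop("malformed or truncated WAV file: ", path)

  base <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  toks <- strsplit(base, "_", fixed = TRUE)[[1]]
  patient <- if (length(toks) >= 2L) toks[1] else ""
  audio_recording(samples, fmt$rate, patient_id = patient, record_id = base)
}

#' Write a mono WAV file
#'
#' Writes samples as 16-bit PCM (default) or 32-bit IEEE float mono WAV.
#' Values outside \[-1, 1\] are clipped before quantization.
#'
#' @param x An [audio_recording] or a numeric vector.
#' @param path Output file path.
#' @param rate Sampling rate in Hz; taken from `x` when it is a recording.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate = NULL, bits = 16L) {
  if (inherits(x, "audio_recording")) {
    rate <- x$rate; x <- x$samples
  }
  if (is.null(rate)) stop("rate must be supplied when x is a plain vector")
  x <- pmin(1, pmax(-1, as.numeric(x)))
  n <- length(x)
  fmt_code <- if (bits == 16L) 1L else if (bits == 32L) 3L else
    stop("bits must be 16 or 32")
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  for (v in c(fmt_code, 1L)) writeBin(v, con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4L, endian = "little")
  for (v in c(as.integer(bytes_per), as.integer(bits)))
    writeBin(v, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmin(32767, round(x * 32768)))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- annotations ------------------------------------------------------------

#' Parse an ICBHI-style annotation file
#'
#' Each non-empty row has four whitespace-separated columns: cycle start (s),
#' cycle end (s), crackle flag (0/1), wheeze flag (0/1).
#'
#' @param path Path to the annotation text file.
#' @return A data frame with columns `start`, `end`, `crackle`, `wheeze`
#'   (one row per respiratory cycle, in file order).
#' @export
parse_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(start = numeric(0), end = numeric(0),
                    crackle = logical(0), wheeze = logical(0))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) < 4L)
      stop(sprintf("annotation line %d: expected 4 columns, got %d",
                   i, length(toks)))
    vals <- suppressWarnings(as.numeric(toks[1:4]))
    if (any(is.na(vals[1:2])))
      stop(sprintf("annotation line %d: non-numeric start/end", i))
    if (!(vals[1] >= 0 && vals[1] < vals[2]))
      stop(sprintf("annotation line %d: need 0 <= start < end", i))
    out[nrow(out) + 1L, ] <- list(vals[1], vals[2],
                                  vals[3] != 0, vals[4] != 0)
  }
  out
}

#' Write an ICBHI-style annotation file
#'
#' @param anns Data frame with `start`, `end`, `crackle`, `wheeze` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(anns, path) {
  lines <- sprintf("%.3f\t%.3f\t%d\t%d", anns$start, anns$end,
                   as.integer(anns$crackle), as.integer(anns$wheeze))
  writeLines(lines, path)
  invisible(path)
}

# ---- resampling -------------------------------------------------------------

#' Resample a recording
#'
#' Polyphase FIR (anti-aliased) rate conversion. The output length is forced
#' to `round(n * target_rate / rate)`.
#'
#' @param rec An [audio_recording].
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return An [audio_recording] at `target_rate`.
#' @export
resample_audio <- function(rec, target_rate) {
  stopifnot(inherits(rec, "audio_recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("target_rate must be a single positive number")
  if (target_rate == rec$rate) return(rec)
  n_out <- round(length(rec$samples) * target_rate / rec$rate)
  frac <- .rat_approx(target_rate / rec$rate)
  y <- signal::resample(rec$samples, frac[1], frac[2])
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else
    y <- c(y, numeric(n_out - length(y)))
  audio_recording(y, target_rate, rec$patient_id, rec$record_id)
}

# small-denominator rational approximation of a positive ratio
.rat_approx <- function(r, max_den = 1000L) {
  best <- c(round(r), 1L); best_err <- abs(r - best[1])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    err <- abs(r - p / q)
    if (err < best_err - 1e-12) { best <- c(p, q); best_err <- err }
    if (best_err < 1e-9) break
  }
  as.integer(best)
}

# ---- respiratory cycles -----------------------------------------------------

#' Map crackle/wheeze flags to the four-class label
#'
#' The class taxonomy is total and exclusive: (FALSE, FALSE) -> `"normal"`,
#' (TRUE, FALSE) -> `"crackle"`, (FALSE, TRUE) -> `"wheeze"`,
#' (TRUE, TRUE) -> `"both"`.
#'
#' @param crackle,wheeze Logical flags (vectorized).
#' @return Character vector of labels.
#' @export
label4_from_flags <- function(crackle, wheeze) {
  ifelse(crackle & wheeze, "both",
         ifelse(crackle, "crackle",
                ifelse(wheeze, "wheeze", "normal")))
}

#' Construct a fixed-length labelled respiratory cycle
#'
#' @param samples Numeric vector of exactly `round(rate * duration)` values.
#' @param rate Sampling rate in Hz.
#' @param duration Cycle duration in seconds.
#' @param patient_id Patient identifier string.
#' @param crackle,wheeze Logical annotation flags.
#' @return An object of class `respiratory_cycle`.
#' @export
respiratory_cycle <- function(samples, rate, duration, patient_id,
                              crackle, wheeze) {
  n_target <- round(rate * duration)
  if (length(samples) != n_target)
    stop(sprintf("cycle must have round(rate*duration) = %d samples, got %d",
                 n_target, length(samples)))
  structure(
    list(samples = as.numeric(samples), rate = rate, duration = duration,
         patient_id = as.character(patient_id),
         label4 = label4_from_flags(isTRUE(crackle), isTRUE(wheeze)),
         crackle = isTRUE(crackle), wheeze = isTRUE(wheeze)),
    class = "respiratory_cycle"
  )
}

#' @export
print.respiratory_cycle <- function(x, ...) {
  cat(sprintf("<respiratory_cycle> %gs @ %g Hz, patient %s, label %s\n",
              x$duration, x$rate, x$patient_id, x$label4))
  invisible(x)
}

#' Cut a recording into fixed-duration labelled cycles
#'
#' Each annotated segment `[start, end)` is converted to samples with
#' `floor(start * rate)` indexing (half-open, so adjacent cycles never
#' overlap), zero-padded at the end when shorter than `duration`, and
#' truncated at the end when longer. Annotations extending beyond the
#' recording are clipped to the recording end with a warning, then padded.
#'
#' @param rec An [audio_recording] already at the working rate.
#' @param anns Annotation data frame from [parse_annotations()].
#' @param duration Fixed cycle duration in seconds (default 6).
#' @return A list of [respiratory_cycle] objects, one per annotation row.
#' @export
extract_cycles <- function(rec, anns, duration = 6) {
  stopifnot(inherits(rec, "audio_recording"))
  if (duration <= 0) stop("duration must be positive")
  n_target <- round(rec$rate * duration)
  n_rec <- length(rec$samples)
  out <- vector("list", nrow(anns))
  for (i in seq_len(nrow(anns))) {
    i0 <- floor(anns$start[i] * rec$rate) + 1L
    i1 <- floor(anns$end[i] * rec$rate)       # half-open [start, end)
    if (i1 > n_rec) {
      warning(sprintf(
        "annotation %d extends past the recording end; clipped and padded", i))
      i1 <- n_rec
    }
    seg <- if (i0 <= i1) rec$samples[i0:i1] else numeric(0)
    if (length(seg) >= n_target) seg <- seg[seq_len(n_target)]
    else seg <- c(seg, numeric(n_target - length(seg)))
    out[[i]] <- respiratory_cycle(seg, rec$rate, duration, rec$patient_id,
                                  anns$crackle[i], anns$wheeze[i])
  }
  out
}
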