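#' Stereo recording container
#'
#' Holds a two-channel audio signal as normalized floating-point amplitudes
#' (full scale is \[-1, 1\]) together with its sample rate. This is the raw
#' container before nasal/oral roles are attached; see [channel_map()] and
#' [assign_channels()].
#'
#' @param left,right Numeric vectors of equal length with finite values,
#'   nominally within \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (positive).
#' @return An object of class `stereo_recording`: a list with elements
#'   `left`, `right` and `sample_rate`.
#' @export
stereo_recording <- function(left, right, sample_rate) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right)) {
    stop("channels must have equal length (", length(left), " vs ",
         length(right), ")")
  }
  if (!all(is.finite(left)) || !all(is.finite(right))) {
    stop("amplitudes must be finite")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  structure(list(left = left, right = right, sample_rate = sample_rate),
            class = "stereo_recording")
}

#' @export
print.stereo_recording <- function(x, ...) {
  cat(sprintf("<stereo_recording> %d samples/channel @ %g Hz (%.3f s)\n",
              length(x$left), x$sample_rate, length(x$left) / x$sample_rate))
  invisible(x)
}

#' Nasal/oral channel assignment
#'
#' Declares which physical channel of a stereo recording carries the nasal
#' microphone and which the oral one. The two roles must differ.
#'
#' @param nasal `"left"` or `"right"`; the oral role is the other channel.
#' @return An object of class `channel_map` with elements `nasal` and `oral`.
#' @export
channel_map <- function(nasal = c("left", "right")) {
  nasal <- match.arg(nasal)
  oral <- if (nasal == "left") "right" else "left"
  structure(list(nasal = nasal, oral = oral), class = "channel_map")
}

#' Dual-channel recording with nasal/oral semantics
#'
#' @param nasal,oral Numeric amplitude vectors of equal length, finite values.
#' @param sample_rate Sampling rate in Hz (positive).
#' @return An object of class `dual_recording`.
#' @export
dual_recording <- function(nasal, oral, sample_rate) {
  nasal <- as.numeric(nasal)
  oral <- as.numeric(oral)
  if (length(nasal) != length(oral)) {
    stop("nasal and oral channels must have equal length")
  }
  if (!all(is.finite(nasal)) || !all(is.finite(oral))) {
    stop("amplitudes must be finite")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a single positive number")
  }
  structure(list(nasal = nasal, oral = oral, sample_rate = sample_rate),
            class = "dual_recording")
}

#' @export
print.dual_recording <- function(x, ...) {
  cat(sprintf("<dual_recording> %d samples/channel @ %g Hz (%.3f s)\n",
              length(x$nasal), x$sample_rate, length(x$nasal) / x$sample_rate))
  invisible(x)
}

#' Attach nasal/oral roles to a stereo recording
#'
#' Selects channels according to the map without altering any sample values.
#'
#' @param rec A [stereo_recording()].
#' @param map A [channel_map()]; default assigns nasal to the left channel.
#' @return A [dual_recording()].
#' @export
assign_channels <- function(rec, map = channel_map("left")) {
  stopifnot(inherits(rec, "stereo_recording"), inherits(map, "channel_map"))
  dual_recording(nasal = rec[[map$nasal]], oral = rec[[map$oral]],
                 sample_rate = rec$sample_rate)
}

#' Swap nasal and oral roles
#'
#' @param rec A [dual_recording()].
#' @return A [dual_recording()] with channels exchanged.
#' @export
swap_channels <- function(rec) {
  stopifnot(inherits(rec, "dual_recording"))
  dual_recording(nasal = rec$oral, oral = rec$nasal,
                 sample_rate = rec$sample_rate)
}

# 16-bit PCM quantization. Symmetric divisor 32768 so -1.0 is reachable;
# +1.0 clips to 32767 (one LSB below full scale).
.pcm16_encode <- function(x) {
  q <- round(x * 32768)
  as.integer(pmin.int(pmax.int(q, -32768), 32767))
}

.pcm16_decode <- function(q) q / 32768

.clamp_audio <- function(x, what) {
  if (any(x > 1 | x < -1)) {
    warning(what, ": amplitudes outside [-1, 1] clamped before quantization")
    x <- pmin(pmax(x, -1), 1)
  }
  x
}

#' Read a stereo PCM WAV file
#'
#' Parses a RIFF/WAVE container holding uncompressed 16-bit integer PCM with
#' exactly two channels. Samples are returned as normalized floats
#' (divisor 32768) and the sample rate is taken from the header.
#'
#' @param path Path to the WAV file.
#' @return A [stereo_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1) {
    stop("unsupported WAV encoding (", fmt$audio_format, "); only PCM is supported")
  }
  if (fmt$n_channels != 2) {
    stop("expected 2 channels, found ", fmt$n_channels)
  }
  if (fmt$bits != 16) stop("unsupported bit depth: ", fmt$bits)
  n <- length(data_raw) %/% 2
  ints <- readBin(data_raw, "integer", n, size = 2, signed = TRUE,
                  endian = "little")
  x <- .pcm16_decode(ints)
  stereo_recording(left = x[seq(1, length(x), by = 2)],
                   right = x[seq(2, length(x), by = 2)],
                   sample_rate = fmt$sample_rate)
}

#' Write a stereo recording as a PCM WAV file
#'
#' Amplitudes outside \[-1, 1\] are clamped with a warning. At 16-bit depth
#' [read_wav()] inverts this function exactly.
#'
#' @param rec A [stereo_recording()].
#' @param path Output path.
#' @param bit_depth Bits per sample; only 16 is supported.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bit_depth = 16) {
  stopifnot(inherits(rec, "stereo_recording"))
  if (bit_depth != 16) stop("unsupported bit depth: ", bit_depth)
  left <- .clamp_audio(rec$left, "write_wav")
  right <- .clamp_audio(rec$right, "write_wav")
  inter <- integer(2 * length(left))
  inter[seq(1, length(inter), by = 2)] <- .pcm16_encode(left)
  inter[seq(2, length(inter), by = 2)] <- .pcm16_encode(right)

  n_bytes <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(2L, con, size = 2, endian = "little")            # channels
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}

#' Read headerless raw PCM stereo audio
#'
#' Decodes 16-bit signed little-endian interleaved stereo (the dialect the
#' mobile recorder writes). The container carries no header, so the sample
#' rate must be supplied.
#'
#' @param path Path to the .pcm file.
#' @param sample_rate Sampling rate in Hz (default 44100, the recorder's rate).
#' @param bit_depth Bits per sample; only 16 is supported.
#' @return A [stereo_recording()].
#' @export
read_raw_pcm <- function(path, sample_rate = 44100, bit_depth = 16) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (bit_depth != 16) stop("unsupported bit depth: ", bit_depth)
  sz <- file.size(path)
  bytes_per_frame <- 2 * bit_depth / 8
  if (sz %% bytes_per_frame != 0) {
    stop("file size (", sz, " bytes) is not a whole number of interleaved ",
         "stereo frames (", bytes_per_frame, " bytes each)")
  }
  ints <- readBin(path, "integer", sz / 2, size = 2, signed = TRUE,
                  endian = "little")
  x <- .pcm16_decode(ints)
  stereo_recording(left = x[seq(1, length(x), by = 2)],
                   right = x[seq(2, length(x), by = 2)],
                   sample_rate = sample_rate)
}

#' Write headerless raw PCM stereo audio
#'
#' Serializes as 16-bit signed little-endian interleaved stereo;
#' [read_raw_pcm()] inverts it exactly.
#'
#' @inheritParams write_wav
#' @return `path`, invisibly.
#' @export
write_raw_pcm <- function(rec, path, bit_depth = 16) {
  stopifnot(inherits(rec, "stereo_recording"))
  if (bit_depth != 16) stop("unsupported bit depth: ", bit_depth)
  left <- .clamp_audio(rec$left, "write_raw_pcm")
  right <- .clamp_audio(rec$right, "write_raw_pcm")
  inter <- integer(2 * length(left))
  inter[seq(1, length(inter), by = 2)] <- .pcm16_encode(left)
  inter[seq(2, length(inter), by = 2)] <- .pcm16_encode(right)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}
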