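# Minimal RIFF/WAVE reader and writer: 16/24-bit integer and 32-bit IEEE
# float PCM in, float (default) or 16-bit PCM out. Mono is the package
# currency; multichannel files are refused unless explicitly downmixed.

#' Read a WAV file
#'
#' Supports 16-bit and 24-bit integer PCM and 32-bit IEEE float, mono by
#' default. Samples are returned on the nominal \eqn{[-1, 1]} full scale.
#'
#' @param path input file.
#' @param downmix average channels of a multichannel file instead of
#'   refusing it.
#' @return \code{audio_buffer}.
#' @export
read_wav <- function(path, downmix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF")
    stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE")
    stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = .le_uint(raw, 1, 2), channels = .le_uint(raw, 3, 2),
        fs = .le_uint(raw, 5, 4), bits = .le_uint(raw, 15, 2))
    } else if (tag == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      samples <- .decode_pcm(readBin(con, "raw", size), fmt)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path, call. = FALSE)
  if (fmt$channels > 1) {
    if (!downmix)
      stop("multichannel WAV; pass downmix = TRUE to average channels",
           call. = FALSE)
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  audio_buffer(samples, fmt$fs)
}

.le_uint <- function(raw, at, n) {
  sum(as.integer(raw[at:(at + n - 1)]) * 256^(0:(n - 1)))
}

.decode_pcm <- function(raw, fmt) {
  if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(raw, "double", length(raw) / 4, 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(raw, "integer", length(raw) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    n <- length(raw) / 3
    m <- matrix(as.integer(raw), nrow = 3)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bits)",
                 fmt$format, fmt$bits), call. = FALSE)
  }
}

#' Write a WAV file
#'
#' Writes mono 32-bit IEEE float (default, lossless for this package's
#' signals) or 16-bit integer PCM.
#'
#' @param x \code{audio_buffer}.
#' @param path output file.
#' @param bits 32 (float) or 16 (integer PCM).
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(x, path, bits = 32) {
  stopifnot(inherits(x, "audio_buffer"), bits %in% c(16, 32))
  fs <- round(x$fs)
  n <- length(x$samples)
  bytes <- bits / 8
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w_u <- function(v, size) writeBin(as.integer(v), con, size, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u(36 + data_size, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u(16, 4)
  w_u(if (bits == 32) 3 else 1, 2); w_u(1, 2)     # format, mono
  w_u(fs, 4); w_u(fs * bytes, 4)                  # rate, byte rate
  w_u(bytes, 2); w_u(bits, 2)                     # block align, bits
  writeChar("data", con, eos = NULL); w_u(data_size, 4)
  if (bits == 32) writeBin(x$samples, con, 4, endian = "little")
  else w_u(pmin(pmax(round(x$samples * 32767), -32768), 32767), 2)
  invisible(path)
}
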