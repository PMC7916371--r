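# Butterworth filters in second-order sections (SOS). The synthesis band
# filters run at orders up to 12 on narrow bands, where flat polynomial
# (b, a) coefficients are numerically fragile; cascaded biquads derived from
# the analog prototype poles via the bilinear transform stay stable at any
# order used here.

# Analog Butterworth prototype poles (unit cutoff), order n, left half-plane.
.butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

#' Design a Butterworth low- or high-pass filter in second-order sections
#'
#' Analog-prototype design with pre-warped cutoff and bilinear transform,
#' returned as cascaded biquads. Only even orders are supported (all filters
#' in the processing chain have even order).
#'
#' @param n filter order (even, >= 2).
#' @param fc -3 dB cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param type \code{"low"} or \code{"high"}.
#' @return matrix with one row per biquad and columns
#'   \code{b0, b1, b2, a1, a2} (the leading denominator coefficient is 1).
#' @export
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stop_if_not_scalar_pos(fc, "fc")
  stop_if_not_scalar_pos(fs, "fs")
  if (fc >= fs / 2) stop("cutoff `fc` must be below Nyquist", call. = FALSE)
  if (n %% 2 != 0 || n < 2) stop("order `n` must be even and >= 2", call. = FALSE)

  wc <- tan(pi * fc / fs)              # pre-warped cutoff (T = 2 convention)
  proto <- .butter_proto_poles(n)
  pairs <- proto[Im(proto) > 0]        # one pole per conjugate pair
  sos <- t(vapply(pairs, function(p) {
    pa <- if (type == "low") wc * p else wc / p
    zp <- (1 + pa) / (1 - pa)          # bilinear s -> z
    a1 <- -2 * Re(zp)
    a2 <- Mod(zp)^2
    if (type == "low") {               # double zero at z = -1, unity at DC
      g <- (1 + a1 + a2) / 4
      c(g, 2 * g, g, a1, a2)
    } else {                           # double zero at z = +1, unity at Nyquist
      g <- (1 - a1 + a2) / 4
      c(g, -2 * g, g, a1, a2)
    }
  }, numeric(5)))
  colnames(sos) <- c("b0", "b1", "b2", "a1", "a2")
  sos
}

#' Apply a second-order-section cascade causally
#'
#' @param sos biquad matrix from \code{\link{butter_sos}} (rows may be
#'   stacked from several filters).
#' @param x numeric signal.
#' @return filtered signal, same length, zero initial conditions.
#' @export
sos_filter <- function(sos, x) {
  as.numeric(sosfilt_cpp(sos, as.numeric(x)))
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos biquad matrix.
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
sos_response <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)     # z^{-1}
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[[i, "b0"]] + sos[[i, "b1"]] * z1 + sos[[i, "b2"]] * z1^2
    den <- 1 + sos[[i, "a1"]] * z1 + sos[[i, "a2"]] * z1^2
    h <- h * num / den
  }
  h
}

# First-order IIR high-pass with exact -3 dB point at fc (pre-emphasis).
# Returns list(b, a).
.first_order_highpass <- function(fc, fs) {
  wc <- tan(pi * fc / fs)
  zp <- (1 - wc) / (1 + wc)
  g <- (1 + zp) / 2
  list(b = c(g, -g), a = c(1, -zp))
}

# Band filter for one synthesis channel: an order-N high-pass at f_low
# cascaded with an order-N low-pass at f_high, so each skirt decays at
# -6N dB/oct. Returns a stacked SOS matrix.
band_filter_sos <- function(f_low, f_high, order, fs) {
  rbind(butter_sos(order, f_low, fs, "high"),
        butter_sos(order, f_high, fs, "low"))
}

#' Resample an audio signal between two rates
#'
#' Polyphase rational-ratio resampling. The processing rate 50000/3 Hz and
#' the 44.1-kHz I/O rate have the exact ratio 500:1323, recovered here by
#' scaling both rates by 3 before reducing by the greatest common divisor.
#'
#' @param x numeric signal or \code{audio_buffer}.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return resampled numeric vector (or \code{audio_buffer} in, buffer out).
#' @export
resample_audio <- function(x, fs_in, fs_out) {
  buf <- inherits(x, "audio_buffer")
  if (buf) { fs_in <- x$fs; s <- x$samples } else s <- x
  if (isTRUE(all.equal(fs_in, fs_out))) {
    return(if (buf) x else s)
  }
  # express both rates as integers (rates used here are k or k/3 Hz)
  p <- fs_out * 3; q <- fs_in * 3
  if (max(abs(p - round(p)), abs(q - round(q))) > 1e-6)
    stop("sampling rates must be rational multiples of 1/3 Hz", call. = FALSE)
  p <- round(p); q <- round(q)
  g <- .gcd(p, q)
  y <- as.numeric(signal::resample(s, p / g, q / g))
  n_out <- round(length(s) * fs_out / fs_in)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, numeric(n_out - length(y)))
  if (buf) audio_buffer(y, fs_out) else y
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
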