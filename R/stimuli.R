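# Stimulus generators: calibrated pure tones, gated masker-probe sequences
# for forward masking, SNR mixing, a babble-like cocktail-party surrogate,
# and synthetic two-syllable word tokens. All generators are deterministic
# under a fixed seed.

#' Calibration between digital full scale and sound pressure level
#'
#' A single affine map used consistently across a simulated session:
#' amplitude = 10^((level_dB_SPL - offset) / 20). With the default offset,
#' digital full scale (0 dB FS) corresponds to 110 dB SPL, so a 65-dB SPL
#' presentation sits at -45 dB FS.
#'
#' @param dbfs_to_dbspl_offset dB SPL at digital full scale (default 110).
#' @return object of class \code{calibration_map}.
#' @export
calibration_map <- function(dbfs_to_dbspl_offset = 110) {
  structure(list(offset = dbfs_to_dbspl_offset), class = "calibration_map")
}

#' Convert dB SPL to linear digital amplitude under a calibration map
#' @param level_db_spl level in dB SPL.
#' @param cal a \code{calibration_map}.
#' @return linear peak-equivalent amplitude.
#' @export
spl_to_amplitude <- function(level_db_spl, cal = calibration_map()) {
  db2lin(level_db_spl - cal$offset)
}

#' Generate a calibrated pure tone
#'
#' Sinusoid with zero initial phase whose RMS level maps to the requested
#' dB SPL under the calibration map.
#'
#' @param f frequency in Hz (0 < f < fs/2).
#' @param dur duration in seconds.
#' @param level_db_spl presentation level in dB SPL.
#' @param fs sampling rate in Hz.
#' @param cal a \code{calibration_map}.
#' @return \code{audio_buffer} of \code{round(dur * fs)} samples.
#' @export
pure_tone <- function(f, dur, level_db_spl = 65, fs = 44100,
                      cal = calibration_map()) {
  stop_if_not_scalar_pos(f, "f")
  stop_if_not_scalar_pos(dur, "dur")
  if (f >= fs / 2) stop("tone frequency at or above Nyquist", call. = FALSE)
  n <- round(dur * fs)
  amp <- spl_to_amplitude(level_db_spl, cal) * sqrt(2)  # RMS-referenced
  audio_buffer(amp * sin(2 * pi * f * (0:(n - 1)) / fs), fs)
}

#' Apply raised-cosine-squared onset/offset ramps
#'
#' Multiplies the first and last \code{ramp} seconds by sin^2-shaped gates
#' (0 at the first sample, full scale at the ramp end, 0.5 mid-ramp); the
#' interior is untouched. Gating is not idempotent: gating twice shortens
#' the effective plateau.
#'
#' @param x \code{audio_buffer}.
#' @param ramp ramp duration in seconds (default 4 ms).
#' @return gated \code{audio_buffer}.
#' @export
raised_cos2_gate <- function(x, ramp = 0.004) {
  nr <- round(ramp * x$fs)
  n <- length(x$samples)
  if (n < 2 * nr) stop("signal shorter than two gating ramps", call. = FALSE)
  g <- sin(pi * (0:(nr - 1)) / (2 * (nr - 1)))^2
  s <- x$samples
  s[1:nr] <- s[1:nr] * g
  s[(n - nr + 1):n] <- s[(n - nr + 1):n] * rev(g)
  audio_buffer(s, x$fs)
}

#' Specification of a forward-masking masker-probe stimulus
#'
#' A 110-ms masker tone immediately followed (no gap) by a 20-ms probe tone,
#' both gated with 4-ms raised-cosine-squared ramps.
#'
#' @param fm masker frequency in Hz.
#' @param fp probe frequency in Hz (default 2226, the activation centre of
#'   channel 8).
#' @param masker_level_db_spl,probe_level_db_spl presentation levels.
#' @param masker_dur,probe_dur,gate_dur segment durations in seconds.
#' @return object of class \code{masker_probe_spec}.
#' @export
masker_probe_spec <- function(fm, fp = 2226, masker_level_db_spl = 60,
                              probe_level_db_spl = 40, masker_dur = 0.110,
                              probe_dur = 0.020, gate_dur = 0.004) {
  if (gate_dur > masker_dur / 2 || gate_dur > probe_dur / 2)
    stop("gate duration must be at most half of each segment", call. = FALSE)
  structure(list(fm = fm, fp = fp,
                 masker_level_db_spl = masker_level_db_spl,
                 probe_level_db_spl = probe_level_db_spl,
                 masker_dur = masker_dur, probe_dur = probe_dur,
                 gate_dur = gate_dur),
            class = "masker_probe_spec")
}

#' Build a vocoded masker(-probe) interval
#'
#' Generates the gated masker tone, optionally followed without gap by the
#' gated probe tone, passes the sequence through the vocoder, and re-gates
#' the processed output to suppress temporal artifacts. The masker segment of
#' the input is sample-identical whether or not the probe is appended, so in
#' a forced-choice trial the only cue is the probe itself.
#'
#' @param spec \code{masker_probe_spec}.
#' @param with_probe logical; append the probe?
#' @param cfg \code{vocoder_config}; \code{cfg$fs_out} sets the output rate.
#' @param table \code{channel_table}.
#' @param cal \code{calibration_map}.
#' @param raw if TRUE skip the vocoder and return the input sequence.
#' @return \code{audio_buffer}; attribute \code{probe_window} gives the
#'   probe onset/offset in seconds.
#' @export
masker_probe_sequence <- function(spec, with_probe = TRUE,
                                  cfg = vocoder_config(),
                                  table = build_channel_table(),
                                  cal = calibration_map(), raw = FALSE) {
  fs <- cfg$fs_proc
  if (spl_to_amplitude(spec$masker_level_db_spl, cal) * sqrt(2) > 1 ||
      spl_to_amplitude(spec$probe_level_db_spl, cal) * sqrt(2) > 1)
    stop("requested level exceeds digital full scale under the calibration",
         call. = FALSE)
  masker <- raised_cos2_gate(
    pure_tone(spec$fm, spec$masker_dur, spec$masker_level_db_spl, fs, cal),
    spec$gate_dur)
  if (with_probe) {
    probe <- raised_cos2_gate(
      pure_tone(spec$fp, spec$probe_dur, spec$probe_level_db_spl, fs, cal),
      spec$gate_dur)
    x <- audio_buffer(c(masker$samples, probe$samples), fs)
  } else {
    # same total duration so intervals are comparable
    x <- audio_buffer(c(masker$samples, numeric(round(spec$probe_dur * fs))),
                      fs)
  }
  out <- if (raw) x else raised_cos2_gate(vocode(x, cfg, table), spec$gate_dur)
  attr(out, "probe_window") <- c(spec$masker_dur,
                                 spec$masker_dur + spec$probe_dur)
  out
}

#' Mix speech and noise at a target signal-to-noise ratio
#'
#' The noise is cropped (seeded random offset when longer than the speech)
#' and scaled so that the full-duration RMS ratio of speech to scaled noise
#' equals \code{snr_db}; the sum is returned.
#'
#' @param speech,noise \code{audio_buffer}s at the same rate; the noise must
#'   be at least as long as the speech.
#' @param snr_db target SNR in dB.
#' @param seed seed for the random noise crop (NULL: start at the beginning).
#' @return mixed \code{audio_buffer} with attribute \code{noise_scale}.
#' @export
mix_at_snr <- function(speech, noise, snr_db, seed = NULL) {
  if (!isTRUE(all.equal(speech$fs, noise$fs)))
    stop("speech and noise must share a sampling rate", call. = FALSE)
  ns <- length(speech$samples); nn <- length(noise$samples)
  if (nn < ns) stop("noise must be at least as long as the speech", call. = FALSE)
  start <- if (nn == ns) 1L else if (is.null(seed)) 1L else
    with_local_seed(seed, sample.int(nn - ns + 1L, 1L))
  ncrop <- noise$samples[start:(start + ns - 1L)]
  rs <- rms(speech$samples); rn <- rms(ncrop)
  if (rs == 0 || rn == 0) stop("zero-RMS input", call. = FALSE)
  scale <- rs / (rn * db2lin(snr_db))
  out <- audio_buffer(speech$samples + scale * ncrop, speech$fs)
  attr(out, "noise_scale") <- scale
  out
}

#' Synthetic cocktail-party noise surrogate
#'
#' Babble-like masker built from independent amplitude-modulated
#' speech-band noise streams (syllabic-rate modulators, 2--10 Hz band with
#' most energy at 4--8 Hz) plus sparse high-frequency transient bursts
#' standing in for tableware clinks. The long-term spectrum is shaped like
#' the long-term speech spectrum (flat below 500 Hz, about -9 dB/oct above).
#' Deterministic under a fixed seed.
#'
#' @param dur duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param n_streams number of independent talker-like streams (>= 8).
#' @param rms_out output RMS (linear full scale).
#' @return \code{audio_buffer}.
#' @export
cocktail_noise <- function(dur, fs = 44100, seed = 1L, n_streams = 8L,
                           rms_out = 0.05) {
  stop_if_not_scalar_pos(dur, "dur")
  n <- round(dur * fs)
  shape <- rbind(butter_sos(2, 100, fs, "high"),
                 matrix(.speech_tilt_sos(500, fs), nrow = 1))
  mod_sos <- butter_sos(4, 8, fs, "low")
  hp_burst <- butter_sos(4, 2000, fs, "high")
  with_local_seed(seed, {
    y <- numeric(n)
    for (k in seq_len(n_streams)) {
      carrier <- sos_filter(shape, stats::rnorm(n))
      m <- sos_filter(mod_sos, stats::rnorm(n))
      m <- m / stats::sd(m)
      mod <- pmax(1 + 1.2 * m, 0)        # fluctuating, occasionally silent
      y <- y + carrier * mod
    }
    y <- y / rms(y)
    # sparse transients: ~1.5 clink-like bursts per second
    n_burst <- stats::rpois(1, 1.5 * dur)
    if (n_burst > 0) {
      for (b in seq_len(n_burst)) {
        bl <- round(stats::runif(1, 0.008, 0.030) * fs)
        at <- sample.int(max(n - bl, 1L), 1L)
        burst <- sos_filter(hp_burst, stats::rnorm(bl)) *
          sin(pi * (0:(bl - 1)) / (bl - 1))^2
        burst <- burst / rms(burst) * stats::runif(1, 3, 5)
        idx <- at:(at + bl - 1L)
        y[idx] <- y[idx] + burst
      }
    }
    audio_buffer(y / rms(y) * rms_out, fs)
  })
}

# One-pole low-pass giving ~ -6 dB/oct tilt above fc; cascaded twice where a
# steeper speech-spectrum rolloff is wanted. Encoded as a first-order SOS row.
.speech_tilt_sos <- function(fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  c(1 - a, 0, 0, -a, 0)
}

#' Synthetic two-syllable word token
#'
#' Stand-in for recorded dissyllabic test words: two voiced harmonic
#' complexes with distinct seeded formant targets, separated by a low-energy
#' gap carrying a brief unvoiced burst. Total duration 400--700 ms,
#' deterministic under a fixed seed.
#'
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @param rms_out output RMS (linear full scale).
#' @return \code{audio_buffer}.
#' @export
word_token <- function(seed = 1L, fs = 44100, rms_out = 0.05) {
  with_local_seed(seed, {
    f0 <- stats::runif(1, 100, 140)
    syl_dur <- stats::runif(2, 0.14, 0.24)
    gap_dur <- stats::runif(1, 0.05, 0.09)
    syl <- lapply(1:2, function(i) {
      formants <- c(stats::runif(1, 300, 800), stats::runif(1, 900, 2400),
                    stats::runif(1, 2400, 3200))
      .voiced_syllable(f0, syl_dur[i], formants, fs)
    })
    ng <- round(gap_dur * fs)
    gap <- stats::rnorm(ng) * 0.002
    bl <- round(0.015 * fs)
    at <- max(1L, ng %/% 2 - bl %/% 2)
    burst <- sos_filter(butter_sos(4, 1500, fs, "high"), stats::rnorm(bl)) *
      sin(pi * (0:(bl - 1)) / (bl - 1))^2
    gap[at:(at + bl - 1L)] <- gap[at:(at + bl - 1L)] + 0.15 * burst / rms(burst)
    y <- c(syl[[1]]$samples, gap, syl[[2]]$samples)
    out <- raised_cos2_gate(audio_buffer(y, fs), 0.004)
    audio_buffer(out$samples / rms(out$samples) * rms_out, fs)
  })
}

# Harmonic complex with gaussian formant peaks (log-amplitude) on a -6 dB/oct
# source tilt, shaped by a raised-cosine syllable envelope.
.voiced_syllable <- function(f0, dur, formants, fs, bw = c(90, 120, 160)) {
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  h <- seq_len(floor(min(fs / 2 * 0.9, 5000) / f0))
  fh <- h * f0
  amp_db <- -6 * log2(fh / f0)
  for (k in seq_along(formants))
    amp_db <- amp_db + 25 * exp(-0.5 * ((fh - formants[k]) / bw[k])^2)
  amp <- db2lin(amp_db - max(amp_db))
  y <- numeric(n)
  for (i in seq_along(h)) y <- y + amp[i] * sin(2 * pi * fh[i] * t)
  # soft syllabic contour; clamp tiny negative fp residues of sin at pi
  envl <- pmax(sin(pi * (0:(n - 1)) / (n - 1)), 0)^0.7
  audio_buffer(y * envl, fs)
}
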