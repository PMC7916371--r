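# Simulated listeners for the forced-choice experiments. Two families:
# response-model listeners defined directly by a psychometric function
# (fast; used for staircase validation) and the vocoder listener, which
# analyses the three audio intervals like the experiment's human subjects
# would and produces V-shaped tuning curves.

.new_listener <- function(type, fields) {
  structure(c(list(type = type), fields), class = c(type, "listener"))
}

#' @export
print.listener <- function(x, ...) {
  cat(sprintf("listener <%s>: threshold %.1f dB SPL, max level %.1f dB SPL\n",
              x$type, x$hearing_threshold_db, x$max_level_db))
  invisible(x)
}

#' Response-model listeners
#'
#' \code{ideal_listener} always detects the probe; \code{guessing_listener}
#' never does (long-run accuracy 1/3); \code{threshold_listener} is correct
#' exactly while the masker is below a fixed level T;
#' \code{psychometric_listener} follows a logistic psychometric function
#' positioned so that performance is 70.7\% correct at \code{l707} (the
#' convergence point of the two-up one-down rule), falling from 100\% towards
#' the 1/3 guessing floor as the masker level rises.
#'
#' @param l707 masker level (dB SPL) at which the listener is 70.7\% correct.
#' @param slope_db logistic spread in dB (smaller = steeper).
#' @param T deterministic masking level for \code{threshold_listener}.
#' @param hearing_threshold_db,max_level_db nominal audibility floor and
#'   maximum acceptable level used by the PTC engine for calibration.
#' @return listener object with a \code{p_correct(level)} response model.
#' @name response_listeners
NULL

#' @rdname response_listeners
#' @export
ideal_listener <- function(hearing_threshold_db = 25, max_level_db = 95) {
  .new_listener("ideal_listener", list(
    p_correct = function(level) 1,
    hearing_threshold_db = hearing_threshold_db,
    max_level_db = max_level_db, dynamic_range_fraction_probe = 0.20))
}

#' @rdname response_listeners
#' @export
guessing_listener <- function(hearing_threshold_db = 25, max_level_db = 95) {
  .new_listener("guessing_listener", list(
    p_correct = function(level) 1 / 3,
    hearing_threshold_db = hearing_threshold_db,
    max_level_db = max_level_db, dynamic_range_fraction_probe = 0.20))
}

#' @rdname response_listeners
#' @export
threshold_listener <- function(T, hearing_threshold_db = 25,
                               max_level_db = 95) {
  force(T)
  .new_listener("threshold_listener", list(
    p_correct = function(level) if (level < T) 1 else 1 / 3,
    masking_level = T,
    hearing_threshold_db = hearing_threshold_db,
    max_level_db = max_level_db, dynamic_range_fraction_probe = 0.20))
}

#' @rdname response_listeners
#' @export
psychometric_listener <- function(l707, slope_db = 2,
                                  hearing_threshold_db = 25,
                                  max_level_db = 95) {
  # place the logistic so that p(l707) = sqrt(1/2)
  c707 <- (sqrt(0.5) - 1 / 3) / (2 / 3)
  alpha <- l707 + slope_db * stats::qlogis(c707)
  .new_listener("psychometric_listener", list(
    p_correct = function(level)
      1 / 3 + (2 / 3) * stats::plogis(-(level - alpha) / slope_db),
    l707 = l707,
    hearing_threshold_db = hearing_threshold_db,
    max_level_db = max_level_db, dynamic_range_fraction_probe = 0.20))
}

#' Simulated listener that analyses the vocoded audio
#'
#' Decision model for the 3IFC forward-masking task: each interval is passed
#' through the listener's own channel analysis (the same 20-band short-time
#' RMS filter bank as the processor). Per channel, two levels are computed
#' in dB: the level in the probe time window (plus a short smoothing tail)
#' and the level in the late masker window. Forward masking is modelled as
#' excitation persistence: the effective level in the probe window is
#' floored at the masker-window level minus \code{forward_masking_db} (the
#' decay of masker excitation over the masker-probe gap), and at the
#' audibility threshold. The detection statistic of an interval is the
#' maximum, over the attended channels, of its effective-level increment
#' above the per-channel median across the three intervals (the masker-only
#' template), corrupted by Gaussian internal noise in dB; the listener
#' chooses the interval with the largest statistic. Performance is at
#' chance when the probe's increment vanishes against the masker's own
#' excitation and its trial-to-trial carrier fluctuations, and grows with
#' the probe-to-masking margin; because the masker's excitation reaches the
#' attended band through the spread-dependent carrier skirts, the resulting
#' tuning curves are V-shaped and flatten as the spread of excitation
#' broadens.
#'
#' @param internal_noise_sd internal decision noise SD in dB.
#' @param hearing_threshold_db audibility floor in dB SPL.
#' @param max_level_db maximum acceptable level in dB SPL.
#' @param forward_masking_db decay (dB) of masker excitation between the
#'   late-masker window and the probe decision window.
#' @param attend_octaves half-width (octaves) of the attended frequency
#'   region around the probe: the decision statistic is taken over channels
#'   whose centre lies within this distance of the probe frequency,
#'   emulating a trained listener who knows what to listen for. NULL
#'   attends to all channels.
#' @param tail_s analysis-window extension beyond the probe offset in
#'   seconds, covering envelope-smoothing decay.
#' @param onset_skip_s analysis-window start relative to the probe onset, in
#'   seconds; skipping the first few milliseconds keeps analysis frames that
#'   straddle the masker offset (and its full-level energy) out of the
#'   decision window.
#' @return listener object with a \code{respond(stimuli, context)} method.
#' @export
vocoder_listener <- function(internal_noise_sd = 1, hearing_threshold_db = 25,
                             max_level_db = 95, forward_masking_db = 25,
                             attend_octaves = 0.6,
                             tail_s = 0.012, onset_skip_s = 0.006) {
  self <- .new_listener("vocoder_listener", list(
    internal_noise_sd = internal_noise_sd,
    hearing_threshold_db = hearing_threshold_db,
    max_level_db = max_level_db,
    forward_masking_db = forward_masking_db,
    attend_octaves = attend_octaves,
    dynamic_range_fraction_probe = 0.20,
    tail_s = tail_s, onset_skip_s = onset_skip_s))
  self$respond <- function(stimuli, context) {
    pw <- context$probe_window
    probe_win <- c(pw[1] + self$onset_skip_s, pw[2] + self$tail_s)
    # late-masker window: steady excitation just before the masker offset
    mask_win <- c(max(pw[1] - 0.045, 0), pw[1] - 0.006)
    lv <- vapply(stimuli, function(b) {
      bl <- .band_levels(b, context)
      lp <- .window_level(bl, probe_win)
      lm <- .window_level(bl, mask_win)
      pmax(lp, lm - self$forward_masking_db, self$hearing_threshold_db)
    }, numeric(20))                                         # 20 x 3
    att <- rep(TRUE, nrow(lv))
    fp <- context$fp
    if (!is.null(self$attend_octaves) && !is.null(fp)) {
      fc <- context$table$analysis$f_center[
        match(seq_len(nrow(lv)), context$table$analysis$channel)]
      att <- abs(log2(fc / fp)) <= self$attend_octaves
    }
    template <- apply(lv, 1, stats::median)
    stat <- apply((lv - template)[att, , drop = FALSE], 2, max) +
      stats::rnorm(3, 0, self$internal_noise_sd)
    which.max(stat)
  }
  self
}

# Calibrated short-time band levels of one interval: 20 x frames matrix in
# dB SPL. The filter bank reports windowed bin magnitudes; the factor
# 2/sum(w) calibrates them so a full-scale sinusoid at a bin centre reads
# ~0 dB FS.
.band_levels <- function(buf, context) {
  cfg <- context$cfg
  if (!isTRUE(all.equal(buf$fs, cfg$fs_proc)))
    buf <- resample_audio(buf, buf$fs, cfg$fs_proc)
  env <- channel_envelopes(buf, cfg, context$table)
  gain <- sum(.hamming_window(cfg$frame_len)) / 2
  lv <- context$cal$offset + 20 * log10(pmax(t(env) / gain, 1e-12))
  attr(lv, "frame_times") <- attr(env, "frame_times")
  lv
}

# Per-channel RMS level (dB) over the frames whose centres fall in a window.
.window_level <- function(band_levels, win) {
  tt <- attr(band_levels, "frame_times")
  sel <- tt >= win[1] & tt <= win[2]
  if (!any(sel)) sel <- rep(TRUE, length(tt))
  amp <- 10^(band_levels[, sel, drop = FALSE] / 20)
  20 * log10(sqrt(rowMeans(amp^2)))
}
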