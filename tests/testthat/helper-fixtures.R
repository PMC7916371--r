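# Shared fixtures: everything is built in code at test time.

fs_proc <- 50000 / 3

tone_buffer <- function(f, dur = 0.3, amp = 0.1, fs = fs_proc) {
  audio_buffer(amp * sin(2 * pi * f * (0:(round(dur * fs) - 1)) / fs), fs)
}

noise_buffer <- function(dur = 0.5, fs = fs_proc, seed = 1, amp = 0.1) {
  set.seed(seed)
  audio_buffer(amp * rnorm(round(dur * fs)), fs)
}

# Noiseless two-sided quadratic PTC on the protocol masker grid, with known
# 10-dB half-widths on each side of the tip.
synthetic_quadratic_ptc <- function(tip_level = 30, half_low = 278.25,
                                    half_high = 278.25, fp = 2226,
                                    fm = masker_frequencies()) {
  th <- ifelse(fm <= fp,
               tip_level + 10 * ((fm - fp) / half_low)^2,
               tip_level + 10 * ((fm - fp) / half_high)^2)
  data.frame(fm = fm, threshold_db_spl = th)
}
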