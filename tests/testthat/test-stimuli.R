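test_that("pure tones have the requested duration, level and limits", {
  x <- pure_tone(2226, 3, 65, fs = 44100)
  expect_length(x$samples, 3 * 44100)
  # +6 dB doubles the amplitude (x2 within rounding)
  a1 <- max(abs(pure_tone(1000, 0.1, 60)$samples))
  a2 <- max(abs(pure_tone(1000, 0.1, 66)$samples))
  expect_equal(a2 / a1, 10^(6 / 20), tolerance = 1e-6)
  # calibration: 0 dB FS reference at 110 dB SPL
  expect_equal(rms(pure_tone(1000, 1, 110)), 1, tolerance = 1e-3)
  expect_error(pure_tone(0, 1), "positive")
  expect_error(pure_tone(30000, 1, fs = 44100), "Nyquist")
})

test_that("raised-cosine-squared gating has the exact ramp profile", {
  fs <- 10250                                # 4-ms ramp = 41 samples (odd)
  x <- audio_buffer(rep(1, fs), fs)          # constant-1, 1 s
  g <- raised_cos2_gate(x, ramp = 0.004)
  nr <- round(0.004 * fs)
  expect_equal(g$samples[1], 0)
  expect_equal(g$samples[nr], 1)             # full scale at ramp end
  expect_equal(g$samples[(nr + 1) / 2], 0.5) # sin^2(pi/4) mid-ramp
  expect_equal(g$samples[nr + 50], 1)        # interior untouched
  # double gating shortens the effective plateau: not idempotent
  g2 <- raised_cos2_gate(g, ramp = 0.004)
  expect_lt(sum(g2$samples), sum(g$samples))
  expect_error(raised_cos2_gate(audio_buffer(rep(1, 10), fs), 0.004),
               "shorter")
})

test_that("masker-probe sequences differ only by the probe", {
  spec <- masker_probe_spec(1637, masker_level_db_spl = 60,
                            probe_level_db_spl = 45)
  cfg <- vocoder_config(seed = 3)
  with_p <- masker_probe_sequence(spec, TRUE, cfg, raw = TRUE)
  no_p <- masker_probe_sequence(spec, FALSE, cfg, raw = TRUE)
  fs <- with_p$fs
  nm <- round(spec$masker_dur * fs)
  expect_identical(with_p$samples[1:nm], no_p$samples[1:nm])
  expect_length(with_p$samples, length(no_p$samples))
  expect_equal(length(with_p$samples) / fs, 0.130, tolerance = 1e-3)
  expect_true(all(no_p$samples[(nm + 1):length(no_p$samples)] == 0))
  expect_equal(attr(with_p, "probe_window"), c(0.110, 0.130))
  expect_error(masker_probe_spec(1637, gate_dur = 0.02), "half")
})

test_that("on-frequency probe and masker excite the same channel", {
  spec <- masker_probe_spec(2226, 2226, masker_level_db_spl = 60,
                            probe_level_db_spl = 60)
  cfg <- vocoder_config(seed = 3)
  cfg$fs_out <- cfg$fs_proc
  ct <- build_channel_table()
  y <- masker_probe_sequence(spec, TRUE, cfg, ct)
  env <- channel_envelopes(y, cfg, ct)
  tt <- attr(env, "frame_times")
  masker_frames <- tt > 0.02 & tt < 0.09
  probe_frames <- tt > 0.115 & tt < 0.128
  peak_m <- which.max(colMeans(env[masker_frames, ]))
  peak_p <- which.max(colMeans(env[probe_frames, ]))
  expect_equal(peak_m, peak_p)
  expect_equal(peak_m, 8)
})

test_that("SNR mixing hits the requested ratio exactly", {
  s <- noise_buffer(dur = 0.5, seed = 1)
  n <- noise_buffer(dur = 0.5, seed = 2)
  # equal length, equal RMS construction
  n$samples <- n$samples * rms(s) / rms(n)
  m0 <- mix_at_snr(s, n, 0)
  expect_equal(attr(m0, "noise_scale"), 1, tolerance = 1e-9)
  m6 <- mix_at_snr(s, n, 6)
  expect_equal(attr(m6, "noise_scale"), 10^(-6 / 20), tolerance = 1e-9)
  # round trip at the speech-test SNR grid
  for (snr in c(-3, 3, 9)) {
    m <- mix_at_snr(s, n, snr)
    sc <- attr(m, "noise_scale")
    achieved <- 20 * log10(rms(s) / (sc * rms(n)))
    expect_equal(achieved, snr, tolerance = 0.01)
  }
  expect_error(mix_at_snr(s, audio_buffer(n$samples, 22050), 0), "rate")
  expect_error(mix_at_snr(audio_buffer(rep(0, 100), fs_proc),
                          audio_buffer(rep(1, 100), fs_proc), 0), "zero-RMS")
  # longer noise is cropped deterministically under a seed
  long_n <- noise_buffer(dur = 1, seed = 3)
  expect_identical(mix_at_snr(s, long_n, 3, seed = 5)$samples,
                   mix_at_snr(s, long_n, 3, seed = 5)$samples)
})

test_that("cocktail noise is seeded, modulated and peaky", {
  a <- cocktail_noise(1.5, fs = 16000, seed = 7)
  b <- cocktail_noise(1.5, fs = 16000, seed = 7)
  expect_identical(a$samples, b$samples)
  # modulation spectrum peaks in the syllabic 2-10 Hz range
  envl <- abs(a$samples)
  envl <- sos_filter(butter_sos(2, 30, 16000, "low"), envl)
  sp <- Mod(stats::fft(envl - mean(envl)))^2
  fr <- (seq_along(sp) - 1) / 1.5
  band <- function(lo, hi) max(sp[fr >= lo & fr <= hi])
  expect_gt(band(2, 10), band(10.5, 40))
  # crest factor above a stationary Gaussian of equal RMS
  set.seed(7)
  gauss <- rnorm(length(a$samples))
  gauss <- gauss / rms(gauss) * rms(a$samples)
  crest <- function(x) max(abs(x)) / rms(x)
  expect_gt(crest(a$samples), crest(gauss))
})

test_that("word tokens are seeded two-syllable objects that survive vocoding", {
  w1 <- word_token(seed = 3, fs = 16000)
  w2 <- word_token(seed = 3, fs = 16000)
  expect_identical(w1$samples, w2$samples)
  dur <- length(w1$samples) / w1$fs
  expect_gte(dur, 0.33)
  expect_lte(dur, 0.70)
  # energy contour: two voiced segments separated by a low-energy gap
  n <- length(w1$samples)
  seg <- floor(seq(1, n, length.out = 41))
  e <- sapply(1:40, function(i)
    rms(w1$samples[seg[i]:seg[i + 1]]))
  e <- e / max(e)
  gap <- which.min(e[8:32]) + 7        # interior minimum
  expect_lt(e[gap], 0.35)
  expect_gt(max(e[1:(gap - 1)]), 0.5)
  expect_gt(max(e[(gap + 1):40]), 0.5)
  # survives vocoding with energy in several channels
  cfg <- vocoder_config(n_maxima = 16, spread = "low", seed = 2)
  cfg$fs_out <- cfg$fs_proc
  y <- vocode(word_token(seed = 3, fs = 44100), cfg)
  env <- channel_envelopes(y, cfg)
  expect_gte(sum(colSums(env) > 0.01 * max(colSums(env))), 4)
})
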