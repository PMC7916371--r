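ct <- build_channel_table()

test_that("frame arithmetic matches the processor description", {
  cfg <- vocoder_config()
  expect_equal(round(cfg$frame_len / cfg$fs_proc * 1000, 1), 7.7)   # ms
  expect_equal(round(cfg$hop / cfg$fs_proc * 1000, 1), 1.9)         # ms
  expect_equal(round(cfg$fs_proc / cfg$frame_len, 1), 130.2)        # Hz
  expect_equal(cfg$hop, 32L)
})

test_that("pre-emphasis is a high-pass with its -3 dB point at fc", {
  x <- tone_buffer(4000, dur = 0.3)
  y_hi <- preemphasize(x, 1200)
  x_lo <- tone_buffer(400, dur = 0.3)
  y_lo <- preemphasize(x_lo, 1200)
  expect_gt(rms(y_hi) / rms(x), rms(y_lo) / rms(x_lo))
  expect_length(y_hi$samples, length(x$samples))
  expect_equal(preemphasize(audio_buffer(rep(0, 1000), fs_proc))$samples,
               rep(0, 1000))
  # frequency-response probe of the implemented filter
  gains <- sapply(seq(1000, 1400, by = 10), function(f) {
    z <- tone_buffer(f, dur = 0.5)
    rms(preemphasize(z, 1200)$samples[2000:8000]) /
      rms(z$samples[2000:8000])
  })
  f3 <- seq(1000, 1400, by = 10)[which.min(abs(20 * log10(gains) +
                                                 10 * log10(2)))]
  expect_lt(abs(f3 - 1200) / 1200, 0.01)
  expect_error(preemphasize(x, 9000), "Nyquist")
})

test_that("channel envelopes localise a tone and vanish for silence", {
  cfg <- vocoder_config()
  env <- channel_envelopes(tone_buffer(2214), cfg, ct)
  interior <- env[20:(nrow(env) - 20), ]
  expect_true(all(apply(interior, 1, which.max) == 8))
  env0 <- channel_envelopes(audio_buffer(rep(0, 5000), fs_proc), cfg, ct)
  expect_true(all(env0 == 0))
  expect_error(channel_envelopes(audio_buffer(rep(0.1, 64), fs_proc), cfg, ct),
               "shorter")
})

test_that("broadband noise excites all 20 channels on average", {
  cfg <- vocoder_config()
  env <- channel_envelopes(noise_buffer(dur = 1, seed = 2), cfg, ct)
  expect_gte(nrow(env), 100)
  expect_true(all(colMeans(env) > 0))
})

test_that("maxima selection keeps the n largest and applies the 45-dB floor", {
  amps <- c(1.0, 0.5, 0.1, 0.001, rep(0, 16))
  env <- matrix(amps, nrow = 1)
  expect_equal(select_maxima(env, 3)[1, 1:4], c(1.0, 0.5, 0.1, 0))
  # 0.001 survives the rank cut at n = 4 but not the floor:
  # 0.001 < 1.0 * 10^(-45/20) ~= 0.00562
  expect_equal(select_maxima(env, 4)[1, 4], 0)
  # identity when everything is within 45 dB of the maximum
  env2 <- matrix(runif(40, 0.5, 1), nrow = 2)
  expect_equal(select_maxima(env2, 20), env2)
  expect_error(select_maxima(env, 0), "1..20")
  expect_error(select_maxima(env, 21), "1..20")
})

test_that("selection ties at the n-th rank go to the lower channel index", {
  env <- matrix(0, nrow = 1, ncol = 20)
  env[1, c(3, 9, 15)] <- 0.5   # three-way tie, n = 2
  out <- select_maxima(env, 2)
  expect_equal(which(out[1, ] > 0), c(3, 9))
})

test_that("sparsity holds for every configured number of maxima", {
  env <- channel_envelopes(noise_buffer(dur = 0.4, seed = 3),
                           vocoder_config(), ct)
  for (n in c(4, 8, 12, 16)) {
    sel <- select_maxima(env, n)
    expect_true(all(rowSums(sel > 0) <= n))
  }
})

test_that("overlap-add reconstruction is constant for constant frame RMS", {
  cfg <- vocoder_config()
  env <- matrix(0, nrow = 200, ncol = 20)
  env[, 5] <- 0.4
  rec <- reconstruct_envelopes(env, cfg)
  interior <- rec[3000:5000, 5]
  expect_lt(max(abs(interior - 0.4)) / 0.4, 0.01)
  expect_true(all(rec >= 0))
  expect_equal(reconstruct_envelopes(matrix(0, 50, 20), cfg),
               matrix(0, (50 - 1) * 32 + 128, 20))
})

test_that("a single nonzero frame yields a bounded smoothed bump", {
  cfg <- vocoder_config()
  env <- matrix(0, nrow = 60, ncol = 20)
  env[30, 8] <- 1
  rec <- reconstruct_envelopes(env, cfg)
  expect_lte(max(rec[, 8]), 1)
  expect_gt(max(rec[, 8]), 0)
  # energy concentrated around the frame, allowing for filter ringing
  peak_at <- which.max(rec[, 8])
  frame_centre <- 29 * 32 + 64
  expect_lt(abs(peak_at - frame_centre) / fs_proc, 0.015)
})

test_that("carriers are seeded, unit-RMS and band-limited", {
  c1 <- make_carriers(ct, "low", 5000, seed = 9)
  c2 <- make_carriers(ct, "low", 5000, seed = 9)
  expect_identical(c1, c2)
  c3 <- make_carriers(ct, "low", 5000, seed = 10)
  expect_false(identical(c1, c3))
  expect_equal(apply(c1, 2, function(x) sqrt(mean(x^2))), rep(1, 20),
               tolerance = 1e-9)
})

test_that("synthesis levels output energy to the input and guards clipping", {
  env <- matrix(0.05, nrow = 5000, ncol = 20)
  car <- make_carriers(ct, "medium", 5000, seed = 1)
  xref <- noise_buffer(dur = 5000 / fs_proc, seed = 5)
  y <- synthesize(env, car, xref)
  expect_equal(rms(y), rms(xref), tolerance = 1e-3)
  # forced clipping: a reference with huge RMS but the peak rule active
  xloud <- audio_buffer(rep(c(2, -2), 2500), fs_proc)
  y2 <- synthesize(env, car, xloud)
  expect_equal(max(abs(y2$samples)), 1, tolerance = 1e-12)
  expect_error(synthesize(env[1:100, ], car, xref), "dimensions")
  # silent input -> silent output
  y0 <- synthesize(matrix(0, 5000, 20), car,
                   audio_buffer(rep(1e-15, 5000), fs_proc))
  expect_lt(max(abs(y0$samples)), 1e-12)
})

test_that("the full chain conserves energy and is deterministic", {
  cfg <- vocoder_config(n_maxima = 20, spread = "low", seed = 7)
  cfg$fs_out <- cfg$fs_proc
  x <- tone_buffer(2226, dur = 0.4)
  y1 <- vocode(x, cfg, ct)
  y2 <- vocode(x, cfg, ct)
  expect_identical(y1$samples, y2$samples)
  expect_lt(abs(rms(y1) - rms(x)) / rms(x), 1e-3)
})

test_that("a vocoded on-centre tone concentrates energy in its channel", {
  band_frac_outside <- function(spread) {
    cfg <- vocoder_config(n_maxima = 20, spread = spread, seed = 7)
    cfg$fs_out <- cfg$fs_proc
    y <- vocode(tone_buffer(2226, dur = 0.4), cfg, ct)
    n <- length(y$samples)
    spec <- Mod(stats::fft(y$samples))^2
    fr <- (seq_len(n) - 1) * fs_proc / n
    half <- fr < fs_proc / 2
    inband <- fr >= 2018 & fr < 2409
    1 - sum(spec[half & inband]) / sum(spec[half])
  }
  out_low <- band_frac_outside("low")
  out_high <- band_frac_outside("high")
  expect_lt(out_low, 0.5)        # band energy maximum in channel 8's band
  expect_gt(out_high, out_low)   # the spread-of-excitation contract
})

test_that("active-channel counts respect the configured maxima end to end", {
  x <- noise_buffer(dur = 0.3, seed = 8)
  for (n in c(4, 20)) {
    cfg <- vocoder_config(n_maxima = n, spread = "low", seed = 2)
    env <- channel_envelopes(preemphasize(x), cfg, ct)
    sel <- select_maxima(env, cfg$n_maxima, cfg$selection_floor_db)
    expect_true(all(rowSums(sel > 0) <= n))
  }
})
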