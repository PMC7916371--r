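test_that("staircase bookkeeping follows the two-up one-down schedule", {
  cfg <- staircase_config(start_level = 40)
  st <- staircase_init(cfg)
  expect_equal(st$level, 40)

  # two correct in a row raise the level by the 4-dB phase-1 step
  st <- update_staircase(st, TRUE, cfg)
  expect_equal(st$level, 40)               # streak of one: no move yet
  st <- update_staircase(st, TRUE, cfg)
  expect_equal(st$level, 44)
  # one wrong drops immediately and records the first reversal
  st <- update_staircase(st, FALSE, cfg)
  expect_equal(st$level, 40)
  expect_equal(st$reversal_levels, 44)

  # streak resets after a move: correct-wrong-correct-correct climbs once
  st2 <- staircase_init(cfg)
  for (r in c(TRUE, FALSE, TRUE, TRUE))
    st2 <- update_staircase(st2, r, cfg)
  expect_equal(st2$level, 40)              # 40 -4 +4
  expect_equal(length(st2$reversal_levels), 1)
})

test_that("step sizes shrink 4 -> 2 -> 1 dB across reversal phases", {
  cfg <- staircase_config(start_level = 60)
  st <- staircase_init(cfg)
  # alternate two-correct / one-wrong to generate reversals quickly
  moves <- function(st) {
    lv <- numeric(0)
    while (length(st$reversal_levels) < 12 && st$n_trials < 200) {
      st <- update_staircase(st, TRUE, cfg)
      st <- update_staircase(st, TRUE, cfg)
      lv <- c(lv, st$level)
      if (st$finished) break
      st <- update_staircase(st, FALSE, cfg)
      lv <- c(lv, st$level)
    }
    list(state = st, levels = lv)
  }
  res <- moves(st)
  steps <- abs(diff(res$levels))
  # early steps are 4 dB, late ones 1 dB
  expect_equal(steps[1], 4)
  expect_equal(steps[length(steps)], 1)
  expect_true(all(steps %in% c(4, 2, 1)))
  expect_true(res$state$finished)
  expect_equal(length(res$state$reversal_levels), 12)
  expect_error(update_staircase(res$state, TRUE, cfg), "finished")
})

test_that("levels never leave the configured bounds", {
  cfg <- staircase_config(start_level = 50, min_level = 45, max_level = 55)
  st <- staircase_init(cfg)
  set.seed(1)
  for (i in 1:100) {
    if (st$finished) break
    st <- update_staircase(st, runif(1) < 0.8, cfg)
    expect_gte(st$level, 45)
    expect_lte(st$level, 55)
  }
})

test_that("trials are chance-level for a guessing listener and perfect for an ideal one", {
  spec <- masker_probe_spec(2226)
  set.seed(10)
  acc <- mean(replicate(10000,
                        run_trial(guessing_listener(), spec)$correct))
  expect_equal(acc, 1 / 3, tolerance = 0.02)
  expect_true(all(replicate(50, run_trial(ideal_listener(), spec)$correct)))
  # fixed seed reproduces the interval sequence
  seq1 <- local({
    set.seed(5)
    replicate(20, run_trial(guessing_listener(), spec)$interval_presented)
  })
  seq2 <- local({
    set.seed(5)
    replicate(20, run_trial(guessing_listener(), spec)$interval_presented)
  })
  expect_identical(seq1, seq2)
})

test_that("the staircase recovers a deterministic masking level", {
  tl <- threshold_listener(T = 62)
  tf <- ptc_trial_fun(tl, masker_probe_spec(2226))
  cfg <- staircase_config(start_level = 50, min_level = 20, max_level = 95)
  ths <- sapply(1:20, function(s) run_staircase(tf, cfg, seed = s)$threshold)
  expect_true(all(abs(ths - 62) <= 2))
})

test_that("the staircase converges on the 70.7%-correct level", {
  l707 <- 60
  tf <- ptc_trial_fun(psychometric_listener(l707, slope_db = 2),
                      masker_probe_spec(2226))
  cfg <- staircase_config(start_level = 50, min_level = 20, max_level = 95)
  ths <- vapply(1:150, function(s) run_staircase(tf, cfg, seed = s)$threshold,
                numeric(1))
  expect_lt(abs(mean(ths) - l707), 1)
  expect_lt(sd(ths), 2)
})

test_that("runs stop at exactly 12 reversals and flag non-convergence", {
  tf <- ptc_trial_fun(psychometric_listener(60), masker_probe_spec(2226))
  cfg <- staircase_config(start_level = 55, min_level = 20, max_level = 95)
  run <- run_staircase(tf, cfg, seed = 3)
  expect_true(run$converged)
  expect_equal(length(run$reversal_levels), 12)
  expect_equal(run$threshold, mean(run$reversal_levels[7:12]))
  expect_equal(nrow(run$log), run$n_trials)

  # an always-correct listener can never reverse: the cap flags the run
  cfg2 <- staircase_config(start_level = 55, min_level = 20, max_level = 95,
                           max_trials = 60)
  run2 <- run_staircase(ptc_trial_fun(ideal_listener(),
                                      masker_probe_spec(2226)),
                        cfg2, seed = 4)
  expect_false(run2$converged)
  expect_true(is.na(run2$threshold))
})

test_that("the simulated-listener tuning curve dips at the probe frequency", {
  # single short end-to-end check; the full three-spread comparison lives in
  # the acceptance suite
  vl <- vocoder_listener()
  fm3 <- c(1440.5, 2226, 3798)
  m <- measure_ptc(vl, fm_list = fm3, spread = "low", seed = 5)
  expect_equal(nrow(m$points), 3)
  expect_true(all(m$points$converged))
  th <- m$points$threshold_db_spl
  expect_lt(th[2], th[1])   # tip below both edges
  expect_lt(th[2], th[3])
})

test_that("the behavioural threshold track recovers the listener's floor", {
  vl <- vocoder_listener(hearing_threshold_db = 25)
  cfg <- vocoder_config(spread = "low", seed = 2)
  cfg$fs_out <- cfg$fs_proc
  ct <- build_channel_table()
  cal <- calibration_map()
  thr <- measure_hearing_threshold(
    vl,
    function(level) {
      c2 <- cfg; c2$seed <- sample.int(1e6, 1)
      raised_cos2_gate(vocode(raised_cos2_gate(
        pure_tone(2226, 0.02, level, cfg$fs_proc), 0.004), c2, ct), 0.004)
    },
    seed = 9, context = list(cfg = cfg, table = ct, cal = cal, fp = 2226))
  expect_lt(abs(thr - 25), 8)
})
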