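# Forward-masking tuning-curve engine: three-interval forced-choice (3IFC)
# trials, a two-up one-down masker-level staircase with the 4/2/1-dB step
# schedule, and assembly of psychophysical tuning curves (PTCs) against a
# pluggable simulated listener.

#' Staircase configuration
#'
#' Two-up one-down rule on the masker level: the masker is raised (made
#' harder) after two consecutive correct responses and lowered after one
#' error, converging on the 70.7\%-correct point. Steps are 4 dB until the
#' third reversal, 2 dB until the sixth, and 1 dB thereafter; a run ends at
#' 12 reversals and the masked threshold is the mean masker level over the
#' last six.
#'
#' @param start_level starting masker level in dB SPL (protocol: hearing
#'   threshold + 10 dB).
#' @param min_level,max_level clamping bounds in dB SPL.
#' @param steps_db step sizes per phase.
#' @param phase_after_reversals reversal counts at which the step decreases.
#' @param n_reversals_total,n_reversals_averaged protocol constants.
#' @param max_trials non-convergence cap; a run hitting it is flagged.
#' @return object of class \code{staircase_config}.
#' @export
staircase_config <- function(start_level = 40, min_level = 0, max_level = 105,
                             steps_db = c(4, 2, 1),
                             phase_after_reversals = c(3, 6),
                             n_reversals_total = 12,
                             n_reversals_averaged = 6,
                             max_trials = 400) {
  if (any(diff(steps_db) > 0) || any(steps_db <= 0))
    stop("steps must be positive and non-increasing", call. = FALSE)
  if (n_reversals_averaged > n_reversals_total)
    stop("cannot average more reversals than are collected", call. = FALSE)
  structure(list(start_level = start_level, min_level = min_level,
                 max_level = max_level, steps_db = steps_db,
                 phase_after_reversals = phase_after_reversals,
                 n_reversals_total = n_reversals_total,
                 n_reversals_averaged = n_reversals_averaged,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' Initialise staircase bookkeeping
#' @param cfg \code{staircase_config}.
#' @return object of class \code{staircase_state}.
#' @export
staircase_init <- function(cfg = staircase_config()) {
  structure(list(level = cfg$start_level, streak = 0L, last_dir = 0L,
                 reversal_levels = numeric(0), n_trials = 0L,
                 finished = FALSE),
            class = "staircase_state")
}

# Step size for the current phase, keyed on completed reversals.
.current_step <- function(n_reversals, cfg) {
  phase <- findInterval(n_reversals, cfg$phase_after_reversals) + 1L
  cfg$steps_db[min(phase, length(cfg$steps_db))]
}

#' Advance the staircase by one response
#'
#' Two consecutive correct responses raise the masker by the current step
#' (and reset the streak); one wrong response lowers it immediately. A
#' direction flip records a reversal at the just-presented level. Levels are
#' clamped to the configured bounds and the run finishes at the configured
#' reversal count.
#'
#' @param state \code{staircase_state}.
#' @param correct logical response.
#' @param cfg \code{staircase_config}.
#' @return updated \code{staircase_state}.
#' @export
update_staircase <- function(state, correct, cfg = staircase_config()) {
  if (state$finished) stop("staircase already finished", call. = FALSE)
  state$n_trials <- state$n_trials + 1L
  move <- 0
  if (correct) {
    state$streak <- state$streak + 1L
    if (state$streak == 2L) {
      move <- +.current_step(length(state$reversal_levels), cfg)
      state$streak <- 0L
    }
  } else {
    state$streak <- 0L
    move <- -.current_step(length(state$reversal_levels), cfg)
  }
  if (move != 0) {
    dir <- sign(move)
    if (state$last_dir != 0 && dir != state$last_dir) {
      state$reversal_levels <- c(state$reversal_levels, state$level)
      if (length(state$reversal_levels) >= cfg$n_reversals_total)
        state$finished <- TRUE
    }
    state$last_dir <- dir
    state$level <- clamp(state$level + move, cfg$min_level, cfg$max_level)
  }
  state
}

#' Run one 3IFC forward-masking trial
#'
#' The probe interval position is drawn uniformly from \{1, 2, 3\}; the
#' listener receives the three vocoded intervals (or, for response-model
#' listeners, answers from its psychometric function) and the outcome
#' records correctness. Uses the current RNG stream; seed the surrounding
#' run for reproducibility.
#'
#' @param listener a listener object (see \code{\link{vocoder_listener}}).
#' @param spec \code{masker_probe_spec} carrying the current masker level.
#' @param cfg \code{vocoder_config} for stimulus generation.
#' @param table \code{channel_table}.
#' @param cal \code{calibration_map}.
#' @return list with \code{correct}, \code{interval_presented},
#'   \code{interval_chosen}, \code{level}.
#' @export
run_trial <- function(listener, spec, cfg = vocoder_config(),
                      table = build_channel_table(),
                      cal = calibration_map()) {
  probe_pos <- sample.int(3L, 1L)
  if (!is.null(listener$p_correct)) {
    p <- listener$p_correct(spec$masker_level_db_spl)
    chosen <- if (stats::runif(1) < p) probe_pos else
      sample(setdiff(1:3, probe_pos), 1L)
  } else {
    stimuli <- lapply(1:3, function(i) {
      icfg <- cfg
      icfg$seed <- sample.int(.Machine$integer.max, 1L)
      masker_probe_sequence(spec, with_probe = (i == probe_pos), icfg,
                            table, cal)
    })
    context <- list(probe_window = attr(stimuli[[1]], "probe_window"),
                    fp = spec$fp, cfg = cfg, table = table, cal = cal)
    chosen <- listener$respond(stimuli, context)
  }
  list(correct = (chosen == probe_pos), interval_presented = probe_pos,
       interval_chosen = chosen, level = spec$masker_level_db_spl)
}

#' Run a complete adaptive staircase
#'
#' Repeats trials under the two-up one-down rule until the configured number
#' of reversals (or the trial cap, in which case the run is flagged as
#' non-converged). The masked threshold is the mean masker level at the last
#' \code{n_reversals_averaged} reversals.
#'
#' @param trial_fun function(level) -> list with element \code{correct}; use
#'   \code{\link{ptc_trial_fun}} for the vocoded forward-masking task.
#' @param cfg \code{staircase_config}.
#' @param seed integer seed for the whole run (NULL: current stream).
#' @return list with \code{threshold}, \code{converged},
#'   \code{reversal_levels}, \code{n_trials} and the per-trial \code{log}
#'   data.frame.
#' @export
run_staircase <- function(trial_fun, cfg = staircase_config(), seed = NULL) {
  with_local_seed(seed, {
    state <- staircase_init(cfg)
    log <- vector("list", cfg$max_trials)
    while (!state$finished && state$n_trials < cfg$max_trials) {
      res <- trial_fun(state$level)
      log[[state$n_trials + 1L]] <- data.frame(
        level = state$level,
        interval_presented = res$interval_presented %||% NA_integer_,
        interval_chosen = res$interval_chosen %||% NA_integer_,
        correct = res$correct)
      state <- update_staircase(state, res$correct, cfg)
    }
    converged <- state$finished
    idx <- seq(to = length(state$reversal_levels),
               length.out = min(cfg$n_reversals_averaged,
                                length(state$reversal_levels)))
    threshold <- if (converged) mean(state$reversal_levels[idx]) else NA_real_
    list(threshold = threshold, converged = converged,
         reversal_levels = state$reversal_levels, n_trials = state$n_trials,
         log = do.call(rbind, log[seq_len(state$n_trials)]))
  })
}

#' Trial closure for the vocoded forward-masking task
#'
#' Binds a listener, stimulus spec and vocoder configuration into the
#' \code{function(level)} interface consumed by \code{\link{run_staircase}}.
#'
#' @inheritParams run_trial
#' @return function(level) -> trial outcome list.
#' @export
ptc_trial_fun <- function(listener, spec, cfg = vocoder_config(),
                          table = build_channel_table(),
                          cal = calibration_map()) {
  force(listener); force(spec); force(cfg); force(table); force(cal)
  function(level) {
    spec$masker_level_db_spl <- level
    run_trial(listener, spec, cfg, table, cal)
  }
}

#' Measure a simulated listener's detection threshold behaviourally
#'
#' Short 1-up-1-down track (converging on 50\% detection) on the unmasked
#' stimulus: each trial presents the stimulus in one of three intervals
#' (the other two silent) and the level moves down after a correct
#' identification, up after an error.
#'
#' @param listener listener object with a \code{respond} method.
#' @param stimulus_fun function(level_db_spl) -> \code{audio_buffer}.
#' @param start_level starting level in dB SPL.
#' @param step_db track step.
#' @param n_reversals reversals collected; the last
#'   \code{n_reversals - 2} are averaged.
#' @param seed integer seed.
#' @param context extra context passed to the listener.
#' @return threshold estimate in dB SPL.
#' @export
measure_hearing_threshold <- function(listener, stimulus_fun,
                                      start_level = 45, step_db = 3,
                                      n_reversals = 8, seed = NULL,
                                      context = list()) {
  with_local_seed(seed, {
    level <- start_level; last_dir <- 0L; reversals <- numeric(0)
    n_trials <- 0L
    while (length(reversals) < n_reversals && n_trials < 200L) {
      n_trials <- n_trials + 1L
      pos <- sample.int(3L, 1L)
      stim <- stimulus_fun(level)
      silence <- audio_buffer(rep(1e-12, length(stim$samples)), stim$fs)
      stimuli <- lapply(1:3, function(i) if (i == pos) stim else silence)
      ctx <- context
      ctx$probe_window <- ctx$probe_window %||%
        c(0, length(stim$samples) / stim$fs)
      chosen <- listener$respond(stimuli, ctx)
      dir <- if (chosen == pos) -1L else +1L
      if (last_dir != 0L && dir != last_dir) reversals <- c(reversals, level)
      last_dir <- dir
      level <- max(level + dir * step_db, 0)
    }
    mean(utils::tail(reversals, max(n_reversals - 2L, 2L)))
  })
}

#' Measure a psychophysical tuning curve
#'
#' One two-up one-down staircase per masker frequency at a fixed probe
#' (default 2226 Hz, channel 8). The probe level is fixed at 20\% of the
#' listener's dynamic range above its detection threshold; each staircase
#' starts 10 dB above the masker detection threshold.
#'
#' @param listener listener object.
#' @param fp probe frequency in Hz.
#' @param fm_list masker frequencies (default the seven activation-band
#'   midpoints of channels 11..5).
#' @param spread spread label or \code{spread_level} for the vocoder.
#' @param cfg \code{vocoder_config} template; the spread is overridden and
#'   the output is kept at the processing rate for the listener's analysis.
#' @param staircase \code{staircase_config} template; start level and bounds
#'   are derived from the listener's thresholds.
#' @param seed integer seed; each masker's staircase draws its own stream
#'   from it.
#' @param table \code{channel_table}.
#' @param cal \code{calibration_map}.
#' @param thresholds \code{"model"} uses the listener's nominal detection
#'   threshold for calibration; \code{"measure"} re-measures it behaviourally
#'   with \code{\link{measure_hearing_threshold}} before the run.
#' @return object of class \code{ptc_measurement}: list with \code{points}
#'   (data.frame \code{fm}, \code{threshold_db_spl}, \code{n_trials},
#'   \code{n_reversals}, \code{converged}), \code{fp}, \code{spread},
#'   \code{probe_level_db_spl}, \code{seed}.
#' @export
measure_ptc <- function(listener, fp = 2226, fm_list = NULL, spread = "low",
                        cfg = vocoder_config(), staircase = staircase_config(),
                        seed = 1L, table = build_channel_table(),
                        cal = calibration_map(),
                        thresholds = c("model", "measure")) {
  thresholds <- match.arg(thresholds)
  if (is.null(fm_list)) fm_list <- masker_frequencies(table)
  cfg$spread <- as_spread(spread)
  cfg$fs_out <- cfg$fs_proc
  thr <- listener$hearing_threshold_db
  if (thresholds == "measure") {
    probe_cfg <- cfg
    thr <- measure_hearing_threshold(
      listener,
      function(level) {
        sp <- masker_probe_spec(fp, fp, probe_level_db_spl = level)
        p <- raised_cos2_gate(
          pure_tone(fp, sp$probe_dur, level, cfg$fs_proc, cal), sp$gate_dur)
        pcfg <- probe_cfg
        pcfg$seed <- sample.int(.Machine$integer.max, 1L)
        raised_cos2_gate(vocode(p, pcfg, table), sp$gate_dur)
      },
      seed = seed + 7L,
      context = list(cfg = cfg, table = table, cal = cal, fp = fp))
  }
  probe_level <- thr + listener$dynamic_range_fraction_probe *
    (listener$max_level_db - thr)
  pts <- vector("list", length(fm_list))
  for (i in seq_along(fm_list)) {
    scfg <- staircase
    scfg$start_level <- thr + 10
    scfg$min_level <- thr
    scfg$max_level <- listener$max_level_db
    spec <- masker_probe_spec(fm_list[i], fp,
                              masker_level_db_spl = scfg$start_level,
                              probe_level_db_spl = probe_level)
    run <- run_staircase(ptc_trial_fun(listener, spec, cfg, table, cal),
                         scfg, seed = seed + i)
    pts[[i]] <- data.frame(fm = fm_list[i], threshold_db_spl = run$threshold,
                           n_trials = run$n_trials,
                           n_reversals = length(run$reversal_levels),
                           converged = run$converged)
  }
  structure(list(points = do.call(rbind, pts), fp = fp,
                 spread = cfg$spread, probe_level_db_spl = probe_level,
                 seed = seed),
            class = "ptc_measurement")
}

#' @export
print.ptc_measurement <- function(x, ...) {
  cat(sprintf("PTC: fp = %g Hz, spread %s, probe at %.1f dB SPL\n",
              x$fp, x$spread$label, x$probe_level_db_spl))
  print(x$points, row.names = FALSE)
  invisible(x)
}
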