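---
title: "Simulating channel interaction in cochlear-implant hearing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating channel interaction in cochlear-implant hearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cisim)
```

## The model

`cisim` emulates a 20-channel cochlear-implant sound processor with a
noise-band vocoder and adds a parametric model of *spread of excitation*
(channel interaction). The processing chain is:

1. **Resampling** to the processor rate `fs_proc = 50000/3` Hz. This exact
   rational value (not 16 700 Hz) is deliberate: it makes the FFT bin step
   `fs_proc / 128 = 130.2` Hz and the frame duration `128 / fs_proc = 7.7`
   ms come out exactly as the emulated processor specifies, and it gives
   the clean resampling ratio 500 : 1323 against 44.1 kHz.
2. **Pre-emphasis**: first-order IIR high-pass, −3 dB at 1200 Hz. The
   filter order is not dictated by the processor description; first order
   is the standard CI front end and is the package's choice.
3. **Analysis**: 128-sample Hamming windows, 75% overlap (hop 32 samples,
   1.9 ms). Each frame yields a one-sided 64-bin spectrum; bins 1–2 and
   63–64 are discarded and the remaining 60 bins (centres 260.4–7942.7 Hz,
   spanning 195–8008 Hz with half-bin flanks) are partitioned into 20
   contiguous channels (`build_channel_table()`). Channel 20 is the most
   apical (lowest-frequency) band, as in clinical electrode numbering.
   A channel's envelope sample is the RMS of its member-bin magnitudes —
   the *mean* square, not the sum, so one-bin and multi-bin channels are
   directly comparable. The partition is re-derived from the bin-step
   arithmetic at build time and verified against the stored per-channel
   bin counts.
4. **Channel picking**: per frame, the `n` channels with the largest RMS
   survive (`n_maxima`, 1–20), then any survivor more than 45 dB below the
   frame maximum is zeroed. The order — select-n first, floor second —
   follows the processor description. Rank ties are broken toward the
   lower channel index so that results are deterministic.
5. **Envelope reconstruction**: overlap-add of RMS-scaled Hamming windows
   at the analysis hop, normalised by the overlap-add (COLA) constant
   computed numerically from the actual window and hop (the symmetric
   Hamming window at 75% overlap is constant to ~0.1% in the interior),
   then smoothed by a 2nd-order Butterworth low-pass at 65 Hz — half the
   bin spacing — and clamped at zero against filter ripple.
6. **Carriers**: one broadband Gaussian noise realisation per output,
   filtered into each analysis band by a cascade of an order-N high-pass
   at `f_low` and an order-N low-pass at `f_high`. The cascade, rather
   than a single bandpass design, pins each skirt's asymptote at exactly
   −6N dB/oct: N = 12, 8, 4 for *low*, *medium*, *high* spread (−72, −48,
   −24 dB/oct). Filters are designed as cascaded biquads from the analog
   Butterworth prototype (bilinear transform with pre-warped cutoffs) and
   applied causally; flat polynomial coefficients are numerically fragile
   at order 12 on narrow bands, second-order sections are not. Carriers
   are RMS-normalised before modulation and fully determined by the
   configured seed.
7. **Synthesis**: modulated carriers are summed, the output RMS is levelled
   to the *raw* input RMS (measured before pre-emphasis — the processor
   description says only "input energy", and the raw signal is the natural
   reference), the waveform is rescaled to peak 1 only if it would clip,
   and the result is resampled to 44.1 kHz.

Edges: only complete analysis frames are processed, so the last partial
frame of a signal is not represented in the envelopes; reconstructed
envelopes are zero-padded to the carrier length. For the stimuli used here
(gated, zero-padded) this is immaterial.

### Measuring the skirt slope

`measure_filter_slope()` regresses the band filter's gain in dB on log2
frequency. The natural band — one to two octaves above the upper edge — is
used only when it lies below 0.15 `fs`: nearer Nyquist the bilinear
transform compresses the frequency axis and the digital skirt is far
steeper than the analog −6N dB/oct asymptote (a factor >3 for channel 8),
which would say nothing about the design claim. For higher channels the
mirrored low-frequency skirt (below `f_low/2`, capped at 0.15 `fs`) is
measured over one octave instead; the high-pass/low-pass cascade is
symmetric by construction, so both skirts share one asymptotic magnitude.
At the measurement bands used, residual warp plus the remaining distance
to the asymptote bias the estimate by under 2%.

## The forward-masking experiment

Stimuli follow the tuning-curve protocol: a 110-ms masker tone followed
with no gap by a 20-ms probe at `fp = 2226` Hz, both gated with 4-ms
raised-cosine² ramps, vocoded, and re-gated after processing. The seven
masker frequencies are the midpoints of the single-electrode activation
bands of channels 11 to 5 (1440.5, 1637, 1898.5, 2226, 2619, 3143,
3798 Hz). Note the deliberate distinction between 2214 Hz (the analysis
centre of channel 8) and 2226 Hz (its activation centre): the probe and
the Q10dB numerator use 2226.

The adaptive track is two-up one-down on the masker level: up after two
consecutive correct 3IFC responses, down after one error, converging on
the 70.7%-correct point. Steps are 4 dB until the third reversal, 2 dB
until the sixth, 1 dB thereafter; the phrase "reversals three to six"
overlaps at its ends, and the package resolves it as phases 1–3 / 4–6 /
7–12. A run ends at 12 reversals; the threshold is the mean level of the
last six, where the recorded reversal level is the level actually
presented when the direction flipped. A 400-trial cap flags runs that
cannot converge (e.g. a listener the masker can never defeat within the
level bounds).

### The simulated listener

Humans answered the real experiment; the package substitutes a model
listener (`vocoder_listener()`) with these components, all in dB:

* its own 20-band short-time analysis of each interval (the same filter
  bank as the processor, calibrated so a full-scale sine reads ~0 dB FS);
* a *probe window* (probe onset + 6 ms to offset + 12 ms — the first
  frames are skipped because analysis windows straddling the masker
  offset still carry full masker energy) and a *late-masker window*
  (the last ~40 ms of the masker);
* **forward masking as excitation persistence**: the effective excitation
  in the probe window is floored at the late-masker level minus
  `forward_masking_db`, and at the audibility threshold
  (`hearing_threshold_db`, default 25 dB SPL under the default
  calibration of 0 dB FS = 110 dB SPL);
* **attention**: the decision uses channels within `attend_octaves`
  (default 0.6) of the probe frequency — a trained listener knows what to
  listen for, and without this the decision statistic is dominated by
  carrier-realisation flicker in remote channels;
* **decision statistic**: per interval, the largest attended-channel
  increment of its effective excitation above the per-channel median
  across the three intervals, plus Gaussian internal noise
  (`internal_noise_sd`, default 1 dB). The interval with the largest
  statistic is chosen.

The probe level is fixed at the protocol's 20% of the dynamic range above
the listener's detection threshold; each staircase starts 10 dB above the
masker's audibility. By default `measure_ptc()` calibrates from the
listener's nominal threshold parameter; `thresholds = "measure"` instead
runs the behavioural 1-up-1-down track (`measure_hearing_threshold()`)
that the protocol prescribes — the model's track recovers its nominal
floor, so the fast path is used for routine simulation.

This listener produces V-shaped tuning curves whose mechanics mirror the
intended physics: masking requires the masker's excitation, delivered
through the spread-dependent carrier skirts and the persistence floor, to
swamp the probe's energy excess in the attended band. With −72 dB/oct
skirts the masker must be intense to reach channel 8 from a remote band
(steep V); with −24 dB/oct it reaches it easily (shallow, flat V). What
the model does *not* capture: absolute human thresholds and dynamic
ranges, informational masking, attention lapses, learning — so simulated
thresholds are comparable across conditions of this simulation, not with
human dB SPL values. Accordingly the package treats the human group
results as a worked example for the fitting code
(`example_group_ptc()`), not as a reproduction target, and the
end-to-end claims kept under test are directional: flatter curves and
lower Q10dB under high spread.

## Tuning-curve fits

`fit_ptc()` fits one quadratic per side in linear frequency (the protocol
does not state linear vs log; linear is the package default and
`log_freq = TRUE` is exposed). Both sides include the tip point. Before
fitting, the monotonicity rule drops any point more than 10 dB below the
running maximum walking outward from the tip (strictly more: an exactly
10-dB deviation stays). The tip level is the mean of the two fitted
values at `fp` — the sides are fitted unconstrained, and a disagreement
larger than 3 dB at the tip is reported in the fit object. `BW10dB` is the
distance between the sides' crossings of tip + 10 dB nearest the tip;
crossings beyond the measured masker range are allowed but flagged as
extrapolated. A side that never rises 10 dB above the tip (flat or
concave) yields an error object rather than a bandwidth; in directional
comparisons the package treats such a curve as the flatness limit
(unbounded bandwidth). On noiseless synthetic quadratics the fit recovers
the generator exactly (R² = 1, Q10dB to at least 4 significant figures).

## Word scores

`rau()` implements the rationalized arcsine transform with the
small-number-of-items correction; the constants 146/π and −23 are fixed
by the printed endpoints of the 20-item scale (−12.78, 112.78) and give
the exact complementarity `rau(x, n) + rau(n − x, n) = 100`. The speech
test's 36 conditions (3 SNRs × 4 maxima counts × 3 spreads) are
enumerated by `condition_grid()`; `aggregate_scores()` averages per-list
RAUs (mean of RAUs, never RAU of the mean) and reports per-factor means
and SDs on both scales. Human intelligibility is *not* modelled: the
package scores response tables, it does not generate them.

## Synthetic stimuli

The word corpus and recorded cocktail-party noise of the original speech
test are not redistributable, so the package generates surrogates and
labels them as such:

* `word_token()` — two voiced harmonic complexes (seeded f0 100–140 Hz,
  three seeded formants each) separated by a gap with a brief unvoiced
  burst; 0.4–0.7 s. It emulates the dissyllabic-word envelope structure,
  not French lexical content.
* `cocktail_noise()` — eight or more amplitude-modulated speech-shaped
  noise streams (syllabic 2–10 Hz modulators, spectrum flat to ~500 Hz
  then rolling off) plus sparse high-frequency transient bursts. It
  reproduces babble's modulation spectrum and crest factor, not
  intelligible chatter; tests on it therefore certify the mixing and
  vocoding machinery, not speech intelligibility.
* SNR mixing uses full-duration RMS of both signals (the measurement
  window is otherwise unspecified) and reports the applied noise scale.
* Tones start at zero phase; no phase roving (none is prescribed).

## Numerical and protocol choices

* Calibration: a single affine map, default 0 dB FS = 110 dB SPL, so a
  65-dB SPL presentation sits at −45 dB FS.
* All randomness flows through explicit integer seeds (carriers, noise,
  tokens, interval order, internal noise); repeated calls with one seed
  are bit-identical, and no function touches the caller's RNG stream.
* Staircase levels are clamped to the listener's audibility and maximum
  acceptable level.
* Problem sizes in the test suite are chosen for a desk-scale run:
  staircase-convergence checks use 150–500 simulated runs of the
  response-model listener; end-to-end tuning curves are measured once per
  spread level at the seven protocol maskers with the audio-analysing
  listener (a few hundred 3IFC trials each); vocoder energy and sparsity
  checks use 0.3–1 s noise and tone signals.

## Known limitations

* The listener model's absolute thresholds are parameters, not
  predictions; only within-simulation contrasts are meaningful.
* Processing is frame-complete and offline; no streaming or real-time
  path.
* The spread model is purely acoustic (filter skirts); no electrode-nerve
  geometry, current focusing or neural adaptation.
* WAV I/O covers mono PCM16/24 and float32 — the formats the toolchain
  produces and consumes.
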