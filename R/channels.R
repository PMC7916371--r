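# Frequency maps of the 20-channel processor emulation: the FFT-bin analysis
# bands and the single-electrode activation bands, plus the auditory-bandwidth
# (ERB) arithmetic they imply. Channel 20 is the most apical (lowest
# frequency) band, matching clinical electrode numbering.

# Analysis band cutoffs (Hz) and printed centre frequencies, channels 1..20
# (channel 1 = highest frequency). Bin counts are re-derived from the bin-step
# arithmetic at build time and cross-checked against these reference counts.
.analysis_bands <- data.frame(
  channel  = 20:1,
  f_low    = c(195, 326, 456, 586, 716, 846, 977, 1107, 1237, 1367, 1497,
               1758, 2018, 2409, 2799, 3451, 4102, 4883, 5794, 6836),
  f_high   = c(326, 456, 586, 716, 846, 977, 1107, 1237, 1367, 1497, 1758,
               2018, 2409, 2799, 3451, 4102, 4883, 5794, 6836, 8008),
  f_center = c(261, 391, 521, 651, 781, 912, 1042, 1172, 1302, 1432, 1628,
               1888, 2214, 2604, 3125, 3777, 4493, 5339, 6315, 7422),
  n_bins   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 3, 3, 5, 5, 6, 7, 8, 9)
)

# Single-electrode activation bands (Hz): the tone-frequency ranges for which
# exactly one electrode of the emulated processor is stimulated.
.activation_bands <- data.frame(
  channel    = 20:1,
  f_act_low  = c(195, 390, 521, 652, 783, 914, 1045, 1176, 1307, 1438, 1569,
                 1830, 2092, 2485, 2878, 3533, 4188, 4973, 5890, 6938),
  f_act_high = c(265, 396, 527, 658, 789, 920, 1051, 1182, 1312, 1443, 1705,
                 1967, 2360, 2753, 3408, 4063, 4848, 5765, 6813, 8115)
)

#' Equivalent rectangular bandwidth of the normal auditory filter
#'
#' Glasberg--Moore ERB of the auditory filter centred at \code{f}:
#' \code{24.7 * (4.37 * f / 1000 + 1)} Hz. Rounding the result to integer Hz
#' reproduces the ERB column of the packaged analysis-band table (e.g. 264 Hz
#' at 2214 Hz).
#'
#' @param f centre frequency in Hz (vectorised, all > 0).
#' @return ERB in Hz (unrounded).
#' @examples
#' round(erb(2214))  # 264
#' @export
erb <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop("`f` must be positive finite frequency in Hz", call. = FALSE)
  24.7 * (4.37 * f / 1000 + 1)
}

#' Build the 20-channel frequency map
#'
#' Assembles the analysis filter bank (cutoffs, centres, FFT-bin membership,
#' ERB) and the single-electrode activation map into one table. The analysis
#' spectrum is the one-sided 64-bin FFT of a 128-sample frame at
#' \code{fs_proc = 50000/3} Hz; the first two and last two bins are discarded
#' and the remaining 60 bins (ordinals 3..62, centre frequencies
#' \code{(ordinal - 1) * fs_proc / 128}) cover 195--8008 Hz in 130.2-Hz steps.
#' Each retained bin is assigned to the unique channel whose
#' \code{[f_low, f_high)} interval contains its centre; the resulting counts
#' are verified against the reference per-channel counts at build time.
#'
#' @return an object of class \code{channel_table}: a list with
#'   \describe{
#'     \item{analysis}{data.frame of 20 rows: \code{channel}, \code{f_low},
#'       \code{f_high}, \code{f_center}, \code{n_bins}, \code{bandwidth},
#'       \code{erb_hz}, and a list-column \code{bins} of retained-bin
#'       ordinals (3..62).}
#'     \item{activation}{data.frame of 20 rows: \code{channel},
#'       \code{f_act_low}, \code{f_act_high}, \code{f_act_center}.}
#'     \item{fs_proc, fft_len, bin_step_hz}{processing rate, FFT length and
#'       bin spacing (\code{fs_proc / fft_len}).}
#'   }
#' @examples
#' ct <- build_channel_table()
#' subset(ct$analysis, channel == 8)
#' @export
build_channel_table <- function() {
  fs_proc <- 50000 / 3
  fft_len <- 128L
  bin_step <- fs_proc / fft_len        # 130.2083 Hz
  ordinals <- 3:62                     # retained bins of the 64-bin spectrum
  bin_freq <- (ordinals - 1) * bin_step

  an <- .analysis_bands
  bins <- lapply(seq_len(nrow(an)), function(i) {
    ordinals[bin_freq >= an$f_low[i] & bin_freq < an$f_high[i]]
  })
  n_assigned <- lengths(bins)
  if (!identical(as.integer(n_assigned), as.integer(an$n_bins)))
    stop("internal error: bin-to-channel assignment does not match the ",
         "reference per-channel bin counts", call. = FALSE)
  if (sum(n_assigned) != 60L || anyDuplicated(unlist(bins)))
    stop("internal error: retained bins must partition into 60 unique bins",
         call. = FALSE)

  analysis <- data.frame(
    channel   = an$channel,
    f_low     = an$f_low,
    f_high    = an$f_high,
    f_center  = an$f_center,
    n_bins    = n_assigned,
    bandwidth = an$f_high - an$f_low,
    erb_hz    = round(erb(an$f_center))
  )
  analysis$bins <- bins

  act <- .activation_bands
  act$f_act_center <- (act$f_act_low + act$f_act_high) / 2

  structure(
    list(analysis = analysis, activation = act,
         fs_proc = fs_proc, fft_len = fft_len, bin_step_hz = bin_step),
    class = "channel_table")
}

#' @export
print.channel_table <- function(x, ...) {
  cat(sprintf("20-channel map: fs_proc = %.1f Hz, %d-point FFT, bin step %.1f Hz\n",
              x$fs_proc, x$fft_len, x$bin_step_hz))
  cat(sprintf("analysis bands span %g-%g Hz over %d retained bins\n",
              min(x$analysis$f_low), max(x$analysis$f_high),
              sum(x$analysis$n_bins)))
  invisible(x)
}

#' Masker frequencies for the forward-masking tuning-curve protocol
#'
#' Midpoints of the single-electrode activation bands for channels 11 down to
#' 5, in ascending frequency order: 1440.5, 1637, 1898.5, 2226, 2619, 3143
#' and 3798 Hz. The fourth entry (channel 8, 2226 Hz) is also the probe
#' frequency.
#'
#' @param table a \code{channel_table}; built internally if missing.
#' @param channels integer channel range (default 11 down to 5).
#' @return numeric vector of masker frequencies in Hz, ascending.
#' @export
masker_frequencies <- function(table = build_channel_table(),
                               channels = 11:5) {
  act <- table$activation
  f <- act$f_act_center[match(channels, act$channel)]
  sort(f)
}

#' Export the packaged frequency maps
#'
#' Writes the analysis and activation tables column-for-column as CSV or JSON.
#'
#' @param path output file path.
#' @param which \code{"analysis"} or \code{"activation"}.
#' @param format \code{"csv"} or \code{"json"}.
#' @param table a \code{channel_table}.
#' @return the exported data.frame, invisibly.
#' @export
export_channel_table <- function(path, which = c("analysis", "activation"),
                                 format = c("csv", "json"),
                                 table = build_channel_table()) {
  which <- match.arg(which)
  format <- match.arg(format)
  df <- table[[which]]
  if (which == "analysis")
    df$bins <- vapply(df$bins, paste, character(1), collapse = ";")
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
  else jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  invisible(df)
}
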