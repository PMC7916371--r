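# Word-score handling: the rationalized arcsine transform with the
# small-number-of-items correction, the 36-condition factorial grid of the
# speech-in-noise test, and per-factor summary tables.

#' Rationalized arcsine units with small-N correction
#'
#' Variance-stabilising transform of a proportion-correct score with a
#' correction for the small number of scored items:
#' \deqn{\theta = \arcsin\sqrt{x/(n+1)} + \arcsin\sqrt{(x+1)/(n+1)},\quad
#'       RAU = (146/\pi)\,\theta - 23.}
#' On a 20-item list the scale runs from -12.78 (0 correct) to 112.78 (all
#' correct) and equals 50 at half; it satisfies the complementarity identity
#' \code{rau(x, n) + rau(n - x, n) = 100}.
#'
#' @param x number of correct items (integer, vectorised).
#' @param n total number of items.
#' @return score(s) in rationalized arcsine units.
#' @examples
#' rau(c(0, 10, 20), 20)
#' @export
rau <- function(x, n) {
  if (any(n < 1 | n != round(n))) stop("`n` must be a positive integer", call. = FALSE)
  if (any(x < 0 | x > n | x != round(x)))
    stop("`x` must be an integer in [0, n]", call. = FALSE)
  theta <- asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))
  (146 / pi) * theta - 23
}

#' The factorial condition grid of the speech-in-noise test
#'
#' Full crossing of SNR (-3, 3, 9 dB), number of selected maxima (4, 8, 12,
#' 16 of 20) and spread of excitation (low, medium, high): 36 conditions.
#' With a seed, word-list numbers 1..36 are assigned to conditions in
#' seeded random order (each listener hears a different list in each
#' condition).
#'
#' @param seed integer seed for the list assignment (NULL: no assignment).
#' @param snr_db,n_maxima,spread factor levels.
#' @return data.frame of conditions in deterministic order, with a
#'   \code{list_id} column when \code{seed} is given.
#' @export
condition_grid <- function(seed = NULL, snr_db = c(-3, 3, 9),
                           n_maxima = c(4, 8, 12, 16),
                           spread = c("low", "medium", "high")) {
  grid <- expand.grid(snr_db = snr_db, n_maxima = n_maxima, spread = spread,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$snr_db, grid$n_maxima, grid$spread), ]
  rownames(grid) <- NULL
  if (!is.null(seed))
    grid$list_id <- with_local_seed(seed, sample.int(nrow(grid)))
  grid
}

#' Summarise scores per factor in percent and RAU
#'
#' Per-factor, per-level means and standard deviations of word scores on
#' both the percent and RAU scales. Scores are transformed per list first
#' and then averaged (mean of RAUs, not RAU of the mean). Missing
#' subject-condition cells are reported via the \code{n} column, never
#' imputed.
#'
#' @param results data.frame with columns \code{snr_db}, \code{n_maxima},
#'   \code{spread}, \code{n_correct}, \code{n_items} (one row per subject
#'   and condition; extra columns such as \code{subject} are allowed).
#' @param factors columns to summarise over.
#' @return data.frame with columns \code{factor}, \code{level}, \code{n},
#'   \code{mean_pct}, \code{sd_pct}, \code{mean_rau}, \code{sd_rau}.
#' @export
aggregate_scores <- function(results,
                             factors = c("snr_db", "n_maxima", "spread")) {
  need <- c(factors, "n_correct", "n_items")
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("`results` must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pct <- 100 * results$n_correct / results$n_items
  rau_scores <- rau(results$n_correct, results$n_items)
  out <- lapply(factors, function(fac) {
    lv <- results[[fac]]
    agg <- lapply(split(seq_along(lv), lv), function(idx) {
      data.frame(n = length(idx),
                 mean_pct = mean(pct[idx]), sd_pct = stats::sd(pct[idx]),
                 mean_rau = mean(rau_scores[idx]),
                 sd_rau = stats::sd(rau_scores[idx]))
    })
    cbind(factor = fac, level = names(agg), do.call(rbind, agg))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
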