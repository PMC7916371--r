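#' Run an expression with a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded operations inside the
#' package never disturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Root-mean-square of a numeric vector
#' @param x numeric vector.
#' @return scalar RMS.
#' @export
rms <- function(x) {
  if (inherits(x, "audio_buffer")) x <- x$samples
  sqrt(mean(x^2))
}

#' Convert a linear amplitude ratio to decibels
#' @param r linear ratio (> 0).
#' @return dB value \code{20 * log10(r)}.
#' @keywords internal
lin2db <- function(r) 20 * log10(r)

#' Convert decibels to a linear amplitude ratio
#' @param db value in dB.
#' @keywords internal
db2lin <- function(db) 10^(db / 20)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
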