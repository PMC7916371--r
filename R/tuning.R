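# Tuning-curve fitting: two one-sided quadratics around the probe frequency,
# a >10-dB monotonicity exclusion rule, and the Q10dB sharpness factor
# (probe frequency divided by the curve bandwidth 10 dB above the tip).

#' Exclude non-monotonic tuning-curve points
#'
#' Masked thresholds are expected to rise monotonically on each side of the
#' probe frequency. Walking outward from the tip on each side, a point whose
#' threshold falls more than 10 dB below the running maximum of the points
#' closer to the tip is excluded; a deviation of exactly 10 dB is retained
#' (strict inequality).
#'
#' @param points data.frame with columns \code{fm} (Hz) and
#'   \code{threshold_db_spl}.
#' @param fp probe frequency in Hz.
#' @param tol_db exclusion tolerance in dB (default 10).
#' @return list with integer index vectors \code{included} and
#'   \code{excluded} (row indices into \code{points}).
#' @export
exclude_nonmonotonic <- function(points, fp = 2226, tol_db = 10) {
  stopifnot(all(c("fm", "threshold_db_spl") %in% names(points)))
  excluded <- integer(0)
  for (side in c("low", "high")) {
    idx <- if (side == "low") which(points$fm <= fp) else which(points$fm >= fp)
    # order walking outward from the tip
    idx <- idx[order(abs(points$fm[idx] - fp))]
    run_max <- -Inf
    for (i in idx) {
      th <- points$threshold_db_spl[i]
      if (th < run_max - tol_db) excluded <- c(excluded, i)
      else run_max <- max(run_max, th)
    }
  }
  excluded <- sort(unique(excluded))
  list(included = setdiff(seq_len(nrow(points)), excluded),
       excluded = excluded)
}

#' Fit a psychophysical tuning curve and compute Q10dB
#'
#' Fits one least-squares quadratic to each side of the probe frequency
#' (both sides include the tip point, the threshold at \code{fm = fp}),
#' after applying the \code{\link{exclude_nonmonotonic}} rule. The tip level
#' is the mean of the two fitted values at \code{fp}; the 10-dB bandwidth is
#' the distance between the two side-quadratics' crossings of
#' \code{tip + 10} dB nearest the tip (extrapolated crossings beyond the
#' masker range are permitted but flagged), and \code{q10db = fp / bw10}.
#'
#' @param points data.frame with columns \code{fm}, \code{threshold_db_spl}
#'   (a \code{ptc_measurement} is also accepted).
#' @param fp probe frequency in Hz (default 2226).
#' @param log_freq fit in log2 frequency instead of linear Hz.
#' @param exclude apply the monotonicity exclusion rule first.
#' @return object of class \code{ptc_fit}: list with per-side quadratic
#'   coefficients (\code{low_side}, \code{high_side}: \code{c(a, b, c)} for
#'   \code{a f^2 + b f + c}), \code{included}/\code{excluded} indices,
#'   \code{tip_level}, \code{tip_freq}, \code{bw10}, \code{q10db},
#'   \code{r_squared}, \code{extrapolated}, \code{reliable}, and
#'   \code{error} (NULL, or a message when the 10-dB bandwidth is
#'   undefined).
#' @export
fit_ptc <- function(points, fp = 2226, log_freq = FALSE, exclude = TRUE) {
  if (inherits(points, "ptc_measurement")) {
    fp <- points$fp
    points <- points$points
  }
  stopifnot(all(c("fm", "threshold_db_spl") %in% names(points)))
  points <- points[is.finite(points$threshold_db_spl), , drop = FALSE]
  if (!any(points$fm == fp))
    stop("tip point (fm == fp) is required for the two-sided fit", call. = FALSE)
  excl <- if (exclude) exclude_nonmonotonic(points, fp)
          else list(included = seq_len(nrow(points)), excluded = integer(0))
  inc <- points[excl$included, , drop = FALSE]

  xf <- function(f) if (log_freq) log2(f) else f
  fit_side <- function(side) {
    pts <- if (side == "low") inc[inc$fm <= fp, ] else inc[inc$fm >= fp, ]
    if (nrow(pts) < 3) return(NULL)
    x <- xf(pts$fm); y <- pts$threshold_db_spl
    fit <- stats::lm(y ~ x + I(x^2))
    cf <- stats::coef(fit)
    list(coeffs = c(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1])),
         fitted = stats::fitted(fit), observed = y, n = nrow(pts))
  }
  low <- fit_side("low"); high <- fit_side("high")
  reliable <- !is.null(low) && !is.null(high)

  out <- structure(list(
    fp = fp, log_freq = log_freq,
    low_side = low$coeffs, high_side = high$coeffs,
    included = excl$included, excluded = excl$excluded,
    n_low = low$n %||% 0L, n_high = high$n %||% 0L,
    tip_level = NA_real_, tip_freq = fp, bw10 = NA_real_, q10db = NA_real_,
    r_squared = NA_real_, extrapolated = FALSE, reliable = reliable,
    error = NULL), class = "ptc_fit")
  if (!reliable) {
    out$error <- "fewer than 3 surviving points on a side"
    return(out)
  }

  qeval <- function(cf, x) cf["a"] * x^2 + cf["b"] * x + cf["c"]
  xp <- xf(fp)
  tip <- mean(c(qeval(low$coeffs, xp), qeval(high$coeffs, xp)))
  out$tip_level <- tip
  target <- tip + 10

  cross <- function(cf, side) {
    a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]] - target
    if (abs(a) < 1e-12) {
      if (abs(b) < 1e-12) return(NA_real_)
      r <- -cc / b
      return(if ((side == "low" && r < xp) || (side == "high" && r > xp)) r
             else NA_real_)
    }
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NA_real_)
    r <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
    r <- if (side == "low") r[r < xp] else r[r > xp]
    if (length(r) == 0) return(NA_real_)
    r[which.min(abs(r - xp))]
  }
  xlo <- cross(low$coeffs, "low")
  xhi <- cross(high$coeffs, "high")
  if (is.na(xlo) || is.na(xhi)) {
    out$error <- "side quadratic never reaches 10 dB above the tip"
    return(out)
  }
  flo <- if (log_freq) 2^xlo else xlo
  fhi <- if (log_freq) 2^xhi else xhi
  out$bw10 <- fhi - flo
  out$q10db <- q10(fp, out$bw10)
  out$extrapolated <- flo < min(points$fm) || fhi > max(points$fm)

  obs <- c(low$observed, high$observed)
  pred <- c(low$fitted, high$fitted)
  sst <- sum((obs - mean(obs))^2)
  out$r_squared <- if (sst > 0) 1 - sum((obs - pred)^2) / sst else 1
  # flag large disagreement of the two side fits at the tip
  out$tip_disagreement_db <-
    abs(qeval(low$coeffs, xp) - qeval(high$coeffs, xp))
  out
}

#' @export
print.ptc_fit <- function(x, ...) {
  cat(sprintf("ptc_fit: fp = %g Hz (%s frequency axis)\n", x$fp,
              if (x$log_freq) "log2" else "linear"))
  if (!is.null(x$error)) {
    cat("  fit undefined:", x$error, "\n")
  } else {
    cat(sprintf("  tip %.1f dB SPL, BW10dB %.1f Hz, Q10dB %.2f (R^2 %.3f)%s\n",
                x$tip_level, x$bw10, x$q10db, x$r_squared,
                if (x$extrapolated) " [10-dB crossing extrapolated]" else ""))
  }
  if (length(x$excluded))
    cat("  excluded points:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Q10dB sharpness factor
#'
#' Probe frequency divided by the tuning-curve bandwidth 10 dB above the
#' tip; higher values mean sharper tuning.
#'
#' @param fp probe frequency in Hz.
#' @param bw10 10-dB bandwidth in Hz (> 0).
#' @return dimensionless sharpness \code{fp / bw10}.
#' @export
q10 <- function(fp, bw10) {
  if (!is.numeric(bw10) || any(!is.finite(bw10)) || any(bw10 <= 0))
    stop("`bw10` must be positive", call. = FALSE)
  fp / bw10
}

#' Bundled example group-average tuning-curve data
#'
#' Group-mean forward-masked thresholds (dB SPL, with standard error and
#' range) at the seven protocol masker frequencies for each spread level,
#' from a 19-listener normal-hearing study run with this simulation's
#' protocol. Useful as a worked example for \code{\link{fit_ptc}}.
#'
#' @return data.frame with columns \code{spread}, \code{fm},
#'   \code{threshold_db_spl}, \code{se}, \code{min}, \code{max}.
#' @export
example_group_ptc <- function() {
  path <- system.file("extdata", "group_mean_ptc.csv", package = "cisim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
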