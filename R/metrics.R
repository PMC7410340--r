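#' Per-tone response extraction
#'
#' Mean or peak of an activity/rate trace over each tone window.
#'
#' @param trace Numeric trace.
#' @param time Time grid (ms) of the trace.
#' @param windows Two-column matrix of `(start, end)` windows (ms).
#' @param measure `"mean"` or `"peak"`.
#' @return Numeric vector, one response per window.
#' @export
tone_response <- function(trace, time, windows,
                          measure = c("mean", "peak")) {
  measure <- match.arg(measure)
  windows <- matrix(windows, ncol = 2)
  apply(windows, 1, function(w) {
    idx <- time >= w[1] & time <= w[2]
    if (!any(idx)) stop("empty tone window [", w[1], ", ", w[2], "]")
    if (measure == "mean") mean(trace[idx]) else max(trace[idx])
  })
}

#' Common-contrast SSA index
#'
#' `CSI = (d1 + d2 - s1 - s2) / (d1 + d2 + s1 + s2)` from the deviant and
#' standard responses at the two oddball frequencies. CSI = 1 indicates full
#' adaptation (standard responses vanish), CSI = 0 none (standards equal
#' deviants). The result is flagged invalid when either standard response
#' falls below `min_standard` (response too weak to measure adaptation) or
#' when the excitatory response saturates; the index value itself is still
#' reported when the denominator is positive.
#'
#' @param d_f1,d_f2 Mean deviant responses at the two frequencies.
#' @param s_f1,s_f2 Mean standard responses.
#' @param saturated Logical: did the Exc response saturate?
#' @param min_standard Validity floor on the standard responses.
#' @return An object of class `csi_result` with fields `csi`, the four
#'   responses, and `valid`.
#' @export
csi <- function(d_f1, d_f2, s_f1, s_f2, saturated = FALSE,
                min_standard = 0.1) {
  vals <- c(d_f1, d_f2, s_f1, s_f2)
  if (any(vals < 0)) stop("responses must be nonnegative")
  den <- sum(vals)
  value <- if (den > 0) (d_f1 + d_f2 - s_f1 - s_f2) / den else NA_real_
  valid <- is.finite(value) && !saturated &&
    s_f1 >= min_standard && s_f2 >= min_standard
  structure(list(csi = value, d_f1 = d_f1, d_f2 = d_f2, s_f1 = s_f1,
                 s_f2 = s_f2, valid = valid, saturated = saturated),
            class = "csi_result")
}

#' @export
print.csi_result <- function(x, ...) {
  cat(sprintf("<csi_result: CSI = %s (%s)>\n",
              format(x$csi, digits = 4),
              if (x$valid) "valid" else "masked"))
  cat(sprintf("  deviants %.4g / %.4g, standards %.4g / %.4g\n",
              x$d_f1, x$d_f2, x$s_f1, x$s_f2))
  invisible(x)
}

#' Onset-aligned Pearson correlation between two traces
#'
#' Pearson correlation of a response trace against a reference (typically
#' the thalamic input), after optionally re-aligning the response in time:
#' `"onset"` shifts it so that its onset (first sample exceeding 10% of its
#' peak) coincides with the reference onset; `"max_xcorr"` (default) picks
#' the integer-lag shift maximizing the cross-correlation, an equivalent
#' formulation; `"none"` compares as-is. Only the response trace is shifted.
#'
#' @param trace Response trace.
#' @param reference Reference trace on the same grid.
#' @param align `"max_xcorr"`, `"onset"` or `"none"`.
#' @param dt Grid step (ms), used only to report the shift in ms.
#' @param max_lag Maximum shift searched (samples) for `"max_xcorr"`.
#' @return An object of class `correlation_result` with fields `r`,
#'   `shift_ms` and `align`; `r` is `NA` (flagged) for constant traces.
#' @export
onset_aligned_correlation <- function(trace, reference,
                                      align = c("max_xcorr", "onset", "none"),
                                      dt = 1, max_lag = length(trace) %/% 2) {
  align <- match.arg(align)
  if (length(trace) != length(reference))
    stop("traces must share one time grid")
  if (stats::sd(trace) == 0 || stats::sd(reference) == 0)
    return(structure(list(r = NA_real_, shift_ms = 0, align = align,
                          degenerate = TRUE), class = "correlation_result"))
  shift <- 0L
  if (align == "onset") {
    onset_of <- function(x) which(x > 0.1 * max(x))[1]
    shift <- onset_of(trace) - onset_of(reference)
  } else if (align == "max_xcorr") {
    lags <- seq(-max_lag, max_lag)
    n <- length(trace)
    best <- -Inf
    for (L in lags) {
      i1 <- max(1, 1 + L); i2 <- min(n, n + L)
      a <- trace[i1:i2]
      b <- reference[(i1 - L):(i2 - L)]
      if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- cor(a, b)
      if (r > best) { best <- r; shift <- L }
    }
  }
  n <- length(trace)
  i1 <- max(1, 1 + shift); i2 <- min(n, n + shift)
  r <- cor(trace[i1:i2], reference[(i1 - shift):(i2 - shift)])
  structure(list(r = r, shift_ms = shift * dt, align = align,
                 degenerate = FALSE), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result: r = %s (align = %s, shift = %g ms)>\n",
              format(x$r, digits = 4), x$align, x$shift_ms))
  invisible(x)
}

#' Excitatory-inhibitory balance fit
#'
#' Fits a least-squares line through the origin to peak (inhibitory,
#' excitatory) recurrent current pairs collected across input strengths:
#' `slope = sum(E * I) / sum(I^2)`. A constant slope across strengths is the
#' signature of balanced excitation and inhibition.
#'
#' @param E,I Peak excitatory and inhibitory current magnitudes per run
#'   (runs without suprathreshold activity must be omitted by the caller).
#' @param strength Optional input-strength labels.
#' @return An object of class `balance_result` with fields `slope`,
#'   `residual` (root-mean-square), and the points.
#' @export
ei_balance <- function(E, I, strength = seq_along(E)) {
  stopifnot(length(E) == length(I), length(E) >= 1)
  slope <- sum(E * I) / sum(I^2)
  res <- sqrt(mean((E - slope * I)^2))
  structure(list(slope = slope, residual = res,
                 points = data.frame(strength = strength, I = I, E = E)),
            class = "balance_result")
}

#' @export
print.balance_result <- function(x, ...) {
  cat(sprintf("<balance_result: E/I slope = %.4g (rms residual %.3g, %d points)>\n",
              x$slope, x$residual, nrow(x$points)))
  invisible(x)
}

#' Light-on / light-off response comparison
#'
#' Pairs tuning-curve responses measured with and without optogenetic drive
#' for a scatter against the unit-slope line: points above the line mark
#' disinhibition, points below suppression. Matching is by frequency
#' distance and tone index.
#'
#' @param light_on,light_off data.frames with columns `distance`, `tone`,
#'   `response` (matched rows).
#' @return data.frame with the paired responses and their `ratio`
#'   (on/off; `NA` and flagged `undefined` where the light-off response is
#'   zero).
#' @export
tuning_light_ratio <- function(light_on, light_off) {
  m <- merge(light_off, light_on, by = c("distance", "tone"),
             suffixes = c("_off", "_on"))
  m$ratio <- ifelse(m$response_off > 0, m$response_on / m$response_off,
                    NA_real_)
  m$undefined <- m$response_off == 0
  m[order(m$distance, m$tone), ]
}
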