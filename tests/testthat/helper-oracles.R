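# Independent explicit-Euler reference integrator for the rate model, built
# on the exported R right-hand-side functions; used as the oracle against
# the compiled RK4 path.

euler_single_unit <- function(params, protocol, t_end, dt,
                              opto_windows = NULL) {
  n <- floor(t_end / dt)
  times <- seq(0, t_end, by = dt)
  i_tr <- tone_input_trace(protocol, 1, params, times = times)
  if (nrow(protocol$tones) && all(protocol$tones$unit != 1)) {
    # single-unit runs address every tone to the one unit
    onsets <- protocol$tones$onset
    i_tr <- numeric(length(times))
    for (o in onsets) {
      idx <- times >= o
      i_tr[idx] <- i_tr[idx] + exp(-(times[idx] - o) / params$tau_q)
    }
  }
  opto_at <- function(t) {
    out <- c(0, 0)
    if (!is.null(opto_windows)) {
      for (w in opto_windows) {
        if (t >= w$start && t < w$end) {
          if (w$target == "PV") out[1] <- out[1] + w$amp
          else out[2] <- out[2] + w$amp
        }
      }
    }
    out
  }
  st <- c(u = 0, p = 0, s = 0, g = params$g0)
  out <- matrix(NA_real_, n + 1, 4,
                dimnames = list(NULL, c("u", "p", "s", "g")))
  out[1, ] <- st
  for (k in seq_len(n)) {
    d <- single_unit_rhs(st, i_tr[k], opto_at(times[k]), params)
    st <- st + dt * d
    out[k + 1, ] <- st
  }
  list(time = times, traces = out)
}

# A tiny two-tone protocol addressed to the single unit.
two_tone_protocol <- function(span = 800) {
  tone_protocol(data.frame(onset = c(100, 400), duration = 100, unit = 1,
                           amp = 1), paradigm = "oracle", span = span)
}

expect_setequal_names <- function(x, nms) {
  testthat::expect_setequal(names(x), nms)
}
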