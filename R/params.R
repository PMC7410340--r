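#' Threshold-linear gain function
#'
#' The population gain used throughout the rate model: zero at or below
#' threshold, linear with slope `r` above it, saturating at 1. It is a
#' piecewise-linear stand-in for a sigmoid, so population activities are
#' normalized firing rates in \[0, 1\].
#'
#' @param x Input (dimensionless). Must be finite.
#' @param r Gain (slope) of the linear segment; must be positive.
#' @param theta Activity threshold subtracted from the input before the gain
#'   is applied.
#' @return Rate value(s) in \[0, 1\], same length as `x`.
#' @examples
#' threshold_linear(0.9, r = 3, theta = 0.7) # 3 * 0.2 = 0.6
#' @export
threshold_linear <- function(x, r = 3, theta = 0) {
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (!is.finite(r) || r <= 0) stop("`r` must be a positive number")
  y <- r * (x - theta)
  pmin(pmax(y, 0), 1)
}

#' Right-hand side of the thalamic depression variable
#'
#' Standard synaptic-resource dynamics for the feedforward thalamic synapse:
#' slow replenishment toward baseline `g0` with time constant `tau_d1` and
#' input-driven depletion with time constant `tau_d2`.
#'
#' @param g Current value of the depression variable, in \[0, g0\].
#' @param i Instantaneous (nonnegative) thalamic input value.
#' @param params A [rate_params()] list supplying `g0`, `tau_d1`, `tau_d2`.
#' @return dg/dt in 1/ms.
#' @export
thalamic_depression_rhs <- function(g, i, params = rate_params()) {
  if (any(i < 0)) stop("thalamic inputs are nonnegative")
  (params$g0 - g) / params$tau_d1 - g * i / params$tau_d2
}

#' Parameters of the single iso-frequency rate unit
#'
#' Defaults are the dimensionless Wilson-Cowan microcircuit constants:
#' within-unit weight matrix `W` (rows: postsynaptic Exc, PV, SST; columns:
#' presynaptic Exc, PV, SST), threshold-linear gain 3, activity
#' thresholds (0.7, 1, 1), 10 ms membrane time constants, input decay
#' `tau_q = 10` ms and thalamic depression time constants 1500/20 ms.
#' SST receives no inhibition (`W[3,2] = W[3,3] = 0`).
#'
#' @param W 3x3 nonnegative weight matrix.
#' @param u_th,p_th,s_th Activity thresholds of Exc, PV, SST.
#' @param r Gain of the threshold-linear function.
#' @param tau_u,tau_p,tau_s Membrane time constants (ms).
#' @param q Thalamic input strength (dimensionless).
#' @param tau_q Input decay time constant (ms).
#' @param tau_d1,tau_d2 Depression replenishment / depletion constants (ms).
#' @param g0 Baseline of the depression variable (1).
#' @return A list of class `rate_params`.
#' @export
rate_params <- function(W = matrix(c(1.1, 2, 1,
                                     1,   2, 2,
                                     6,   0, 0), 3, 3, byrow = TRUE),
                        u_th = 0.7, p_th = 1, s_th = 1, r = 3,
                        tau_u = 10, tau_p = 10, tau_s = 10,
                        q = 5, tau_q = 10,
                        tau_d1 = 1500, tau_d2 = 20, g0 = 1) {
  W <- matrix(as.numeric(W), 3, 3)
  stopifnot(all(W >= 0), all(W[3, 2:3] == 0))
  taus <- c(tau_u, tau_p, tau_s, tau_q, tau_d1, tau_d2)
  if (any(taus <= 0)) stop("all time constants must be positive")
  if (r <= 0) stop("`r` must be positive")
  if (g0 != 1) stop("`g0` must equal 1")
  structure(list(W = W, u_th = u_th, p_th = p_th, s_th = s_th, r = r,
                 tau_u = tau_u, tau_p = tau_p, tau_s = tau_s,
                 q = q, tau_q = tau_q,
                 tau_d1 = tau_d1, tau_d2 = tau_d2, g0 = g0),
            class = "rate_params")
}

#' Parameters of the three-unit tonotopic rate model
#'
#' Extends [rate_params()] with lateral (between-unit) excitatory weights, a
#' thalamic cross-unit spread fraction `alpha`, short-term plasticity of the
#' PV->Exc (depressing, strength `a_dep`) and lateral SST->Exc (facilitating,
#' strength `b_fac`) synapses, and the weak/strong baseline-inhibition regime
#' switch: under strong baseline inhibition the Exc-row inhibitory weights
#' rise to `W_strong` and the SST threshold drops to `s_th_strong`.
#'
#' @param base Single-unit parameters ([rate_params()]).
#' @param w_ee_lat,w_pe_lat,w_se_lat Lateral Exc->Exc, Exc->PV, Exc->SST
#'   weights; weaker than their within-unit counterparts.
#' @param alpha Fraction of thalamic input reaching the adjacent unit.
#' @param a_dep PV->Exc depression strength.
#' @param b_fac Lateral SST->Exc facilitation strength (the printed circuit
#'   corresponds to `b_fac = 1`; 2 is an alternate reading).
#' @param tau_F1,tau_F2 Time constants (ms) of the slow baseline facilitation
#'   variable that classifies the inhibition regime.
#' @param F_th Regime threshold on the baseline-facilitation asymptote.
#' @param W_strong Weight matrix under strong baseline inhibition.
#' @param s_th_strong SST threshold under strong baseline inhibition.
#' @param h_gain Gain of the sigmoidal soft regime switch (smooth variant).
#' @param use_proxy If `TRUE` (default) the facilitation and depression
#'   variables are tied to the thalamic resource: `F = 1 - g`, `D = g`.
#'   Otherwise their own differential equations are integrated, driven by the
#'   unit's thalamic input with the depression time constants.
#' @return A list of class `three_unit_params`.
#' @export
three_unit_params <- function(base = rate_params(),
                              w_ee_lat = 0.667, w_pe_lat = 1.25,
                              w_se_lat = 0.125, alpha = 0.65,
                              a_dep = 0.5, b_fac = 1,
                              tau_F1 = 1500, tau_F2 = 100, F_th = 0.22,
                              W_strong = matrix(c(1.1, 3, 3,
                                                  1,   2, 2,
                                                  6,   0, 0), 3, 3,
                                                byrow = TRUE),
                              s_th_strong = 0, h_gain = 25,
                              use_proxy = TRUE) {
  stopifnot(inherits(base, "rate_params"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (w_ee_lat >= base$W[1, 1] || w_se_lat >= base$W[3, 1])
    stop("lateral Exc->Exc / Exc->SST weights must be weaker than their within-unit counterparts")
  W_strong <- matrix(as.numeric(W_strong), 3, 3)
  d <- W_strong - base$W
  if (any(d[-c(4, 7)] != 0))
    stop("strong-regime matrix may differ only in the Exc-row inhibitory entries")
  # effective PV->Exc weight w_ep - a_dep*(1-D) must keep its sign on D in [0,1]
  if (a_dep >= min(base$W[1, 2], W_strong[1, 2]))
    stop("`a_dep` too large: effective PV->Exc weight would change sign")
  structure(c(unclass(base),
              list(w_ee_lat = w_ee_lat, w_pe_lat = w_pe_lat,
                   w_se_lat = w_se_lat, alpha = alpha,
                   a_dep = a_dep, b_fac = b_fac,
                   tau_F1 = tau_F1, tau_F2 = tau_F2, F_th = F_th,
                   W_strong = W_strong, s_th_strong = s_th_strong,
                   h_gain = h_gain, use_proxy = use_proxy)),
            class = c("three_unit_params", "rate_params"))
}

#' Baseline-facilitation trajectory of a protocol
#'
#' Integrates the slow facilitation variable `Fbar` that classifies a
#' paradigm's baseline-inhibition regime:
#' `dFbar/dt = -Fbar^2 / tau_F1 + Ibar / tau_F2`, where `Ibar(t)` is the sum
#' of the (unit-amplitude) thalamic input traces of all tones regardless of
#' frequency, starting from `Fbar(0) = 0`.
#'
#' @param protocol A [tone_protocol()].
#' @param params [three_unit_params()].
#' @param t_end Integration span (ms); the protocol should cover at least
#'   30 s for a meaningful asymptote.
#' @param dt Integration step (ms).
#' @return A data.frame with columns `time_ms` and `Fbar`, with the asymptote
#'   (mean over the final 5 s) attached as attribute `"asymptote"`.
#' @export
baseline_facilitation <- function(protocol, params = three_unit_params(),
                                  t_end = 30000, dt = 0.5) {
  tt <- seq(0, t_end, by = dt)
  ibar <- numeric(length(tt))
  for (k in seq_len(3)) {
    tr <- tone_input_trace(protocol, unit = k, params = params, times = tt)
    ibar <- ibar + tr
  }
  fb <- numeric(length(tt))
  f <- 0
  for (j in seq_along(tt)[-1]) {
    # Heun step; the equation is stiff-free and smooth between tone onsets
    d1 <- -f^2 / params$tau_F1 + ibar[j - 1] / params$tau_F2
    fp <- f + dt * d1
    d2 <- -fp^2 / params$tau_F1 + ibar[j] / params$tau_F2
    f <- f + dt * (d1 + d2) / 2
    fb[j] <- f
  }
  out <- data.frame(time_ms = tt, Fbar = fb)
  last5 <- tt >= (t_end - 5000)
  attr(out, "asymptote") <- mean(fb[last5])
  out
}

#' Select the baseline-inhibition regime
#'
#' Maps the asymptote of the slow baseline-facilitation variable to the
#' weak- or strong-inhibition parameter set: at or above the threshold
#' `F_th` the weak regime applies (nominal weights, SST threshold 1); below
#' it the Exc-row inhibitory weights strengthen and the SST threshold drops
#' to 0. `mode = "smooth"` instead returns the sigmoidal blend of the two
#' parameter sets at the given `Fbar` value.
#'
#' @param Fbar_asymptote Nonnegative asymptote of the baseline facilitation.
#' @param params [three_unit_params()].
#' @param mode `"heaviside"` (default) or `"smooth"`.
#' @return A list with elements `regime` ("weak"/"strong"/"blend"), `W`
#'   (3x3 effective weight matrix) and `s_th`.
#' @export
select_regime <- function(Fbar_asymptote, params = three_unit_params(),
                          mode = c("heaviside", "smooth")) {
  mode <- match.arg(mode)
  if (!is.finite(Fbar_asymptote) || Fbar_asymptote < 0)
    stop("`Fbar_asymptote` must be a nonnegative number")
  if (mode == "heaviside") {
    if (Fbar_asymptote >= params$F_th)
      list(regime = "weak", W = params$W, s_th = params$s_th)
    else
      list(regime = "strong", W = params$W_strong, s_th = params$s_th_strong)
  } else {
    h <- 1 / (1 + exp(-params$h_gain * (Fbar_asymptote - params$F_th)))
    W <- h * params$W + (1 - h) * params$W_strong
    list(regime = "blend", W = W,
         s_th = h * params$s_th + (1 - h) * params$s_th_strong, h = h)
  }
}

#' @export
print.rate_params <- function(x, ...) {
  tier <- if (inherits(x, "three_unit_params")) "three-unit" else "single-unit"
  cat(sprintf("<%s rate model parameters>\n", tier))
  cat("  W (post x pre, Exc/PV/SST):\n")
  print(x$W)
  cat(sprintf("  thresholds u/p/s: %.2f %.2f %.2f   gain r: %.1f\n",
              x$u_th, x$p_th, x$s_th, x$r))
  cat(sprintf("  q = %.2f, tau_q = %g ms, depression tau = %g/%g ms\n",
              x$q, x$tau_q, x$tau_d1, x$tau_d2))
  if (inherits(x, "three_unit_params"))
    cat(sprintf("  lateral w: %.3f/%.3f/%.3f, alpha = %.2f, a = %.2f, b = %.2f\n",
                x$w_ee_lat, x$w_pe_lat, x$w_se_lat, x$alpha, x$a_dep, x$b_fac))
  invisible(x)
}
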