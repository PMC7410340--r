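#' Right-hand side of the single iso-frequency unit
#'
#' Reference (plain R) evaluation of the Wilson-Cowan derivatives of one
#' unit: Exc and PV receive the depressed thalamic drive, SST receives only
#' recurrent excitation, and the optogenetic drives enter the PV and SST
#' gain arguments before thresholding. Used as the independent oracle for
#' the compiled integrator and for didactic inspection; the simulator itself
#' runs compiled code.
#'
#' @param state Named list or vector with `u`, `p`, `s`, `g`.
#' @param drive Instantaneous raw thalamic input value `i(t)` (nonnegative).
#' @param opto Length-2 numeric `(I_pv, I_sst)`.
#' @param params [rate_params()].
#' @return Named numeric vector of derivatives `(du, dp, ds, dg)` per ms.
#' @export
single_unit_rhs <- function(state, drive, opto = c(0, 0),
                            params = rate_params()) {
  u <- state[["u"]]; p <- state[["p"]]; s <- state[["s"]]; g <- state[["g"]]
  W <- params$W
  thal <- params$q * g * drive
  fu <- threshold_linear(W[1, 1] * u - W[1, 2] * p - W[1, 3] * s + thal,
                         params$r, params$u_th)
  fp <- threshold_linear(W[2, 1] * u - W[2, 2] * p - W[2, 3] * s +
                           opto[1] + thal, params$r, params$p_th)
  fs <- threshold_linear(W[3, 1] * u - W[3, 2] * p - W[3, 3] * s + opto[2],
                         params$r, params$s_th)
  c(du = (-u + fu) / params$tau_u,
    dp = (-p + fp) / params$tau_p,
    ds = (-s + fs) / params$tau_s,
    dg = (params$g0 - g) / params$tau_d1 - g * drive / params$tau_d2)
}

#' Lateral coupling terms of the three-unit model
#'
#' Computes the between-unit inputs `(J1, J2, J3)` (into Exc, PV, SST) of
#' one unit: edge units receive from the center only, the center receives
#' the mean of the two edges. `J1` carries the facilitation-gated lateral
#' SST inhibition and the thalamic drive (with cross-unit spread already
#' mixed into `I`), `J2` the lateral Exc->PV excitation plus the thalamic
#' drive, `J3` the lateral Exc->SST excitation.
#'
#' @param unit Unit index (1..3).
#' @param u,s Length-3 activity vectors of the Exc and SST populations.
#' @param Fi Facilitation value of the receiving unit.
#' @param I Length-3 vector of depressed, spread-mixed thalamic drives.
#' @param params [three_unit_params()].
#' @return Named numeric `(J1, J2, J3)`.
#' @export
lateral_terms <- function(unit, u, s, Fi, I, params = three_unit_params()) {
  if (length(u) != 3 || length(s) != 3 || length(I) != 3)
    stop("the tonotopic model has exactly 3 units")
  if (unit == 2) {
    lat_u <- (u[1] + u[3]) / 2
    lat_s <- s[1] + s[3]
  } else {
    lat_u <- u[2]
    lat_s <- s[2]
  }
  c(J1 = -params$b_fac * Fi * lat_s + params$q * I[unit] +
      params$w_ee_lat * lat_u,
    J2 = params$q * I[unit] + params$w_pe_lat * lat_u,
    J3 = params$w_se_lat * lat_u)
}

#' Simulate the rate model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the single-unit or
#' three-unit rate model under a tone protocol and optional optogenetic
#' schedule. Initial state: all activities 0, thalamic depression at
#' baseline (g = 1), facilitation 0, PV->Exc depression 1. The exogenous
#' tone traces are advanced analytically between steps, so tone onsets land
#' exactly on the grid.
#'
#' For the three-unit model the baseline-inhibition regime is resolved once,
#' before the run: `regime = "auto"` looks the paradigm up in the preset
#' table and falls back to classifying the protocol through
#' [baseline_facilitation()] and [select_regime()] for unknown paradigms.
#'
#' @param params [rate_params()] or [three_unit_params()]; the tier follows
#'   the class (`n_units` 1 or 3).
#' @param protocol A [tone_protocol()].
#' @param opto `NULL`, an [make_opto()] schedule, or a list of them.
#' @param dt Integration step (ms).
#' @param t_end Simulation span (ms); defaults to the protocol span.
#' @param record_dt Sampling interval of the stored traces (ms); must be a
#'   multiple of `dt`.
#' @param regime `"auto"`, `"weak"` or `"strong"` (three-unit only).
#' @return A `rate_trajectory`: list with `time` (ms), `traces` (3-d array
#'   time x variable x unit, variables u, p, s, g, F, D, exc, inh, thal),
#'   and metadata (`params`, `regime`, `paradigm`, `dt`).
#' @export
simulate_rate <- function(params, protocol, opto = NULL, dt = 0.1,
                          t_end = NULL, record_dt = 1,
                          regime = c("auto", "weak", "strong")) {
  regime <- match.arg(regime)
  three <- inherits(params, "three_unit_params")
  n <- if (three) 3L else 1L
  if (is.null(t_end)) t_end <- protocol$span
  rec_every <- as.integer(round(record_dt / dt))
  if (rec_every < 1 || abs(rec_every * dt - record_dt) > 1e-9)
    stop("`record_dt` must be a positive multiple of `dt`")

  W <- params$W; s_th <- params$s_th
  used_regime <- "single_unit"
  if (three) {
    if (regime == "auto") {
      preset_regime <- tryCatch(paradigm_preset(protocol$paradigm)$regime,
                                error = function(e) NULL)
      regime <- if (!is.null(preset_regime)) preset_regime else {
        fb <- baseline_facilitation(protocol, params)
        select_regime(attr(fb, "asymptote"), params)$regime
      }
    }
    used_regime <- regime
    if (regime == "strong") {
      W <- params$W_strong
      s_th <- params$s_th_strong
    }
  }

  pars <- list(n_units = n, W = as.numeric(t(W)),
               u_th = params$u_th, p_th = params$p_th, s_th = s_th,
               r = params$r, tau_u = params$tau_u, tau_p = params$tau_p,
               tau_s = params$tau_s, q = params$q, tau_q = params$tau_q,
               tau_d1 = params$tau_d1, tau_d2 = params$tau_d2,
               g0 = params$g0,
               a_dep = if (three) params$a_dep else 0,
               b_fac = if (three) params$b_fac else 0,
               alpha = if (three) params$alpha else 0,
               w_ee_lat = if (three) params$w_ee_lat else 0,
               w_pe_lat = if (three) params$w_pe_lat else 0,
               w_se_lat = if (three) params$w_se_lat else 0,
               use_proxy = if (three) params$use_proxy else TRUE)

  tn <- protocol$tones
  onsets <- lapply(seq_len(n), function(k) tn$onset[tn$unit == k])
  amps <- lapply(seq_len(n), function(k) tn$amp[tn$unit == k])
  if (n == 1 && nrow(tn)) { onsets[[1]] <- tn$onset; amps[[1]] <- tn$amp }
  ow <- .opto_windows(opto)

  res <- .rate_integrate_cpp(pars, onsets, amps, ow$pv, ow$sst,
                             t_end, dt, rec_every)
  m <- res$traces
  vars <- c("u", "p", "s", "g", "F", "D", "exc", "inh", "thal")
  arr <- array(m[, -1, drop = FALSE],
               dim = c(nrow(m), 9, n),
               dimnames = list(NULL, vars, paste0("unit", seq_len(n))))
  structure(list(time = m[, 1], traces = arr, params = params,
                 protocol = protocol, regime = used_regime,
                 paradigm = protocol$paradigm, opto = opto, dt = dt,
                 record_dt = record_dt),
            class = "rate_trajectory")
}

#' Extract one trace from a rate trajectory
#'
#' @param x A `rate_trajectory`.
#' @param var Variable name (`"u"`, `"p"`, `"s"`, `"g"`, `"F"`, `"D"`,
#'   `"exc"`, `"inh"`, `"thal"`).
#' @param unit Unit index.
#' @return Numeric vector on the trajectory's time grid.
#' @export
trace_of <- function(x, var = "u", unit = if (dim(x$traces)[3] == 3) 2 else 1) {
  stopifnot(inherits(x, "rate_trajectory"))
  x$traces[, var, unit]
}

#' @export
print.rate_trajectory <- function(x, ...) {
  n <- dim(x$traces)[3]
  cat(sprintf("<rate_trajectory: %d unit(s), %.2f s at dt = %g ms (%s regime)>\n",
              n, max(x$time) / 1000, x$dt, x$regime))
  peak <- apply(x$traces[, "u", , drop = FALSE], 3, max)
  cat(sprintf("  peak Exc activity per unit: %s\n",
              paste(sprintf("%.3f", peak), collapse = " ")))
  invisible(x)
}

#' @export
summary.rate_trajectory <- function(object, ...) {
  n <- dim(object$traces)[3]
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    data.frame(unit = k,
               peak_u = max(object$traces[, "u", k]),
               mean_u = mean(object$traces[, "u", k]),
               peak_p = max(object$traces[, "p", k]),
               peak_s = max(object$traces[, "s", k]),
               min_g = min(object$traces[, "g", k]))
  }))
  out
}

#' @export
plot.rate_trajectory <- function(x, unit = if (dim(x$traces)[3] == 3) 2 else 1,
                                 vars = c("u", "p", "s"), ...) {
  cols <- c(u = "blue", p = "cyan3", s = "magenta", g = "gray40",
            thal = "red", exc = "darkgreen", inh = "darkorange")
  matplot(x$time / 1000, x$traces[, vars, unit], type = "l", lty = 1,
          col = cols[vars], xlab = "time (s)", ylab = "activity", ...)
  legend("topright", legend = vars, col = cols[vars], lty = 1, bty = "n")
  invisible(x)
}

#' Tidy data.frame of a rate trajectory
#'
#' @param x A `rate_trajectory`.
#' @param ... Unused.
#' @return Long-format data.frame with columns `time_ms`, `unit`,
#'   `variable`, `value`.
#' @export
as.data.frame.rate_trajectory <- function(x, ...) {
  n <- dim(x$traces)[3]
  vars <- dimnames(x$traces)[[2]]
  do.call(rbind, lapply(seq_len(n), function(k) {
    do.call(rbind, lapply(vars, function(v) {
      data.frame(time_ms = x$time, unit = k, variable = v,
                 value = x$traces[, v, k])
    }))
  }))
}

#' Write a trajectory to tidy CSV with a JSON sidecar
#'
#' The CSV holds the long-format traces; the sidecar records the paradigm,
#' regime, integration step and parameters so a run can be identified later.
#'
#' @param x A `rate_trajectory`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(paradigm = x$paradigm, regime = x$regime, dt = x$dt,
               record_dt = x$record_dt, span = max(x$time),
               params = unclass(x$params)[c("q", "u_th", "p_th", "s_th", "r",
                                            "tau_d1", "tau_d2")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
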