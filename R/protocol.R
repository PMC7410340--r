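#' Construct a tone protocol
#'
#' A tone protocol is the full stimulus timetable of a paradigm: a table of
#' tones (onset, duration, target iso-frequency unit, amplitude scale), the
#' trial boundaries, a paradigm id and the total simulated span. The three
#' iso-frequency units are abstract frequency channels (left = 1,
#' center = 2, right = 3); there is no frequency axis in Hz.
#'
#' @param tones data.frame with columns `onset`, `duration`, `unit`, `amp`
#'   (ms, ms, 1..3, dimensionless).
#' @param paradigm Paradigm id, one of `"ssa"`, `"ssa_simple"`, `"fws"`,
#'   `"tca"`, `"pv_act"`, or a free label.
#' @param span Total protocol span (ms); defaults to last offset + 500 ms.
#' @param trial_starts Optional trial boundary onsets (ms).
#' @param seed RNG seed used to generate the protocol, if any.
#' @return An object of class `tone_protocol`.
#' @export
tone_protocol <- function(tones, paradigm = "custom", span = NULL,
                          trial_starts = NULL, seed = NA_integer_) {
  tones <- as.data.frame(tones)
  stopifnot(all(c("onset", "duration", "unit", "amp") %in% names(tones)))
  tones <- tones[order(tones$onset), , drop = FALSE]
  rownames(tones) <- NULL
  if (nrow(tones) && (any(tones$duration <= 0) ||
                      any(!tones$unit %in% 1:3) || any(tones$amp < 0)))
    stop("invalid tone table")
  for (u in unique(tones$unit)) {
    tu <- tones[tones$unit == u, ]
    if (nrow(tu) > 1 &&
        any(tu$onset[-1] < (tu$onset + tu$duration)[-nrow(tu)]))
      stop("overlapping tones addressed to unit ", u)
  }
  if (is.null(span))
    span <- if (nrow(tones)) max(tones$onset + tones$duration) + 500 else 1000
  structure(list(tones = tones, paradigm = paradigm, span = span,
                 trial_starts = trial_starts, seed = seed),
            class = "tone_protocol")
}

#' @export
print.tone_protocol <- function(x, ...) {
  cat(sprintf("<tone_protocol '%s': %d tones over %.1f s>\n",
              x$paradigm, nrow(x$tones), x$span / 1000))
  if (nrow(x$tones)) {
    per_unit <- table(factor(x$tones$unit, levels = 1:3))
    cat(sprintf("  tones per unit (L/C/R): %s\n",
                paste(per_unit, collapse = "/")))
  }
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Oddball (stimulus-specific adaptation) protocol
#'
#' A continuous stream of tones addressed to the two edge units flanking the
#' recorded center unit: the standard tone appears with probability
#' `1 - p_deviant`, the deviant with `p_deviant`. The first tone is never a
#' deviant and deviants are never consecutive. `swap = TRUE` exchanges the
#' standard and deviant units, producing the counterbalanced block needed by
#' the common-contrast SSA index.
#'
#' @param n_tones Number of tones in the block.
#' @param p_deviant Deviant probability, in (0, 1) (0 gives all standards).
#' @param units Length-2 integer vector `(standard, deviant)` unit indices.
#' @param seed RNG seed for the deviant placement.
#' @param swap Exchange standard and deviant units (identical timing).
#' @param duration Tone duration (ms).
#' @param isi Silent gap between tone offset and the next onset (ms).
#' @param t0 Onset of the first tone (ms).
#' @return A [tone_protocol()]; deviant tone rows carry `amp = 1` and the
#'   logical column `deviant`.
#' @export
make_oddball <- function(n_tones = 500, p_deviant = 0.1, units = c(1, 3),
                         seed = 1, swap = FALSE, duration = 100, isi = 300,
                         t0 = 100) {
  if (p_deviant < 0 || p_deviant >= 1) stop("`p_deviant` must lie in [0, 1)")
  stopifnot(length(units) == 2, all(units %in% 1:3), units[1] != units[2])
  if (swap) units <- rev(units)
  dev <- with_seed(seed, runif(n_tones) < p_deviant)
  dev[1] <- FALSE
  for (j in seq_len(n_tones)[-1]) if (dev[j] && dev[j - 1]) dev[j] <- FALSE
  onsets <- t0 + (seq_len(n_tones) - 1) * (duration + isi)
  tones <- data.frame(onset = onsets, duration = duration,
                      unit = ifelse(dev, units[2], units[1]), amp = 1,
                      deviant = dev)
  tone_protocol(tones, paradigm = "ssa", seed = seed)
}

#' Forward-suppression protocol
#'
#' Pairs of tones: a masker whose frequency (unit) varies between trials,
#' followed 20 ms later by a probe fixed at the center unit. A masker-absent
#' trial provides the unsuppressed reference that defines 100% when probe
#' responses are normalized. Trials are 500 ms long (50 ms masker + 20 ms
#' gap + 50 ms probe + 380 ms inter-trial interval) and preceded by 500 ms
#' of silence so that tone-locked optogenetic windows fit before the first
#' masker.
#'
#' @param masker_units Masker units per trial; `NA` marks the masker-absent
#'   reference trial.
#' @param probe_unit Probe unit; must be the center (2).
#' @param duration Tone duration (ms).
#' @param gap Masker-offset to probe-onset gap (ms).
#' @param iti Inter-trial interval after the probe (ms).
#' @return A [tone_protocol()] whose tone rows carry a `role` column
#'   ("masker"/"probe") and a `trial` index.
#' @export
make_forward_suppression <- function(masker_units = c(NA, 1, 2, 3),
                                     probe_unit = 2, duration = 50,
                                     gap = 20, iti = 380) {
  if (probe_unit != 2) stop("the probe is fixed at the center unit")
  trial_span <- 2 * duration + gap + iti
  starts <- 500 + (seq_along(masker_units) - 1) * trial_span
  rows <- list()
  for (j in seq_along(masker_units)) {
    m <- masker_units[j]
    if (!is.na(m))
      rows[[length(rows) + 1]] <- data.frame(onset = starts[j],
                                             duration = duration, unit = m,
                                             amp = 1, role = "masker",
                                             trial = j)
    rows[[length(rows) + 1]] <- data.frame(onset = starts[j] + duration + gap,
                                           duration = duration,
                                           unit = probe_unit, amp = 1,
                                           role = "probe", trial = j)
  }
  tone_protocol(do.call(rbind, rows), paradigm = "fws",
                span = max(starts) + trial_span, trial_starts = starts)
}

#' Tuning-curve adaptation protocol
#'
#' For each iso-frequency unit in turn, a trial of `n_repeats` identical
#' tones (100 ms tone, 300 ms inter-stimulus interval); successive trials
#' are separated by a 2400 ms inter-trial interval measured from the last
#' tone offset.
#'
#' @param n_repeats Tones per trial (8).
#' @param units Stimulated units, one trial each.
#' @param duration Tone duration (ms).
#' @param isi Within-trial silent gap (ms).
#' @param iti Inter-trial interval (ms).
#' @param t0 Onset of the first tone (ms).
#' @return A [tone_protocol()] with `trial` and `rep` columns.
#' @export
make_tuning_adaptation <- function(n_repeats = 8, units = 1:3,
                                   duration = 100, isi = 300, iti = 2400,
                                   t0 = 100) {
  rows <- list()
  t <- t0
  starts <- numeric(length(units))
  for (j in seq_along(units)) {
    starts[j] <- t
    onsets <- t + (seq_len(n_repeats) - 1) * (duration + isi)
    rows[[j]] <- data.frame(onset = onsets, duration = duration,
                            unit = units[j], amp = 1, trial = j,
                            rep = seq_len(n_repeats))
    t <- onsets[n_repeats] + duration + iti
  }
  tone_protocol(do.call(rbind, rows), paradigm = "tca",
                trial_starts = starts)
}

#' Single-tone (PV activation) protocol
#'
#' One 50 ms tone per 1 s trial, presented 100 ms into the trial, at the
#' named unit. Used for the feedforward-connectivity paradigm in which a
#' sustained laser accompanies the tone on stimulation trials.
#'
#' @param unit Stimulated unit.
#' @param n_trials Number of trials.
#' @param duration Tone duration (ms).
#' @param iti Inter-trial interval after tone offset (ms).
#' @return A [tone_protocol()].
#' @export
make_single_tone <- function(unit = 2, n_trials = 1, duration = 50,
                             iti = 950) {
  if (n_trials < 1) return(tone_protocol(
    data.frame(onset = numeric(), duration = numeric(), unit = integer(),
               amp = numeric()), paradigm = "pv_act", span = 0))
  trial_span <- duration + iti
  starts <- (seq_len(n_trials) - 1) * trial_span
  tones <- data.frame(onset = starts + 100, duration = duration, unit = unit,
                      amp = 1, trial = seq_len(n_trials))
  tone_protocol(tones, paradigm = "pv_act", span = n_trials * trial_span,
                trial_starts = starts)
}

#' Thalamic input trace of one unit
#'
#' Each tone produces an instantaneous rise of the unit's input trace by the
#' tone amplitude followed by exponential decay with `tau_q`. With
#' `spread = TRUE` the trace also includes the fraction `alpha` of tones
#' addressed to adjacent units that reaches this unit through the divergent
#' thalamic projection. The depression variable of a unit is driven by the
#' raw (`spread = FALSE`) trace of that unit's own tones only.
#'
#' @param protocol A [tone_protocol()].
#' @param unit Unit index (1..3).
#' @param params [rate_params()] (supplies `tau_q` and, for spread, `alpha`).
#' @param times Evaluation grid (ms); defaults to 1 ms sampling of the span.
#' @param spread Include the cross-unit thalamic spread.
#' @return Numeric vector of input values at `times`.
#' @export
tone_input_trace <- function(protocol, unit, params = three_unit_params(),
                             times = NULL, spread = FALSE) {
  if (is.null(times)) times <- seq(0, protocol$span, by = 1)
  tr <- numeric(length(times))
  add_tone <- function(tr, onset, amp) {
    idx <- times >= onset
    tr[idx] <- tr[idx] + amp * exp(-(times[idx] - onset) / params$tau_q)
    tr
  }
  tones <- protocol$tones
  for (j in seq_len(nrow(tones))) {
    if (tones$unit[j] == unit) {
      tr <- add_tone(tr, tones$onset[j], tones$amp[j])
    } else if (spread && abs(tones$unit[j] - unit) == 1) {
      tr <- add_tone(tr, tones$onset[j], params$alpha * tones$amp[j])
    }
  }
  tr
}

#' Serialize / read a tone protocol (JSON)
#'
#' @param protocol A [tone_protocol()].
#' @param path File path.
#' @return `read_protocol_json()` returns the [tone_protocol()];
#'   `write_protocol_json()` returns `path` invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  obj <- list(paradigm = protocol$paradigm, span = protocol$span,
              trial_starts = protocol$trial_starts, seed = protocol$seed,
              tones = protocol$tones)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- if (is.null(obj$seed)) NA_integer_ else obj$seed
  ts <- obj$trial_starts
  if (!is.null(ts) && length(ts) == 0) ts <- NULL
  tone_protocol(obj$tones, paradigm = obj$paradigm, span = obj$span,
                trial_starts = ts, seed = seed)
}
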