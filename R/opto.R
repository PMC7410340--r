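# Per-paradigm defaults: input strength q, baseline-inhibition regime and
# optogenetic drive amplitudes (rate tier dimensionless, spiking tier nA).
# Suppression amplitudes are negative, activation positive.
.preset_table <- function() {
  list(
    ssa_simple = list(q = 5, regime = "weak", timing = "tone_locked",
                      rate = c(pv_suppress = -2, sst_suppress = -1),
                      spiking = c()),
    ssa = list(q = 5, regime = "weak", timing = "tone_locked",
               rate = c(pv_suppress = -4, pv_activate = 0.5,
                        sst_suppress = -2, sst_activate = 1.2),
               spiking = c(pv_suppress = -0.2, sst_suppress = -1)),
    fws = list(q = 1.3, regime = "strong", timing = "tone_locked",
               rate = c(pv_suppress = -0.5, pv_activate = 0.25,
                        sst_suppress = -0.5, sst_activate = 0.1),
               spiking = c(pv_suppress = -0.2, pv_activate = 0.1,
                           sst_suppress = -1, sst_activate = 2)),
    tca = list(q = 5, regime = "strong", timing = "sustained",
               rate = c(pv_suppress = -0.5, pv_activate = 1.2,
                        sst_suppress = -1, sst_activate = 0.1),
               spiking = c(pv_suppress = -1, sst_suppress = -1)),
    pv_act = list(q = 5, regime = "strong", timing = "sustained",
                  rate = c(pv_activate = 2),
                  spiking = c(pv_activate = 0.5))
  )
}

#' Paradigm preset defaults
#'
#' Returns the per-paradigm defaults shared by both model tiers: the
#' thalamic input strength `q`, the baseline-inhibition regime the paradigm
#' settles into, the optogenetic timing mode (tone-locked or sustained) and
#' the optogenetic amplitudes for each (target, condition, tier).
#'
#' @param name One of `"ssa_simple"`, `"ssa"`, `"fws"`, `"tca"`, `"pv_act"`.
#' @return A list with elements `q`, `regime`, `timing`, `rate`, `spiking`.
#' @export
paradigm_preset <- function(name) {
  tab <- .preset_table()
  if (!name %in% names(tab)) stop("unknown paradigm preset: ", name)
  tab[[name]]
}

#' Optogenetic schedule for a protocol
#'
#' Builds the laser-drive schedule of a paradigm: an additive current into
#' the PV or SST population, either locked to the tones (a window opening
#' 100 ms before each tone onset and closing 100 ms after its offset, with
#' overlapping windows merged) or sustained over the whole protocol span.
#' Amplitudes come from the per-paradigm defaults unless overridden:
#' positive values activate, negative values suppress.
#'
#' @param protocol A [tone_protocol()].
#' @param preset Paradigm preset name; defaults to the protocol's paradigm.
#' @param target `"PV"` or `"SST"`.
#' @param condition `"suppress"` or `"activate"`.
#' @param tier `"rate"` (dimensionless amplitude) or `"spiking"` (nA).
#' @param amplitude Override amplitude (sign encodes direction).
#' @param mode Override timing mode (`"tone_locked"` or `"sustained"`).
#' @param pre,post Tone-locked window margins before onset / after offset
#'   (ms). Defaults: 100/100 for suppression (the laser precedes the tone by
#'   100 ms and outlasts it by 100 ms); 0/0 for activation (the laser is
#'   concurrent with the tone).
#' @return An object of class `opto_schedule` with a `windows` matrix
#'   (columns start, end, amplitude).
#' @export
make_opto <- function(protocol, preset = protocol$paradigm,
                      target = c("PV", "SST"),
                      condition = c("suppress", "activate"),
                      tier = c("rate", "spiking"),
                      amplitude = NULL, mode = NULL,
                      pre = NULL, post = NULL) {
  target <- match.arg(target)
  condition <- match.arg(condition)
  tier <- match.arg(tier)
  if (is.null(pre)) pre <- if (condition == "suppress") 100 else 0
  if (is.null(post)) post <- if (condition == "suppress") 100 else 0
  p <- paradigm_preset(preset)
  key <- paste0(tolower(target), "_", condition)
  if (is.null(amplitude)) {
    amps <- p[[tier]]
    if (!key %in% names(amps))
      stop(sprintf("no %s-tier %s amplitude defined for preset '%s'",
                   tier, key, preset))
    amplitude <- unname(amps[key])
  }
  if (is.null(mode)) mode <- p$timing
  if (!mode %in% c("tone_locked", "sustained")) stop("unknown opto mode")

  if (mode == "sustained") {
    win <- cbind(0, protocol$span, amplitude)
  } else {
    tn <- protocol$tones
    if (!nrow(tn)) {
      win <- matrix(numeric(), 0, 3)
    } else {
      s <- pmax(0, tn$onset - pre)
      e <- tn$onset + tn$duration + post
      o <- order(s)
      s <- s[o]; e <- e[o]
      ms <- s[1]; me <- e[1]; out <- list()
      for (j in seq_along(s)[-1]) {
        if (s[j] <= me) me <- max(me, e[j])
        else { out[[length(out) + 1]] <- c(ms, me); ms <- s[j]; me <- e[j] }
      }
      out[[length(out) + 1]] <- c(ms, me)
      win <- cbind(do.call(rbind, out), amplitude)
    }
  }
  colnames(win) <- c("start", "end", "amplitude")
  structure(list(target = target, condition = condition, tier = tier,
                 amplitude = amplitude, mode = mode, windows = win),
            class = "opto_schedule")
}

#' @export
print.opto_schedule <- function(x, ...) {
  cat(sprintf("<opto_schedule: %s %s (%s tier), amplitude %g, %s, %d window(s)>\n",
              x$target, x$condition, x$tier, x$amplitude, x$mode,
              nrow(x$windows)))
  invisible(x)
}

# Split an optional opto schedule into the (PV, SST) window matrices the
# integrators expect.
.opto_windows <- function(opto) {
  empty <- matrix(numeric(), 0, 3)
  pv <- empty; sst <- empty
  if (!is.null(opto)) {
    if (inherits(opto, "opto_schedule")) opto <- list(opto)
    for (o in opto) {
      stopifnot(inherits(o, "opto_schedule"))
      if (o$target == "PV") pv <- rbind(pv, o$windows)
      else sst <- rbind(sst, o$windows)
    }
    if (nrow(pv)) pv <- pv[order(pv[, 1]), , drop = FALSE]
    if (nrow(sst)) sst <- sst[order(sst[, 1]), , drop = FALSE]
  }
  list(pv = pv, sst = sst)
}
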