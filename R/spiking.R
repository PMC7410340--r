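#' Spiking neuron parameters
#'
#' Constants of the conductance-based adaptive exponential
#' integrate-and-fire (AdEx) neurons: two-compartment (ball-and-stick)
#' excitatory cells and single-compartment PV and SST cells. The population
#' vectors are ordered (Exc, PV, SST). Membrane constants follow the model's
#' standard table; the adaptation constants (`a_w`, `tau_w`, spike increment
#' `b_w`), the 2 ms refractory period and the spike cutoff `V_T + 5 Delta_T`
#' are canonical AdEx choices exposed here for adjustment.
#'
#' @param C_m Capacitance (pF) per population.
#' @param E_L Leak reversal (mV).
#' @param g_L Leak conductance (nS).
#' @param Delta_T Spike sharpness (mV).
#' @param V_T Exponential threshold (mV).
#' @param V_reset Post-spike reset (mV).
#' @param I_baseline Constant background drive (nA).
#' @param g_sd Somato-dendritic coupling conductance (nS, Exc only).
#' @param kappa Somatic-to-total surface ratio of Exc cells.
#' @param noise_sigma Free-membrane voltage noise SD (mV).
#' @param a_w,tau_w,b_w Adaptation coupling (nS), time constant (ms) and
#'   spike-triggered increment (nA).
#' @param refractory Absolute refractory period (ms).
#' @param spike_cutoff Numerical spike detection voltage (mV) per population.
#' @param a_pv PV->Exc depression scale.
#' @param b_fac Dendritic facilitation strength.
#' @param tau_I,tau_d_fast,tau_d1,tau_d2,tau_f1,tau_f2 Time constants (ms)
#'   of the thalamic input profile (fast rise, fast/slow depression) and of
#'   the PV->Exc depression / dendritic facilitation variables.
#' @param lateral_spread Fraction of the thalamic amplitude reaching the
#'   adjacent unit.
#' @return A list of class `spiking_params`.
#' @export
spiking_params <- function(C_m = c(180, 80, 80), E_L = c(-60, -60, -60),
                           g_L = c(6.25, 5, 5), Delta_T = c(1, 0.25, 1),
                           V_T = c(-40, -40, -45),
                           V_reset = c(-60, -60, -60),
                           I_baseline = c(0.35, 0.05, 0.025),
                           g_sd = 18.75, kappa = 0.3, noise_sigma = 20,
                           a_w = 4, tau_w = 150, b_w = 0.08,
                           refractory = 2,
                           spike_cutoff = V_T + 5 * Delta_T,
                           a_pv = 1.7, b_fac = 3,
                           tau_I = 1, tau_d_fast = 10,
                           tau_d1 = 1000, tau_d2 = 250,
                           tau_f1 = 1000, tau_f2 = 250,
                           lateral_spread = 0.85) {
  stopifnot(all(C_m > 0), all(Delta_T > 0), kappa > 0, kappa < 1)
  structure(list(C_m = C_m, E_L = E_L, g_L = g_L, Delta_T = Delta_T,
                 V_T = V_T, V_reset = V_reset, I_baseline = I_baseline,
                 g_sd = g_sd, kappa = kappa, noise_sigma = noise_sigma,
                 a_w = a_w, tau_w = tau_w, b_w = b_w,
                 refractory = refractory, spike_cutoff = spike_cutoff,
                 a_pv = a_pv, b_fac = b_fac, tau_I = tau_I,
                 tau_d_fast = tau_d_fast, tau_d1 = tau_d1, tau_d2 = tau_d2,
                 tau_f1 = tau_f1, tau_f2 = tau_f2,
                 lateral_spread = lateral_spread,
                 C_m_dend = 180, g_L_dend = 6.25),
            class = "spiking_params")
}

#' Synaptic conductance parameters
#'
#' Maximal conductances (nS), decay time constants (ms) and reversal
#' potentials of the event-driven synapses. Rows of `Gmax` are postsynaptic
#' (Exc, PV, SST), columns presynaptic; SST receives no inhibition. In the
#' weak baseline-inhibition regime the inhibitory inputs into Exc drop from
#' 40/20 nS to 38/19 nS. Every presynaptic spike increments the postsynaptic
#' conductance by `Gmax / n_X`, `n_X` the presynaptic population size.
#'
#' @param regime `"strong"` or `"weak"` baseline inhibition.
#' @param Gmax 3x3 maximal conductance matrix (nS).
#' @param g_ep_weak,g_es_weak Weak-regime PV->Exc and SST->Exc maxima (nS).
#' @param tau_default,tau_pe,tau_se Conductance decay constants (ms).
#' @param E_exc,E_inh Excitatory / inhibitory reversal potentials (mV).
#' @return A list of class `synapse_params`.
#' @export
synapse_params <- function(regime = c("strong", "weak"),
                           Gmax = matrix(c(20, 40, 20,
                                           240, 40, 12,
                                           120, 0, 0), 3, 3, byrow = TRUE),
                           g_ep_weak = 38, g_es_weak = 19,
                           tau_default = 1, tau_pe = 25, tau_se = 15,
                           E_exc = 0, E_inh = -67) {
  regime <- match.arg(regime)
  Gmax <- matrix(as.numeric(Gmax), 3, 3)
  stopifnot(all(Gmax >= 0), all(Gmax[3, 2:3] == 0))
  if (regime == "weak") {
    Gmax[1, 2] <- g_ep_weak
    Gmax[1, 3] <- g_es_weak
  }
  structure(list(regime = regime, Gmax = Gmax,
                 tau_default = tau_default, tau_pe = tau_pe,
                 tau_se = tau_se, E_exc = E_exc, E_inh = E_inh),
            class = "synapse_params")
}

# class codes shared with the compiled integrator
.cls_codes <- c(ee = 0L, ep = 1L, es = 2L, pe = 3L, pp = 4L, ps = 5L,
                se = 6L)

.sample_edges <- function(n_pre, n_post, p, no_self = FALSE) {
  if (p <= 0 || n_pre == 0 || n_post == 0)
    return(cbind(pre = integer(), post = integer()))
  idx <- which(runif(n_pre * n_post) < p) - 1L
  pre <- idx %/% n_post
  post <- idx %% n_post
  if (no_self) {
    keep <- pre != post
    pre <- pre[keep]; post <- post[keep]
  }
  cbind(pre = pre, post = post)
}

#' Build a spiking network realization
#'
#' Samples the random connectivity of the three-unit spiking network:
#' within a unit every ordered pair is connected independently with the
#' class probability (0.1 for Exc->Exc, 0.6 for all other classes); between
#' adjacent units only excitatory-source connections exist (Exc->Exc,
#' Exc->PV, Exc->SST) with probability 0.1. Self-connections are excluded.
#' Identical seeds give bit-identical realizations.
#'
#' @param n_units Number of iso-frequency units.
#' @param n_e,n_p,n_s Neurons per population per unit.
#' @param p_ee Within-unit Exc->Exc connection probability.
#' @param p_within Probability for every other within-unit class.
#' @param p_lateral Adjacent-unit excitatory-source probability.
#' @param seed RNG seed.
#' @return An object of class `spiking_network` holding the flattened
#'   adjacency (`out_ptr`, `out_tgt`, `out_cls`, 0-based) and realized
#'   per-class connection counts.
#' @export
build_network <- function(n_units = 3, n_e = 1600, n_p = 200, n_s = 200,
                          p_ee = 0.1, p_within = 0.6, p_lateral = 0.1,
                          seed = 1) {
  stopifnot(n_units >= 1, n_e > 0, n_p > 0, n_s > 0,
            all(c(p_ee, p_within, p_lateral) >= 0),
            all(c(p_ee, p_within, p_lateral) <= 1))
  per_unit <- n_e + n_p + n_s
  N <- n_units * per_unit
  base_of <- function(k) (k - 1L) * per_unit
  off <- c(e = 0L, p = n_e, s = n_e + n_p)
  sizes <- c(e = n_e, p = n_p, s = n_s)

  pre_l <- list(); post_l <- list(); cls_l <- list()
  add <- function(edges, k_pre, pop_pre, k_post, pop_post, cls) {
    if (!nrow(edges)) return()
    i <- length(pre_l) + 1L
    pre_l[[i]] <<- base_of(k_pre) + off[[pop_pre]] + edges[, 1]
    post_l[[i]] <<- base_of(k_post) + off[[pop_post]] + edges[, 2]
    cls_l[[i]] <<- rep(.cls_codes[[cls]], nrow(edges))
  }

  with_seed(seed, {
    for (k in seq_len(n_units)) {
      add(.sample_edges(n_e, n_e, p_ee, no_self = TRUE), k, "e", k, "e", "ee")
      add(.sample_edges(n_p, n_e, p_within), k, "p", k, "e", "ep")
      add(.sample_edges(n_s, n_e, p_within), k, "s", k, "e", "es")
      add(.sample_edges(n_e, n_p, p_within), k, "e", k, "p", "pe")
      add(.sample_edges(n_p, n_p, p_within, no_self = TRUE), k, "p", k, "p", "pp")
      add(.sample_edges(n_s, n_p, p_within), k, "s", k, "p", "ps")
      add(.sample_edges(n_e, n_s, p_within), k, "e", k, "s", "se")
    }
    for (k in seq_len(n_units)) for (k2 in c(k - 1L, k + 1L)) {
      if (k2 < 1 || k2 > n_units) next
      add(.sample_edges(n_e, n_e, p_lateral), k, "e", k2, "e", "ee")
      add(.sample_edges(n_e, n_p, p_lateral), k, "e", k2, "p", "pe")
      add(.sample_edges(n_e, n_s, p_lateral), k, "e", k2, "s", "se")
    }
  })

  pre <- as.integer(unlist(pre_l, use.names = FALSE))
  post <- as.integer(unlist(post_l, use.names = FALSE))
  cls <- as.integer(unlist(cls_l, use.names = FALSE))
  o <- order(pre, post)
  pre <- pre[o]; post <- post[o]; cls <- cls[o]
  ptr <- c(0L, cumsum(tabulate(pre + 1L, nbins = N)))
  cls_counts <- table(factor(cls, levels = .cls_codes,
                             labels = names(.cls_codes)))
  structure(list(n_units = n_units, n_e = n_e, n_p = n_p, n_s = n_s,
                 out_ptr = as.integer(ptr), out_tgt = as.integer(post),
                 out_cls = as.integer(cls),
                 n_synapses = length(post),
                 class_counts = cls_counts, seed = seed,
                 p = c(ee = p_ee, within = p_within, lateral = p_lateral)),
            class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("<spiking_network: %d units x (%d Exc + %d PV + %d SST), %d synapses (seed %s)>\n",
              x$n_units, x$n_e, x$n_p, x$n_s, x$n_synapses,
              format(x$seed)))
  print(x$class_counts)
  invisible(x)
}

#' Simulate the spiking network
#'
#' Euler-Maruyama integration (default dt = 0.05 ms) of the conductance-
#' based AdEx network under a tone protocol: square-wave tones drive a
#' depressing thalamic current into Exc and PV neurons (with a 0.85-scaled
#' copy into adjacent units), optogenetic currents enter PV and/or SST
#' somas, and spikes propagate through the sampled adjacency with
#' exponentially decaying conductances. The baseline-inhibition regime
#' (weak for the oddball and forward-suppression paradigms, strong for
#' tuning-curve adaptation and PV activation) selects the PV->Exc and
#' SST->Exc maximal conductances.
#'
#' @param network A [build_network()] realization.
#' @param protocol A [tone_protocol()].
#' @param opto `NULL`, one [make_opto()] schedule (spiking tier), or a list.
#' @param params [spiking_params()].
#' @param synapses [synapse_params()]; if `NULL`, chosen from the paradigm
#'   preset's regime.
#' @param q Thalamic input strength (nA); defaults to the paradigm preset.
#' @param dt Integration step (ms).
#' @param t_end Simulation span (ms); defaults to the protocol span.
#' @param seed Seed of the membrane-noise generator.
#' @param record_dt Bin width of rate and current traces (ms).
#' @param return_spikes Keep the full spike list (set `FALSE` for long runs).
#' @return A `spike_result`: spike events, binned per-population spike
#'   counts, per-unit mean synaptic current decomposition into Exc
#'   (recurrent excitatory, PV-somatic inhibitory, SST-dendritic inhibitory
#'   magnitudes, thalamic drive; nA), and metadata.
#' @export
simulate_spiking <- function(network, protocol, opto = NULL,
                             params = spiking_params(), synapses = NULL,
                             q = NULL, dt = 0.05, t_end = NULL, seed = 1,
                             record_dt = 1, return_spikes = TRUE) {
  stopifnot(inherits(network, "spiking_network"))
  preset <- tryCatch(paradigm_preset(protocol$paradigm),
                     error = function(e) NULL)
  if (is.null(synapses)) {
    regime <- if (!is.null(preset)) preset$regime else "strong"
    synapses <- synapse_params(regime)
  }
  if (is.null(q)) q <- if (!is.null(preset)) preset$q else 5
  if (is.null(t_end)) t_end <- protocol$span

  G <- synapses$Gmax
  n_src <- c(ee = network$n_e, ep = network$n_p, es = network$n_s,
             pe = network$n_e, pp = network$n_p, ps = network$n_p,
             se = network$n_e)
  n_src["ps"] <- network$n_s
  gmax <- c(ee = G[1, 1], ep = G[1, 2], es = G[1, 3],
            pe = G[2, 1], pp = G[2, 2], ps = G[2, 3], se = G[3, 1])
  increment <- unname(gmax / n_src[names(gmax)])
  tau_syn <- unname(c(ee = synapses$tau_default, ep = synapses$tau_default,
                      es = synapses$tau_default, pe = synapses$tau_pe,
                      pp = synapses$tau_default, ps = synapses$tau_default,
                      se = synapses$tau_se))

  tn <- protocol$tones
  tone_int <- lapply(seq_len(network$n_units), function(k) {
    tk <- tn[tn$unit == k, , drop = FALSE]
    if (!nrow(tk)) matrix(numeric(), 0, 2)
    else cbind(tk$onset, tk$onset + tk$duration)
  })
  ow <- .opto_windows(opto)

  pars <- c(params[c("C_m", "E_L", "g_L", "Delta_T", "V_T", "V_reset",
                     "I_baseline", "spike_cutoff", "a_w", "tau_w", "b_w",
                     "refractory", "a_pv", "b_fac", "kappa", "g_sd",
                     "noise_sigma", "tau_I", "tau_d_fast", "tau_d1",
                     "tau_d2", "tau_f1", "tau_f2", "lateral_spread",
                     "C_m_dend", "g_L_dend")],
            list(E_exc = synapses$E_exc, E_inh = synapses$E_inh, q = q))

  net <- list(n_units = network$n_units, n_e = network$n_e,
              n_p = network$n_p, n_s = network$n_s,
              out_ptr = network$out_ptr, out_tgt = network$out_tgt,
              out_cls = network$out_cls, increment = increment,
              tau_syn = tau_syn)

  res <- .spiking_integrate_cpp(net, pars, tone_int, ow$pv, ow$sst,
                                t_end, dt, record_dt, as.numeric(seed),
                                return_spikes)
  spikes <- if (return_spikes)
    data.frame(time_ms = res$spike_t, neuron = res$spike_id) else NULL

  structure(list(spikes = spikes, counts = res$counts,
                 currents = res$currents, time = res$time,
                 network = network[c("n_units", "n_e", "n_p", "n_s", "seed")],
                 paradigm = protocol$paradigm, regime = synapses$regime,
                 q = q, dt = dt, record_dt = record_dt, seed = seed,
                 opto = opto, span = t_end),
            class = "spike_result")
}

#' @export
print.spike_result <- function(x, ...) {
  nsp <- if (!is.null(x$spikes)) nrow(x$spikes) else sum(x$counts)
  cat(sprintf("<spike_result '%s': %d units, %.2f s, %d spikes (%s regime, seed %s)>\n",
              x$paradigm, x$network$n_units, x$span / 1000, nsp, x$regime,
              format(x$seed)))
  invisible(x)
}

#' Population firing-rate trace
#'
#' Per-neuron normalized firing rate of one population: binned spike counts
#' divided by bin width and population size, then smoothed with a Gaussian
#' kernel.
#'
#' @param x A `spike_result`.
#' @param population `"e"`, `"p"` or `"s"`.
#' @param unit Unit index.
#' @param smooth_sd Gaussian smoothing SD (ms); 0 disables smoothing.
#' @return Numeric vector of rates (Hz) with the bin centers attached as
#'   attribute `"time"`.
#' @export
population_rate <- function(x, population = c("e", "p", "s"), unit = 2,
                            smooth_sd = 5) {
  population <- match.arg(population)
  pop_i <- match(population, c("e", "p", "s"))
  n_pop <- switch(population, e = x$network$n_e, p = x$network$n_p,
                  s = x$network$n_s)
  if (n_pop == 0) stop("empty population")
  col <- (unit - 1) * 3 + pop_i
  counts <- x$counts[, col]
  rate <- counts / (n_pop * x$record_dt / 1000)
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd / x$record_dt)
    kern <- dnorm(seq(-half, half) * x$record_dt, sd = smooth_sd)
    kern <- kern / sum(kern)
    n <- length(rate)
    padded <- c(rep(rate[1], half), rate, rep(rate[n], half))
    rate <- as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n)]
  }
  attr(rate, "time") <- x$time
  rate
}

#' Mean synaptic-current trace into the Exc population of one unit
#'
#' @param x A `spike_result`.
#' @param unit Unit index.
#' @return data.frame with columns `time_ms`, `exc_recurrent` (nA, inward
#'   positive), `inh_pv`, `inh_sst` (nA, magnitudes of the PV-somatic and
#'   SST-dendritic inhibitory currents) and `thalamic` (nA).
#' @export
exc_current_trace <- function(x, unit = 2) {
  j <- (unit - 1) * 4
  data.frame(time_ms = x$time,
             exc_recurrent = x$currents[, j + 1],
             inh_pv = x$currents[, j + 2],
             inh_sst = x$currents[, j + 3],
             thalamic = x$currents[, j + 4])
}

#' Raster plot of a spike result
#'
#' @param x A `spike_result` with stored spikes.
#' @param max_points Subsample cap for very large rasters.
#' @param ... Passed to [plot()].
#' @export
plot.spike_result <- function(x, max_points = 2e5, ...) {
  if (is.null(x$spikes)) stop("spikes were not stored for this run")
  sp <- x$spikes
  if (nrow(sp) > max_points) sp <- sp[seq(1, nrow(sp), length.out = max_points), ]
  plot(sp$time_ms / 1000, sp$neuron, pch = ".", xlab = "time (s)",
       ylab = "neuron", ...)
  invisible(x)
}

#' Write spike events as a two-column text list
#'
#' @param x A `spike_result` with stored spikes.
#' @param path Output path; a population-map JSON is written alongside as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_spikes_txt <- function(x, path) {
  if (is.null(x$spikes)) stop("spikes were not stored for this run")
  utils::write.table(x$spikes[, c("time_ms", "neuron")], path,
                     row.names = FALSE, col.names = c("time_ms", "neuron_id"),
                     quote = FALSE)
  per_unit <- x$network$n_e + x$network$n_p + x$network$n_s
  meta <- list(n_units = x$network$n_units, n_e = x$network$n_e,
               n_p = x$network$n_p, n_s = x$network$n_s,
               per_unit = per_unit, seed = x$seed, paradigm = x$paradigm,
               layout = "unit-major; within unit: Exc, PV, SST; ids 1-based")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
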