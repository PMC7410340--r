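# Spiking-tier structural tests run on reduced networks; per-synapse
# increments scale with the presynaptic population size, so the mean-field
# drive is unchanged.

small_net <- function(seed = 1, ...) {
  build_network(n_e = 200, n_p = 25, n_s = 25, seed = seed, ...)
}
quiet_protocol <- function(span = 500, paradigm = "pv_act") {
  tone_protocol(data.frame(onset = numeric(), duration = numeric(),
                           unit = integer(), amp = numeric()),
                paradigm = paradigm, span = span)
}

test_that("network realizations are binomial and seed-deterministic", {
  net0 <- build_network(n_e = 50, n_p = 10, n_s = 10, p_ee = 0,
                        p_within = 0, p_lateral = 0, seed = 1)
  expect_equal(net0$n_synapses, 0L)
  net1 <- small_net(seed = 42)
  net2 <- small_net(seed = 42)
  expect_identical(net1$out_tgt, net2$out_tgt)
  expect_identical(net1$out_cls, net2$out_cls)
  net3 <- small_net(seed = 43)
  expect_false(identical(net1$out_tgt, net3$out_tgt))
  # realized counts within 4 SD of the binomial expectation, per class
  n_e <- 200; n_p <- 25; n_s <- 25; units <- 3
  exp_ct <- c(ee = units * (n_e * (n_e - 1)) * 0.1 + 4 * n_e * n_e * 0.1,
              ep = units * n_p * n_e * 0.6,
              es = units * n_s * n_e * 0.6,
              pe = units * n_e * n_p * 0.6 + 4 * n_e * n_p * 0.1,
              pp = units * n_p * (n_p - 1) * 0.6,
              ps = units * n_s * n_p * 0.6,
              se = units * n_e * n_s * 0.6 + 4 * n_e * n_s * 0.1)
  for (cl in names(exp_ct)) {
    sd4 <- 4 * sqrt(exp_ct[cl]) # p(1-p) < 1: conservative bound
    expect_lt(abs(net1$class_counts[[cl]] - exp_ct[[cl]]), sd4 + 4)
  }
})

test_that("simulations are bit-identical under a fixed seed", {
  net <- small_net()
  proto <- make_single_tone(n_trials = 1, iti = 350)
  a <- simulate_spiking(net, proto, seed = 9)
  b <- simulate_spiking(net, proto, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$counts, b$counts)
  c_ <- simulate_spiking(net, proto, seed = 10)
  expect_false(identical(a$spikes, c_$spikes))
})

test_that("a silent network stays silent and drive raises the Exc rate", {
  net <- small_net()
  pars0 <- spiking_params(I_baseline = c(0, 0, 0), noise_sigma = 0)
  quiet <- simulate_spiking(net, quiet_protocol(), params = pars0, seed = 1)
  expect_equal(nrow(quiet$spikes), 0)
  # doubling the Exc baseline current strictly raises the mean Exc rate
  base <- simulate_spiking(net, quiet_protocol(1000), seed = 2)
  boosted <- simulate_spiking(net, quiet_protocol(1000),
                              params = spiking_params(
                                I_baseline = c(0.7, 0.05, 0.025)),
                              seed = 2)
  r <- function(x) mean(population_rate(x, "e", 2, smooth_sd = 0))
  expect_gt(r(boosted), r(base))
})

test_that("every neuron honors the refractory period", {
  net <- small_net()
  proto <- make_single_tone(n_trials = 1, iti = 450)
  sim <- simulate_spiking(net, proto, seed = 3)
  sp <- sim$spikes
  isi_ok <- tapply(sp$time_ms, sp$neuron, function(t) {
    length(t) < 2 || min(diff(sort(t))) >= spiking_params()$refractory - 1e-9
  })
  expect_true(all(isi_ok))
  expect_true(all(sp$time_ms >= 0 & sp$time_ms < proto$span))
})

test_that("population rates count spikes with per-neuron normalization", {
  net <- small_net()
  proto <- make_single_tone(n_trials = 1, iti = 250)
  sim <- simulate_spiking(net, proto, seed = 4)
  # conservation: rate integral x population size equals the spike count
  for (pp in c("e", "p", "s")) {
    n_pop <- switch(pp, e = 200, p = 25, s = 25)
    for (u in 1:3) {
      raw <- population_rate(sim, pp, unit = u, smooth_sd = 0)
      per_unit <- 250
      lo <- (u - 1) * per_unit + switch(pp, e = 0, p = 200, s = 225)
      ids <- sim$spikes$neuron - 1
      n_sp <- sum(ids >= lo & ids < lo + n_pop)
      expect_equal(sum(raw) * n_pop * sim$record_dt / 1000, n_sp)
    }
  }
  # smoothing preserves the integral
  sm <- population_rate(sim, "e", 2, smooth_sd = 5)
  raw <- population_rate(sim, "e", 2, smooth_sd = 0)
  expect_equal(sum(sm), sum(raw), tolerance = 0.02)
  expect_error(population_rate(sim, "q"), "arg")
})

test_that("the thalamic input depresses within a tone and spreads at 0.85", {
  net <- small_net()
  long_tone <- tone_protocol(data.frame(onset = 100, duration = 300,
                                        unit = 1, amp = 1),
                             paradigm = "pv_act", span = 600)
  sim <- simulate_spiking(net, long_tone, seed = 5)
  th1 <- exc_current_trace(sim, 1)$thalamic
  th2 <- exc_current_trace(sim, 2)$thalamic
  th3 <- exc_current_trace(sim, 3)$thalamic
  tm <- sim$time
  # fast within-tone depression: the current collapses well before offset
  expect_lt(max(th1[tm > 250 & tm < 400]), 0.05 * max(th1))
  # adjacent-unit copy is scaled by exactly 0.85; the far unit gets nothing
  expect_equal(max(th2), 0.85 * max(th1), tolerance = 1e-9)
  expect_equal(th2, 0.85 * th1, tolerance = 1e-9)
  expect_equal(max(abs(th3)), 0)
})

test_that("tone-evoked PV response precedes the SST response", {
  net <- build_network(n_e = 400, n_p = 50, n_s = 50, seed = 6)
  proto <- make_single_tone(n_trials = 1, iti = 450)
  sim <- simulate_spiking(net, proto, seed = 6)
  tm <- sim$time
  w <- tm >= 100 & tm <= 250
  base_p <- mean(population_rate(sim, "p", 2, 5)[tm < 100])
  base_s <- mean(population_rate(sim, "s", 2, 5)[tm < 100])
  half_rise <- function(pp, base) {
    r <- population_rate(sim, pp, 2, 5)[w]
    tm[w][which(r - base >= 0.5 * (max(r) - base))[1]]
  }
  expect_lt(half_rise("p", base_p), half_rise("s", base_s))
})

test_that("spike events serialize to a two-column text list", {
  net <- small_net()
  proto <- make_single_tone(n_trials = 1, iti = 150)
  sim <- simulate_spiking(net, proto, seed = 7)
  f <- tempfile(fileext = ".txt")
  write_spikes_txt(sim, f)
  back <- read.table(f, header = TRUE)
  expect_equal(nrow(back), nrow(sim$spikes))
  expect_equal(back$neuron_id, sim$spikes$neuron)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$n_e, 200)
  unlink(c(f, paste0(f, ".json")))
})
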