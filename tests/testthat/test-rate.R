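test_that("the rhs evaluations match their closed forms", {
  p <- rate_params()
  z <- single_unit_rhs(c(u = 0, p = 0, s = 0, g = 1), 0, c(0, 0), p)
  expect_equal(unname(z), c(0, 0, 0, 0))
  # q g i = 1.0: only the Exc row is above threshold, u' = f(0.3)/10
  d <- single_unit_rhs(c(u = 0, p = 0, s = 0, g = 1), 1 / p$q, c(0, 0), p)
  expect_equal(unname(d["du"]), 0.9 / 10)
  # strong SST suppression clamps the SST gain at zero, so s decays
  d2 <- single_unit_rhs(c(u = 0.5, p = 0, s = 0.4, g = 1), 0, c(0, -10), p)
  expect_lt(d2[["ds"]], 0)

  p3 <- three_unit_params()
  J <- lateral_terms(2, u = c(0, 0, 0), s = c(0, 0, 0), Fi = 0,
                     I = c(0, 0, 0), p3)
  expect_equal(unname(J), c(0, 0, 0))
  Jc <- lateral_terms(2, u = c(0.3, 0, 0.3), s = c(0, 0, 0), Fi = 0,
                      I = c(0, 0, 0), p3)
  expect_equal(Jc[["J1"]], 0.667 * 0.3) # mean of the edges, weight 0.667
  Je <- lateral_terms(1, u = c(0, 0.4, 0), s = c(0, 0, 0), Fi = 0,
                      I = c(0, 0, 0), p3)
  expect_equal(Je[["J3"]], 0.125 * 0.4)
  expect_error(lateral_terms(1, u = c(0, 0), s = c(0, 0), Fi = 0,
                             I = c(0, 0), p3), "3 units")
})

test_that("the zero state is a fixed point without input", {
  empty <- tone_protocol(data.frame(onset = numeric(), duration = numeric(),
                                    unit = integer(), amp = numeric()),
                         span = 10000)
  for (pars in list(rate_params(), three_unit_params())) {
    tr <- simulate_rate(pars, empty, regime = "weak")
    expect_equal(max(abs(tr$traces[, c("u", "p", "s"), ])), 0)
    expect_equal(max(abs(tr$traces[, "g", ] - 1)), 0)
  }
})

test_that("compiled RK4 agrees with the independent Euler oracle", {
  pars <- rate_params()
  proto <- two_tone_protocol()
  rk <- simulate_rate(pars, proto, dt = 0.1, record_dt = 1)
  eu <- euler_single_unit(pars, proto, t_end = proto$span, dt = 0.001)
  idx <- match(rk$time, round(eu$time, 6))
  for (v in c("u", "p", "s", "g")) {
    expect_lt(max(abs(rk$traces[, v, 1] - eu$traces[idx, v])), 1e-3)
  }
  # with tone-locked opto as well
  ow <- list(list(start = 0, end = 300, target = "PV", amp = -2),
             list(start = 300, end = 600, target = "SST", amp = -1))
  oo <- list(structure(list(target = "PV", windows = cbind(0, 300, -2)),
                       class = "opto_schedule"),
             structure(list(target = "SST", windows = cbind(300, 600, -1)),
                       class = "opto_schedule"))
  rk2 <- simulate_rate(pars, proto, opto = oo, dt = 0.1, record_dt = 1)
  eu2 <- euler_single_unit(pars, proto, t_end = proto$span, dt = 0.001,
                           opto_windows = ow)
  expect_lt(max(abs(rk2$traces[, "u", 1] - eu2$traces[idx, "u"])), 1e-3)
})

test_that("RK4 is converged at the default step", {
  # the threshold-linear gain has kinks, so formal 4th-order accuracy is
  # lost at threshold crossings; step-halving agreement at 1e-4 matches
  # the 1e-3 oracle budget with margin
  pars <- three_unit_params()
  proto <- two_tone_protocol(span = 600)
  a <- simulate_rate(pars, proto, dt = 0.1, record_dt = 1, regime = "weak")
  b <- simulate_rate(pars, proto, dt = 0.05, record_dt = 1, regime = "weak")
  expect_lt(max(abs(a$traces - b$traces)), 2e-4)
})

test_that("activities and resources stay in their invariant boxes", {
  pars <- three_unit_params()
  proto <- make_oddball(n_tones = 40, seed = 2)
  tr <- simulate_rate(pars, proto)
  act <- tr$traces[, c("u", "p", "s"), ]
  expect_true(all(act >= 0 & act <= 1))
  g <- tr$traces[, "g", ]
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(tr$traces[, "D", ] > 0 & tr$traces[, "D", ] <= 1))
  expect_true(all(tr$traces[, "F", ] >= 0))
})

test_that("the recorded current decomposition reconstructs the Exc drive", {
  pars <- three_unit_params()
  proto <- make_oddball(n_tones = 10, seed = 1)
  tr <- simulate_rate(pars, proto, regime = "weak")
  for (k in 1:3) {
    u <- tr$traces[, "u", k]; s <- tr$traces[, "s", k]
    p_ <- tr$traces[, "p", k]; D <- tr$traces[, "D", k]
    F_ <- tr$traces[, "F", k]
    thal <- tr$traces[, "thal", k]
    wep_eff <- pars$W[1, 2] - pars$a_dep * (1 - D)
    lat_u <- if (k == 2) (tr$traces[, "u", 1] + tr$traces[, "u", 3]) / 2
             else tr$traces[, "u", 2]
    lat_s <- if (k == 2) tr$traces[, "s", 1] + tr$traces[, "s", 3]
             else tr$traces[, "s", 2]
    exc_expect <- pars$W[1, 1] * u + pars$w_ee_lat * lat_u + thal
    inh_expect <- wep_eff * p_ + pars$W[1, 3] * s + pars$b_fac * F_ * lat_s
    expect_equal(tr$traces[, "exc", k], exc_expect, tolerance = 1e-10)
    expect_equal(tr$traces[, "inh", k], inh_expect, tolerance = 1e-10)
  }
})

test_that("PV responds faster than SST to a tone", {
  pars <- rate_params()
  proto <- tone_protocol(data.frame(onset = 100, duration = 100, unit = 1,
                                    amp = 1), span = 600)
  tr <- simulate_rate(pars, proto, record_dt = 0.5)
  t_peak <- function(v) tr$time[which.max(tr$traces[, v, 1])]
  expect_lt(t_peak("p"), t_peak("s"))
  expect_gt(max(tr$traces[, "u", 1]), 0)
})

test_that("PVs compensate for suppressed SSTs but not vice versa", {
  # single-unit oddball-timing paradigm: on tone 1 the total inhibitory
  # current into Exc barely changes under SST suppression (PV compensation)
  # while PV suppression removes inhibition outright
  pars <- rate_params()
  tones <- data.frame(onset = 100 + (0:7) * 400, duration = 100, unit = 1,
                      amp = 1)
  proto <- tone_protocol(tones, paradigm = "ssa_simple")
  inh_on_tone <- function(opto) {
    tr <- simulate_rate(pars, proto, opto, record_dt = 0.5)
    idx <- tr$time >= 100 & tr$time <= 200
    max(tr$traces[idx, "inh", 1])
  }
  i_ctrl <- inh_on_tone(NULL)
  i_sst <- inh_on_tone(make_opto(proto, "ssa_simple", "SST", "suppress",
                                 "rate"))
  i_pv <- inh_on_tone(make_opto(proto, "ssa_simple", "PV", "suppress",
                                "rate"))
  expect_lt(abs(i_sst - i_ctrl) / i_ctrl, 0.10)
  expect_lt(i_pv, 0.90 * i_ctrl)
})

test_that("repeated tones adapt the Exc response monotonically", {
  pars <- rate_params()
  tones <- data.frame(onset = 100 + (0:7) * 400, duration = 100, unit = 1,
                      amp = 1)
  proto <- tone_protocol(tones, paradigm = "ssa_simple")
  tr <- simulate_rate(pars, proto)
  resp <- tone_response(tr$traces[, "u", 1], tr$time,
                        cbind(tones$onset, tones$onset + 100), "mean")
  expect_true(all(diff(resp) <= 1e-9))
})

test_that("trajectories serialize to tidy CSV with a JSON sidecar", {
  pars <- rate_params()
  proto <- two_tone_protocol(span = 400)
  tr <- simulate_rate(pars, proto, record_dt = 10)
  df <- as.data.frame(tr)
  expect_setequal_names(df, c("time_ms", "unit", "variable", "value"))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(df))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$paradigm, "oracle")
  unlink(c(f, paste0(f, ".json")))
})
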