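test_that("threshold-linear gain covers its three branches", {
  expect_equal(threshold_linear(-1, r = 3, theta = 0), 0)
  expect_equal(threshold_linear(10, r = 3, theta = 0), 1)
  expect_equal(threshold_linear(0.9, r = 3, theta = 0.7), 0.6)
  # vectorized, monotone, bounded
  x <- seq(-2, 2, by = 0.01)
  y <- threshold_linear(x, r = 3, theta = 0.5)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(threshold_linear(NaN), "finite")
  expect_error(threshold_linear(1, r = -2), "positive")
})

test_that("thalamic depression rhs matches its closed form", {
  p <- rate_params()
  expect_equal(thalamic_depression_rhs(1, 0, p), 0)
  expect_equal(thalamic_depression_rhs(0.5, 0, p), 0.5 / 1500)
  expect_equal(thalamic_depression_rhs(1, 1, p), -1 / 20)
  expect_error(thalamic_depression_rhs(1, -0.5, p), "nonnegative")
})

test_that("parameter constructors enforce the circuit's structure", {
  p <- rate_params()
  expect_equal(p$W, matrix(c(1.1, 2, 1, 1, 2, 2, 6, 0, 0), 3, 3,
                           byrow = TRUE))
  expect_equal(c(p$u_th, p$p_th, p$s_th), c(0.7, 1, 1))
  # SST receives no inhibition in either regime
  W_bad <- p$W; W_bad[3, 2] <- 1
  expect_error(rate_params(W = W_bad))
  expect_error(rate_params(tau_u = -1), "positive")
  p3 <- three_unit_params()
  expect_equal(p3$W_strong[1, 2:3], c(3, 3))
  expect_true(p3$a_dep < min(p3$W[1, 2], p3$W_strong[1, 2]))
  expect_error(three_unit_params(alpha = 1.5), "alpha")
  expect_error(three_unit_params(a_dep = 3), "a_dep")
  # strong matrix may differ from the weak one only in the Exc row
  Ws <- p3$W_strong; Ws[2, 1] <- 2
  expect_error(three_unit_params(W_strong = Ws), "Exc-row")
})

test_that("regime selection maps the facilitation asymptote to weights", {
  p <- three_unit_params()
  weak <- select_regime(0.5, p)
  expect_equal(weak$regime, "weak")
  expect_equal(weak$W[1, 2:3], c(2, 1))
  expect_equal(weak$s_th, 1)
  strong <- select_regime(0.1, p)
  expect_equal(strong$regime, "strong")
  expect_equal(strong$W[1, 2:3], c(3, 3))
  expect_equal(strong$s_th, 0)
  # tie goes to the weak regime
  expect_equal(select_regime(p$F_th, p)$regime, "weak")
  # smooth blend at the threshold sits halfway between the parameter sets
  mid <- select_regime(p$F_th, p, mode = "smooth")
  expect_equal(mid$h, 0.5)
  expect_equal(mid$W[1, 2], 2.5)
  expect_error(select_regime(-0.1, p), "nonnegative")
})

test_that("baseline facilitation integrates to the analytic steady state", {
  p <- three_unit_params()
  # no input: identically zero
  empty <- tone_protocol(data.frame(onset = numeric(), duration = numeric(),
                                    unit = integer(), amp = numeric()),
                         span = 31000)
  fb0 <- baseline_facilitation(empty, p)
  expect_equal(max(abs(fb0$Fbar)), 0)
  # dense tone train approximates a constant drive c = amp * tau_q * rate;
  # steady state is sqrt(c * tau_F1 / tau_F2)
  dense <- tone_protocol(data.frame(onset = seq(0, 30995, by = 5),
                                    duration = 5, unit = 1, amp = 1),
                         span = 31000)
  fb <- baseline_facilitation(dense, p, t_end = 30000)
  c_eff <- 10 / 5 # tau_q * (1 tone / 5 ms)
  expect_equal(attr(fb, "asymptote"), sqrt(c_eff * p$tau_F1 / p$tau_F2),
               tolerance = 0.02)
})

test_that("oddball/suppression paradigms saturate the baseline facilitation above the adapting paradigms", {
  p <- three_unit_params()
  asym <- function(proto) attr(baseline_facilitation(proto, p), "asymptote")
  high <- c(ssa = asym(make_oddball(n_tones = 80)),
            fws = asym(make_forward_suppression(
              masker_units = rep(c(NA, 1, 2, 3), 16))))
  low <- c(tca = asym(make_tuning_adaptation(units = rep(1:3, 2))),
           pv_act = asym(make_single_tone(n_trials = 31)))
  expect_true(min(high) > max(low))
})
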