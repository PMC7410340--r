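test_that("oddball protocol respects the deviant placement rules", {
  # degenerate: no deviants at all
  p0 <- make_oddball(n_tones = 50, p_deviant = 0, seed = 1)
  expect_false(any(p0$tones$deviant))
  p <- make_oddball(n_tones = 1000, p_deviant = 0.1, seed = 7)
  frac <- mean(p$tones$deviant)
  expect_gt(frac, 0.07)
  expect_lt(frac, 0.13)
  expect_false(p$tones$deviant[1])
  expect_false(any(p$tones$deviant[-1] & p$tones$deviant[-1000]))
  # timing: 100 ms tones every 400 ms
  expect_true(all(diff(p$tones$onset) == 400))
  expect_true(all(p$tones$duration == 100))
  # counterbalanced block: identical timing, complementary unit labels
  ps <- make_oddball(n_tones = 1000, p_deviant = 0.1, seed = 7, swap = TRUE)
  expect_equal(ps$tones$onset, p$tones$onset)
  expect_equal(ps$tones$deviant, p$tones$deviant)
  expect_true(all(ps$tones$unit + p$tones$unit == 4))
})

test_that("forward-suppression trials have the masker-probe structure", {
  p <- make_forward_suppression()
  expect_equal(diff(p$trial_starts), rep(500, 3)) # 50+20+50+380
  probes <- p$tones[p$tones$role == "probe", ]
  maskers <- p$tones[p$tones$role == "masker", ]
  expect_true(all(probes$unit == 2))
  # probe onset - masker offset = 20 ms in every masker trial
  for (tr in maskers$trial) {
    m <- maskers[maskers$trial == tr, ]
    pr <- probes[probes$trial == tr, ]
    expect_equal(pr$onset - (m$onset + m$duration), 20)
  }
  # the same-frequency condition (masker = probe unit) exists
  expect_true(any(maskers$unit == 2))
  # a masker-absent reference trial exists
  expect_true(length(setdiff(probes$trial, maskers$trial)) >= 1)
})

test_that("tuning-adaptation protocol times its trials per the paradigm table", {
  p <- make_tuning_adaptation()
  expect_equal(nrow(p$tones), 24) # 3 units x 8 repeats
  for (tr in 1:3) {
    tt <- p$tones[p$tones$trial == tr, ]
    expect_equal(diff(tt$onset), rep(400, 7)) # 100 ms tone + 300 ms ISI
    expect_equal(length(unique(tt$unit)), 1)
  }
  # 2400 ms from last offset of one trial to first onset of the next
  for (tr in 1:2) {
    last_off <- max(p$tones$onset[p$tones$trial == tr]) + 100
    first_on <- min(p$tones$onset[p$tones$trial == tr + 1])
    expect_equal(first_on - last_off, 2400)
  }
})

test_that("single-tone protocol has 1 s trials with the tone at 100 ms", {
  p <- make_single_tone(n_trials = 3)
  expect_equal(p$span, 3000)
  expect_equal(p$tones$onset, c(100, 1100, 2100))
  expect_equal(p$tones$duration, rep(50, 3))
  expect_equal(nrow(make_single_tone(n_trials = 0)$tones), 0)
})

test_that("tone input traces decay exponentially and spread by alpha", {
  pars <- three_unit_params()
  empty <- tone_protocol(data.frame(onset = numeric(), duration = numeric(),
                                    unit = integer(), amp = numeric()),
                         span = 500)
  expect_equal(max(abs(tone_input_trace(empty, 1, pars))), 0)
  one <- tone_protocol(data.frame(onset = 0, duration = 100, unit = 1,
                                  amp = 1), span = 300)
  tt <- seq(0, 300, by = 1)
  tr <- tone_input_trace(one, 1, pars, times = tt)
  expect_equal(tr, exp(-tt / 10), tolerance = 1e-12)
  # the center unit sees alpha times the left unit's trace
  tr2 <- tone_input_trace(one, 2, pars, times = tt, spread = TRUE)
  expect_equal(tr2, 0.65 * tr, tolerance = 1e-12)
  # without spread the center sees nothing (its depression is not driven)
  expect_equal(max(abs(tone_input_trace(one, 2, pars, times = tt))), 0)
})

test_that("protocols reject overlapping tones and round-trip through JSON", {
  expect_error(tone_protocol(data.frame(onset = c(0, 50), duration = 100,
                                        unit = 1, amp = 1)), "overlap")
  p <- make_oddball(n_tones = 20, seed = 3)
  f <- tempfile(fileext = ".json")
  write_protocol_json(p, f)
  q <- read_protocol_json(f)
  expect_equal(q$tones$onset, p$tones$onset)
  expect_equal(q$tones$unit, p$tones$unit)
  expect_equal(q$tones$deviant, p$tones$deviant)
  expect_equal(q$paradigm, p$paradigm)
  expect_equal(q$span, p$span)
  unlink(f)
})

test_that("opto schedules carry the preset amplitudes and timing modes", {
  p <- make_oddball(n_tones = 10, seed = 1)
  o <- make_opto(p, "ssa", "PV", "suppress", "rate")
  expect_equal(o$amplitude, -4)
  expect_equal(o$mode, "tone_locked")
  # suppression windows open 100 ms early and close 100 ms after offset
  expect_equal(unname(o$windows[1, "start"]), p$tones$onset[1] - 100)
  expect_equal(unname(o$windows[1, "end"]), p$tones$onset[1] + 100 + 100)
  # SSA windows never overlap across consecutive tones (300 ms gap > 200 ms)
  expect_true(all(o$windows[-1, "start"] >= o$windows[-nrow(o$windows), "end"]))
  # activation windows are concurrent with the tone
  oa <- make_opto(p, "ssa", "SST", "activate", "rate")
  expect_equal(oa$amplitude, 1.2)
  expect_equal(unname(oa$windows[1, 1:2]), c(p$tones$onset[1],
                                             p$tones$onset[1] + 100))
  st <- make_opto(make_single_tone(), "pv_act", "PV", "activate", "rate")
  expect_equal(st$amplitude, 2)
  expect_equal(st$mode, "sustained")
  expect_equal(nrow(st$windows), 1)
  sp <- make_opto(make_tuning_adaptation(), "tca", "SST", "suppress",
                  "spiking")
  expect_equal(sp$amplitude, -1)
  expect_equal(sp$mode, "sustained")
  expect_error(make_opto(p, "ssa", "PV", "activate", "spiking"), "amplitude")
  expect_error(make_opto(p, "nope", "PV", "suppress"), "unknown")
  # forward suppression: masker and probe windows merge across the 20 ms gap
  fp <- make_forward_suppression(masker_units = 2)
  of <- make_opto(fp, "fws", "PV", "suppress", "rate")
  expect_equal(nrow(of$windows), 1)
})
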