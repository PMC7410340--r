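# Experiment-driver tests use shortened oddball blocks; the acceptance
# checks run the full-length protocols.

test_that("oddball runs summarize adaptation and counterbalanced CSI", {
  res <- run_ssa("rate", "control", n_tones = 80)
  expect_s3_class(res$csi, "csi_result")
  # symmetric circuit + identical block timing: the two deviants agree
  expect_equal(res$csi$d_f1, res$csi$d_f2, tolerance = 1e-9)
  # adaptation: deviant response above the late standards
  bp <- res$by_position$response
  expect_gt(bp[1], mean(bp[6:8]))
  # per-tone table covers both blocks
  expect_equal(sort(unique(res$responses$block)), c(1, 2))
  expect_equal(nrow(res$responses), 2 * 80)
  # difference vs itself is identically zero
  d <- ssa_difference(res, res)
  expect_equal(max(abs(d$difference)), 0)
})

test_that("the CSI sweep reproduces the control run at its control point", {
  res <- run_ssa("rate", "control", n_tones = 60)
  sw <- run_csi_sweep(param = "w_ee", param_grid = 1.1,
                      opto_target = "PV", amp_grid = c(-2, 0),
                      n_tones = 60)
  expect_equal(sw$csi[sw$amplitude == 0], res$csi$csi)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("param", "value", "amplitude", "csi", "valid") %in%
                    names(sw)))
  expect_error(run_csi_sweep(param_grid = c(2, 1)), "increasing")
})

test_that("forward suppression is strongest at the shared frequency", {
  res <- run_forward_suppression("rate", "control")
  p <- res$probes
  expect_equal(p$normalized[is.na(p$masker)], 100)
  same <- p$normalized[!is.na(p$masker) & p$masker == 2]
  side <- p$normalized[!is.na(p$masker) & p$masker != 2]
  expect_lt(same, min(side))
  # edge maskers act symmetrically on the center probe
  expect_equal(side[1], side[2], tolerance = 1e-9)
})

test_that("tuning adaptation weakens the repeated-tone response at the preferred frequency", {
  res <- run_tuning_adaptation("rate", "control")
  tab <- res$responses
  pref1 <- mean(tab$response[tab$distance == 0 & tab$tone == 1])
  pref8 <- mean(tab$response[tab$distance == 0 & tab$tone == 8])
  expect_lt(pref8, pref1)
  rr <- tca_ratio(res, res)
  expect_true(all(rr$ratio[!rr$undefined] == 1))
})

test_that("balance scans pool only suprathreshold samples", {
  # all-subthreshold strengths cannot produce a fit
  expect_error(run_balance_scan("rate", strengths = c(0.05, 0.1, 0.12)),
               "suprathreshold")
  b <- run_balance_scan("rate", strengths = c(0.1, 2, 4, 6))
  # the q = 0.1 run contributes no points
  expect_false(0.1 %in% b$points$strength)
  expect_gt(b$slope, 0)
})

test_that("configs load, validate, merge and round-trip", {
  f <- tempfile(fileext = ".json")
  writeLines("", f)
  cfg <- load_config(f)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$paradigm, "ssa")
  expect_equal(cfg$rate.w_ee, 1.1)
  # a single override changes exactly one leaf
  jsonlite::write_json(list(rate.w_ee = 1.3), f, auto_unbox = TRUE)
  cfg2 <- load_config(f)
  changed <- names(which(mapply(function(a, b) !identical(a, b),
                                unclass(cfg), unclass(cfg2))))
  expect_equal(changed, "rate.w_ee")
  expect_equal(cfg2$rate.w_ee, 1.3)
  # unknown keys and out-of-range values are rejected
  jsonlite::write_json(list(bogus_key = 1), f, auto_unbox = TRUE)
  expect_error(load_config(f), "unknown config key")
  jsonlite::write_json(list(rate.r = -1), f, auto_unbox = TRUE)
  expect_error(load_config(f), "out of range")
  # save/load round-trip
  f2 <- tempfile(fileext = ".json")
  save_config(cfg2, f2)
  cfg3 <- load_config(f2)
  expect_equal(unclass(cfg3), unclass(cfg2))
  unlink(c(f, f2))
})

test_that("target verification distinguishes pass, fail and not-run", {
  targets <- data.frame(id = c("a", "b", "c"), value = c(1, 2, 3),
                        type = c("deterministic", "deterministic",
                                 "stochastic"))
  out <- verify_targets(list(a = 1.01, c = c(2.8, 3.1, 3.2)), targets)
  expect_equal(out$status, c("pass", "not_run", "pass"))
  out2 <- verify_targets(list(a = 1.5, b = 2, c = c(10, 10.1, 10.2)),
                         targets)
  expect_equal(out2$status, c("fail", "pass", "fail"))
})
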