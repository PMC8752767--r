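make_ap <- function(...) simulate_ap_trace(...)

test_that("ratio traces are pointwise channel ratios with flagged samples", {
  t <- seq(0, 1000, by = 2)
  r <- ratio_trace(rep(4, length(t)), rep(2, length(t)), t)
  expect_true(all(r$signal == 2))
  r1 <- ratio_trace(rep(3, length(t)), rep(3, length(t)), t)
  expect_true(all(r1$signal == 1))
  den <- rep(2, length(t)); den[5] <- 0
  expect_warning(rf <- ratio_trace(rep(4, length(t)), den, t),
                 "non-positive denominator")
  expect_true(is.na(rf$signal[5]))
  # two-channel generator output reproduces the stored signal truth
  s <- make_ap(n_beats = 3, two_channel = TRUE)
  rr <- ratio_trace(s$channels$numerator, s$channels$denominator, s$trace$time)
  expect_equal(rr$signal, s$trace$signal)
})

test_that("AP detection finds every upstroke, ignores flat noise, resists drift", {
  flat <- as_trace_for_test(seq(0, 5000, 2), rnorm(2501, 1, 0.02))
  expect_length(detect_aps(flat), 0)
  s <- make_ap(n_beats = 5, upstroke_duration = 0)
  ups <- detect_aps(s$trace)
  expect_length(ups, 5)
  expect_true(all(abs(s$trace$time[ups] - s$truth$onset_ms) <=
                    s$trace$sampling_interval))
  # same beats, SNR 10 plus strong linear drift
  s2 <- make_ap(n_beats = 5, upstroke_duration = 0, noise_sd = 0.1,
                drift_per_s = -0.05, rng_seed = 12)
  ups2 <- detect_aps(s2$trace)
  expect_length(ups2, 5)
  expect_true(all(abs(s2$trace$time[ups2] - s$truth$onset_ms) <= 10))
})

test_that("APD at level matches the analytic piecewise-linear geometry", {
  s <- make_ap(n_beats = 4, baseline = 1, amplitude = 1, upstroke_duration = 0,
               plateau_duration = 200, repolarization_duration = 200,
               beat_interval = 1000, sampling_interval = 2)
  ups <- detect_aps(s$trace)
  a90 <- apd_at_level(s$trace, ups[2], level = 0.9)
  expect_lt(abs(a90 - 380), s$trace$sampling_interval)
  a50 <- apd_at_level(s$trace, ups[2], level = 0.5)
  expect_lt(abs(a50 - 300), s$trace$sampling_interval)
  # positive affine transform leaves the features unchanged
  tr <- s$trace
  tr$signal <- 3 * tr$signal + 7
  expect_equal(apd_at_level(tr, ups[2], 0.9), a90, tolerance = 1e-10)
})

test_that("Bazett correction has the closed form, identity and monotonicity", {
  expect_identical(bazett_correct(400, 1000), 400)
  expect_equal(bazett_correct(400, 640), 500, tolerance = 1e-12)
  expect_identical(bazett_correct(0, 640), 0)
  rrs <- seq(400, 2000, by = 100)
  expect_true(all(diff(bazett_correct(300, rrs)) < 0))
  expect_error(bazett_correct(400, 0), "positive")
  expect_identical(cfpd(300, 1000), 300)
  expect_equal(cfpd(300, 2250), 200, tolerance = 1e-12)
})

test_that("AP averaging is idempotent on identical beats and warns when short", {
  s <- make_ap(n_beats = 20, upstroke_duration = 10)
  ups <- detect_aps(s$trace)
  av <- average_ap(s$trace, ups, n = 15)
  expect_equal(av$n_averaged, 15)
  # identical noiseless beats: the average equals any single beat window
  one <- s$trace$signal[(ups[3] - round(100 / 2)):(ups[3] + round(1000 / 2))]
  expect_equal(av$signal, one, tolerance = 1e-9)
  s5 <- make_ap(n_beats = 5)
  u5 <- detect_aps(s5$trace)
  expect_warning(av5 <- average_ap(s5$trace, u5, n = 15), "averaging all")
  expect_lte(av5$n_averaged, 5)
  expect_error(average_ap(s5$trace, u5[1], n = 2), "at least 2")
  # noise averages down roughly as 1/sqrt(n)
  sn <- make_ap(n_beats = 30, noise_sd = 0.1, rng_seed = 3)
  avn <- average_ap(sn$trace, detect_aps(sn$trace), n = 25)
  plateau <- avn$signal[avn$time > 60 & avn$time < 140]
  expect_lt(sd(plateau), 0.1 / sqrt(25) * 3)
})

test_that("per-cell summaries report median cAPD90 and flag poor cells", {
  s <- make_ap(n_beats = 8, upstroke_duration = 0, plateau_duration = 200,
               repolarization_duration = 200, beat_interval = 640,
               sampling_interval = 2)
  cell <- analyze_cell(s$trace)
  true_capd <- 380 / sqrt(0.64)   # 475 ms
  expect_false(cell$flagged)
  expect_lt(abs(cell$median_capd90 - true_capd) / true_capd, 0.02)
  expect_equal(cell$median_rr, 640)
  # order of cells in a batch does not matter (stateless analysis)
  s2 <- make_ap(n_beats = 6, beat_interval = 900, rng_seed = 2)
  a <- analyze_cell(s$trace); b <- analyze_cell(s2$trace)
  b2 <- analyze_cell(s2$trace); a2 <- analyze_cell(s$trace)
  expect_equal(a$median_apd90, a2$median_apd90)
  expect_equal(b$median_apd90, b2$median_apd90)
  # truncated trace: repolarizations incomplete, cell flagged
  tr <- s$trace
  keep <- tr$time <= s$truth$onset_ms[2] + 100
  short <- as_trace_for_test(tr$time[keep], tr$signal[keep])
  expect_true(analyze_cell(short)$flagged)
})

test_that("IV curves normalize to capacitance and subtract cleanly", {
  steps <- list(list(v = -10, i = c(-100, -500, -300)),
                list(v = 0, i = c(0, 0, 0)),
                list(v = 10, i = c(100, 250, 200)))
  cv <- iv_curve(steps, capacitance = 25, mode = "peak")
  expect_equal(cv$current_density, c(-20, 0, 10))
  cv2 <- iv_curve(steps, capacitance = 50, mode = "peak")
  expect_equal(cv2$current_density, cv$current_density / 2)  # linearity
  # end mode: mean over the terminal window
  stepe <- list(list(v = 40, i = c(rep(0, 90), rep(250, 10))))
  expect_equal(iv_curve(stepe, 25, mode = "end")$current_density, 10)
  # drug subtraction recovers a planted sensitive component
  ctrl <- iv_curve(list(list(v = 0, i = 125), list(v = 40, i = 250)), 25, "peak")
  drug <- iv_curve(list(list(v = 0, i = 75), list(v = 40, i = 50)), 25, "peak")
  diffc <- drug_subtract(ctrl, drug)
  expect_equal(diffc$current_density, c(2, 8))
  expect_equal(drug_subtract(ctrl, ctrl)$current_density, c(0, 0))
  bad <- iv_curve(list(list(v = -10, i = 1), list(v = 40, i = 1)), 25, "peak")
  expect_error(drug_subtract(ctrl, bad), "grid")
})

test_that("linear leak subtraction nulls a purely ohmic curve", {
  v <- seq(-80, 40, by = 20)
  ohmic <- iv_curve(lapply(v, function(x) list(v = x, i = 2 * x)), 1, "peak")
  out <- suppressMessages(leak_subtract(ohmic, fit_range = c(-80, -40)))
  expect_true(all(abs(out$current_density) < 1e-9))
})

test_that("best-effort FPD extractor finds spike-to-repolarization time", {
  t <- seq(0, 1000, by = 1)
  x <- -dnorm(t, 100, 3) * 10 + dnorm(t, 400, 30)
  tr <- as_trace_for_test(t, x)
  f <- fpd_extract(tr)
  expect_lt(abs(f$fpd - 300), 15)
})
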