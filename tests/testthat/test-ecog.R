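test_that("slow-band filter passes 0.2 Hz, attenuates 5 Hz by >=20 dB, removes DC", {
  fs <- 20
  t <- seq(0, 7200 - 1 / fs, by = 1 / fs)
  layout <- default_layout()
  mk <- function(x) ts_recording(matrix(rep(x, 10), ncol = 10), layout$contacts,
                                 sampling_rate = fs, occlusion_time_s = 600)
  s02 <- slow_band(mk(sin(2 * pi * 0.2 * t)), band = c(0.002, 0.5))
  mid <- seq(round(0.3 * length(t)), round(0.7 * length(t)))
  gain02 <- max(abs(s02[mid, 1]))
  expect_gte(gain02, 0.9)
  s5 <- slow_band(mk(sin(2 * pi * 5 * t)), band = c(0.002, 0.5))
  expect_lte(max(abs(s5[mid, 1])), 10^(-20 / 20))
  sdc <- slow_band(mk(rep(3, length(t))), band = c(0.002, 0.5))
  expect_lte(max(abs(sdc[mid, 1])), 1e-6)
})

test_that("slow_band enforces its preconditions", {
  short <- flat_recording(hours = 0.2)
  expect_error(slow_band(short, band = c(0.002, 0.5)), "shorter than 10x")
  layout <- default_layout()
  slow_fs <- ts_recording(matrix(0, 1000, 10), layout$contacts,
                          sampling_rate = 5, occlusion_time_s = 10)
  expect_error(slow_band(slow_fs), "at least 10 Hz")
})

test_that("SPC detection: flat traces give nothing, sub-threshold deflections are rejected", {
  t <- seq(0, 3600, by = 0.1)
  expect_identical(nrow(detect_spc(numeric(length(t)), t)), 0L)
  small <- lognormal_pulse(t, 600, -0.5, 90)
  expect_identical(nrow(detect_spc(small, t)), 0L)
  big <- lognormal_pulse(t, 600, -5, 90)
  out <- detect_spc(big, t)
  expect_identical(nrow(out), 1L)
  expect_equal(out$onset_s, 600, tolerance = 0.01)
  expect_equal(out$depth_mV, 5, tolerance = 1e-3)
  expect_equal(out$duration_s, 90, tolerance = 0.5)
})

test_that("deflections outside the duration band are rejected", {
  t <- seq(0, 7200, by = 0.1)
  too_short <- lognormal_pulse(t, 600, -5, 10)
  expect_identical(nrow(detect_spc(too_short, t)), 0L)
  too_long <- lognormal_pulse(t, 600, -5, 400)
  expect_identical(nrow(detect_spc(too_long, t)), 0L)
})

test_that("raising the amplitude threshold never increases the candidate count", {
  set.seed(11)
  t <- seq(0, 7200, by = 0.1)
  x <- stats::rnorm(length(t), 0, 0.3)
  for (d in c(2.5, 3.5, 5, 8)) x <- x + lognormal_pulse(t, d * 700, -d, 90)
  counts <- vapply(c(1, 2, 3, 4, 6, 9), function(thr)
    nrow(detect_spc(x, t, ecog_config(amp_threshold_mV = thr))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("grouping follows the propagation-plausibility band", {
  layout <- default_layout()
  cfg <- ecog_config()
  # two contacts 10 mm apart, 200 s lag -> 3 mm/min, one event
  cands <- data.frame(sensor_id = c("L2", "L3"), onset_s = c(1000, 1200),
                      amplitude = c(5, 5))
  g <- group_events(cands, layout$contacts, cfg)
  expect_length(g$events, 1)
  expect_equal(g$events[[1]]$expansion_pct, 40)
  # 2 s lag -> 300 mm/min, implausible: two orphans
  cands2 <- transform(cands, onset_s = c(1000, 1002))
  g2 <- group_events(cands2, layout$contacts, cfg)
  expect_length(g2$events, 0)
  expect_identical(nrow(g2$orphans), 2L)
  # events never span the midline
  cands3 <- data.frame(sensor_id = c("L2", "R2"), onset_s = c(1000, 1080),
                       amplitude = c(5, 5))
  g3 <- group_events(cands3, layout$contacts, cfg)
  expect_length(g3$events, 0)
})

test_that("expansion percentages follow the configured denominator scope", {
  layout <- default_layout()
  expect_equal(expansion_pct(5, "left", layout$contacts, "all"), 50)
  expect_equal(expansion_pct(5, "left", layout$contacts, "hemisphere"), 100)
  expect_equal(expansion_pct(2, "right", layout$contacts, "hemisphere"), 40)
})

test_that("detection is translation-invariant in time", {
  r <- unit_roster()
  b <- simulate_animal(r, "u01", what = "ecog", noise_scale = 0)
  det <- detect_sd_ecog(b$ecog)
  shift_s <- 120
  fs <- b$ecog$sampling_rate
  shifted <- ts_recording(
    rbind(matrix(0, shift_s * fs, ncol(b$ecog$samples)), b$ecog$samples),
    b$ecog$channels, sampling_rate = fs,
    occlusion_time_s = b$ecog$occlusion_time_s + shift_s)
  det2 <- detect_sd_ecog(shifted)
  expect_length(det2$events, length(det$events))
  for (i in seq_along(det$events))
    expect_equal(det2$events[[i]]$onsets, det$events[[i]]$onsets + shift_s,
                 tolerance = 0.2 / mean(det$events[[i]]$onsets + shift_s))
})

test_that("injected events are recovered with depression-confirmed status", {
  det <- detect_sd_ecog(unit_sim()$ecog)
  expect_length(det$events, 2)
  expect_true(all(det$candidates$status == "confirmed"))
  expect_true(all(det$candidates$depression_frac <= 0.5, na.rm = TRUE))
  r <- unit_roster()
  for (i in 1:2) {
    tpl <- sdwave:::ecog_template(r, i)
    arr <- template_arrivals(tpl, r$layout$contacts)
    gt <- stats::setNames(600 + arr$arrival_min * 60, arr$id)
    ons <- det$events[[i]]$onsets
    expect_equal(length(ons), r$ecog_events$reached_n[i])
    expect_lt(max(abs(ons - gt[names(ons)])), 2)
  }
})
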