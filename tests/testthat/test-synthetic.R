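test_that("roster arrival times follow onset + distance/speed exactly", {
  layout <- default_layout()
  tpl <- sd_template(origin = c(0, 0), onset_min = 5, speed_mm_per_min = 3,
                     hemisphere = "left", target_expansion = 1)
  arr <- template_arrivals(tpl, layout$contacts)
  d <- sqrt((layout$contacts$x_mm - 0)^2 + (layout$contacts$y_mm - 0)^2)
  d <- d[layout$contacts$hemisphere == "left"]
  expect_equal(sort(arr$arrival_min), sort(5 + d / 3), tolerance = 1e-12)
  # collinear contacts 10 mm apart at speed 3 mm/min lag by ~200 s; for the
  # strip geometry the first spacing is shortened by the lateral offset
  expect_equal(diff(sort(arr$arrival_min))[-1] * 60,
               rep(200, 3), tolerance = 12)
})

test_that("template validation rejects out-of-band speeds and bad expansion", {
  expect_error(sd_template(c(0, 0), 1, speed_mm_per_min = 0.5, hemisphere = "left"),
               "plausibility band")
  expect_error(sd_template(c(0, 0), 1, 3, "left", target_expansion = 0),
               "target_expansion")
  expect_error(component_spec("II", +5, 1), "negative")
  expect_error(component_spec("III", -5, 1), "positive")
})

test_that("identical (preset, seed) produce identical recordings", {
  a <- simulate_animal(unit_roster(), "u01")
  b <- simulate_animal(build_roster("unit_test", 1), "u01")
  expect_identical(a$ecog$samples, b$ecog$samples)
  expect_identical(a$ios$traces, b$ios$traces)
  c2 <- simulate_animal(build_roster("unit_test", 2), "u01")
  expect_false(identical(a$ecog$samples, c2$ecog$samples))
})

test_that("unit preset delivers one animal with exactly two rostered SDs", {
  r <- unit_roster()
  expect_equal(nrow(r$animals), 1L)
  expect_equal(nrow(r$ecog_events), 2L)
  expect_equal(nrow(r$ios_events), 2L)
  expect_equal(r$animals$ecog_hours, 2)
})

test_that("replication roster self-statistics equal the encoded cohort values", {
  s <- roster_stats(build_roster("paper_replication", 1))
  expect_identical(s$ecog_total, 26L)
  expect_identical(s$ios_total, 16L)
  expect_identical(s$hourly_ecog[4:6], c(0L, 0L, 0L))
  expect_identical(s$hourly_ecog[1], 17L)
  expect_equal(s$ecog_expansion_mean, 69.4, tolerance = 0.0501 / 69.4)
  expect_equal(s$ios_expansion_mean, 85.8, tolerance = 0.0501 / 85.8)
  expect_equal(s$incidence_mean, 0.3, tolerance = 0.05 / 0.3)
  expect_equal(s$first_sd_ecog_mean_min, 49.3, tolerance = 1e-9)
  expect_equal(s$first_sd_ios_mean_min, 101, tolerance = 1e-9)
  expect_equal(s$first_amp_mean, 18.5, tolerance = 1e-9)
  expect_equal(s$last_amp_mean, 16.3, tolerance = 1e-9)
  expect_equal(s$first_dur_mean, 3.1, tolerance = 1e-9)
  expect_equal(s$last_dur_mean, 8.3, tolerance = 1e-9)
  expect_equal(unname(s$morphology_prevalence["monophasic"]), 31.25)
  expect_equal(unname(s$morphology_prevalence["biphasic"]), 31.25)
  expect_equal(s$lsci_cbf_mean, 61.5)
})

test_that("ECoG injection modifies only reached contacts and flags truncation", {
  rec <- flat_recording(hours = 1)
  tpl <- sd_template(c(0, 0), onset_min = 10, speed_mm_per_min = 3,
                     hemisphere = "left", dc_amplitude_mV = 5,
                     target_expansion = 4 / 5)
  out <- inject_sd_ecog(rec, tpl)
  touched <- apply(out$samples != rec$samples, 2, any)
  expect_identical(unname(touched),
                   rec$channels$hemisphere == "left" & rec$channels$id != "L5")
  # full-strip template reaches all five ipsilateral contacts
  out5 <- inject_sd_ecog(rec, sd_template(c(0, 0), 10, 3, "left",
                                          target_expansion = 1))
  expect_identical(unname(apply(out5$samples != rec$samples, 2, any)),
                   rec$channels$hemisphere == "left")
  # onset chosen so only the farthest contact arrives beyond the end
  expect_warning(
    trunc <- inject_sd_ecog(rec, sd_template(c(0, 0), 46, 3, "left",
                                             target_expansion = 1)),
    "truncated")
  expect_true(attr(trunc, "truncated"))
})

test_that("optical injection follows the inverted CBV sign convention", {
  ts <- flat_ios()
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = list(component_spec("III", 18, 3, 2)),
                     target_expansion = 1)
  out <- inject_sd_optical(ts, tpl)
  j <- which(ts$rois$id == "iL1")
  # +18% CBV = intensity dip of 18% of baseline
  expect_equal(min(out$traces[, j]), 1000 * (1 - 0.18), tolerance = 1e-6)
  expect_true(all(out$traces[, which(ts$rois$hemisphere == "right")] == 1000))
  # CBV round-trip recovers the injected pulse
  cbv <- to_cbv(out$traces[, j], 1000)
  expect_equal(max(cbv), 18, tolerance = 1e-6)
})

test_that("a [II,III,IV] response crosses baseline twice before the main dip", {
  ts <- flat_ios()
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = morphology_components("triphasic", 18, 3),
                     target_expansion = 1)
  out <- inject_sd_optical(ts, tpl)
  j <- which(ts$rois$id == "iL1")
  x <- out$traces[, j] - 1000
  i_dip <- which.min(x)       # main dip = peak hyperemia (intensity minimum)
  segs <- rle(sign(x[1:i_dip])[abs(x[1:i_dip]) > 0.5])$values
  # baseline -> hypoperfusion bump (+ intensity) -> hyperemic dip (-):
  # the trace leaves and then re-crosses the baseline before the dip
  expect_identical(segs, c(1, -1))
})

test_that("component II before I is rejected", {
  ts <- flat_ios()
  bad <- list(component_spec("I", 4, 1, 2), component_spec("II", -5, 1, 2))
  bad[[2]]$lag_min <- 1   # II placed before I
  tpl <- sd_template(c(0, 0), 10, 3, "left", components = list(component_spec("III", 10, 2)))
  tpl$components <- bad   # bypass ordered-lag constructor check
  expect_error(inject_sd_optical(ts, tpl), "component II")
})

test_that("LSCI injection couples OxyHb up, deOxyHb down; zero amplitude is a no-op", {
  ts <- flat_lsci()
  tpl0 <- sd_template(c(0, 0), 10, 3, "right", cbf_amplitude_pct = 0,
                      target_expansion = 1)
  expect_identical(inject_sd_lsci(ts, tpl0)$traces, ts$traces)
  tpl <- sd_template(c(0, 0), 10, 3, "right", cbf_amplitude_pct = 61.5,
                     target_expansion = 1)
  out <- inject_sd_lsci(ts, tpl)
  expect_equal(max(out$traces$cbf[, 1]), 100 * 1.615, tolerance = 1e-4)
  expect_gt(max(out$traces$oxyhb[, 1] - 60), 0)
  expect_lt(min(out$traces$deoxyhb[, 1] - 40), 0)
})

test_that("simulate_cohort writes a complete, hash-stable artifact bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort("unit_test", seed = 3, out_dir = d1, what = c("ecog", "ios"))
  simulate_cohort("unit_test", seed = 3, out_dir = d2, what = c("ecog", "ios"))
  files <- sort(list.files(d1))
  expect_setequal(files, c("roster.json", "u01_ecog.edf", "u01_ecog.edf.json",
                           "u01_ios.csv", "u01_ios.csv.json"))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("hash of", f))
  expect_error(build_roster("nope"), "arg")
  expect_error(build_roster("unit_test", seed = 1.5), "integer")
})
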