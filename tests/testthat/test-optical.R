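test_that("CBV conversion: definition, zeros, and positive-scale invariance", {
  tr <- c(1000, 820, 1000)    # 18% intensity dip
  expect_equal(to_cbv(tr, 1000), c(0, 18, 0))
  expect_true(all(to_cbv(rep(7, 100), 7) == 0))
  expect_error(to_cbv(tr, 0), "positive")
  # multiplying raw intensity by any positive constant leaves percent intact
  for (k in c(0.25, 3, 117)) expect_equal(to_cbv(tr * k, 1000 * k), c(0, 18, 0))
})

test_that("baseline: median immune to spikes, sigma calibrated, short window widened", {
  t <- seq_len(2000)
  x <- rep(500, 2000); x[c(100, 700, 1500)] <- 5000
  bl <- establish_baseline(x, t, detrend = FALSE)
  expect_equal(bl$I0, 500)
  # Monte-Carlo: sigma-hat within 10% of truth at n = 300
  set.seed(20)
  errs <- replicate(200, {
    y <- stats::rnorm(300, 100, 2)
    establish_baseline(y, seq_len(300), detrend = FALSE)$sigma
  })
  expect_lt(abs(mean(errs) - 2) / 2, 0.10)
  expect_warning(
    establish_baseline(x, t, mask = t < 100, detrend = FALSE, min_window_s = 300),
    "widening")
})

test_that("baseline mask excludes event windows from the location estimate", {
  t <- seq_len(1000)
  x <- rep(1000, 1000); x[400:600] <- 800      # an event-sized deflection
  mask <- !(t %in% 380:620)
  bl <- establish_baseline(x, t, mask = mask, detrend = FALSE)
  expect_equal(bl$I0, 1000)
  no_mask <- establish_baseline(x, t, detrend = FALSE)
  expect_equal(no_mask$I0, 1000)               # median still robust at 20% outliers
})

test_that("deviation detection: flat gives none, k -> Inf gives none, injected III is found", {
  t <- seq(0, 3600)
  expect_identical(nrow(detect_deviations(numeric(length(t)), t, 0.5)), 0L)
  cbv <- lognormal_pulse(t, 900, 18, 3.1 * 60)
  dev <- detect_deviations(cbv, t, 0.5)
  expect_identical(nrow(dev), 1L)
  expect_equal(dev$polarity, 1)
  expect_equal(dev$onset_s, 900, tolerance = 3 / 900)
  huge_k <- optical_config(k_sigma = 1e9)
  expect_identical(nrow(detect_deviations(cbv, t, 0.5, huge_k)), 0L)
})

test_that("a deviation on a single ROI never becomes an SD event", {
  ts <- flat_ios(hours = 1, sigma = 5)
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = list(component_spec("III", 18, 3, 2)),
                     target_expansion = 1 / 6)   # one ROI only
  out <- inject_sd_optical(ts, tpl)
  det <- detect_sd_ios(out)
  expect_length(det$events, 0)
  expect_gte(nrow(det$orphans), 1)
})

test_that("noiseless decomposition recovers kinds, amplitude and duration", {
  ts <- flat_ios(hours = 1.5)
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = morphology_components("triphasic", 18, 3),
                     target_expansion = 1)
  out <- inject_sd_optical(ts, tpl)
  det <- detect_sd_ios(out)
  expect_length(det$events, 1)
  t <- traceset_time(out)
  onset <- det$events[[1]]$onsets[["iL1"]]
  comp <- decompose_components(det$cbv[, "iL1"], t, c(onset - 120, onset + 1800),
                               det$baselines[[1]]$sigma_pct)
  expect_identical(comp$kind, c("II", "III", "IV"))
  i3 <- which(comp$kind == "III")
  expect_equal(comp$peak_pct[i3], 18, tolerance = 0.5 / 18)
  expect_equal(comp$duration_min[i3], 3, tolerance = 0.2 / 3)

  # a pure-noise window yields an empty component list
  noise <- flat_ios(hours = 1, sigma = 5)
  tn <- traceset_time(noise)
  cbvn <- to_cbv(noise$traces[, 1], 1000)
  expect_identical(nrow(decompose_components(cbvn, tn, c(1000, 2500), 0.5)), 0L)
})

test_that("monophasic 18%/3.1 min responses are measured within +-0.5% and +-0.2 min", {
  ts <- flat_ios(hours = 1)
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = morphology_components("monophasic", 18, 3.1),
                     target_expansion = 1)
  out <- inject_sd_optical(ts, tpl)
  det <- detect_sd_ios(out)
  resp <- classify_responses(det, out)
  expect_true(all(resp$morphology == "monophasic"))
  expect_true(all(abs(resp$amplitude_pct - 18) <= 0.5))
  expect_true(all(abs(resp$duration_min - 3.1) <= 0.2))
})

test_that("decomposition + re-synthesis reproduces the noiseless trace (RMSE <= 1%)", {
  ts <- flat_ios(hours = 1.5)
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = morphology_components("tetraphasic", 18, 3),
                     target_expansion = 1)
  out <- inject_sd_optical(ts, tpl)
  det <- detect_sd_ios(out)
  t <- traceset_time(out)
  onset <- det$events[[1]]$onsets[["iL1"]]
  sel <- which(t >= onset - 120 & t <= onset + 1800)
  comp <- decompose_components(det$cbv[, "iL1"], t, c(onset - 120, onset + 1800),
                               det$baselines[[1]]$sigma_pct)
  expect_identical(comp$kind, c("I", "II", "III", "IV"))
  resyn <- numeric(length(sel))
  for (k in seq_len(nrow(comp)))
    resyn <- resyn + lognormal_pulse(t[sel], comp$onset_s[k], comp$peak_pct[k],
                                     comp$duration_min[k] * 60)
  rmse <- sqrt(mean((resyn - det$cbv[sel, "iL1"])^2))
  expect_lte(rmse, 1)
})

test_that("morphology classification is a pure function of the kind sequence", {
  expect_identical(classify_morphology("III"), "monophasic")
  expect_identical(classify_morphology(c("III", "IV")), "biphasic")
  expect_identical(classify_morphology(c("II", "III", "IV")), "triphasic")
  expect_identical(classify_morphology(c("I", "II", "III", "IV")), "tetraphasic")
  expect_identical(classify_morphology("V"), "other")
  expect_error(classify_morphology(character()), "empty")
  # property: over random sequences, only the four canonical orders map to a
  # named class; everything else is "other"
  set.seed(33)
  canonical <- list("III", c("III", "IV"), c("II", "III", "IV"),
                    c("I", "II", "III", "IV"))
  for (i in 1:200) {
    kinds <- sample(c("I", "II", "III", "IV", "V"), sample(1:5, 1), replace = TRUE)
    lab <- classify_morphology(kinds)
    hit <- any(vapply(canonical, identical, TRUE, y = kinds))
    expect_identical(lab != "other", hit)
  }
})

test_that("hyperemia metrics report component III and survive a superimposed IV", {
  comp <- data.frame(kind = c("II", "III", "IV"), onset_s = c(0, 100, 500),
                     peak_pct = c(-5, 18.5, 6), duration_min = c(1, 3.1, 2.5),
                     peak_s = c(30, 200, 560))
  m <- hyperemia_metrics(comp)
  expect_equal(unname(m["amplitude_pct"]), 18.5)
  expect_equal(unname(m["duration_min"]), 3.1)
  expect_true(all(is.na(hyperemia_metrics(comp[comp$kind == "II", , drop = FALSE]))))
})

test_that("motion QC flags global jumps and leaves static series unflagged", {
  frames <- rep(list(matrix(0.4, 24, 24)), 30)
  qc0 <- motion_qc(frames)
  expect_false(any(qc0$exclude))
  set.seed(5)
  pattern <- outer(seq(0, 1, length.out = 24), seq(0, 1, length.out = 24))
  frames <- lapply(1:30, function(i) pattern + stats::rnorm(576, 0, 0.005))
  shifted <- frames[[16]]
  shifted[, 11:24] <- frames[[16]][, 1:14]   # 10-pixel jump at frame 16
  frames[[16]] <- shifted
  qc <- motion_qc(frames, threshold = 5)
  expect_true(qc$exclude[15] || qc$exclude[16])
  # flagged intervals suppress detections there
  ts <- flat_ios(hours = 1, sigma = 2)
  tpl <- sd_template(c(0, 0), 10, 3, "left",
                     components = list(component_spec("III", 18, 3, 2)),
                     target_expansion = 1)
  out <- inject_sd_optical(ts, tpl)
  t_on <- 600 + 10 * 60
  qc_all <- data.frame(start_s = 0, end_s = length(traceset_time(out)),
                       score = 99, exclude = TRUE)
  det <- detect_sd_ios(out, qc = qc_all)
  expect_length(det$events, 0)
})
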