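test_that("percent elevation: printed-value arithmetic, flat traces, APU rescaling", {
  t <- seq(0, 600, by = 5)
  cbf <- rep(100, length(t)); cbf[60:80] <- seq(100, 161.5, length.out = 21)
  cbf[81:length(t)] <- 100
  pe <- percent_elevation(cbf, t, baseline_window = 1:50)
  expect_equal(pe$elevation_pct, 61.5)
  expect_true(pe$returns_to_baseline)
  flat <- percent_elevation(rep(42, 50), seq_len(50) * 5, 1:10)
  expect_equal(flat$elevation_pct, 0)
  # arbitrary-perfusion-unit contract: positive rescaling changes nothing
  for (k in c(0.1, 7, 250))
    expect_equal(percent_elevation(cbf * k, t, 1:50)$elevation_pct, 61.5)
  expect_error(percent_elevation(cbf, t, 1:2), "3 baseline samples")
})

test_that("SD-free LSCI traces yield no events", {
  det <- detect_sd_lsci(flat_lsci(hours = 2, sigma = 0.5))
  expect_length(det$events, 0)
})

test_that("replication LSCI: one SD at 9 min, parietal-to-frontal order, ~61.5% elevation", {
  r <- build_roster("paper_replication", 1)
  b <- simulate_animal(r, "a13", what = "lsci")
  det <- detect_sd_lsci(b$lsci)
  expect_length(det$events, 1)
  ev <- det$events[[1]]
  expect_equal((event_onset(ev) - b$lsci$occlusion_time_s) / 60, 9,
               tolerance = 0.5 / 9)
  expect_identical(names(sort(ev$onsets)), c("p4", "p3", "p2", "p1"))
  expect_identical(det$responses$propagation_order[1], "p4>p3>p2>p1")
  expect_equal(mean(det$responses$elevation_pct), 61.5, tolerance = 2 / 61.5)
  expect_true(all(det$responses$pattern == "monophasic"))
})

test_that("oxy coupling signs: replication (+,-) with a positive deOxyHb lag", {
  r <- build_roster("paper_replication", 1)
  b <- simulate_animal(r, "a13", what = "lsci")
  det <- detect_sd_lsci(b$lsci)
  ev <- det$events[[1]]
  oc <- oxy_coupling(b$lsci, "p4", c(event_onset(ev) - 60, event_onset(ev) + 600))
  expect_identical(oc$oxy_sign, 1)
  expect_identical(oc$deoxy_sign, -1)
  expect_gt(oc$deoxy_lag_s, 0)
  expect_false(oc$low_confidence)
})

test_that("inverted coupling and uncorrelated noise are reported faithfully", {
  ts <- flat_lsci(hours = 1)
  t <- traceset_time(ts)
  pulse <- lognormal_pulse(t, 1200, 0.5, 150)
  inv <- ts
  inv$traces$cbf[, 1] <- 100 * (1 + pulse)
  inv$traces$oxyhb[, 1] <- 60 * (1 - 0.6 * pulse)   # inverted fixture
  inv$traces$deoxyhb[, 1] <- 40 * (1 + 0.4 * pulse)
  oc <- oxy_coupling(inv, "p1", c(1100, 1900))
  expect_identical(oc$oxy_sign, -1)
  expect_identical(oc$deoxy_sign, 1)

  noisy <- flat_lsci(hours = 1, sigma = 0.5)
  noisy$traces$cbf[, 1] <- 100 * (1 + pulse) + stats::rnorm(length(t), 0, 0.5)
  oc2 <- oxy_coupling(noisy, "p1", c(1100, 1900))
  expect_true(oc2$low_confidence)
})

test_that("cross-modal matching is windowed, one-to-one and symmetric", {
  mk <- function(id, onset_min, modality)
    sd_event(id, modality, stats::setNames(c(onset_min, onset_min + 1) * 60,
                                           c("s1", "s2")),
             "right", 50)
  lsci <- list(mk("P1", 9, "LSCI"))
  ecog <- list(mk("E1", 12, "ECoG"))
  m <- match_modalities(lsci, ecog, window_min = 5)
  expect_identical(nrow(m), 1L)
  expect_equal(m$lag_s, 3 * 60)
  far <- list(mk("E9", 30, "ECoG"))
  expect_identical(nrow(match_modalities(lsci, far, window_min = 5)), 0L)
  expect_identical(nrow(match_modalities(list(), list())), 0L)
  # symmetry: swapping the argument order gives the same pair set
  a <- list(mk("A1", 10, "LSCI"), mk("A2", 20, "LSCI"))
  b <- list(mk("B1", 11, "ECoG"), mk("B2", 19, "ECoG"), mk("B3", 60, "ECoG"))
  m1 <- match_modalities(a, b)
  m2 <- match_modalities(b, a)
  expect_setequal(paste(m1$id_a, m1$id_b), paste(m2$id_b, m2$id_a))
})

test_that("the replication LSCI SD matches its ECoG counterpart at ~3 min offset", {
  r <- build_roster("paper_replication", 1)
  b <- simulate_animal(r, "a13", what = c("ecog", "lsci"))
  lsci_det <- detect_sd_lsci(b$lsci)
  ecog_det <- detect_sd_ecog(b$ecog)
  expect_length(ecog_det$events, 1)
  m <- match_modalities(lsci_det$events, ecog_det$events, window_min = 5)
  expect_identical(nrow(m), 1L)
  expect_equal(m$lag_s / 60, 3, tolerance = 0.5 / 3)
})
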