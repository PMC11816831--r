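test_that("incidence: rates, hourly bins, and the printed hour-1 arithmetic", {
  events <- data.frame(
    animal_id = rep(sprintf("s%02d", 1:9), times = c(3, 3, 2, 2, 2, 2, 1, 1, 1)),
    onset_min = c(10, 20, 30, 5, 15, 25, 8, 40, 12, 44, 9, 50, 14, 45, 11, 22, 33))
  monitored <- data.frame(animal_id = sprintf("s%02d", 1:12), hours = rep(8, 12))
  inc <- incidence(events, monitored)
  expect_equal(sum(inc$per_animal$hour1), 17)
  expect_equal(inc$hour1_mean, 17 / 12, tolerance = 1e-12)
  expect_equal(round(inc$hour1_mean, 1), 1.4)
  expect_equal(inc$rate_pooled, 17 / 96)
  none <- incidence(events[0, ], monitored)
  expect_true(all(none$per_animal$rate == 0))
  expect_true(all(none$hourly == 0))
})

test_that("per-animal expansion averages only animals with events", {
  ev <- data.frame(animal_id = c("a", "a", "b"), expansion_pct = c(40, 80, 100))
  s <- expansion_summary(ev)
  expect_equal(s$per_animal$mean_expansion, c(60, 100))
  expect_equal(s$mean, 80)
})

test_that("Wilcoxon signed-rank: enumeration examples, zeros, and sign symmetry", {
  # pairs (2,0),(1,0),(3,0): all positive ranks, W = 6, exact p = 2/8
  w <- wilcoxon_signed_rank(c(2, 1, 3), c(0, 0, 0))
  expect_equal(w$W, 6)
  expect_equal(w$p, 2 / 8)
  expect_identical(w$method, "exact")
  expect_warning(w0 <- wilcoxon_signed_rank(c(0, 0), c(0, 0)), "zero")
  expect_equal(w0$p, 1)
  # zero differences are dropped, not counted
  wz <- wilcoxon_signed_rank(c(2, 1, 3, 5), c(0, 0, 0, 5))
  expect_equal(wz$n, 3L)
  # negating all differences preserves p
  set.seed(2)
  for (i in 1:20) {
    d <- sample(-6:6, 7, replace = TRUE)
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(-d)$p)
  }
})

test_that("signed-rank enumeration agrees with brute force and with stats::wilcox.test", {
  set.seed(3)
  for (i in 1:25) {
    d <- sample(c(-9:-1, 1:9), sample(3:8, 1), replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_signed_rank_p(d))
  }
  # tie-free case (distinct magnitudes) cross-checked against base R
  for (i in 1:10) {
    d <- sample(1:50, 8) * sample(c(-1, 1), 8, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("Mann-Whitney: enumeration examples, label swap, brute force, wilcox.test", {
  m <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  expect_equal(m$p, 1 / 3)
  ident <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ident$U, 9 / 2)   # n_a * n_b / 2
  expect_equal(ident$p, 1)
  # label swap maps U -> n_a*n_b - U with the same p
  set.seed(4)
  for (i in 1:20) {
    a <- sample(1:40, 4); b <- sample(1:40, 5)
    m1 <- mann_whitney_u(a, b); m2 <- mann_whitney_u(b, a)
    expect_equal(m1$U, length(a) * length(b) - m2$U)
    expect_equal(m1$p, m2$p)
  }
  for (i in 1:25) {
    a <- sample(1:9, sample(2:4, 1), replace = TRUE)
    b <- sample(1:9, sample(2:4, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p, oracle_mann_whitney_p(a, b))
  }
  for (i in 1:10) {
    a <- sample(1:100, 5); b <- sample(101:200, 5)  # tie-free
    expect_equal(mann_whitney_u(a, b)$p,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("exact enumeration meets the normal approximation at the crossover size", {
  set.seed(6)
  for (i in 1:10) {
    d <- sample(c(-30:-1, 1:30), 15)
    p_ex <- wilcoxon_signed_rank(d, exact_n = 15)$p
    p_no <- wilcoxon_signed_rank(d, exact_n = 0)$p
    expect_lt(abs(p_ex - p_no), 0.02)
    a <- sample(1:100, 6); b <- sample(1:100, 6)
    expect_lt(abs(mann_whitney_u(a, b, exact_n = 12)$p -
                  mann_whitney_u(a, b, exact_n = 0)$p), 0.02)
  }
})

test_that("first/last comparison pairs per ROI and degenerates to p = 1 on ties", {
  resp <- data.frame(
    animal_id = "a1", roi_id = rep(c("r1", "r2", "r3"), each = 2),
    onset_s = rep(c(100, 5000), 3),
    amplitude_pct = c(18, 16, 19, 17, 18.5, 15.5),
    duration_min = c(3, 8, 3.2, 8.2, 2.9, 8.4))
  fl <- first_last_comparison(resp)
  expect_identical(nrow(fl$pairs), 3L)
  expect_equal(fl$first_amp_mean, mean(c(18, 19, 18.5)))
  expect_equal(fl$last_dur_mean, mean(c(8, 8.2, 8.4)))
  expect_lt(fl$duration_test$p, 0.2)
  # identical first/last sets: U test over tied values gives p = 1
  tied <- transform(resp, amplitude_pct = 17, duration_min = 5)
  fl2 <- first_last_comparison(tied)
  expect_equal(fl2$amplitude_test$p, 1)
  # ROIs with fewer than two responses are excluded
  one <- resp[c(1, 3, 5), ]
  expect_null(first_last_comparison(one)$pairs)
})

test_that("summary bookkeeping: totals, permutation invariance, empty inputs", {
  ev <- data.frame(animal_id = c("a", "a", "b"), onset_min = c(10, 70, 30),
                   expansion_pct = c(40, 60, 100))
  mon <- data.frame(animal_id = c("a", "b"), hours = c(2, 3))
  s <- summarize_cohort(ev, monitored_ecog = mon)
  expect_equal(s$ecog$total, 3)
  expect_equal(sum(s$ecog$incidence$hourly), 3)
  # permuting animal order leaves every statistic unchanged
  s2 <- summarize_cohort(ev[c(3, 1, 2), ], monitored_ecog = mon[c(2, 1), ])
  expect_equal(s2$ecog$incidence$rate_mean, s$ecog$incidence$rate_mean)
  expect_equal(s2$ecog$expansion$mean, s$ecog$expansion$mean)
  # empty inputs degenerate to the all-zero hour test (warns) but stay valid
  empty <- suppressWarnings(summarize_cohort(ev[0, ], monitored_ecog = mon))
  expect_equal(empty$ecog$total, 0)
  p <- withr::local_tempfile()
  s3 <- summarize_cohort(ev, monitored_ecog = mon, out_prefix = p)
  expect_true(file.exists(paste0(p, "_summary.json")))
  expect_identical(nrow(utils::read.csv(paste0(p, "_events.csv"))), 3L)
})
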