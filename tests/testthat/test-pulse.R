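test_that("log-normal pulse honors its peak/FWHM/onset parameterization", {
  t <- seq(0, 2000, by = 0.1)
  c1 <- sqrt(2 * log(2))
  for (fwhm in c(30, 90, 500)) {
    p <- lognormal_pulse(t, onset = 400, peak = -5, fwhm_s = fwhm)
    expect_equal(min(p), -5, tolerance = 1e-4)
    above <- t[p <= -2.5]
    expect_equal(min(above), 400, tolerance = 0.2)          # leading half-max
    expect_equal(diff(range(above)), fwhm, tolerance = 0.3) # FWHM
    # strictly causal: zero before the analytic support start
    t0 <- 400 - (fwhm / (2 * sinh(c1 * 0.35))) * exp(-c1 * 0.35)
    expect_true(all(p[t < t0 - 0.2] == 0))
  }
})

test_that("pulse is asymmetric with a longer tail than rise", {
  t <- seq(0, 3000, by = 0.1)
  p <- lognormal_pulse(t, onset = 500, peak = 10, fwhm_s = 120)
  i_pk <- which.max(p)
  rise <- t[i_pk] - 500
  fall <- max(t[p >= 5]) - t[i_pk]
  expect_gt(fall, rise)
})

test_that("half-max crossings recover a symmetric triangular pulse at base/2", {
  # triangular pulse of height h and base b has half-max width b/2
  b <- 200; h <- 8
  t <- seq(0, 1000, by = 1)
  x <- pmax(0, h * (1 - abs(t - 500) / (b / 2)))
  hm <- sdwave:::half_max_crossings(t, x, which.max(x))
  expect_equal(hm$fwhm, b / 2, tolerance = 1e-6)
  expect_equal(hm$onset, 500 - b / 4, tolerance = 1e-6)
})
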