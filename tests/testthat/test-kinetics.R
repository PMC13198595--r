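test_that("rate estimation is exact on noiseless data", {
  t <- seq(0, 10, 0.5)
  tr <- kinetic_trace(t, 0.1 + 0.02 * t)
  f <- estimate_rate(tr, "full")
  expect_equal(f$slope, 0.02, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_equal(f$window, c(0, 10))
  # constant trace: zero slope, r2 defined as 1 (perfect fit)
  fc <- estimate_rate(kinetic_trace(t, rep(0.3, length(t))), "full")
  expect_equal(fc$slope, 0)
  expect_equal(fc$r2, 1)
  expect_error(kinetic_trace(c(0, 1), c(0, 1)), "3 points")
  expect_error(kinetic_trace(c(0, 1, 1), c(0, 1, 2)), "increasing")
})

test_that("best-linear windowing finds the linear phase of a saturating trace", {
  t <- seq(0, 10, 0.5)
  # linear for 0-5 min, then the signal collapses into erratic readings
  a <- ifelse(t <= 5, 0.1 + 0.05 * t, 0.20 + 0.06 * (-1)^(seq_along(t)))
  f <- estimate_rate(kinetic_trace(t, a), "best_linear")
  expect_equal(f$slope, 0.05, tolerance = 1e-9)
  expect_equal(f$window[1], 0)
  expect_equal(f$window[2], 5)
  expect_gte(f$r2, 0.98)
  # hopeless trace falls back to full window with a warning
  set.seed(61)
  noisy <- kinetic_trace(t, rnorm(length(t)))
  expect_warning(estimate_rate(noisy, "best_linear"), "linearity")
})

test_that("noisy slope recovery: truth inside the 95% CI in >= 93/100 replicates", {
  covered <- 0L
  for (k in 1:100) {
    tr <- make_kinetic_trace(slope = 0.02, sigma = 0.002, seed = 1000 + k)
    f <- estimate_rate(tr, "full")
    half <- qt(0.975, f$n - 2) * f$slope_se
    if (abs(f$slope - 0.02) <= half) covered <- covered + 1L
  }
  expect_gte(covered, 93L)
})

test_that("Beer-Lambert unit conversion is exact and linear in volume", {
  r <- rate_to_units(0.0372, eps = 37.2, pathlength = 1, volume = 200)
  expect_equal(r$rate_conc, 0.001, tolerance = 1e-12)   # mM/min
  expect_equal(r$units_U, 0.2, tolerance = 1e-12)       # 1 U = 1 nmol TBBr2/min
  expect_equal(rate_to_units(0, volume = 200)$units_U, 0)
  r2 <- rate_to_units(0.0372, eps = 37.2, pathlength = 1, volume = 400)
  expect_equal(r2$units_U, 2 * r$units_U)
  expect_error(rate_to_units(0.1, eps = -1), "positive")
  # dimensional round trip: slope = U * eps * path / volume
  set.seed(62)
  for (i in 1:20) {
    sl <- runif(1, 0, 0.1); ep <- runif(1, 10, 60)
    pl <- runif(1, 0.2, 1); vo <- runif(1, 50, 300)
    u <- rate_to_units(sl, ep, pl, vo)$units_U
    expect_equal(u * ep * pl / vo, sl, tolerance = 1e-12)
  }
})

test_that("specific activity round-trips against protein amount", {
  r <- specific_activity(rate_to_units(0.0372, 37.2, 1, 200), 0.1)
  expect_equal(r$specific_activity, 2.0, tolerance = 1e-12)
  expect_error(specific_activity(r, 0), "positive")
  set.seed(63)
  for (i in 1:20) {
    u <- rate_to_units(runif(1, 0, 0.2), 37.2, 1, 200)
    mg <- runif(1, 0.01, 2)
    s <- specific_activity(u, mg)
    expect_equal(s$specific_activity * mg, u$units_U, tolerance = 1e-12)
  }
})

test_that("blank subtraction removes a shared background trend", {
  t <- seq(0, 10, 0.5)
  tr <- kinetic_trace(t, 0.1 + 0.03 * t + 0.005 * t)   # enzyme + drift
  bl <- kinetic_trace(t, 0.05 + 0.005 * t)             # drift only
  f <- estimate_rate(subtract_blank(tr, bl), "full")
  expect_equal(f$slope, 0.03, tolerance = 1e-12)
  expect_error(subtract_blank(tr, kinetic_trace(t + 1, t)), "time grid")
})

test_that("fraction selection pools the contiguous run around the activity peak", {
  tri <- data.frame(fraction_index = 1:9,
                    activity = c(0, 1, 3, 6, 10, 7, 4, 1, 0))
  expect_equal(select_active_fractions(tri, 0.5), 4:6)        # >= 5 U around apex
  expect_equal(select_active_fractions(tri, 0.3, contiguous = FALSE), 3:7)
  expect_warning(sel0 <- select_active_fractions(
    data.frame(fraction_index = 1:4, activity = rep(0, 4))), "empty")
  expect_length(sel0, 0)
  # two peaks: only the run containing the global maximum survives
  two <- data.frame(fraction_index = 1:11,
                    activity = c(0, 6, 7, 6, 0, 0, 8, 10, 8, 0, 0))
  expect_equal(select_active_fractions(two, 0.5), 7:9)
  # scale invariance
  two2 <- two; two2$activity <- two2$activity * 37.2
  expect_equal(select_active_fractions(two2, 0.5), 7:9)
})

test_that("kinetics TSV reader reconstructs per-sample traces", {
  t <- seq(0, 10, 0.5)
  d <- rbind(data.frame(sample_id = "s1", time_min = t, a620 = 0.1 + 0.02 * t),
             data.frame(sample_id = "s2", time_min = t, a620 = 0.2 + 0.01 * t))
  tf <- tempfile(fileext = ".tsv")
  write.table(d, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  traces <- read_kinetics_tsv(tf, volume = 150)
  expect_named(traces, c("s1", "s2"))
  expect_equal(estimate_rate(traces$s1, "full")$slope, 0.02, tolerance = 1e-12)
  expect_equal(traces$s2$volume, 150)
})
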