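test_that("coupling fraction: perfect pairing, empty inputs, order invariance", {
  tr <- data.frame(t_min = c(1, 5, 9), x_um = c(10, 50, 90),
                   y_um = c(10, 50, 90))
  ev <- data.frame(t_onset_min = c(1.5, 5.5, 9.5), x_um = c(10, 50, 90),
                   y_um = c(10, 50, 90), is_positive = TRUE)
  cf <- coupling_fraction(tr, ev)
  expect_equal(cf$fraction, 1)
  expect_equal(cf$coupled, 3L)
  # events before the transient or far away do not couple
  ev2 <- data.frame(t_onset_min = c(0.5, 5.5, 9.5), x_um = c(10, 500, 90),
                    y_um = c(10, 50, 90), is_positive = TRUE)
  cf2 <- coupling_fraction(tr, ev2)
  expect_equal(cf2$fraction, 1 / 3)
  # permuting rows changes nothing
  cf3 <- coupling_fraction(tr[c(3, 1, 2), ], ev[c(2, 3, 1), ])
  expect_equal(cf3$fraction, cf$fraction)
  # no transients: undefined fraction, counts still reported
  cf4 <- coupling_fraction(tr[0, ], ev)
  expect_true(is.na(cf4$fraction))
  expect_equal(cf4$total, 0L)
  # an event couples to at most one transient
  tr2 <- data.frame(t_min = c(1, 1.2), x_um = c(10, 12), y_um = c(10, 10))
  ev3 <- data.frame(t_onset_min = 1.5, x_um = 11, y_um = 10,
                    is_positive = TRUE)
  cf5 <- coupling_fraction(tr2, ev3)
  expect_equal(cf5$coupled, 1L)
})

test_that("coupling fraction recovers the generator trigger probability", {
  cells <- data.frame(cell_id = 1:400,
                      x_um = runif(400, 0, 2000), y_um = runif(400, 0, 2000))
  cfg <- scene_config(duration = 60, transient_rate = 5,
                      rspa_probability = 0.1, seed = 31)
  truth <- schedule_events(cfg, cells)
  n <- nrow(truth$transients)
  expect_gt(n, 1500)
  cf <- coupling_fraction(truth$transients[, c("t_min", "cell_id")],
                          truth$rspa_events, positions = cells)
  se2 <- 2 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(cf$fraction - 0.1), se2 + 0.01)
})

test_that("ERK at event centres: null map, enriched bands, size independence", {
  # constant map: centre and random means are identical, test degenerate
  flat <- matrix(2, 100, 100)
  centers <- data.frame(x_um = c(20, 50, 80), y_um = c(30, 60, 20))
  r0 <- erk_at_centers(flat, centers, pixel_size = 1, seed = 1)
  expect_equal(mean(r0$center_values), mean(r0$random_values))
  # events seeded only inside high-ERK bands: centres read higher, p < 0.05
  erk <- matrix(1, 120, 120)
  erk[, 41:80] <- 3                       # vertical high-activity band
  set.seed(41)
  ctr <- data.frame(x_um = runif(12, 45, 75), y_um = runif(12, 15, 105))
  res <- erk_at_centers(erk, ctr, pixel_size = 1, n_random = 40, seed = 5)
  expect_gt(mean(res$center_values), mean(res$random_values))
  expect_lt(res$test$p, 0.05)
  set.seed(43)
  ctr2 <- data.frame(x_um = runif(50, 45, 75), y_um = runif(50, 15, 105))
  res2 <- erk_at_centers(erk, ctr2, pixel_size = 1, n_random = 50, seed = 5)
  # event size is independent of centre ERK activity by construction
  radius <- rnorm(50, 50, 10)
  expect_lt(abs(cor(res2$center_values, radius)), 0.3)
  expect_error(erk_at_centers(flat, data.frame(x_um = 500, y_um = 0),
                              pixel_size = 1), "outside")
})

test_that("cross-correlation: identity, known delay, sign, and antisymmetry", {
  t5 <- seq(0, 60, by = 5)
  t1 <- seq(0, 60, by = 1)
  bump <- function(t) exp(-(t - 30)^2 / 50)
  self <- cross_correlate(list(times = t1, values = bump(t1)),
                          list(times = t1, values = bump(t1)), max_lag = 10)
  expect_equal(self$peak_lag, 0)
  expect_equal(max(self$correlation), 1, tolerance = 1e-12)
  # PKA delayed by 3 min: positive peak lag of 3 (ERK leads)
  erk <- list(times = t5, values = bump(t5))
  pka <- list(times = t1, values = bump(t1 - 3))
  lag <- cross_correlate(erk, pka, max_lag = 10)
  expect_lt(abs(lag$peak_lag - 3), 0.5)
  # anti-correlated traces peak at non-positive correlation
  anti <- cross_correlate(list(times = t1, values = bump(t1)),
                          list(times = t1, values = -bump(t1)), max_lag = 10)
  expect_lte(anti$peak_corr, 1e-9)
  # swapping the traces negates the peak lag
  swap <- cross_correlate(pka, erk, max_lag = 10)
  expect_equal(swap$peak_lag, -lag$peak_lag, tolerance = 0.26)
  expect_error(cross_correlate(erk, list(times = t1, values = rep(1, 61)),
                               max_lag = 10), "constant")
  expect_error(cross_correlate(list(times = 0:5, values = bump(0:5)),
                               list(times = 0:5, values = bump(0:5)),
                               max_lag = 10), "overlap")
})

test_that("switch threshold estimation: midpoint, censoring, population recovery", {
  tr <- data.frame(cell_id = 1, peak_ff0 = c(1.2, 1.6, 1.8, 2.5),
                   fired = c(FALSE, FALSE, TRUE, TRUE))
  est <- estimate_threshold(tr)
  expect_equal(est$per_cell$theta, 1.7)
  expect_true(est$per_cell$monotone)
  # all trials fired: only an upper bound
  allf <- estimate_threshold(data.frame(cell_id = 2,
                                        peak_ff0 = c(1.8, 2.0),
                                        fired = TRUE))
  expect_true(is.na(allf$per_cell$theta))
  expect_equal(allf$per_cell$theta_high, 1.8)
  expect_false(is.finite(allf$per_cell$theta_low))
  # non-monotone cells are flagged
  nm <- estimate_threshold(data.frame(cell_id = 3,
                                      peak_ff0 = c(1.5, 2.0),
                                      fired = c(TRUE, FALSE)))
  expect_false(nm$per_cell$monotone)
  # recovered thresholds on the optogenetic synthetic set lie in the
  # generator range with midpoint slack
  tab <- generate_opto_series(opto_series_config(n_cells = 30, seed = 6))
  rec <- estimate_threshold(tab[, c("cell_id", "peak_ff0", "fired")])
  th <- rec$per_cell$theta[!is.na(rec$per_cell$theta) & rec$per_cell$monotone]
  expect_gt(length(th), 10)
  expect_true(all(th >= 1.4 & th <= 2.2))
})

test_that("event frequency and per-cell probability are count normalizations", {
  f <- event_frequency(12, field_area_cm2 = 0.01, duration_hr = 1)
  expect_equal(f$per_cm2_hr, 1200)
  expect_equal(event_frequency(0, 0.01, 1)$per_cm2_hr, 0)
  ev <- data.frame(is_positive = c(TRUE, TRUE, FALSE))
  f2 <- event_frequency(ev, 0.02, 2, n_cells = 50)
  expect_equal(f2$per_cm2_hr, 50)
  expect_equal(f2$per_cell_hr, 0.02)
})

test_that("the frequency estimator is unbiased on Poisson scenes", {
  rate <- 300; area <- 0.05; hr <- 4
  set.seed(1)
  est <- replicate(100, {
    n <- rpois(1, rate * area * hr)
    event_frequency(n, area, hr)$per_cm2_hr
  })
  se <- sqrt(rate / (area * hr)) / sqrt(100)
  expect_lt(abs(mean(est) - rate), 2 * se)
})

test_that("Welch's t-test agrees with the textbook formulas", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welch_t(a, b)
  expect_equal(w$t, -1.0954451, tolerance = 1e-6)
  expect_equal(w$df, 6, tolerance = 1e-9)
  expect_equal(w$p, 0.3153336, tolerance = 1e-6)
  expect_false(w$significant)
  # identical (non-degenerate) samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # agreement with the independent formula implementation on random pairs
  set.seed(19)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    w1 <- welch_t(x, y); w2 <- oracle_welch(x, y)
    expect_equal(w1$t, w2$t, tolerance = 1e-10)
    expect_equal(w1$df, w2$df, tolerance = 1e-10)
    expect_equal(w1$p, w2$p, tolerance = 1e-10)
  }
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
})
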