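test_that("ratio computation subtracts background and invalidates bad pixels", {
  num <- array(200, dim = c(4, 4, 2))
  den <- array(100, dim = c(4, 4, 2))
  rs <- compute_ratio_stack(num, den, c(50, 50), 1, 1)
  expect_equal(max(abs(rs$frames - 3)), 0)
  rs1 <- compute_ratio_stack(den, den, c(0, 0), 1, 1)
  expect_equal(max(abs(rs1$frames - 1)), 0)
  # denominator equal to background: pixel invalid, not NaN/Inf
  den2 <- den; den2[1, 1, ] <- 50
  rs2 <- compute_ratio_stack(num, den2, c(50, 50), 1, 1)
  expect_true(all(is.na(rs2$frames[1, 1, ])))
  expect_true(all(is.finite(rs2$frames[-1, , ])))
  expect_error(compute_ratio_stack(num, den[, 1:3, , drop = FALSE], c(0, 0), 1, 1),
               "shape")
})

test_that("denoising: zero sizes are the identity, flat fields are invariant, hot pixels are removed", {
  set.seed(1)
  fr <- array(runif(2 * 16 * 16, 0.8, 1.6), dim = c(16, 16, 2))
  rs <- ratio_stack(fr, 1, 1)
  expect_equal(denoise(rs, 0, 0)$frames, fr)
  flat <- ratio_stack(array(1.2, dim = c(16, 16, 2)), 1, 1)
  expect_equal(denoise(flat, 1, 1)$frames, flat$frames, tolerance = 1e-3)
  hot <- array(1, dim = c(9, 9, 2)); hot[5, 5, ] <- 10
  out <- denoise(ratio_stack(hot, 1, 1), 1, 0)
  expect_equal(out$frames[5, 5, 1], 1, tolerance = 1e-3)
})

test_that("minimum-projection normalization: fixed point, worked traces, idempotence", {
  fr <- array(0, dim = c(2, 2, 3))
  fr[1, 1, ] <- c(1.0, 1.2, 1.5)
  fr[1, 2, ] <- c(2.0, 2.4, 2.2)
  fr[2, 1, ] <- c(0.8, 0.9, 1.0)
  fr[2, 2, ] <- c(3.0, 3.0, 3.0)
  rs <- normalize_min_projection(ratio_stack(fr, 1, 1))
  expect_equal(rs$frames[1, 1, ], c(1.0, 1.2, 1.5))
  expect_equal(rs$frames[1, 2, ], c(1.0, 1.2, 1.1))
  expect_equal(apply(rs$frames, c(1, 2), min), matrix(1, 2, 2))
  expect_equal(normalize_min_projection(rs)$frames, rs$frames)
  expect_equal(rs$provenance, "normalized")
  # invalid pixels are excluded from the minimum and stay invalid when always NA
  fr2 <- fr; fr2[1, 1, 1] <- NA; fr2[2, 2, ] <- NA
  rs2 <- normalize_min_projection(ratio_stack(fr2, 1, 1))
  expect_equal(rs2$frames[1, 1, 2:3], c(1.0, 1.25))
  expect_true(all(is.na(rs2$frames[2, 2, ])))
})

test_that("binarization threshold is strict and foreground is monotone in threshold", {
  expect_equal(sum(binarize_clean(uniform_stack(1.0))), 0)
  expect_equal(sum(binarize_clean(uniform_stack(1.3))), 0)
  expect_gt(sum(binarize_clean(uniform_stack(1.3 + 1e-9))), 0)
  # raising the threshold never adds foreground
  set.seed(42)
  fr <- array(1, dim = c(40, 40, 2))
  fr[, , 1] <- 1 + as.matrix(EBImage::gblur(matrix(runif(1600, 0, 1), 40), 2))
  rs <- ratio_stack(fr, 1, 1, provenance = "normalized")
  lo <- binarize_clean(rs, threshold = 1.2)
  hi <- binarize_clean(rs, threshold = 1.45)
  expect_true(all(lo[hi]))
})

test_that("a uniform disc binarizes to its geometric area", {
  fr <- array(1, dim = c(80, 80, 2))
  d2 <- outer((0:79 - 40)^2, (0:79 - 40)^2, `+`)
  fr[, , 1][d2 <= 20^2] <- 1.5
  rs <- ratio_stack(fr, 1, 1, provenance = "normalized")
  m <- binarize_clean(rs)
  expect_lt(abs(sum(m[, , 1]) - pi * 400) / (pi * 400), 0.05)
  expect_equal(sum(m[, , 2]), 0)
})

test_that("candidate extraction: equivalent radius, disc recovery, 8-connectivity", {
  # 315-pixel component at 1 um^2/px
  m <- matrix(FALSE, 40, 40); m[1:35, 1:9] <- TRUE                # 315 px
  cand <- extract_candidates(as_mask_stack(list(m)))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$r_um, sqrt(315 / pi), tolerance = 1e-12)
  expect_true(cand$edge)
  # rasterized disc of radius 20 um
  d2 <- outer((0:79 - 40)^2, (0:79 - 40)^2, `+`)
  disc <- d2 <= 20^2
  cd <- extract_candidates(as_mask_stack(list(disc)))
  expect_equal(cd$r_um, 20, tolerance = 0.5 / 20)
  expect_equal(cd$x_um, 40, tolerance = 1e-6)
  # two discs touching at exactly one corner form one 8-connected component
  corner <- matrix(FALSE, 20, 20)
  corner[3:7, 3:7] <- TRUE; corner[8:12, 8:12] <- TRUE
  cc <- extract_candidates(as_mask_stack(list(corner)))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$n_px, 50L)
})

test_that("8-connected labelling matches a brute-force flood-fill oracle", {
  set.seed(13)
  for (i in 1:8) {
    m <- matrix(runif(12 * 12) < 0.35, 12, 12)
    lab <- label_components(m)
    ora <- oracle_label8(m)
    expect_equal(max(lab), max(ora))
    # identical partitions (labels may be permuted)
    if (max(lab) > 0) {
      key <- paste(lab[m], ora[m])
      expect_equal(length(unique(key)), max(lab))
    }
    expect_equal(sort(tabulate(lab[m])), sort(tabulate(ora[m])))
  }
})

test_that("linking respects the 100 um gate and resolves conflicts by distance", {
  mk <- function(frame, x, y, r = 20)
    data.frame(frame = frame, t_min = frame - 1, x_um = x, y_um = y,
               area_um2 = pi * r^2, r_um = r, n_px = 1L, edge = FALSE)
  # 50 um apart in successive frames: one event
  ev <- link_events(rbind(mk(1, 100, 100), mk(2, 150, 100)))
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$n_frames, 2L)
  # 150 um apart: two events
  ev2 <- link_events(rbind(mk(1, 100, 100), mk(2, 250, 100)))
  expect_equal(nrow(ev2$events), 2L)
  # exactly 100 um: gate is strict ("less than 100 um")
  ev3 <- link_events(rbind(mk(1, 100, 100), mk(2, 200, 100)))
  expect_equal(nrow(ev3$events), 2L)
  # two candidates within the gate of one prior event: nearer one linked
  ev4 <- link_events(rbind(mk(1, 100, 100), mk(2, 160, 100), mk(2, 130, 100)))
  expect_equal(nrow(ev4$events), 2L)
  comp <- ev4$components
  expect_equal(comp$event_id[comp$frame == 2 & comp$x_um == 130],
               comp$event_id[comp$frame == 1])
  expect_false(comp$event_id[comp$frame == 2 & comp$x_um == 160] ==
                 comp$event_id[comp$frame == 1])
  # exhaustive-assignment oracle on a 2x2 conflict: total linked distance
  # of the greedy mutual-nearest solution equals the best assignment here
  ev5 <- link_events(rbind(mk(1, 0, 0), mk(1, 90, 0),
                           mk(2, 10, 0), mk(2, 80, 0)))
  expect_equal(nrow(ev5$events), 2L)
  expect_equal(sort(table(ev5$components$event_id)), sort(c(2L, 2L)),
               ignore_attr = TRUE)
})

test_that("positive call uses the strict 15 um rule on the lifetime maximum", {
  mk <- function(frame, r) data.frame(frame = frame, t_min = frame - 1,
                                      x_um = 0, y_um = 0, area_um2 = pi * r^2,
                                      r_um = r, n_px = 1L, edge = FALSE)
  ev <- call_positive(link_events(rbind(mk(1, 10), mk(2, 30))))
  expect_true(ev$events$is_positive)
  ev2 <- call_positive(link_events(mk(1, 15)))
  expect_false(ev2$events$is_positive)
  # grows past the cutoff later in life: the lifetime maximum decides
  ev3 <- call_positive(link_events(rbind(mk(1, 14), mk(2, 16))))
  expect_true(ev3$events$is_positive)
  expect_equal(ev3$events$peak_radius_um, 16)
})

test_that("concentric-ROI radius: uniform field, disc, and baseline cases", {
  u <- uniform_stack(1.5, n = 100, pixel_size = 1)
  rings <- seq(6.4, 44.8, by = 6.4)
  rc <- radius_time_course(u, c(50, 50), ring_radii = rings)
  expect_equal(rc$radii, rep(44.8, 2))
  expect_equal(rc$detection_limit, 6.4)
  b <- uniform_stack(1.0, n = 100, pixel_size = 1)
  expect_equal(radius_time_course(b, c(50, 50), ring_radii = rings)$radii,
               rep(0, 2))
  # disc of radius 40 um at 1.5: measured radius within one ring spacing
  fr <- array(1, dim = c(100, 100, 2))
  d2 <- outer((0:99 - 50)^2, (0:99 - 50)^2, `+`)
  fr[, , 1][d2 <= 40^2] <- 1.5
  ds <- ratio_stack(fr, 1, 1, provenance = "normalized")
  rd <- radius_time_course(ds, c(50, 50), ring_radii = rings)
  expect_lt(abs(rd$radii[1] - 40), 6.4)
  expect_equal(rd$radii[2], 0)
  expect_error(radius_time_course(u, c(500, 50), ring_radii = rings),
               "outside")
})

test_that("expansion speed: exact linear course, no-growth course, degenerate input", {
  course <- structure(list(times = 0:4 * 0.25, radii = c(0, 25, 50, 75, 100),
                           detection_limit = 6.4, truncated = FALSE),
                      class = "radius_time_course")
  expect_equal(estimate_expansion_speed(course), 100, tolerance = 1e-12)
  flat <- structure(list(times = 0:3, radii = rep(40, 4),
                         detection_limit = 6.4, truncated = FALSE),
                    class = "radius_time_course")
  expect_equal(estimate_expansion_speed(flat), 0, tolerance = 1e-12)
  one <- structure(list(times = 0:2, radii = c(0, 30, 0),
                        detection_limit = 6.4, truncated = FALSE),
                   class = "radius_time_course")
  expect_error(estimate_expansion_speed(one), "fewer than 2")
})

test_that("fitted equivalent radius agrees with the concentric-ROI radius on a noiseless disc", {
  cfg <- scene_config(field_size = 200, pixel_size = 2, duration = 3,
                      frame_interval = 0.25, peak_radius = 40, noise_sd = 0,
                      decay_time = 0.8, seed = 2)
  truth <- single_event_truth(100, 100, onset = 0.5, radius = 40)
  sc <- render_scene(cfg, truth)
  rs <- normalize_min_projection(
    compute_ratio_stack(sc$num, sc$den, c(0, 0), 2, 0.25))
  k <- round(1.25 / 0.25) + 1       # plateau frame, full 40 um disc
  cand <- extract_candidates(binarize_clean(rs, open_radius = 0,
                                            close_radius = 0))
  r_fit <- cand$r_um[cand$frame == k]
  rc <- radius_time_course(rs, c(100, 100), ring_width = 6.4,
                           max_radius = 57.6)
  expect_lt(abs(r_fit - rc$radii[k]), 6.4)
})

test_that("the detector matches the flood-fill pipeline oracle on small random stacks", {
  set.seed(99)
  for (rep in 1:3) {
    fr <- array(exp(rnorm(32 * 32 * 10, 0, 0.1)), dim = c(32, 32, 10))
    fr[10:20, 10:20, 3:6] <- 2
    rs <- normalize_min_projection(ratio_stack(fr, 1, 1))
    masks <- binarize_clean(rs, open_radius = 0, close_radius = 0)
    cand <- extract_candidates(masks)
    for (k in sample(10, 3)) {
      ora <- oracle_label8(masks[, , k])
      ck <- cand[cand$frame == k, ]
      expect_equal(nrow(ck), max(ora))
      expect_equal(sort(ck$n_px), sort(tabulate(ora[ora > 0])))
    }
  }
})

test_that("default detector recovers large synthetic events and rarely fires on null scenes", {
  cfg <- scene_config(field_size = 400, pixel_size = 2, duration = 8,
                      frame_interval = 0.25, transient_rate = 1.2,
                      rspa_probability = 0.25, noise_sd = 0.05, seed = 21)
  scene <- render_scene(cfg)
  det <- detect_rspa(scene$num, scene$den, cfg$pixel_size, cfg$frame_interval)
  truth_ev <- scene$truth$rspa_events
  big <- truth_ev[truth_ev$peak_radius_um >= 30 &
                    truth_ev$t_onset_min <= cfg$duration - 1, ]
  expect_gt(nrow(big), 2)
  pos_comp <- det$events$components[
    det$events$components$event_id %in%
      det$events$events$event_id[det$events$events$is_positive], ]
  recovered <- vapply(seq_len(nrow(big)), function(i) {
    any(sqrt((pos_comp$x_um - big$x_um[i])^2 +
             (pos_comp$y_um - big$y_um[i])^2) < 50 &
        abs(pos_comp$t_min - big$t_onset_min[i]) < 2.5)
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  # null scene: at most one spurious positive per 10 frames
  cfg0 <- scene_config(field_size = 400, pixel_size = 2, duration = 2.25,
                       frame_interval = 0.25, noise_sd = 0.05, seed = 22)
  sc0 <- render_scene(cfg0, empty_truth())
  det0 <- detect_rspa(sc0$num, sc0$den, 2, 0.25)
  expect_lte(sum(det0$events$events$is_positive), 1)
})
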