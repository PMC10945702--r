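#' Fraction of calcium transients coupled to RSPA events
#'
#' A transient is coupled when some positive event's onset falls within
#' `max_delay` minutes after the transient (inclusive window `[t, t +
#' max_delay]`) and within `max_distance` of the transient's position. Each
#' event can couple to at most one transient (the nearest in time);
#' candidate pairs are assigned greedily in order of increasing time
#' separation. Reports the coupled fraction with a Clopper-Pearson 95%
#' binomial confidence interval.
#'
#' @param transients data.frame with `t_min` (or `t_peak_min`) and `x_um`,
#'   `y_um` (taken from `positions` by `cell_id` if absent).
#' @param events data.frame with `t_onset_min`, `x_um`, `y_um` and
#'   optionally `is_positive` (only positive events couple; all rows are
#'   used if the column is absent).
#' @param max_delay Coupling window, min (default 2).
#' @param max_distance Coupling distance, um (default 20).
#' @param positions Optional `cell_id`, `x_um`, `y_um` lookup for
#'   transients.
#' @return List: `fraction`, `coupled`, `total`, `conf_int` (95% CI;
#'   `fraction` is `NA` when `total` is 0).
#' @export
coupling_fraction <- function(transients, events, max_delay = 2,
                              max_distance = 20, positions = NULL) {
  tt <- if ("t_min" %in% names(transients)) transients$t_min else
    transients$t_peak_min
  if (is.null(tt)) stop("transients need a `t_min` or `t_peak_min` column")
  if (!all(c("x_um", "y_um") %in% names(transients))) {
    if (is.null(positions))
      stop("transients lack coordinates and no `positions` given")
    m <- match(transients$cell_id, positions$cell_id)
    transients$x_um <- positions$x_um[m]
    transients$y_um <- positions$y_um[m]
  }
  if (!is.null(events$is_positive))
    events <- events[events$is_positive, , drop = FALSE]
  n <- length(tt)
  if (n == 0L)
    return(list(fraction = NA_real_, coupled = 0L, total = 0L,
                conf_int = c(NA_real_, NA_real_)))
  pairs <- NULL
  if (nrow(events) > 0L) {
    dt <- outer(tt, events$t_onset_min, function(a, b) b - a)
    dx <- outer(transients$x_um, events$x_um, `-`)
    dy <- outer(transients$y_um, events$y_um, `-`)
    ok <- dt >= 0 & dt <= max_delay & sqrt(dx^2 + dy^2) <= max_distance
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx))
      pairs <- data.frame(tr = idx[, 1], ev = idx[, 2],
                          dt = dt[idx])[order(dt[idx]), , drop = FALSE]
  }
  coupled <- logical(n)
  if (!is.null(pairs)) {
    ev_used <- logical(nrow(events))
    for (i in seq_len(nrow(pairs))) {
      if (ev_used[pairs$ev[i]]) next
      ev_used[pairs$ev[i]] <- TRUE
      coupled[pairs$tr[i]] <- TRUE
    }
  }
  k <- sum(coupled)
  ci <- as.numeric(stats::binom.test(k, n)$conf.int)
  list(fraction = k / n, coupled = k, total = n, conf_int = ci)
}

#' ERK activity at event centres versus random positions
#'
#' Compares the mean ERK activity within `roi_radius` of each event centre
#' with that at uniformly random in-field positions (drawn outside a border
#' of `roi_radius`), and tests the difference with Welch's t-test.
#'
#' @param erk_map Numeric matrix of ERK activity (one frame).
#' @param centers data.frame with `x_um`, `y_um` event centres.
#' @param pixel_size um/px of `erk_map`.
#' @param n_random Number of random control positions (default: one per
#'   event).
#' @param roi_radius ROI radius, um (default 10).
#' @param seed Optional RNG seed for the random positions.
#' @return List: `center_values`, `random_values`, `test` (a [welch_t()]
#'   result).
#' @export
erk_at_centers <- function(erk_map, centers, pixel_size,
                           n_random = nrow(centers), roi_radius = 10,
                           seed = NULL) {
  if (n_random < nrow(centers))
    stop("`n_random` must be at least the number of events")
  d <- dim(erk_map)
  fx <- (d[2] - 1) * pixel_size
  fy <- (d[1] - 1) * pixel_size
  disc_mean <- function(x, y) {
    if (x < 0 || x > fx || y < 0 || y > fy)
      stop("ROI centre outside the field")
    d2 <- pixel_dist2(d[1], d[2], pixel_size, c(x, y))
    mean(erk_map[d2 <= roi_radius^2], na.rm = TRUE)
  }
  cv <- mapply(disc_mean, centers$x_um, centers$y_um)
  if (!is.null(seed)) set.seed(seed)
  rx <- stats::runif(n_random, roi_radius, fx - roi_radius)
  ry <- stats::runif(n_random, roi_radius, fy - roi_radius)
  rv <- mapply(disc_mean, rx, ry)
  test <- tryCatch(welch_t(cv, rv), error = function(e) NULL)
  list(center_values = as.numeric(cv), random_values = as.numeric(rv),
       test = test)
}

#' Normalized cross-correlation between ERK and PKA activity traces
#'
#' Resamples both traces to a common uniform grid by linear interpolation
#' (ERK was typically sampled every 5 min and PKA every 1 min, so the finer
#' grid is the default), mean-subtracts and variance-scales them, and
#' computes the correlation at every lag in `[-max_lag, max_lag]`. The sign
#' convention is that a positive peak lag means ERK leads PKA. The peak lag
#' is refined by a local parabola through the three points around the argmax.
#'
#' @param erk,pka Lists or data.frames with `times`/`t_min` (min) and
#'   `values`/`value`.
#' @param max_lag Maximum lag, min (default 10).
#' @param dt Common grid step, min; default the finer of the two median
#'   sampling intervals.
#' @return List of class `lag_curve`: `lags`, `correlation`, `peak_lag`
#'   (parabolically refined), `peak_corr`.
#' @export
cross_correlate <- function(erk, pka, max_lag = 10, dt = NULL) {
  get <- function(x) {
    tms <- if (!is.null(x$times)) x$times else x$t_min
    val <- if (!is.null(x$values)) x$values else x$value
    if (is.null(tms) || is.null(val)) stop("trace needs times and values")
    list(t = tms, v = val)
  }
  e <- get(erk); p <- get(pka)
  if (is.null(dt))
    dt <- min(stats::median(diff(e$t)), stats::median(diff(p$t)))
  t0 <- max(min(e$t), min(p$t))
  t1 <- min(max(e$t), max(p$t))
  if (t1 - t0 < 2 * max_lag)
    stop("traces overlap less than twice the maximum lag")
  grid <- seq(t0, t1, by = dt)
  ev <- stats::approx(e$t, e$v, grid)$y
  pv <- stats::approx(p$t, p$v, grid)$y
  if (stats::sd(ev) == 0 || stats::sd(pv) == 0)
    stop("constant trace: cross-correlation undefined")
  ev <- (ev - mean(ev)) / stats::sd(ev)
  pv <- (pv - mean(pv)) / stats::sd(pv)
  kmax <- floor(max_lag / dt)
  lags <- (-kmax:kmax) * dt
  n <- length(grid)
  cc <- vapply(-kmax:kmax, function(k) {
    # lag k: correlate erk(t) with pka(t + k dt); positive k = ERK leads
    if (k >= 0) stats::cor(ev[1:(n - k)], pv[(1 + k):n])
    else stats::cor(ev[(1 - k):n], pv[1:(n + k)])
  }, numeric(1))
  i <- which.max(cc)
  peak <- lags[i]
  if (i > 1L && i < length(cc)) {
    a <- cc[i - 1]; b <- cc[i]; c <- cc[i + 1]
    den <- a - 2 * b + c
    if (den < 0) peak <- peak + dt * 0.5 * (a - c) / den
  }
  structure(list(lags = lags, correlation = cc, peak_lag = peak,
                 peak_corr = cc[i]), class = "lag_curve")
}

#' Estimate per-cell switch thresholds from graded stimulation series
#'
#' For each cell, the firing threshold is the midpoint between the largest
#' calcium peak that did not evoke an event and the smallest peak that did.
#' Cells with only fired or only non-fired trials yield one-sided intervals;
#' cells where some fired peak lies below a non-fired peak are flagged
#' non-monotone.
#'
#' @param trials data.frame: `cell_id`, `peak_ff0`, `fired` (logical).
#' @return List: `per_cell` (data.frame `cell_id`, `theta_low`,
#'   `theta_high`, `theta`, `monotone`), `range` (range of point estimates,
#'   `NA` if none).
#' @export
estimate_threshold <- function(trials) {
  out <- lapply(split(trials, trials$cell_id), function(g) {
    lo <- suppressWarnings(max(g$peak_ff0[!g$fired]))   # -Inf if none
    hi <- suppressWarnings(min(g$peak_ff0[g$fired]))    #  Inf if none
    data.frame(cell_id = g$cell_id[1],
               theta_low = lo, theta_high = hi,
               theta = if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
                       else NA_real_,
               monotone = !(is.finite(lo) && is.finite(hi) && hi < lo))
  })
  per_cell <- do.call(rbind, out)
  rownames(per_cell) <- NULL
  th <- per_cell$theta[per_cell$monotone & !is.na(per_cell$theta)]
  list(per_cell = per_cell,
       range = if (length(th)) range(th) else c(NA_real_, NA_real_))
}

#' Areal event frequency and per-cell probability
#'
#' @param n_events Count of positive events (or an events data.frame, in
#'   which case rows with `is_positive` are counted).
#' @param field_area_cm2 Field area, cm^2.
#' @param duration_hr Observation time, hr.
#' @param n_cells Optional cell count for the per-cell rate.
#' @return List: `per_cm2_hr`, and `per_cell_hr` when `n_cells` is given.
#' @export
event_frequency <- function(n_events, field_area_cm2, duration_hr,
                            n_cells = NULL) {
  if (is.data.frame(n_events)) {
    n_events <- if (!is.null(n_events$is_positive))
      sum(n_events$is_positive) else nrow(n_events)
  }
  if (field_area_cm2 <= 0 || duration_hr <= 0)
    stop("area and duration must be positive")
  out <- list(per_cm2_hr = n_events / (field_area_cm2 * duration_hr))
  if (!is.null(n_cells))
    out$per_cell_hr <- n_events / (n_cells * duration_hr)
  out
}

#' Welch's t-test
#'
#' Two-sample t-test with unequal variances (Welch-Satterthwaite degrees of
#' freedom), the test used for all group comparisons here, with the p < 0.05
#' significance rule.
#'
#' @param a,b Numeric samples (each n >= 2, nonzero variance).
#' @return List: `t`, `df`, `p`, `significant` (p < 0.05).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate samples: both variances are zero")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < 0.05)
}
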