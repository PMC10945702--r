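#' Synthetic scene configuration
#'
#' Parameters of the ground-truthed synthetic microscopy scene generator. The
#' defaults emulate a confluent MDCK monolayer imaged ratiometrically:
#' sparse per-cell calcium transients (homogeneous Poisson process), of which
#' a fraction `rspa_probability` discharge a firework-like radial PKA
#' activation event expanding at `expansion_speed` and relaxing back to
#' baseline with time constant `decay_time`.
#'
#' @param field_size Square field side, um.
#' @param pixel_size um/px; `field_size / pixel_size` must be an integer.
#' @param frame_interval min.
#' @param duration Total imaged time, min (>= 1 frame interval).
#' @param cell_density cells/cm^2.
#' @param transient_rate Calcium transients per cell per hour.
#' @param rspa_probability Probability that a transient discharges an event,
#'   in `[0, 1]`.
#' @param expansion_speed Radial expansion speed, um/min.
#' @param peak_radius Plateau radius of the activation disc, um.
#' @param rise_time Time to reach the plateau, min; defaults to
#'   `peak_radius / expansion_speed`.
#' @param decay_time Exponential decay constant after the plateau, min.
#' @param peak_ratio_amplitude Normalized-ratio amplitude inside the disc
#'   (baseline 1.0).
#' @param radius_jitter Half-width of the uniform per-event multiplier on
#'   `peak_radius` (0 = all events identical).
#' @param noise_sd Channel noise sd as a fraction of the basal intensity.
#' @param basal_intensity Basal denominator-channel intensity, AU.
#' @param seed Integer RNG seed.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(field_size = 600, pixel_size = 2,
                         frame_interval = 0.25, duration = 10,
                         cell_density = 2.4e5, transient_rate = 1,
                         rspa_probability = 0.1, expansion_speed = 100,
                         peak_radius = 50, rise_time = NULL, decay_time = 2,
                         peak_ratio_amplitude = 1.5, radius_jitter = 0.3,
                         noise_sd = 0.05, basal_intensity = 1000,
                         seed = 1L) {
  if (is.null(rise_time)) rise_time <- peak_radius / expansion_speed
  cfg <- list(field_size = field_size, pixel_size = pixel_size,
              frame_interval = frame_interval, duration = duration,
              cell_density = cell_density, transient_rate = transient_rate,
              rspa_probability = rspa_probability,
              expansion_speed = expansion_speed, peak_radius = peak_radius,
              rise_time = rise_time, decay_time = decay_time,
              peak_ratio_amplitude = peak_ratio_amplitude,
              radius_jitter = radius_jitter, noise_sd = noise_sd,
              basal_intensity = basal_intensity, seed = as.integer(seed))
  pos <- c("field_size", "pixel_size", "frame_interval", "duration",
           "cell_density", "transient_rate", "expansion_speed", "peak_radius",
           "rise_time", "decay_time", "basal_intensity")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0)
      stop("`", p, "` must be a single positive number")
  if (cfg$rspa_probability < 0 || cfg$rspa_probability > 1)
    stop("`rspa_probability` must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  npx <- field_size / pixel_size
  if (abs(npx - round(npx)) > 1e-9)
    stop("field_size / pixel_size must be an integer pixel grid")
  if (duration / frame_interval < 1)
    stop("duration must cover at least 2 frames")
  if (cfg$peak_ratio_amplitude <= 1)
    stop("`peak_ratio_amplitude` must exceed the 1.0 baseline")
  structure(cfg, class = "scene_config")
}

#' Generate a jittered hexagonal cell field
#'
#' Places `round(cell_density x field area)` cells on a jittered hexagonal
#' packing, emulating a confluent epithelial monolayer. Deterministic for a
#' fixed `seed`.
#'
#' @param config A `scene_config`.
#' @return data.frame with `cell_id`, `x_um`, `y_um` (all inside the field).
#' @export
generate_cell_field <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  area_cm2 <- (config$field_size * 1e-4)^2
  n <- round(config$cell_density * area_cm2)
  if (n < 1) stop("cell_density too low: field would hold no cells")
  dens_um2 <- config$cell_density / 1e8        # cells per um^2
  spacing <- sqrt(2 / (sqrt(3) * dens_um2))    # hexagonal lattice constant
  if (spacing < config$pixel_size)
    stop("cell_density too high: lattice spacing below one pixel")
  set.seed(config$seed)
  dy <- spacing * sqrt(3) / 2
  ys <- seq(dy / 2, config$field_size - 1e-9, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(spacing / 2 + off, config$field_size - 1e-9, by = spacing)
    cbind(xs, ys[i])
  }))
  jit <- matrix(stats::runif(2 * nrow(pts), -spacing / 4, spacing / 4),
                ncol = 2)
  pts <- pts + jit
  pts[, 1] <- pmin(pmax(pts[, 1], 0), config$field_size - 1e-9)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), config$field_size - 1e-9)
  if (nrow(pts) >= n) {
    pts <- pts[sample.int(nrow(pts), n), , drop = FALSE]
  } else {
    extra <- cbind(stats::runif(n - nrow(pts), 0, config$field_size),
                   stats::runif(n - nrow(pts), 0, config$field_size))
    pts <- rbind(pts, extra)
  }
  data.frame(cell_id = seq_len(n), x_um = pts[, 1], y_um = pts[, 2])
}

#' Schedule calcium transients and the events they discharge
#'
#' Draws per-cell transient times from a homogeneous Poisson process at
#' `transient_rate`; each transient independently discharges an event with
#' probability `rspa_probability`, at the same cell and time. Transient peak
#' F/F0 values are drawn uniformly from 3.5-8 (above the standard calling
#' threshold of 3); per-event peak radii are `peak_radius` times a uniform
#' multiplier in `1 +/- radius_jitter`.
#'
#' @param config A `scene_config`.
#' @param cells data.frame from [generate_cell_field()].
#' @return List of class `scene_truth`: `cells`, `transients` (`cell_id`,
#'   `t_min`, `peak_ff0`, `evokes_rspa`), `rspa_events` (`event_id`,
#'   `cell_id`, `t_onset_min`, `x_um`, `y_um`, `speed_um_min`,
#'   `peak_radius_um`, `truncated`).
#' @export
schedule_events <- function(config, cells) {
  stopifnot(inherits(config, "scene_config"))
  if (nrow(cells) == 0) stop("`cells` is empty")
  set.seed(config$seed + 1L)
  dur_hr <- config$duration / 60
  counts <- stats::rpois(nrow(cells), config$transient_rate * dur_hr)
  cell_of <- rep(cells$cell_id, counts)
  # times are snapped to the frame grid so the brief indicator pulse peak
  # is always sampled at its full amplitude
  raw_t <- stats::runif(sum(counts), 0, config$duration)
  tr <- data.frame(
    cell_id = cell_of,
    t_min = round(raw_t / config$frame_interval) * config$frame_interval,
    peak_ff0 = stats::runif(sum(counts), 3.5, 8))
  tr <- tr[order(tr$t_min), , drop = FALSE]
  rownames(tr) <- NULL
  tr$evokes_rspa <- stats::runif(nrow(tr)) < config$rspa_probability
  ev <- tr[tr$evokes_rspa, , drop = FALSE]
  nev <- nrow(ev)
  radius <- config$peak_radius *
    stats::runif(nev, 1 - config$radius_jitter, 1 + config$radius_jitter)
  pos <- cells[match(ev$cell_id, cells$cell_id), ]
  margin <- pmin(pos$x_um, config$field_size - pos$x_um,
                 pos$y_um, config$field_size - pos$y_um)
  events <- data.frame(
    event_id = seq_len(nev), cell_id = ev$cell_id,
    t_onset_min = ev$t_min, x_um = pos$x_um, y_um = pos$y_um,
    speed_um_min = rep(config$expansion_speed, nev),
    peak_radius_um = radius,
    truncated = radius + 5 > margin)
  rownames(events) <- NULL
  structure(list(cells = cells, transients = tr, rspa_events = events),
            class = "scene_truth")
}

# normalized radial activation profile of one event at age `a` (min):
# a disc of core radius min(speed*a, peak_radius) with a 5 um linear edge,
# amplitude at plateau until rise_time, then exponential relaxation
event_ratio_profile <- function(dist, age, speed, peak_radius, rise_time,
                                decay_time, amplitude, edge_width = 5) {
  if (age < 0) return(rep(0, length(dist)))
  core <- min(speed * age, peak_radius)
  amp <- if (age <= rise_time) amplitude - 1 else
    (amplitude - 1) * exp(-(age - rise_time) / decay_time)
  shape <- pmin(1, pmax(0, 1 - (dist - core) / edge_width))
  amp * shape
}

#' Render a synthetic two-channel scene
#'
#' Renders the scheduled ground truth into numerator/denominator channel
#' stacks plus a single-channel calcium-indicator stack. The true ratio field
#' is 1.0 at baseline; inside each event it is elevated by a top-hat disc
#' with a 5 um linear edge whose core radius grows at `expansion_speed` to
#' the event's peak radius and whose amplitude then relaxes exponentially.
#' Each channel receives independent additive Gaussian noise with sd
#' `noise_sd x basal_intensity`; with `noise_sd = 0` the per-pixel
#' numerator/denominator ratio equals the true ratio field exactly. Calcium
#' transients are rendered as 30 s triangular F/F0 pulses in discs of 5 um
#' around their cell.
#'
#' @param config A `scene_config`.
#' @param truth A `scene_truth` from [schedule_events()]; generated from
#'   `config` if `NULL`.
#' @return List of class `rspa_scene`: `num`, `den`, `ca` (3-D arrays),
#'   `truth`, `config`.
#' @export
render_scene <- function(config, truth = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(truth))
    truth <- schedule_events(config, generate_cell_field(config))
  npx <- as.integer(round(config$field_size / config$pixel_size))
  nt <- as.integer(floor(config$duration / config$frame_interval)) + 1L
  times <- (seq_len(nt) - 1) * config$frame_interval
  basal <- config$basal_intensity
  ratio <- array(1, dim = c(npx, npx, nt))
  ev <- truth$rspa_events
  for (i in seq_len(nrow(ev))) {
    reach <- ev$peak_radius_um[i] + 5
    d2 <- pixel_dist2(npx, npx, config$pixel_size,
                      c(ev$x_um[i], ev$y_um[i]))
    box <- which(d2 <= reach^2)
    dist <- sqrt(d2[box])
    rise <- max(config$rise_time, ev$peak_radius_um[i] / ev$speed_um_min[i])
    for (k in seq_len(nt)) {
      age <- times[k] - ev$t_onset_min[i]
      if (age < 0) next
      if (age > rise && (age - rise) / config$decay_time > 8) break
      prof <- event_ratio_profile(dist, age, ev$speed_um_min[i],
                                  ev$peak_radius_um[i], rise,
                                  config$decay_time,
                                  config$peak_ratio_amplitude)
      f <- ratio[, , k]
      f[box] <- pmax(f[box], 1 + prof)
      ratio[, , k] <- f
    }
  }
  # calcium indicator: baseline 100 AU, triangular 0.5 min pulses
  ca <- array(100, dim = c(npx, npx, nt))
  tr <- truth$transients
  cells <- truth$cells
  for (i in seq_len(nrow(tr))) {
    p <- cells[match(tr$cell_id[i], cells$cell_id), ]
    d2 <- pixel_dist2(npx, npx, config$pixel_size, c(p$x_um, p$y_um))
    box <- which(d2 <= 25)                     # 5 um indicator disc
    for (k in seq_len(nt)) {
      w <- 1 - abs(times[k] - tr$t_min[i]) / 0.25
      if (w <= 0) next
      f <- ca[, , k]
      f[box] <- pmax(f[box], 100 * (1 + (tr$peak_ff0[i] - 1) * w))
      ca[, , k] <- f
    }
  }
  set.seed(config$seed + 2L)
  sd <- config$noise_sd * basal
  den <- basal + array(stats::rnorm(npx * npx * nt, 0, sd), dim = dim(ratio))
  num <- basal * ratio +
    array(stats::rnorm(npx * npx * nt, 0, sd), dim = dim(ratio))
  if (sd > 0)
    ca <- ca + array(stats::rnorm(npx * npx * nt, 0, config$noise_sd * 100),
                     dim = dim(ca))
  structure(list(num = num, den = den, ca = ca, truth = truth,
                 config = config), class = "rspa_scene")
}

#' Per-cell calcium indicator traces of a scene
#'
#' Analytic indicator traces at each cell: baseline 100 AU with the 30 s
#' triangular pulses of the scheduled transients, plus Gaussian noise at
#' `noise_sd` of baseline. Cheaper than sampling the rendered indicator
#' stack, with the same statistical structure.
#'
#' @param config A `scene_config`.
#' @param truth A `scene_truth`.
#' @return Long data.frame: `cell_id`, `t_min`, `intensity`.
#' @export
generate_traces <- function(config, truth) {
  stopifnot(inherits(config, "scene_config"), inherits(truth, "scene_truth"))
  nt <- as.integer(floor(config$duration / config$frame_interval)) + 1L
  times <- (seq_len(nt) - 1) * config$frame_interval
  cells <- truth$cells
  tr <- truth$transients
  set.seed(config$seed + 3L)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    f <- rep(1, nt)
    mine <- tr[tr$cell_id == cells$cell_id[i], , drop = FALSE]
    for (j in seq_len(nrow(mine))) {
      w <- pmax(0, 1 - abs(times - mine$t_min[j]) / 0.25)
      f <- pmax(f, 1 + (mine$peak_ff0[j] - 1) * w)
    }
    data.frame(cell_id = cells$cell_id[i], t_min = times,
               intensity = 100 * f)
  })
  out <- do.call(rbind, out)
  out$intensity <- out$intensity +
    stats::rnorm(nrow(out), 0, config$noise_sd * 100)
  out$intensity <- pmax(out$intensity, 1)
  rownames(out) <- NULL
  out
}

#' Dose-response generator configuration
#'
#' Defaults encode the density-dependent PGE2 sensitivity setting: two cell
#' densities whose EC50s differ tenfold, a unit Hill slope, and an 8-point
#' log-spaced concentration series spanning both transitions. Absolute EC50
#' values are assumptions (the reproduction surface is their ratio).
#'
#' @param densities cells/cm^2.
#' @param ec50_by_density EC50 in uM for each density.
#' @param hill_slope Dimensionless Hill coefficient.
#' @param r_min,r_max Ratio-unit asymptotes.
#' @param concentrations Strictly increasing uM series.
#' @param noise_sd Gaussian response noise, ratio units.
#' @param n_replicates Replicates per (density, concentration).
#' @param seed Integer RNG seed.
#' @return A validated list of class `dose_response_config`.
#' @export
dose_response_config <- function(densities = c(1.5e4, 2.4e5),
                                 ec50_by_density = c(1.0, 0.1),
                                 hill_slope = 1, r_min = 1, r_max = 2,
                                 concentrations = 10^seq(-3, 1.5, length.out = 8),
                                 noise_sd = 0.02, n_replicates = 3,
                                 seed = 1L) {
  if (length(ec50_by_density) != length(densities))
    stop("one EC50 per density is required")
  if (any(ec50_by_density <= 0)) stop("EC50 must be > 0")
  if (r_max <= r_min) stop("r_max must exceed r_min")
  if (any(diff(concentrations) <= 0))
    stop("`concentrations` must be strictly increasing")
  structure(list(densities = densities, ec50_by_density = ec50_by_density,
                 hill_slope = hill_slope, r_min = r_min, r_max = r_max,
                 concentrations = concentrations, noise_sd = noise_sd,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "dose_response_config")
}

#' Hill dose-response curve
#'
#' `R(C) = r_min + (r_max - r_min) C^h / (EC50^h + C^h)`, evaluated directly
#' (so `C = 0` gives `r_min`).
#'
#' @param conc Concentrations (same units as `ec50`).
#' @param r_min,r_max Asymptotes.
#' @param ec50 Half-maximal concentration (> 0).
#' @param hill Hill coefficient.
#' @return Responses.
#' @export
hill_response <- function(conc, r_min, r_max, ec50, hill = 1) {
  r_min + (r_max - r_min) * conc^hill / (ec50^hill + conc^hill)
}

#' Generate a synthetic titration table
#'
#' @param config A `dose_response_config`.
#' @return data.frame: `density`, `concentration_uM`, `replicate`,
#'   `response`.
#' @export
generate_dose_response <- function(config) {
  stopifnot(inherits(config, "dose_response_config"))
  set.seed(config$seed)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      concentration_uM = config$concentrations,
                      density = config$densities)
  ec50 <- config$ec50_by_density[match(grid$density, config$densities)]
  mu <- hill_response(grid$concentration_uM, config$r_min, config$r_max,
                      ec50, config$hill_slope)
  grid$response <- mu + stats::rnorm(nrow(grid), 0, config$noise_sd)
  grid[, c("density", "concentration_uM", "replicate", "response")]
}

#' Optogenetic stimulation series configuration
#'
#' Defaults emulate the graded-light-dose experiment revealing the
#' switch-like secretion threshold: per-cell firing thresholds drawn
#' uniformly from F/F0 1.5-2.1, calcium peaks rising linearly with light
#' power, and event radii independent of the supra-threshold calcium
#' amplitude.
#'
#' @param n_cells Number of producer cells.
#' @param threshold_range `c(low, high)` per-cell threshold range in F/F0
#'   units (`low > 1`).
#' @param light_powers Strictly increasing stimulus series, uW/mm^2.
#' @param f_gain F/F0 increase per stimulus unit.
#' @param radius_mean,radius_sd Event radius distribution given firing, um.
#' @param noise_sd Gaussian F/F0 measurement noise.
#' @param seed Integer RNG seed.
#' @return A validated list of class `opto_series_config`.
#' @export
opto_series_config <- function(n_cells = 13,
                               threshold_range = c(1.5, 2.1),
                               light_powers = round(exp(seq(log(0.8), log(67),
                                                            length.out = 8)), 2),
                               f_gain = 0.035, radius_mean = 60,
                               radius_sd = 15, noise_sd = 0.03, seed = 1L) {
  if (threshold_range[1] >= threshold_range[2])
    stop("threshold_range low must be below high")
  if (threshold_range[1] <= 1)
    stop("threshold_range low must exceed the F/F0 baseline of 1")
  if (any(diff(light_powers) <= 0))
    stop("`light_powers` must be strictly increasing")
  structure(list(n_cells = n_cells, threshold_range = threshold_range,
                 light_powers = light_powers, f_gain = f_gain,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "opto_series_config")
}

#' Generate a per-cell optogenetic trial table
#'
#' Per cell, a firing threshold is drawn uniformly from `threshold_range`;
#' each flash yields peak F/F0 `1 + f_gain x power + noise`, the cell fires
#' iff the peak reaches its threshold, and the event radius (drawn
#' independently of the calcium amplitude) is recorded when it fires.
#'
#' @param config An `opto_series_config`.
#' @return data.frame: `cell_id`, `light_power`, `peak_ff0`, `fired`,
#'   `radius_um`, `theta_true`.
#' @export
generate_opto_series <- function(config) {
  stopifnot(inherits(config, "opto_series_config"))
  set.seed(config$seed)
  theta <- stats::runif(config$n_cells, config$threshold_range[1],
                        config$threshold_range[2])
  grid <- expand.grid(light_power = config$light_powers,
                      cell_id = seq_len(config$n_cells))
  grid <- grid[, c("cell_id", "light_power")]
  grid$peak_ff0 <- 1 + config$f_gain * grid$light_power +
    stats::rnorm(nrow(grid), 0, config$noise_sd)
  grid$fired <- grid$peak_ff0 >= theta[grid$cell_id]
  grid$radius_um <- ifelse(
    grid$fired,
    pmax(1, stats::rnorm(nrow(grid), config$radius_mean, config$radius_sd)),
    0)
  grid$theta_true <- theta[grid$cell_id]
  grid
}

#' Ground truth for a chemogenetic producer-cell stimulation experiment
#'
#' Emulates the sparse-producer design: a small number of stimulable
#' producer cells scattered on a jittered grid (far enough apart that their
#' events never overlap), each showing exactly one ligand-triggered calcium
#' transient at a random time in `t_range`; each transient discharges an
#' event with `trigger_probability` (default 0.76, the stimulated-mode
#' preset, against 0.1 for spontaneous transients).
#'
#' @param config A `scene_config` (field geometry, event kinetics and the
#'   seed are taken from it).
#' @param n_producers Number of producer cells.
#' @param trigger_probability Probability a transient discharges an event.
#' @param t_range `c(from, to)` window of stimulation-evoked transient
#'   times, min; snapped to the frame grid.
#' @param spacing Minimum producer spacing, um (default 120, beyond twice
#'   the default event reach).
#' @return A `scene_truth` renderable by [render_scene()].
#' @export
generate_dreadd_truth <- function(config, n_producers = 100,
                                  trigger_probability = 0.76,
                                  t_range = c(2, config$duration - 6),
                                  spacing = 120) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed + 4L)
  margin <- spacing / 2
  grid1 <- seq(margin, config$field_size - margin, by = spacing)
  pts <- expand.grid(x = grid1, y = grid1)
  if (nrow(pts) < n_producers)
    stop("field too small for ", n_producers, " producers at ", spacing,
         " um spacing")
  pts <- pts[sample.int(nrow(pts), n_producers), ]
  jit <- spacing / 8
  cells <- data.frame(
    cell_id = seq_len(n_producers),
    x_um = pts$x + stats::runif(n_producers, -jit, jit),
    y_um = pts$y + stats::runif(n_producers, -jit, jit))
  tmin <- stats::runif(n_producers, t_range[1], t_range[2])
  tmin <- round(tmin / config$frame_interval) * config$frame_interval
  tr <- data.frame(cell_id = cells$cell_id, t_min = tmin,
                   peak_ff0 = stats::runif(n_producers, 4.5, 8))
  tr$evokes_rspa <- stats::runif(n_producers) < trigger_probability
  ev <- tr[tr$evokes_rspa, , drop = FALSE]
  nev <- nrow(ev)
  pos <- cells[match(ev$cell_id, cells$cell_id), ]
  radius <- config$peak_radius *
    stats::runif(nev, 1 - config$radius_jitter, 1 + config$radius_jitter)
  events <- data.frame(
    event_id = seq_len(nev), cell_id = ev$cell_id,
    t_onset_min = ev$t_min, x_um = pos$x_um, y_um = pos$y_um,
    speed_um_min = rep(config$expansion_speed, nev),
    peak_radius_um = radius,
    truncated = radius + 5 > pmin(pos$x_um, config$field_size - pos$x_um,
                                  pos$y_um, config$field_size - pos$y_um))
  rownames(events) <- NULL
  structure(list(cells = cells, transients = tr, rspa_events = events),
            class = "scene_truth")
}

#' Generator presets mirroring the study conditions
#'
#' Named presets: `mdck` (confluent MDCK monolayer, densities of the
#' cell-density series), `dreadd` (chemogenetic producer-cell stimulation,
#' trigger probability 0.76), and `invivo` (mouse epidermal basal layer:
#' areal event rate 300 events/cm^2/hr, 6.4 um detection limit, cell density
#' 2e6 cells/cm^2).
#'
#' @return Named list of preset parameter lists.
#' @export
scene_presets <- function() {
  list(
    mdck = list(densities = c(6e4, 1.2e5, 2.4e5), rspa_probability = 0.1,
                expansion_speed = 100, detection_limit = 6.4),
    dreadd = list(rspa_probability = 0.76, detection_limit = 6.4),
    invivo = list(areal_event_rate = 300, cell_density = 2e6,
                  detection_limit = 6.4),
    opto = list(threshold_range = c(1.5, 2.1), detection_limit = 26))
}
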