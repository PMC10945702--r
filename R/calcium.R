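#' Rolling-minimum baseline F0
#'
#' Baseline for F/F0 calcium signals: at each sample, F0 is the minimum
#' intensity over the `window` minutes before that sample (the half-open
#' interval `[t - window, t)`). Before a full window of history exists the
#' minimum is taken over all available preceding samples; the very first
#' sample uses its own intensity (F/F0 = 1 there).
#'
#' @param times Strictly increasing sample times, min.
#' @param intensities Positive intensities, AU.
#' @param window Baseline window, min (default 5).
#' @return Numeric vector F0, same length as `intensities`.
#' @export
rolling_min_f0 <- function(times, intensities, window = 5) {
  n <- length(times)
  if (n < 2L) stop("trace has fewer than 2 samples")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(intensities <= 0)) stop("intensities must be positive")
  f0 <- numeric(n)
  for (i in seq_len(n)) {
    sel <- which(times >= times[i] - window & times < times[i])
    f0[i] <- if (length(sel)) min(intensities[sel]) else intensities[i]
  }
  f0
}

#' Pre-stimulus baseline F0
#'
#' Baseline convention for stimulation experiments (e.g. chemogenetic
#' ligand addition): F0 is the mean intensity over all samples strictly
#' before the stimulus.
#'
#' @param times Sample times, min.
#' @param intensities Intensities, AU.
#' @param stimulus_time Stimulus time, min.
#' @return Scalar F0.
#' @export
prestim_f0 <- function(times, intensities, stimulus_time) {
  pre <- intensities[times < stimulus_time]
  if (length(pre) == 0L)
    stop("no samples precede the stimulus: baseline undefined")
  mean(pre)
}

#' Per-flash baseline and peak F/F0
#'
#' Baseline convention for repeated optogenetic flashes: for each flash, F0
#' is the intensity of the last sample before the flash, and the peak F/F0
#' is the maximum of intensity/F0 between that flash and the next (or the
#' end of the trace).
#'
#' @param times Sample times, min.
#' @param intensities Intensities, AU.
#' @param flash_times Strictly increasing flash times, min.
#' @return data.frame: `flash_time`, `f0`, `peak_ff0`.
#' @export
preflash_f0 <- function(times, intensities, flash_times) {
  if (any(diff(flash_times) <= 0))
    stop("`flash_times` must be strictly increasing")
  bounds <- c(flash_times, Inf)
  out <- lapply(seq_along(flash_times), function(i) {
    ft <- flash_times[i]
    lo <- if (i == 1) -Inf else flash_times[i - 1]
    pre <- which(times < ft & times > lo)
    if (length(pre) == 0L)
      stop("no sample between flash ", i - 1, " and flash ", i)
    f0 <- intensities[max(pre)]
    post <- which(times >= ft & times < bounds[i + 1])
    peak <- if (length(post)) max(intensities[post]) / f0 else NA_real_
    data.frame(flash_time = ft, f0 = f0, peak_ff0 = peak)
  })
  do.call(rbind, out)
}

#' Call calcium transients from indicator traces
#'
#' Computes F/F0 per cell with the rolling-minimum baseline and segments
#' supra-threshold excursions (strictly above `threshold`) into transients.
#' Two excursions of the same cell separated by at most `merge_gap` minutes
#' are one transient; separations longer than `merge_gap` count separately.
#' Simultaneous (time-overlapping) excursions in cells within
#' `merge_distance` of each other are merged into a single transient whose
#' member cells are recorded, mirroring the convention that adjacent cells
#' firing together count once.
#'
#' @param traces Long data.frame: `cell_id`, `t_min`, `intensity`.
#' @param threshold F/F0 calling threshold, strict (default 3; use 4 for the
#'   chemogenetic-stimulation convention).
#' @param positions Optional data.frame `cell_id`, `x_um`, `y_um`; required
#'   for spatial merging.
#' @param merge_distance Adjacency distance in um (default 20, about one
#'   MDCK cell diameter).
#' @param merge_gap Temporal merge gap in min (default 1).
#' @param f0_window Rolling-minimum window in min (default 5).
#' @return data.frame of transients: `transient_id`, `cell_id` (cell with
#'   the highest peak), `t_onset_min`, `t_peak_min`, `peak_ff0`,
#'   `member_cell_ids` (comma-separated), `n_cells`, `warmup` (onset before
#'   one full baseline window).
#' @export
call_transients <- function(traces, threshold = 3, positions = NULL,
                            merge_distance = 20, merge_gap = 1,
                            f0_window = 5) {
  segs <- lapply(split(traces, traces$cell_id), function(g) {
    g <- g[order(g$t_min), , drop = FALSE]
    ff0 <- g$intensity / rolling_min_f0(g$t_min, g$intensity, f0_window)
    above <- ff0 > threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge same-cell excursions separated by <= merge_gap
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1]) {
      gap <- g$t_min[runs$start[i]] - g$t_min[merged$end[nrow(merged)]]
      if (gap <= merge_gap) merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    t0 <- min(g$t_min)
    do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
      idx <- merged$start[i]:merged$end[i]
      pk <- idx[which.max(ff0[idx])]
      data.frame(cell_id = g$cell_id[1],
                 t_onset_min = g$t_min[merged$start[i]],
                 t_end_min = g$t_min[merged$end[i]],
                 t_peak_min = g$t_min[pk], peak_ff0 = ff0[pk],
                 warmup = g$t_min[merged$start[i]] < t0 + f0_window)
    }))
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L)
    return(data.frame(transient_id = integer(), cell_id = integer(),
                      t_onset_min = numeric(), t_peak_min = numeric(),
                      peak_ff0 = numeric(), member_cell_ids = character(),
                      n_cells = integer(), warmup = logical()))
  rownames(segs) <- NULL
  n <- nrow(segs)
  # union-find over spatially adjacent, time-overlapping excursions
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(positions) && n > 1L) {
    px <- positions$x_um[match(segs$cell_id, positions$cell_id)]
    py <- positions$y_um[match(segs$cell_id, positions$cell_id)]
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (segs$cell_id[i] == segs$cell_id[j]) next
      overlap <- segs$t_onset_min[i] <= segs$t_end_min[j] &&
        segs$t_onset_min[j] <= segs$t_end_min[i]
      if (!overlap) next
      dij <- sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)
      if (is.na(dij) || dij > merge_distance) next
      parent[find(i)] <- find(j)
    }
  }
  group <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), group), function(idx) {
    g <- segs[idx, , drop = FALSE]
    lead <- which.max(g$peak_ff0)
    data.frame(cell_id = g$cell_id[lead],
               t_onset_min = min(g$t_onset_min),
               t_peak_min = g$t_peak_min[lead],
               peak_ff0 = g$peak_ff0[lead],
               member_cell_ids = paste(sort(unique(g$cell_id)),
                                       collapse = ","),
               n_cells = length(unique(g$cell_id)),
               warmup = any(g$warmup))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$t_onset_min, out$cell_id), , drop = FALSE]
  out <- cbind(transient_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Calcium transient rate
#'
#' Transients per cell per hour; with `field_area_cm2` also events per cm^2
#' per hour.
#'
#' @param n_transients Transient count (or a transients data.frame).
#' @param n_cells Number of cells observed.
#' @param duration_min Observation duration, min.
#' @param field_area_cm2 Optional field area, cm^2.
#' @return List: `per_cell_hr`, and `per_cm2_hr` when area is given.
#' @export
transient_rate <- function(n_transients, n_cells, duration_min,
                           field_area_cm2 = NULL) {
  if (is.data.frame(n_transients)) n_transients <- nrow(n_transients)
  if (n_cells <= 0 || duration_min <= 0)
    stop("`n_cells` and `duration_min` must be positive")
  hr <- duration_min / 60
  out <- list(per_cell_hr = n_transients / (n_cells * hr))
  if (!is.null(field_area_cm2))
    out$per_cm2_hr <- n_transients / (field_area_cm2 * hr)
  out
}
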