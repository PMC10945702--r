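# Independent oracles used across test files. These deliberately use naive
# algorithms (recursion, brute force) so they share no code with the package.

# brute-force 8-connected labelling by repeated neighbourhood expansion
oracle_label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  repeat {
    todo <- which(mask & lab == 0L)
    if (!length(todo)) break
    cur <- cur + 1L
    lab[todo[1]] <- cur
    repeat {
      grew <- FALSE
      idx <- which(lab == cur)
      for (p in idx) {
        r <- ((p - 1L) %% ny) + 1L; cc <- ((p - 1L) %/% ny) + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; c2 <- cc + dc
          if (rr < 1 || rr > ny || c2 < 1 || c2 > nx) next
          q <- (c2 - 1L) * ny + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; grew <- TRUE }
        }
      }
      if (!grew) break
    }
  }
  lab
}

# textbook Welch statistic (computed from the defining formulas)
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force sliding minimum over [t - w, t)
oracle_rolling_min <- function(times, x, w) {
  sapply(seq_along(times), function(i) {
    sel <- times >= times[i] - w & times < times[i]
    if (any(sel)) min(x[sel]) else x[i]
  })
}

# a normalized ratio_stack with constant frames (for binarize/mask tests)
uniform_stack <- function(value, n = 32, nt = 2, pixel_size = 1,
                          frame_interval = 1) {
  ratio_stack(array(value, dim = c(n, n, nt)), pixel_size, frame_interval,
              provenance = "normalized")
}

# mask stack (logical array + metadata attributes) built from a list of
# logical matrices
as_mask_stack <- function(frames, pixel_size = 1, frame_interval = 1) {
  arr <- array(FALSE, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                              length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  structure(arr, pixel_size = pixel_size, frame_interval = frame_interval,
            class = "mask_stack")
}

# single-component disc mask with a prescribed equivalent radius: the
# `n = round(pi r^2 / ps^2)` pixels nearest the centre
disc_mask <- function(r_um, pixel_size = 0.5, n_px_grid = 200) {
  n_target <- round(pi * r_um^2 / pixel_size^2)
  ctr <- (n_px_grid / 2) * pixel_size
  xs <- (seq_len(n_px_grid) - 1) * pixel_size
  d2 <- outer((xs - ctr)^2, (xs - ctr)^2, `+`)
  m <- matrix(FALSE, n_px_grid, n_px_grid)
  m[order(d2)[seq_len(n_target)]] <- TRUE
  m
}

# one-event ground truth at a given position/onset (bypasses scheduling)
single_event_truth <- function(x, y, onset, radius, speed = 100) {
  structure(list(
    cells = data.frame(cell_id = 1L, x_um = x, y_um = y),
    transients = data.frame(cell_id = 1L, t_min = onset, peak_ff0 = 5,
                            evokes_rspa = TRUE),
    rspa_events = data.frame(event_id = 1L, cell_id = 1L, t_onset_min = onset,
                             x_um = x, y_um = y, speed_um_min = speed,
                             peak_radius_um = radius, truncated = FALSE)),
    class = "scene_truth")
}

empty_truth <- function() {
  structure(list(
    cells = data.frame(cell_id = 1L, x_um = 10, y_um = 10),
    transients = data.frame(cell_id = integer(), t_min = numeric(),
                            peak_ff0 = numeric(), evokes_rspa = logical()),
    rspa_events = data.frame(event_id = integer(), cell_id = integer(),
                             t_onset_min = numeric(), x_um = numeric(),
                             y_um = numeric(), speed_um_min = numeric(),
                             peak_radius_um = numeric(),
                             truncated = logical())),
    class = "scene_truth")
}
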