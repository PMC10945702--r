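#' Compute a ratio stack from two fluorescence channels
#'
#' Forms the per-pixel ratio (numerator - bg) / (denominator - bg) after
#' constant background subtraction, the first step of the RSPA quantification
#' pipeline. Pixels whose denominator falls to or below zero after
#' subtraction are marked invalid (`NA`) rather than propagating infinities.
#'
#' @param numerator,denominator 3-D arrays `[row, col, frame]` of channel
#'   intensities with identical dimensions.
#' @param background Length-2 numeric `c(numerator, denominator)` background
#'   levels (>= 0). If `NULL`, each channel's background is estimated as the
#'   mode of its first frame (histogram mode over 256 bins).
#' @param pixel_size,frame_interval Physical metadata passed to
#'   [ratio_stack()].
#' @return A `ratio_stack` with provenance `"raw"`.
#' @export
compute_ratio_stack <- function(numerator, denominator, background = c(0, 0),
                                pixel_size, frame_interval) {
  if (!identical(dim(numerator), dim(denominator)))
    stop("numerator and denominator stacks differ in shape")
  if (is.null(background))
    background <- c(intensity_mode(numerator[, , 1]),
                    intensity_mode(denominator[, , 1]))
  if (length(background) != 2L || any(background < 0))
    stop("`background` must be two non-negative values c(num, den)")
  num <- numerator - background[1]
  den <- denominator - background[2]
  ratio <- num / den
  ratio[den <= 0] <- NA_real_
  ratio[!is.na(ratio) & ratio <= 0] <- NA_real_
  nt <- dim(ratio)[3]
  for (k in seq_len(nt))
    if (all(is.na(ratio[, , k])))
      stop("frame ", k, " has no valid pixels after background subtraction")
  ratio_stack(ratio, pixel_size, frame_interval, provenance = "raw")
}

intensity_mode <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Denoise a ratio stack
#'
#' Applies, per frame, a 2-D median filter followed by a Gaussian filter, the
#' noise-reduction step preceding normalization and thresholding. A radius or
#' sigma of zero skips the corresponding filter, so
#' `denoise(x, 0, 0)` is the identity.
#'
#' @param stack A `ratio_stack`.
#' @param median_radius Median filter half-width in pixels (integer >= 0).
#' @param gaussian_sigma Gaussian sigma in pixels (>= 0).
#' @return A `ratio_stack` with the same metadata and provenance.
#' @export
denoise <- function(stack, median_radius = 1L, gaussian_sigma = 1) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (median_radius < 0 || gaussian_sigma < 0)
    stop("filter sizes must be non-negative")
  fr <- stack$frames
  nt <- dim(fr)[3]
  for (k in seq_len(nt)) {
    f <- fr[, , k]
    na <- is.na(f)
    if (any(na)) f[na] <- stats::median(f[!na])
    if (median_radius > 0) {
      # EBImage's constant-time median works on [0, 1]; rescale by a power
      # of two above the data range so the transform is exact
      sc <- 2^ceiling(log2(max(f)))
      f <- EBImage::medianFilter(f / sc, as.integer(median_radius)) * sc
    }
    if (gaussian_sigma > 0)
      f <- as.matrix(EBImage::gblur(f, sigma = gaussian_sigma))
    f[na] <- NA_real_
    fr[, , k] <- f
  }
  ratio_stack(fr, stack$pixel_size, stack$frame_interval,
              provenance = stack$provenance)
}

#' Normalize a ratio stack by its minimum intensity projection
#'
#' Divides every pixel's time course by its minimum over time, so each
#' pixel's baseline becomes exactly 1 and transient elevations become
#' fold-changes over baseline. Invalid pixels are excluded from the minimum;
#' a pixel invalid at all times stays invalid. Normalizing an
#' already-normalized stack is the identity.
#'
#' @param stack A `ratio_stack`.
#' @return A `ratio_stack` with provenance `"normalized"`.
#' @export
normalize_min_projection <- function(stack) {
  stopifnot(inherits(stack, "ratio_stack"))
  fr <- stack$frames
  mn <- apply(fr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) min(v) else NA_real_
  })
  out <- sweep(fr, c(1, 2), mn, `/`)
  ratio_stack(out, stack$pixel_size, stack$frame_interval,
              provenance = "normalized")
}

#' Binarize a normalized ratio stack and clean the masks morphologically
#'
#' Thresholds each normalized frame (strictly greater than `threshold`,
#' default 1.3) and refines the foreground by binary opening then closing
#' with disc structuring elements. Invalid pixels are background.
#'
#' @param stack A normalized `ratio_stack`.
#' @param threshold Normalized-ratio threshold; foreground is `value >
#'   threshold` (strict). Default 1.3.
#' @param open_radius,close_radius Structuring disc radii in px (0 skips the
#'   operation). Defaults 1.
#' @return A logical 3-D array of masks with attributes `pixel_size` and
#'   `frame_interval`, class `mask_stack`.
#' @export
binarize_clean <- function(stack, threshold = 1.3, open_radius = 1L,
                           close_radius = 1L) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (stack$provenance != "normalized")
    stop("binarize_clean expects a normalized stack; run normalize_min_projection first")
  fr <- stack$frames
  masks <- !is.na(fr) & fr > threshold
  nt <- dim(fr)[3]
  for (k in seq_len(nt)) {
    m <- masks[, , k] * 1
    if (open_radius > 0)
      m <- EBImage::opening(m, EBImage::makeBrush(2L * as.integer(open_radius) + 1L, "disc"))
    if (close_radius > 0)
      m <- EBImage::closing(m, EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc"))
    masks[, , k] <- as.matrix(m) > 0.5
  }
  structure(masks, pixel_size = stack$pixel_size,
            frame_interval = stack$frame_interval, class = "mask_stack")
}

#' Label 8-connected components of a binary mask
#'
#' Breadth-first labelling with 8-connectivity: pixels touching at a corner
#' belong to the same component.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  fg <- which(mask)
  cur <- 0L
  queue <- integer(length(fg))
  for (p in fg) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    queue[1] <- p; head <- 1L; tail <- 1L
    while (head <= tail) {
      q <- queue[head]; head <- head + 1L
      r <- ((q - 1L) %% ny) + 1L
      cc <- ((q - 1L) %/% ny) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc2 <- cc + dc
        if (rr < 1L || rr > ny || cc2 < 1L || cc2 > nx) next
        qq <- (cc2 - 1L) * ny + rr
        if (mask[qq] && lab[qq] == 0L) {
          lab[qq] <- cur
          tail <- tail + 1L
          if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail] <- qq
        }
      }
    }
  }
  lab
}

#' Extract candidate components from binary masks
#'
#' Finds 8-connected foreground components per frame and summarizes each by
#' its unweighted centroid (um), area (um^2) and fitted equivalent radius
#' `r = sqrt(area / pi)` (um) -- the radius of the circle with the same area.
#' Components touching the field border are flagged.
#'
#' @param masks A `mask_stack` from [binarize_clean()], or a logical 3-D
#'   array (then `pixel_size`/`frame_interval` must be given).
#' @param pixel_size um/px; defaults to the `mask_stack` attribute.
#' @param frame_interval min; defaults to the `mask_stack` attribute.
#' @return data.frame with columns `frame`, `t_min`, `x_um`, `y_um`,
#'   `area_um2`, `r_um`, `n_px`, `edge`.
#' @export
extract_candidates <- function(masks, pixel_size = attr(masks, "pixel_size"),
                               frame_interval = attr(masks, "frame_interval")) {
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("pixel_size and frame_interval are required")
  d <- dim(masks)
  out <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    lab <- label_components(masks[, , k])
    n <- max(lab)
    if (n == 0L) next
    idx <- which(lab > 0L)
    comp <- lab[idx]
    rows <- ((idx - 1L) %% d[1]) + 1L
    cols <- ((idx - 1L) %/% d[1]) + 1L
    npx <- tabulate(comp, n)
    cx <- tapply(cols, comp, mean)
    cy <- tapply(rows, comp, mean)
    edge <- tapply(rows == 1L | rows == d[1] | cols == 1L | cols == d[2],
                   comp, any)
    area <- npx * pixel_size^2
    out[[k]] <- data.frame(
      frame = k, t_min = (k - 1) * frame_interval,
      x_um = as.numeric(cx - 1) * pixel_size,
      y_um = as.numeric(cy - 1) * pixel_size,
      area_um2 = area, r_um = sqrt(area / pi),
      n_px = npx, edge = as.logical(edge))
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), t_min = numeric(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric(), r_um = numeric(),
                      n_px = integer(), edge = logical())
  rownames(out) <- NULL
  out
}

#' Link candidate components across frames into events
#'
#' Greedy nearest-neighbour linking between successive frames: a candidate is
#' linked to an event whose previous-frame component lies within the hard
#' distance gate (default 100 um); links are assigned in order of increasing
#' distance, each event and each candidate at most once per frame pair.
#' Unlinked candidates start new events. No gap closing: an event not matched
#' in the next frame is terminated.
#'
#' @param candidates data.frame from [extract_candidates()].
#' @param max_distance Linking gate in um (default 100).
#' @return Object of class `rspa_events`: list with `components` (the input
#'   plus `event_id`) and `events` (one row per event: `event_id`,
#'   `t_onset_min`, `x_um`, `y_um` centroid at first frame, `peak_radius_um`,
#'   `n_frames`, `edge_flag`).
#' @export
link_events <- function(candidates, max_distance = 100) {
  cand <- candidates[order(candidates$frame), , drop = FALSE]
  n <- nrow(cand)
  event_id <- integer(n)
  next_id <- 0L
  frames <- sort(unique(cand$frame))
  prev_idx <- integer(0)
  prev_frame <- -1L
  for (f in frames) {
    cur_idx <- which(cand$frame == f)
    if (f == prev_frame + 1L && length(prev_idx)) {
      dx <- outer(cand$x_um[prev_idx], cand$x_um[cur_idx], `-`)
      dy <- outer(cand$y_um[prev_idx], cand$y_um[cur_idx], `-`)
      dist <- sqrt(dx^2 + dy^2)
      dist[dist >= max_distance] <- NA_real_
      while (any(!is.na(dist))) {
        k <- arrayInd(which.min(dist), dim(dist))
        i <- k[1]; j <- k[2]
        event_id[cur_idx[j]] <- event_id[prev_idx[i]]
        dist[i, ] <- NA_real_
        dist[, j] <- NA_real_
      }
    }
    for (j in cur_idx) if (event_id[j] == 0L) {
      next_id <- next_id + 1L
      event_id[j] <- next_id
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  cand$event_id <- event_id
  ev <- lapply(split(cand, cand$event_id), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    data.frame(event_id = g$event_id[1], t_onset_min = g$t_min[1],
               x_um = g$x_um[1], y_um = g$y_um[1],
               peak_radius_um = max(g$r_um), n_frames = nrow(g),
               edge_flag = any(g$edge))
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(event_id = integer(), t_onset_min = numeric(),
                     x_um = numeric(), y_um = numeric(),
                     peak_radius_um = numeric(), n_frames = integer(),
                     edge_flag = logical())
  ev <- ev[order(ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(components = cand, events = ev), class = "rspa_events")
}

#' Call events positive by the fitted-radius criterion
#'
#' An event is counted as RSPA when its fitted equivalent radius exceeds
#' `min_radius` (strictly greater than, default 15 um) in at least one frame
#' of its lifetime.
#'
#' @param events An `rspa_events` object from [link_events()].
#' @param min_radius Positive-call radius in um (default 15).
#' @return The `rspa_events` object with a logical `is_positive` column added
#'   to `$events`.
#' @export
call_positive <- function(events, min_radius = 15) {
  stopifnot(inherits(events, "rspa_events"))
  events$events$is_positive <- events$events$peak_radius_um > min_radius
  events$min_radius <- min_radius
  events
}

#' @export
print.rspa_events <- function(x, ...) {
  np <- if (!is.null(x$events$is_positive)) sum(x$events$is_positive) else NA
  cat(sprintf("rspa_events: %d linked events (%s positive), %d components\n",
              nrow(x$events), ifelse(is.na(np), "uncalled", np),
              nrow(x$components)))
  invisible(x)
}

#' Concentric-ROI radius time course of an event
#'
#' Measures the event radius per frame from concentric annuli centred on the
#' event: the radius is the outer radius of the outermost annulus in the
#' contiguous run (from the centre outward) whose median normalized ratio
#' exceeds `threshold`; 0 if the innermost region already fails. The
#' innermost annulus radius is the detection limit of the measurement.
#'
#' @param stack A normalized `ratio_stack`.
#' @param center `c(x, y)` in um.
#' @param ring_radii Strictly increasing outer annulus radii in um; default
#'   annuli of width 6.4 um out to 96 um. `ring_width`/`max_radius` build the
#'   default sequence.
#' @param threshold Median-ratio threshold (strict), default 1.3.
#' @param onset_frame Frame index taken as time 0 of the course (default 1).
#' @param ring_width,max_radius Used only when `ring_radii` is `NULL`.
#' @return List of class `radius_time_course`: `times` (min, relative to
#'   onset), `radii` (um), `detection_limit` (um), `truncated` (TRUE if the
#'   outermost ring extends beyond the field).
#' @export
radius_time_course <- function(stack, center, ring_radii = NULL,
                               threshold = 1.3, onset_frame = 1L,
                               ring_width = 6.4, max_radius = 96) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (is.null(ring_radii))
    ring_radii <- seq(ring_width, max_radius, by = ring_width)
  if (any(diff(ring_radii) <= 0) || any(ring_radii <= 0))
    stop("`ring_radii` must be positive and strictly increasing")
  d <- dim(stack$frames)
  fx <- (d[2] - 1) * stack$pixel_size
  fy <- (d[1] - 1) * stack$pixel_size
  if (center[1] < 0 || center[1] > fx || center[2] < 0 || center[2] > fy)
    stop("`center` lies outside the field")
  dist2 <- pixel_dist2(d[1], d[2], stack$pixel_size, center)
  inner <- c(0, ring_radii[-length(ring_radii)])
  ring_of <- lapply(seq_along(ring_radii), function(i)
    which(dist2 > inner[i]^2 & dist2 <= ring_radii[i]^2))
  truncated <- min(center[1], fx - center[1], center[2], fy - center[2]) <
    ring_radii[length(ring_radii)]
  nt <- d[3]
  radii <- numeric(nt)
  for (k in seq_len(nt)) {
    f <- stack$frames[, , k]
    r <- 0
    for (i in seq_along(ring_radii)) {
      med <- stats::median(f[ring_of[[i]]], na.rm = TRUE)
      if (is.na(med) || med <= threshold) break
      r <- ring_radii[i]
    }
    radii[k] <- r
  }
  structure(list(times = (seq_len(nt) - onset_frame) * stack$frame_interval,
                 radii = radii, detection_limit = ring_radii[1],
                 truncated = truncated),
            class = "radius_time_course")
}

#' Estimate the radial expansion speed of an event
#'
#' Least-squares slope of radius versus time over the event's growth phase:
#' from the frame preceding the first nonzero radius (the onset zero, when
#' present) through the first frame attaining the peak radius. A course with
#' no growth (constant nonzero radius) yields 0.
#'
#' @param course A `radius_time_course`.
#' @return Expansion speed in um/min.
#' @export
estimate_expansion_speed <- function(course) {
  stopifnot(inherits(course, "radius_time_course"))
  nz <- which(course$radii > 0)
  if (length(nz) < 2L)
    stop("expansion speed is undefined: fewer than 2 nonzero radii")
  i1 <- nz[1]
  i0 <- max(1L, i1 - 1L)
  ipk <- which.max(course$radii)
  idx <- if (ipk > i0) i0:ipk else nz
  fit <- stats::lm.fit(cbind(1, course$times[idx]), course$radii[idx])
  unname(fit$coefficients[2])
}

#' Detect RSPA events in a two-channel stack
#'
#' Convenience wrapper running the full detection chain: ratio computation,
#' denoising, minimum-projection normalization, thresholding with
#' morphological cleanup, component extraction, linking, and the positive
#' call.
#'
#' @param numerator,denominator 3-D channel arrays.
#' @param pixel_size,frame_interval Physical metadata.
#' @param background Per-channel background, see [compute_ratio_stack()].
#' @param threshold Binarization threshold (default 1.3).
#' @param min_radius Positive-call radius in um (default 15).
#' @param median_radius,gaussian_sigma Denoising parameters.
#' @param open_radius,close_radius Morphology disc radii in px.
#' @param max_distance Linking gate in um (default 100).
#' @return List: `events` (called `rspa_events`), `normalized` (the
#'   normalized `ratio_stack`).
#' @export
detect_rspa <- function(numerator, denominator, pixel_size, frame_interval,
                        background = c(0, 0), threshold = 1.3,
                        min_radius = 15, median_radius = 1L,
                        gaussian_sigma = 1, open_radius = 1L,
                        close_radius = 1L, max_distance = 100) {
  rs <- compute_ratio_stack(numerator, denominator, background,
                            pixel_size, frame_interval)
  rs <- denoise(rs, median_radius, gaussian_sigma)
  rs <- normalize_min_projection(rs)
  masks <- binarize_clean(rs, threshold, open_radius, close_radius)
  cand <- extract_candidates(masks)
  ev <- call_positive(link_events(cand, max_distance), min_radius)
  list(events = ev, normalized = rs)
}
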