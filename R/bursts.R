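#' Burst detection parameters
#'
#' @param k_sigma Threshold multiplier on the noise-trace standard deviation
#'   (default 1.96): a rising edge is a burst when its base-to-peak change
#'   exceeds `k_sigma * SD(noise trace)`.
#' @param min_separation_s Events whose bases fall closer than this (s) are
#'   merged keeping the larger amplitude; suppresses double-counting of
#'   noisy edges within one calcium transient. `0` disables merging.
#' @param base_frac Onset refinement tolerance: the base frame is the last
#'   frame before the peak whose value is within `base_frac` of the segment
#'   amplitude above the segment minimum. Keeps the reported onset at the
#'   foot of the steep rise instead of wherever baseline noise last dipped.
#' @param edge_guard_s Events whose rising edge falls within this many
#'   seconds of the start or end of the record are discarded (default 0.5 s,
#'   half the default smoothing window): a centered running mean shrinks at
#'   the record edges, so those frames are under-smoothed and their residual
#'   noise produces spurious threshold crossings. `0` disables the guard.
#' @return A list of class `"detection_params"`.
#' @export
detection_params <- function(k_sigma = 1.96, min_separation_s = 0.5,
                             base_frac = 0.05, edge_guard_s = 0.5) {
  stop_if_not_scalar_pos(k_sigma, "k_sigma")
  stop_if_not_scalar_pos(min_separation_s, "min_separation_s", strict = FALSE)
  if (base_frac < 0 || base_frac >= 1) {
    stop("`base_frac` must be in [0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_pos(edge_guard_s, "edge_guard_s", strict = FALSE)
  structure(list(k_sigma = k_sigma, min_separation_s = min_separation_s,
                 base_frac = base_frac, edge_guard_s = edge_guard_s),
            class = "detection_params")
}

# local extrema of a trace by first-difference sign change; plateaus are
# broken at their first frame by carrying the *next* nonzero sign backwards.
# Frame 1 counts as a minimum when the trace initially rises, but the last
# frame never counts as a maximum: a rising edge must terminate at an
# observed turnaround, otherwise its base-to-peak amplitude is undefined
# (and an endpoint "peak" would let half an excursion — any upward drift
# into the record end — pass the threshold).
local_extrema <- function(x) {
  n <- length(x)
  s <- sign(diff(x))
  nz <- s != 0
  if (!any(nz)) return(list(minima = integer(0), maxima = integer(0)))
  # carry-back fill of zero runs with the next nonzero sign; a trailing flat
  # run after a rise ends the rise (treated as a fall starting there)
  filled <- rev(cummax_sign(rev(s)))
  minima <- integer(0)
  maxima <- integer(0)
  if (filled[1] > 0) minima <- 1L
  for (t in seq_len(max(n - 2L, 0L)) + 1L) {
    if (filled[t - 1] < 0 && filled[t] > 0) minima <- c(minima, t)
    if (filled[t - 1] > 0 && filled[t] < 0) maxima <- c(maxima, t)
  }
  list(minima = minima, maxima = maxima)
}

# helper for local_extrema: propagate the last seen nonzero value forward,
# with zeros before any nonzero becoming -1 (flat tail = end of any rise)
cummax_sign <- function(s) {
  last <- -1
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  s
}

#' Detect bursts on one ROI's signal trace
#'
#' Identifies rising edges (local minimum to next local maximum segments) of
#' the signal trace and keeps those whose base-to-peak amplitude exceeds
#' `k_sigma` times the standard deviation of the same ROI's noise trace.
#' The base frame is refined to the foot of the rise (see
#' [detection_params()]); events with bases closer than `min_separation_s`
#' are merged, keeping the larger amplitude.
#'
#' @param signal_trace,noise_trace Numeric vectors of equal length: the
#'   signal and noise versions of one ROI (typically rows of a
#'   [pca_split()]).
#' @param fps Frames per second.
#' @param params A [detection_params()].
#' @param roi_id Optional integer stored in the output.
#' @return A data frame with one row per burst: `roi_id`, `base_frame`,
#'   `peak_frame`, `base_value`, `peak_value`, `amplitude`
#'   (`peak_value - base_value`), and `position_s` (`(base_frame - 1)/fps`;
#'   frame 1 is time 0). Ordered by `base_frame`.
#' @export
detect_bursts <- function(signal_trace, noise_trace, fps,
                          params = detection_params(), roi_id = NA_integer_) {
  x <- as.numeric(signal_trace)
  n <- length(x)
  if (length(noise_trace) != n) {
    stop("signal and noise traces must have equal length", call. = FALSE)
  }
  stop_if_not_scalar_pos(fps, "fps")
  empty <- data.frame(roi_id = integer(0), base_frame = integer(0),
                      peak_frame = integer(0), base_value = numeric(0),
                      peak_value = numeric(0), amplitude = numeric(0),
                      position_s = numeric(0))
  sd_noise <- stats::sd(noise_trace)
  if (!is.finite(sd_noise) || sd_noise <= 0) {
    warning("noise trace has zero variance; using an epsilon-scale threshold",
            call. = FALSE)
    sd_noise <- max(diff(range(x)), 1) * .Machine$double.eps
  }
  thr <- params$k_sigma * sd_noise
  ex <- local_extrema(x)
  if (length(ex$maxima) == 0L) return(empty)
  ev <- vector("list", length(ex$maxima))
  for (i in seq_along(ex$maxima)) {
    p <- ex$maxima[i]
    prior <- ex$minima[ex$minima < p]
    if (length(prior) == 0L) next
    m <- prior[length(prior)]
    seg_amp <- x[p] - x[m]
    if (seg_amp <= 0) next
    tol <- x[m] + params$base_frac * seg_amp
    below <- which(x[m:p] <= tol)
    b <- m + below[length(below)] - 1L
    if (b >= p) b <- m
    amp <- x[p] - x[b]
    if (amp > thr) {
      ev[[i]] <- c(b, p, x[b], x[p], amp)
    }
  }
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (length(ev) == 0L) return(empty)
  em <- do.call(rbind, ev)
  em <- em[order(em[, 1]), , drop = FALSE]
  if (params$edge_guard_s > 0) {
    # the whole rising edge must lie in the fully smoothed interior
    guard <- params$edge_guard_s * fps
    em <- em[em[, 1] > guard & em[, 2] <= n - guard, , drop = FALSE]
    if (nrow(em) == 0L) return(empty)
  }
  # merge events with bases closer than min_separation_s (keep larger amplitude)
  if (params$min_separation_s > 0 && nrow(em) > 1L) {
    gap <- params$min_separation_s * fps
    keep <- em[1, , drop = FALSE]
    for (i in 2:nrow(em)) {
      last <- nrow(keep)
      if (em[i, 1] - keep[last, 1] < gap) {
        if (em[i, 5] > keep[last, 5]) keep[last, ] <- em[i, ]
      } else {
        keep <- rbind(keep, em[i, , drop = FALSE])
      }
    }
    em <- keep
  }
  data.frame(roi_id = roi_id, base_frame = as.integer(em[, 1]),
             peak_frame = as.integer(em[, 2]), base_value = em[, 3],
             peak_value = em[, 4], amplitude = em[, 5],
             position_s = (em[, 1] - 1) / fps)
}

#' Detect bursts on every ROI of a signal/noise split
#'
#' @param split A [pca_split()] result.
#' @param fps Frames per second (defaults to the split's own).
#' @param params A [detection_params()].
#' @return A single data frame of events (see [detect_bursts()]) with
#'   `roi_id` filled in.
#' @export
detect_bursts_all <- function(split, fps = split$fps,
                              params = detection_params()) {
  stopifnot(inherits(split, "signal_noise_split"))
  out <- lapply(seq_len(nrow(split$signal)), function(r) {
    detect_bursts(split$signal[r, ], split$noise[r, ], fps, params, roi_id = r)
  })
  do.call(rbind, out)
}

empty_catalog <- function(n_rois, window_s, min_support = NA_real_) {
  structure(list(
    entries = data.frame(catalog_id = integer(0), time_s = numeric(0),
                         support_count = integer(0),
                         support_fraction = numeric(0),
                         amplitude_mean = numeric(0)),
    assignments = data.frame(roi_id = integer(0), catalog_id = integer(0),
                             position_s = numeric(0), amplitude = numeric(0)),
    sequences = rep(list(integer(0)), n_rois),
    n_rois = as.integer(n_rois), window_s = window_s,
    min_support = min_support
  ), class = "burst_catalog")
}

#' Catalog distinct network burst positions
#'
#' Pools the burst events of all ROIs and greedily clusters them into
#' distinct network-wide burst positions: the earliest unassigned event
#' seeds a new catalog entry, every unassigned event within `window_s`
#' seconds of the seed joins it (at most one per ROI — the nearest wins,
#' the earlier on ties), the entry's representative time is the mean of its
#' members, and the process repeats. Each ROI is then re-described as the
#' ordered sequence of catalog entries it participated in.
#'
#' @param events Event data frame from [detect_bursts_all()] (needs
#'   `roi_id`, `position_s`, and `amplitude` columns).
#' @param n_rois Total number of ROIs (for support fractions).
#' @param window_s Half-width of the catalog window in seconds (default 1:
#'   events within +/- 1 s of a seed are the same network burst).
#' @return An object of class `"burst_catalog"` with `entries`
#'   (`catalog_id`, `time_s`, `support_count`, `support_fraction`,
#'   `amplitude_mean`), per-event `assignments`, and per-ROI `sequences`
#'   (list of catalog id vectors in time order). `min_support` is `NA`
#'   until [filter_catalog()] is applied.
#' @export
catalog_bursts <- function(events, n_rois, window_s = 1) {
  stop_if_not_scalar_pos(n_rois, "n_rois")
  stop_if_not_scalar_pos(window_s, "window_s")
  if (is.null(events) || nrow(events) == 0L) {
    return(empty_catalog(n_rois, window_s))
  }
  ord <- order(events$position_s, events$roi_id)
  pos <- events$position_s[ord]
  roi <- events$roi_id[ord]
  amp <- events$amplitude[ord]
  n <- length(pos)
  entry_of <- integer(n)
  next_unassigned <- 1L
  entry_times <- numeric(0)
  k <- 0L
  while (next_unassigned <= n) {
    seed_pos <- pos[next_unassigned]
    cand <- which(entry_of == 0L & pos <= seed_pos + window_s &
                    pos >= seed_pos - window_s)
    k <- k + 1L
    for (r in unique(roi[cand])) {
      rc <- cand[roi[cand] == r]
      pick <- rc[which.min(abs(pos[rc] - seed_pos))] # ties: earlier (sorted)
      entry_of[pick] <- k
    }
    entry_times[k] <- mean(pos[entry_of == k])
    while (next_unassigned <= n && entry_of[next_unassigned] != 0L) {
      next_unassigned <- next_unassigned + 1L
    }
  }
  # relabel entries in representative-time order (ties: seed order)
  perm <- order(entry_times, seq_len(k))
  relabel <- integer(k)
  relabel[perm] <- seq_len(k)
  entry_of <- relabel[entry_of]
  entry_times <- entry_times[perm]
  assignments <- data.frame(roi_id = roi, catalog_id = entry_of,
                            position_s = pos, amplitude = amp)
  support <- tabulate(entry_of, nbins = k)
  amp_mean <- vapply(seq_len(k), function(i) mean(amp[entry_of == i]),
                     numeric(1))
  entries <- data.frame(catalog_id = seq_len(k), time_s = entry_times,
                        support_count = support,
                        support_fraction = support / n_rois,
                        amplitude_mean = amp_mean)
  sequences <- lapply(seq_len(n_rois), function(r) {
    sel <- roi == r
    entry_of[sel][order(pos[sel])]
  })
  structure(list(entries = entries, assignments = assignments,
                 sequences = sequences, n_rois = as.integer(n_rois),
                 window_s = window_s, min_support = NA_real_),
            class = "burst_catalog")
}

#' @export
print.burst_catalog <- function(x, ...) {
  cat(sprintf("<burst_catalog> %d entries over %d ROIs (window +/- %g s%s)\n",
              nrow(x$entries), x$n_rois, x$window_s,
              if (is.na(x$min_support)) "" else
                sprintf(", min support %g", x$min_support)))
  invisible(x)
}

#' Filter a burst catalog by ROI support
#'
#' Removes catalog entries supported by strictly less than `min_support` of
#' the ROIs (default 4%), renumbers the survivors in time order, and
#' rebuilds the per-ROI sequences. Applying the same filter twice changes
#' nothing.
#'
#' @param catalog A [catalog_bursts()] result.
#' @param min_support Minimum support fraction (default 0.04).
#' @param n_rois ROI count used for the fractions (defaults to the
#'   catalog's).
#' @return The filtered `"burst_catalog"`.
#' @export
filter_catalog <- function(catalog, min_support = 0.04,
                           n_rois = catalog$n_rois) {
  stopifnot(inherits(catalog, "burst_catalog"))
  if (min_support < 0 || min_support > 1) {
    stop("`min_support` must be in [0, 1]", call. = FALSE)
  }
  ent <- catalog$entries
  frac <- ent$support_count / n_rois
  keep <- which(frac >= min_support)
  if (length(keep) == 0L && nrow(ent) > 0L) {
    warning("all catalog entries fall below the support threshold",
            call. = FALSE)
  }
  relabel <- integer(nrow(ent))
  relabel[keep] <- seq_along(keep)
  entries <- ent[keep, , drop = FALSE]
  entries$catalog_id <- seq_along(keep)
  entries$support_fraction <- entries$support_count / n_rois
  rownames(entries) <- NULL
  asg <- catalog$assignments
  asg <- asg[asg$catalog_id %in% keep, , drop = FALSE]
  asg$catalog_id <- relabel[asg$catalog_id]
  rownames(asg) <- NULL
  sequences <- lapply(seq_len(catalog$n_rois), function(r) {
    sel <- asg$roi_id == r
    asg$catalog_id[sel][order(asg$position_s[sel])]
  })
  structure(list(entries = entries, assignments = asg, sequences = sequences,
                 n_rois = catalog$n_rois, window_s = catalog$window_s,
                 min_support = min_support),
            class = "burst_catalog")
}

#' Network-level burst train from a catalog
#'
#' Treats the catalog's representative times as the network's burst train,
#' with each entry's amplitude the mean amplitude of its supporting events.
#'
#' @param catalog A (typically filtered) `"burst_catalog"`.
#' @param duration Recording length (s).
#' @return A [burst_train()].
#' @export
network_burst_train <- function(catalog, duration) {
  stopifnot(inherits(catalog, "burst_catalog"))
  burst_train(catalog$entries$time_s, catalog$entries$amplitude_mean, duration)
}
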