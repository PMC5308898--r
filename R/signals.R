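#' Movie stack container
#'
#' A thin container for a grayscale movie: a `time x height x width` integer
#' intensity array on the 8-bit scale together with the frame rate.
#'
#' @param frames Numeric or integer 3-D array, `time x height x width`,
#'   values in `[0, 255]`.
#' @param fps Frames per second.
#' @return An object of class `"movie_stack"`.
#' @export
movie_stack <- function(frames, fps = 20) {
  if (length(dim(frames)) != 3L) {
    stop("`frames` must be a time x height x width array", call. = FALSE)
  }
  if (dim(frames)[1] < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  stop_if_not_scalar_pos(fps, "fps")
  structure(list(frames = frames, fps = fps), class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d frames of %dx%d px at %g fps (%.1f s)\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps))
  invisible(x)
}

# 1-D resampling weight matrix (n_out x n_in).
# Downscaling: exact area overlap of output cells with input cells, so a
# constant image stays constant and total intensity is conserved.
# Upscaling: linear interpolation between input pixel centers, clamped at
# the borders.
resample_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  W <- matrix(0, n_out, n_in)
  if (n_out < n_in) {
    r <- n_in / n_out
    for (j in seq_len(n_out)) {
      a <- (j - 1) * r
      b <- j * r
      i_lo <- floor(a + 1e-12) + 1L
      i_hi <- min(ceiling(b - 1e-12), n_in)
      for (i in i_lo:i_hi) {
        W[j, i] <- (min(b, i) - max(a, i - 1)) / r
      }
    }
  } else {
    for (j in seq_len(n_out)) {
      pos <- (j - 0.5) * n_in / n_out + 0.5 # in input pixel-center coordinates
      i0 <- floor(pos)
      frac <- pos - i0
      i0c <- min(max(i0, 1L), n_in)
      i1c <- min(max(i0 + 1L, 1L), n_in)
      W[j, i0c] <- W[j, i0c] + (1 - frac)
      W[j, i1c] <- W[j, i1c] + frac
    }
  }
  W
}

resize_frame <- function(x, new_h, new_w) {
  resample_weights(nrow(x), new_h) %*% x %*% t(resample_weights(ncol(x), new_w))
}

#' Load a multi-page TIFF stack
#'
#' Reads a multi-page 8-bit grayscale TIFF and resizes each frame to
#' `target_size x target_size`. Downscaling uses area-mean pooling
#' (intensity-conserving); upscaling uses bilinear interpolation.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param fps Frame rate to attach (not stored in the TIFF), default 20.
#' @param target_size Output frame side in pixels (default 128); `NULL`
#'   keeps the native size.
#' @return A [movie_stack()].
#' @export
load_stack <- function(path, fps = 20, target_size = 128) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    stop("stack has a single frame; a movie needs at least 2", call. = FALSE)
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop("stack is not grayscale; convert to single-channel before loading",
         call. = FALSE)
  }
  # readTIFF(as.is = TRUE) returns raw integer samples for 8-bit input but
  # [0,1] doubles for some encodings; normalize to the 0..255 scale
  to255 <- function(p) {
    if (is.double(p) && max(p) <= 1) p * 255 else p
  }
  pages <- lapply(pages, to255)
  if (!is.null(target_size)) {
    pages <- lapply(pages, function(p) {
      if (nrow(p) == target_size && ncol(p) == target_size) p
      else resize_frame(p, target_size, target_size)
    })
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  movie_stack(frames, fps)
}

#' Boolean oval ROI footprint
#'
#' Pixels inside the ellipse inscribed in the `size x size` square (the
#' center pixel is always included).
#'
#' @param size Side of the ROI square in pixels.
#' @return `size x size` logical matrix.
#' @export
oval_mask <- function(size) {
  c0 <- (size + 1) / 2
  r <- size / 2
  i <- matrix(seq_len(size), size, size)
  j <- t(i)
  ((i - c0) / r)^2 + ((j - c0) / r)^2 <= 1
}

#' Tile a frame with a lattice of oval ROIs
#'
#' Places `roi_size x roi_size` oval ROIs on a regular lattice with the
#' given center-to-center spacing, starting at the frame's top-left corner
#' and keeping every placement whose square footprint fits inside the frame.
#' A spacing smaller than `roi_size` (the default 9 px spacing for 11 px
#' ROIs) gives slight overlap between neighbours. A 128 x 128 frame yields
#' 196 ROIs (a 14 x 14 lattice).
#'
#' @param height,width Frame size in pixels.
#' @param roi_size ROI side in pixels (default 11).
#' @param spacing Lattice spacing in pixels (default 9).
#' @return An object of class `"roi_grid"`: `centers` data frame
#'   (`roi_id`, `top`, `left`, `row`, `col` of the center), the oval
#'   `footprint` mask, and the geometry parameters.
#' @export
tile_rois <- function(height, width, roi_size = 11, spacing = 9) {
  stop_if_not_scalar_pos(roi_size, "roi_size")
  if (spacing < 1) stop("`spacing` must be >= 1", call. = FALSE)
  if (roi_size > height || roi_size > width) {
    stop("`roi_size` exceeds the frame", call. = FALSE)
  }
  tops <- seq(1L, height - roi_size + 1L, by = spacing)
  lefts <- seq(1L, width - roi_size + 1L, by = spacing)
  centers <- expand.grid(top = tops, left = lefts, KEEP.OUT.ATTRS = FALSE)
  # column-major order: ROIs run down each lattice column, then across
  centers <- centers[order(centers$left, centers$top), , drop = FALSE]
  centers$roi_id <- seq_len(nrow(centers))
  half <- (roi_size - 1) / 2
  centers$row <- centers$top + half
  centers$col <- centers$left + half
  rownames(centers) <- NULL
  structure(list(
    centers = centers[, c("roi_id", "top", "left", "row", "col")],
    footprint = oval_mask(roi_size),
    roi_size = as.integer(roi_size), spacing = as.integer(spacing),
    height = as.integer(height), width = as.integer(width)
  ), class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("<roi_grid> %d ROIs (%dx%d px oval, %d px spacing) on %dx%d frame\n",
              nrow(x$centers), x$roi_size, x$roi_size, x$spacing,
              x$height, x$width))
  invisible(x)
}

#' ROI x time trace matrix
#'
#' @param values Numeric `ROI x time` matrix.
#' @param fps Frames per second.
#' @param stage One of `"raw"`, `"smoothed"`, `"dff"`.
#' @param grid The [tile_rois()] grid the rows refer to (optional).
#' @return An object of class `"trace_matrix"`.
#' @export
trace_matrix <- function(values, fps, stage = c("raw", "smoothed", "dff"),
                         grid = NULL) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values))
  stop_if_not_scalar_pos(fps, "fps")
  if (!is.null(grid) && nrow(values) != nrow(grid$centers)) {
    stop("row count must equal the grid's ROI count", call. = FALSE)
  }
  structure(list(values = values, fps = fps, stage = stage, grid = grid),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROIs x %d frames at %g fps, stage = %s\n",
              nrow(x$values), ncol(x$values), x$fps, x$stage))
  invisible(x)
}

#' Extract mean-intensity ROI traces from a movie
#'
#' Each trace is the mean intensity over the ROI's oval footprint at every
#' frame.
#'
#' @param movie A [movie_stack()].
#' @param grid A [tile_rois()] grid that fits the movie.
#' @return A `"trace_matrix"` at stage `"raw"`.
#' @export
extract_traces <- function(movie, grid) {
  stopifnot(inherits(movie, "movie_stack"), inherits(grid, "roi_grid"))
  d <- dim(movie$frames)
  if (grid$height != d[2] || grid$width != d[3]) {
    stop("grid geometry does not match the movie", call. = FALSE)
  }
  n_px <- d[2] * d[3]
  n_roi <- nrow(grid$centers)
  fp <- grid$footprint
  n_fp <- sum(fp)
  W <- matrix(0, n_px, n_roi)
  s <- grid$roi_size
  for (r in seq_len(n_roi)) {
    top <- grid$centers$top[r]
    left <- grid$centers$left[r]
    rows <- top:(top + s - 1L)
    cols <- left:(left + s - 1L)
    idx <- outer(rows, (cols - 1L) * d[2], "+")[fp]
    W[idx, r] <- 1 / n_fp
  }
  M <- movie$frames
  dim(M) <- c(d[1], n_px)
  trace_matrix(t(M %*% W), movie$fps, "raw", grid)
}

#' Running-mean smoothing of traces
#'
#' Centered running mean over `round(window_s * fps)` frames, forced to the
#' nearest odd count so the window is symmetric. At the trace edges the
#' window shrinks symmetrically (no values are invented beyond the record).
#'
#' @param traces A raw `"trace_matrix"`.
#' @param window_s Window width in seconds (default 1).
#' @return A `"trace_matrix"` at stage `"smoothed"`.
#' @export
smooth_traces <- function(traces, window_s = 1) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (traces$stage != "raw") stop("expected a raw trace matrix", call. = FALSE)
  w <- round(window_s * traces$fps)
  if (w < 1) stop("window shorter than one frame", call. = FALSE)
  if (w %% 2 == 0) w <- w + 1L
  nt <- ncol(traces$values)
  if (w > nt) stop("smoothing window longer than the trace", call. = FALSE)
  half <- (w - 1L) / 2L
  cs <- cbind(0, t(apply(traces$values, 1L, cumsum)))
  out <- matrix(0, nrow(traces$values), nt)
  for (t in seq_len(nt)) {
    hh <- min(half, t - 1L, nt - t)
    out[, t] <- (cs[, t + hh + 1L] - cs[, t - hh]) / (2L * hh + 1L)
  }
  trace_matrix(out, traces$fps, "smoothed", traces$grid)
}

#' Delta-F/F transform
#'
#' Per ROI, `dF/F(t) = (F(t) - F0) / F0` with `F0` the trace's
#' `baseline_percentile` percentile — a baseline estimate robust to bursts
#' occupying a minority of frames.
#'
#' @param traces A smoothed `"trace_matrix"`.
#' @param baseline_percentile Percentile (0-100) defining `F0` (default 10).
#' @return A `"trace_matrix"` at stage `"dff"` (dimensionless).
#' @export
dff <- function(traces, baseline_percentile = 10) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (traces$stage != "smoothed") {
    stop("expected a smoothed trace matrix", call. = FALSE)
  }
  if (baseline_percentile < 0 || baseline_percentile > 100) {
    stop("`baseline_percentile` must be in [0, 100]", call. = FALSE)
  }
  f0 <- apply(traces$values, 1L, stats::quantile,
              probs = baseline_percentile / 100, names = FALSE)
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive baseline F0 for ROI(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  trace_matrix((traces$values - f0) / f0, traces$fps, "dff", traces$grid)
}

#' Scree-plot elbow index
#'
#' Finds the elbow of a descending eigenvalue spectrum as the point with
#' maximum perpendicular distance from the straight line joining the first
#' and last eigenvalues (both axes normalized to `[0, 1]` first).
#'
#' @param eigenvalues Descending numeric vector.
#' @return Integer elbow index.
#' @export
scree_elbow <- function(eigenvalues) {
  m <- length(eigenvalues)
  if (m < 3L) return(1L)
  x <- (seq_len(m) - 1) / (m - 1)
  span <- eigenvalues[1] - eigenvalues[m]
  if (span <= 0) return(1L)
  y <- (eigenvalues - eigenvalues[m]) / span
  # distance from (x, y) to the line through (0, 1) and (1, 0)
  d <- abs(-x - y + 1) / sqrt(2)
  which.max(d)
}

#' PCA signal/noise separation of a trace matrix
#'
#' Treats ROIs as observations (each ROI trace is mean-centered over time),
#' decomposes the centered matrix by singular values, locates the scree-plot
#' elbow of the eigenvalue spectrum, and keeps the elbow index plus two
#' components as "signal" (component selection at the bare elbow was found
#' too aggressive, so two extra components are retained). The signal matrix
#' is the reconstruction from the retained components with the removed ROI
#' means added back; the noise matrix is the remainder, so
#' `signal + noise` reproduces the input exactly (to numerical tolerance).
#'
#' @param traces A `"trace_matrix"` at stage `"dff"` with at least 3 ROIs.
#' @param extra_components Components kept past the elbow (default 2).
#' @return An object of class `"signal_noise_split"`: `signal` and `noise`
#'   matrices, `n_signal_components`, and the descending `eigenvalues`.
#' @export
pca_split <- function(traces, extra_components = 2L) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (traces$stage != "dff") stop("expected a dff trace matrix", call. = FALSE)
  X <- traces$values
  n_roi <- nrow(X)
  nt <- ncol(X)
  if (n_roi < 3L) stop("PCA split needs at least 3 ROIs", call. = FALSE)
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  if (all(abs(Xc) < .Machine$double.eps * 100)) {
    warning("zero-variance input: assigning everything to signal", call. = FALSE)
    return(structure(list(signal = X, noise = matrix(0, n_roi, nt),
                          n_signal_components = 1L,
                          eigenvalues = rep(0, min(n_roi, nt)),
                          fps = traces$fps, grid = traces$grid),
                     class = "signal_noise_split"))
  }
  sv <- svd(Xc)
  ev <- sv$d^2 / (nt - 1)
  elbow <- scree_elbow(ev)
  n_sig <- min(elbow + as.integer(extra_components), n_roi, length(sv$d))
  n_sig <- max(n_sig, 1L)
  ks <- seq_len(n_sig)
  signal <- sv$u[, ks, drop = FALSE] %*%
    (sv$d[ks] * t(sv$v[, ks, drop = FALSE])) + rm_
  noise <- X - signal
  structure(list(signal = signal, noise = noise,
                 n_signal_components = n_sig, eigenvalues = ev,
                 fps = traces$fps, grid = traces$grid),
            class = "signal_noise_split")
}

#' @export
print.signal_noise_split <- function(x, ...) {
  cat(sprintf("<signal_noise_split> %d ROIs x %d frames, %d signal component(s)\n",
              nrow(x$signal), ncol(x$signal), x$n_signal_components))
  invisible(x)
}
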