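#' Burst train container
#'
#' An ordered set of burst times (s) with optional per-burst amplitudes over
#' a recording of known duration.
#'
#' @param positions Strictly increasing burst times in `[0, duration]`.
#' @param amplitudes Optional positive amplitudes (delta-F/F), one per burst.
#' @param duration Recording length (s).
#' @return An object of class `"burst_train"`.
#' @export
burst_train <- function(positions, amplitudes = NULL, duration) {
  stop_if_not_scalar_pos(duration, "duration")
  positions <- as.numeric(positions)
  if (length(positions) && (any(diff(positions) <= 0) ||
                            positions[1] < 0 ||
                            positions[length(positions)] > duration)) {
    stop("positions must be strictly increasing within [0, duration]",
         call. = FALSE)
  }
  if (!is.null(amplitudes)) {
    if (length(amplitudes) != length(positions)) {
      stop("one amplitude per burst required", call. = FALSE)
    }
    if (any(amplitudes <= 0)) stop("amplitudes must be positive", call. = FALSE)
  }
  structure(list(positions = positions, amplitudes = amplitudes,
                 duration = duration), class = "burst_train")
}

#' @export
print.burst_train <- function(x, ...) {
  cat(sprintf("<burst_train> %d bursts over %g s\n",
              length(x$positions), x$duration))
  invisible(x)
}

#' Burst frequency in bursts per minute
#'
#' @param train A [burst_train()].
#' @return Bursts/min: `count / duration * 60`.
#' @export
burst_frequency <- function(train) {
  stopifnot(inherits(train, "burst_train"))
  length(train$positions) / train$duration * 60
}

#' Interval coefficient of variation (rhythmicity)
#'
#' Sample SD of the inter-burst intervals divided by their mean. Low values
#' indicate rhythmic bursting. Undefined (`NA`) with fewer than 3 bursts
#' (2 intervals).
#'
#' @param train A [burst_train()].
#' @return The I.C.V., or `NA` if not computable.
#' @export
interval_cv <- function(train) {
  stopifnot(inherits(train, "burst_train"))
  if (length(train$positions) < 3L) return(NA_real_)
  sample_cv(diff(train$positions))
}

#' Classify a burst train as rhythmic
#'
#' Rhythmic means the interval coefficient of variation is strictly below
#' the threshold (default 0.2); the boundary value counts as non-rhythmic.
#'
#' @param icv Interval coefficient of variation.
#' @param threshold Classification cut (default 0.2).
#' @return `TRUE`, `FALSE`, or `NA` when `icv` is not computable.
#' @export
classify_rhythmic <- function(icv, threshold = 0.2) {
  if (is.na(icv)) return(NA)
  icv < threshold
}

#' Burst amplitude summary
#'
#' @param train A [burst_train()] with amplitudes.
#' @return A list: `mean` amplitude and amplitude `cv` (sample SD/mean;
#'   `NA` with fewer than 2 bursts).
#' @export
amplitude_stats <- function(train) {
  stopifnot(inherits(train, "burst_train"))
  a <- train$amplitudes
  if (is.null(a) || length(a) == 0L) {
    return(list(mean = NA_real_, cv = NA_real_))
  }
  list(mean = mean(a), cv = sample_cv(a))
}

#' Pairwise cross-correlation synchrony
#'
#' Zero-lag Pearson correlation for every unordered pair of delta-F/F
#' traces; synchrony is summarised as the mean over pairs. Optionally the
#' maximum correlation over integer-frame lags up to `max_lag_s` can be
#' taken per pair instead of the zero-lag value.
#'
#' Traces with zero variance cannot be correlated: their pairs are `NA` and
#' are excluded from the mean (a message reports how many).
#'
#' @param traces A `"trace_matrix"` at stage `"dff"` with >= 2 ROIs, or a
#'   plain ROI x time matrix.
#' @param max_lag_s Maximum lag (s) searched per pair; `0` (default) is the
#'   plain zero-lag correlation.
#' @param fps Frames per second (taken from `traces` when available;
#'   required for `max_lag_s > 0` on a plain matrix).
#' @return A list: `mean` pairwise correlation and the symmetric `matrix`
#'   of pair correlations (unit diagonal).
#' @export
pairwise_synchrony <- function(traces, max_lag_s = 0, fps = NULL) {
  if (inherits(traces, "trace_matrix")) {
    if (traces$stage != "dff") {
      stop("expected delta-F/F traces", call. = FALSE)
    }
    fps <- traces$fps
    vals <- traces$values
  } else {
    vals <- as.matrix(traces)
  }
  n <- nrow(vals)
  if (n < 2L) stop("need at least 2 traces", call. = FALSE)
  v <- apply(vals, 1L, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  if (max_lag_s > 0) {
    if (is.null(fps)) stop("`fps` required for lagged correlation", call. = FALSE)
    L <- round(max_lag_s * fps)
    nt <- ncol(vals)
    C <- diag(1, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (i %in% bad || j %in% bad) {
          C[i, j] <- C[j, i] <- NA_real_
          next
        }
        best <- -Inf
        for (l in -L:L) {
          xi <- vals[i, max(1, 1 + l):min(nt, nt + l)]
          xj <- vals[j, max(1, 1 - l):min(nt, nt - l)]
          best <- max(best, stats::cor(xi, xj))
        }
        C[i, j] <- C[j, i] <- best
      }
    }
  } else {
    C <- suppressWarnings(stats::cor(t(vals)))
    C[bad, ] <- NA_real_
    C[, bad] <- NA_real_
    diag(C) <- ifelse(seq_len(n) %in% bad, NA_real_, 1)
  }
  if (length(bad)) {
    message(sprintf("%d zero-variance trace(s) excluded from synchrony", length(bad)))
  }
  up <- C[upper.tri(C)]
  list(mean = mean(up, na.rm = TRUE), matrix = C)
}

#' Two-sided Student t-test between groups
#'
#' Paired or unpaired (pooled-variance) Student t-test. Degenerate inputs
#' with zero variance (e.g. identical paired samples) are reported as not
#' computable rather than an error.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Paired test?
#' @return A list: `t`, `p_value`, `df`, `method`, `computable`.
#' @export
group_ttest <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired test requires equal-length groups", call. = FALSE)
  }
  res <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = TRUE),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$statistic)) {
    return(list(t = NA_real_, p_value = NA_real_, df = NA_real_,
                method = if (paired) "paired t-test" else "unpaired t-test",
                computable = FALSE))
  }
  list(t = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter),
       method = if (paired) "paired t-test" else "unpaired t-test",
       computable = TRUE)
}

#' Per-ROI burst-train metrics table
#'
#' Summarises each ROI's detected events as a burst train: frequency,
#' interval C.V., rhythmic classification, and amplitude statistics.
#'
#' @param events Event data frame from [detect_bursts_all()].
#' @param n_rois Number of ROIs.
#' @param duration Recording length (s).
#' @param icv_threshold Rhythmicity cut (default 0.2).
#' @return Data frame with one row per ROI: `roi_id`, `n_bursts`,
#'   `frequency_bpm`, `icv`, `rhythmic`, `amp_mean`, `amp_cv`.
#' @export
roi_metrics <- function(events, n_rois, duration, icv_threshold = 0.2) {
  out <- lapply(seq_len(n_rois), function(r) {
    ev <- events[events$roi_id == r, , drop = FALSE]
    tr <- burst_train(ev$position_s, if (nrow(ev)) ev$amplitude else NULL,
                      duration)
    icv <- interval_cv(tr)
    amp <- amplitude_stats(tr)
    data.frame(roi_id = r, n_bursts = nrow(ev),
               frequency_bpm = burst_frequency(tr), icv = icv,
               rhythmic = classify_rhythmic(icv, icv_threshold),
               amp_mean = amp$mean, amp_cv = amp$cv)
  })
  do.call(rbind, out)
}
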