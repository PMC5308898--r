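#' Configuration for a synthetic circuitoid movie
#'
#' Bundles and validates every knob of the synthetic movie generator. The
#' defaults describe a two-minute recording at the standard acquisition
#' geometry (20 frames/s, 128 x 128 pixels, 8-bit) of a single rhythmic
#' network bursting every 10 s.
#'
#' @param n_frames Number of frames to render (default 2400, i.e. two
#'   minutes at 20 frames/s).
#' @param fps Acquisition rate in frames per second.
#' @param height,width Frame size in pixels.
#' @param n_subnetworks Number of spatial subnetworks (`1` = one fully
#'   synchronized network; `k > 1` = a segmented field).
#' @param mean_period Mean inter-burst interval per subnetwork, in seconds.
#' @param period_jitter_cv Coefficient of variation of inter-burst intervals;
#'   `0` renders a perfectly rhythmic schedule, values near 0.5 an irregular
#'   one.
#' @param shared_fraction Fraction of each subnetwork's burst rate that comes
#'   from a schedule shared by all subnetworks, in `[0, 1]`. `0` makes
#'   subnetworks fully independent, `1` fully synchronized.
#' @param amplitude_mean Mean burst amplitude in delta-F/F units (fractional
#'   fluorescence increase at the transient peak).
#' @param amplitude_cv Coefficient of variation of burst amplitudes.
#' @param tau_rise,tau_decay Rise and decay time constants (s) of the
#'   difference-of-exponentials calcium kernel; `tau_decay > tau_rise`.
#' @param baseline Resting fluorescence in 8-bit intensity units.
#' @param noise_sd Standard deviation of additive per-pixel Gaussian noise,
#'   in intensity units.
#' @param seed Integer seed; the rendered movie and ground truth are
#'   bit-reproducible given the full configuration.
#' @param partition_method `"stripes"` (contiguous vertical stripes, the
#'   default) or `"blobs"` (seeded Voronoi regions).
#'
#' @return A validated list of class `"synth_config"`.
#' @seealso [render_movie()], [make_schedule()], [assign_partition()]
#' @export
synth_config <- function(n_frames = 2400L, fps = 20, height = 128L, width = 128L,
                         n_subnetworks = 1L, mean_period = 10,
                         period_jitter_cv = 0, shared_fraction = 0,
                         amplitude_mean = 1, amplitude_cv = 0.1,
                         tau_rise = 0.1, tau_decay = 1,
                         baseline = 50, noise_sd = 2, seed = 1L,
                         partition_method = c("stripes", "blobs")) {
  partition_method <- match.arg(partition_method)
  stop_if_not_scalar_pos(n_frames, "n_frames")
  stop_if_not_scalar_pos(fps, "fps")
  stop_if_not_scalar_pos(height, "height")
  stop_if_not_scalar_pos(width, "width")
  stop_if_not_scalar_pos(mean_period, "mean_period")
  stop_if_not_scalar_pos(period_jitter_cv, "period_jitter_cv", strict = FALSE)
  stop_if_not_scalar_pos(amplitude_mean, "amplitude_mean")
  stop_if_not_scalar_pos(amplitude_cv, "amplitude_cv", strict = FALSE)
  stop_if_not_scalar_pos(tau_rise, "tau_rise")
  stop_if_not_scalar_pos(tau_decay, "tau_decay")
  stop_if_not_scalar_pos(baseline, "baseline")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  if (n_frames < 2) stop("`n_frames` must be at least 2", call. = FALSE)
  if (tau_decay <= tau_rise) {
    stop("`tau_decay` must exceed `tau_rise`", call. = FALSE)
  }
  if (n_subnetworks < 1 || n_subnetworks > height * width) {
    stop("`n_subnetworks` must be between 1 and height*width", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("`shared_fraction` must lie in [0, 1]", call. = FALSE)
  }
  cfg <- list(
    n_frames = as.integer(n_frames), fps = fps,
    height = as.integer(height), width = as.integer(width),
    n_subnetworks = as.integer(n_subnetworks),
    mean_period = mean_period, period_jitter_cv = period_jitter_cv,
    shared_fraction = shared_fraction,
    amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
    tau_rise = tau_rise, tau_decay = tau_decay,
    baseline = baseline, noise_sd = noise_sd,
    seed = as.integer(seed), partition_method = partition_method
  )
  structure(cfg, class = "synth_config")
}

#' Normalized calcium transient kernel
#'
#' Difference-of-exponentials kernel
#' `K(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / K(t_peak)` for `t >= 0`
#' and 0 otherwise, scaled so its maximum is exactly 1. This is the simplest
#' waveform with the fast-rise/slow-decay morphology of somatic calcium
#' transients that the burst detector assumes.
#'
#' @param t Numeric vector of times (s), relative to transient onset.
#' @param tau_rise,tau_decay Rise/decay time constants (s), `tau_decay >
#'   tau_rise > 0`.
#' @return Numeric vector of kernel values with peak value 1.
#' @export
calcium_kernel <- function(t, tau_rise = 0.1, tau_decay = 1) {
  stop_if_not_scalar_pos(tau_rise, "tau_rise")
  stop_if_not_scalar_pos(tau_decay, "tau_decay")
  if (tau_decay <= tau_rise) stop("`tau_decay` must exceed `tau_rise`", call. = FALSE)
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  k <- ifelse(t > 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak, 0)
  k[!is.finite(k)] <- 0
  k
}

#' Generate a burst schedule
#'
#' Draws an ordered sequence of burst onset times on `(0, duration)` whose
#' inter-burst intervals have mean `mean_period` and coefficient of variation
#' `jitter_cv`. With `jitter_cv = 0` the schedule is perfectly periodic
#' (bursts at `mean_period, 2*mean_period, ...`). With `jitter_cv > 0`
#' intervals are drawn from a gamma renewal process with shape
#' `1/jitter_cv^2`, which has exactly the requested mean and CV on positive
#' support; draws below `min_interval` (default twice the kernel rise time,
#' below which transients are unresolvable) are rejected and redrawn.
#'
#' @param duration Recording length (s).
#' @param mean_period Mean inter-burst interval (s).
#' @param jitter_cv Interval coefficient of variation, `>= 0`.
#' @param seed Optional integer seed; `NULL` uses (and advances) the ambient
#'   RNG stream.
#' @param min_interval Smallest admissible interval (s).
#' @return Strictly increasing numeric vector of burst times in
#'   `(0, duration)`; empty when `duration <= mean_period` allows no burst.
#' @export
make_schedule <- function(duration, mean_period, jitter_cv = 0, seed = NULL,
                          min_interval = 0.2) {
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(mean_period, "mean_period")
  stop_if_not_scalar_pos(jitter_cv, "jitter_cv", strict = FALSE)
  stop_if_not_scalar_pos(min_interval, "min_interval", strict = FALSE)
  if (duration <= mean_period) return(numeric(0))
  if (jitter_cv == 0) {
    times <- seq(mean_period, duration, by = mean_period)
    return(times[times < duration])
  }
  shape <- 1 / jitter_cv^2
  scale <- mean_period * jitter_cv^2
  with_seed(seed, {
    times <- numeric(0)
    total <- 0
    repeat {
      n_draw <- max(16L, ceiling((duration - total) / mean_period * 1.5))
      iv <- stats::rgamma(n_draw, shape = shape, scale = scale)
      iv <- iv[iv >= min_interval]
      if (length(iv) == 0L) next
      tt <- total + cumsum(iv)
      times <- c(times, tt)
      total <- tt[length(tt)]
      if (total >= duration) break
    }
    times[times < duration]
  })
}

#' Partition a frame into subnetwork territories
#'
#' Assigns every pixel to one of `n_subnetworks` spatially contiguous
#' regions. The default carves the field into vertical stripes of near-equal
#' width (deterministic); `method = "blobs"` grows seeded Voronoi regions
#' around random centers for irregular territories.
#'
#' @param height,width Frame size in pixels.
#' @param n_subnetworks Number of regions, between 1 and `height * width`
#'   (at most `width` for stripes).
#' @param seed Optional seed (used by the `"blobs"` method only).
#' @param method `"stripes"` or `"blobs"`.
#' @return Integer `height x width` matrix of labels in `1:n_subnetworks`;
#'   every label occurs at least once.
#' @export
assign_partition <- function(height, width, n_subnetworks, seed = NULL,
                             method = c("stripes", "blobs")) {
  method <- match.arg(method)
  stop_if_not_scalar_pos(height, "height")
  stop_if_not_scalar_pos(width, "width")
  if (n_subnetworks < 1 || n_subnetworks > height * width) {
    stop("`n_subnetworks` must be between 1 and height*width", call. = FALSE)
  }
  if (method == "stripes") {
    if (n_subnetworks > width) {
      stop("more stripe subnetworks than pixel columns", call. = FALSE)
    }
    breaks <- round(seq(0, width, length.out = n_subnetworks + 1))
    col_labels <- rep.int(seq_len(n_subnetworks), diff(breaks))
    return(matrix(rep(col_labels, each = height), nrow = height))
  }
  with_seed(seed, {
    k <- n_subnetworks
    ctr_r <- stats::runif(k, 0.5, height + 0.5)
    ctr_c <- stats::runif(k, 0.5, width + 0.5)
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(rep(seq_len(width), each = height), height, width)
    best <- matrix(Inf, height, width)
    lab <- matrix(1L, height, width)
    for (i in seq_len(k)) {
      d <- (rows - ctr_r[i])^2 + (cols - ctr_c[i])^2
      take <- d < best
      lab[take] <- i
      best[take] <- d[take]
    }
    # guarantee every label is nonempty: give label i its own nearest pixel
    for (i in seq_len(k)) {
      if (!any(lab == i)) {
        d <- (rows - ctr_r[i])^2 + (cols - ctr_c[i])^2
        lab[which.min(d)] <- i
      }
    }
    lab
  })
}

# draw per-burst amplitudes with mean m and CV cv (gamma; constant if cv = 0)
draw_amplitudes <- function(n, m, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0) return(rep.int(m, n))
  stats::rgamma(n, shape = 1 / cv^2, scale = m * cv^2)
}

#' Render a synthetic circuitoid movie with ground truth
#'
#' Generates per-subnetwork burst schedules, draws per-burst amplitudes,
#' and renders each pixel's fluorescence as
#' `baseline * (1 + sum_b A_b * K(t - t_b)) + N(0, noise_sd)` over the
#' bursts of the pixel's subnetwork, where `K` is [calcium_kernel()].
#' Frames are clipped to `[0, 255]` and quantized to 8 bits (round half up).
#'
#' For `n_subnetworks > 1`, each subnetwork's schedule is the union of its
#' own gamma-renewal schedule (rate `(1 - shared_fraction) / mean_period`)
#' and one schedule shared by all subnetworks (rate
#' `shared_fraction / mean_period`), so the per-subnetwork burst rate stays
#' at `1 / mean_period` while `shared_fraction` controls how many burst
#' times all subnetworks have in common.
#'
#' @param config A [synth_config()].
#' @return A list with components `movie` (a [movie_stack()]) and `truth`
#'   (class `"ground_truth"`: `partition` label matrix, `schedules` data
#'   frame with columns `subnetwork_id`, `time_s`, `amplitude`, and the
#'   `config`).
#' @export
render_movie <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be built with synth_config()", call. = FALSE)
  }
  cfg <- config
  duration <- cfg$n_frames / cfg$fps
  min_iv <- 2 * cfg$tau_rise
  with_seed(cfg$seed, {
    partition <- assign_partition(cfg$height, cfg$width, cfg$n_subnetworks,
                                  seed = NULL, method = cfg$partition_method)
    k <- cfg$n_subnetworks
    sf <- cfg$shared_fraction
    jit <- cfg$period_jitter_cv
    if (k == 1L) {
      shared_t <- numeric(0)
      own_t <- list(make_schedule(duration, cfg$mean_period, jit,
                                  min_interval = min_iv))
    } else {
      shared_t <- if (sf > 0) {
        make_schedule(duration, cfg$mean_period / sf, jit, min_interval = min_iv)
      } else numeric(0)
      own_t <- lapply(seq_len(k), function(i) {
        if (sf < 1) {
          make_schedule(duration, cfg$mean_period / (1 - sf), jit,
                        min_interval = min_iv)
        } else numeric(0)
      })
    }
    shared_a <- draw_amplitudes(length(shared_t), cfg$amplitude_mean, cfg$amplitude_cv)
    own_a <- lapply(own_t, function(tt) {
      draw_amplitudes(length(tt), cfg$amplitude_mean, cfg$amplitude_cv)
    })
    schedules <- lapply(seq_len(k), function(i) {
      tt <- c(own_t[[i]], shared_t)
      aa <- c(own_a[[i]], shared_a)
      if (length(tt) == 0L) {
        return(list(time_s = numeric(0), amplitude = numeric(0)))
      }
      o <- order(tt)
      tt <- tt[o]; aa <- aa[o]
      # drop bursts unresolvably close to their predecessor (own vs shared clashes)
      keep <- c(TRUE, diff(tt) >= min_iv)
      list(time_s = tt[keep], amplitude = aa[keep])
    })

    tvec <- (seq_len(cfg$n_frames) - 1) / cfg$fps
    S <- matrix(0, cfg$n_frames, k)
    for (i in seq_len(k)) {
      sch <- schedules[[i]]
      for (b in seq_along(sch$time_s)) {
        S[, i] <- S[, i] +
          sch$amplitude[b] * calcium_kernel(tvec - sch$time_s[b],
                                            cfg$tau_rise, cfg$tau_decay)
      }
    }
    labels <- as.vector(partition)
    M <- cfg$baseline * (1 + S[, labels, drop = FALSE])
    if (cfg$noise_sd > 0) {
      M <- M + stats::rnorm(length(M), sd = cfg$noise_sd)
    }
    over <- mean(M > 255)
    if (over > 0.10) {
      warning(sprintf("%.1f%% of rendered intensities exceed the 8-bit range and were clipped",
                      100 * over), call. = FALSE)
    }
    Mq <- round_half_up(pmin(pmax(M, 0), 255))
    frames <- array(as.integer(Mq), dim = c(cfg$n_frames, cfg$height, cfg$width))
    sched_df <- do.call(rbind, c(
      list(data.frame(subnetwork_id = integer(0), time_s = numeric(0),
                      amplitude = numeric(0))),
      lapply(seq_len(k), function(i) {
        if (length(schedules[[i]]$time_s) == 0L) return(NULL)
        data.frame(subnetwork_id = i,
                   time_s = schedules[[i]]$time_s,
                   amplitude = schedules[[i]]$amplitude)
      })
    ))
    truth <- structure(list(partition = partition, schedules = sched_df,
                            config = cfg),
                       class = "ground_truth")
    list(movie = movie_stack(frames, cfg$fps), truth = truth)
  })
}

#' Write a movie stack as a multi-page 8-bit grayscale TIFF
#'
#' @param movie A [movie_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  pages <- lapply(seq_len(dim(movie$frames)[1]),
                  function(t) movie$frames[t, , ] / 255)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  if (ok != length(pages)) stop("failed to write all TIFF pages", call. = FALSE)
  invisible(path)
}

#' Write ground truth as plain-text CSV files
#'
#' Writes `schedules.csv` (`subnetwork_id,time_s,amplitude`; one row per
#' burst, shared bursts repeated per subnetwork) and `partition.csv`
#' (`row,col,label`) into `dir`.
#'
#' @param truth A `"ground_truth"` object from [render_movie()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sched_path <- file.path(dir, "schedules.csv")
  part_path <- file.path(dir, "partition.csv")
  utils::write.csv(truth$schedules, sched_path, row.names = FALSE)
  p <- truth$partition
  part_df <- data.frame(row = as.vector(row(p)), col = as.vector(col(p)),
                        label = as.vector(p))
  utils::write.csv(part_df, part_path, row.names = FALSE)
  invisible(c(schedules = sched_path, partition = part_path))
}
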