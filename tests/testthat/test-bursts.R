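# build a clean signal trace from a list of onset times (s)
kernel_trace <- function(onsets, n = 1200, fps = 20, amp = 1) {
  tvec <- (seq_len(n) - 1) / fps
  x <- numeric(n)
  for (t0 in onsets) x <- x + amp * calcium_kernel(tvec - t0)
  x
}

test_that("a flat trace yields no events", {
  set.seed(1)
  noise <- rnorm(1200, sd = 0.01)
  ev <- detect_bursts(rep(0.5, 1200), noise, 20)
  expect_equal(nrow(ev), 0L)
})

test_that("a single clean transient yields exactly one event at its foot", {
  set.seed(2)
  noise <- rnorm(1200, sd = 0.02)
  x <- kernel_trace(30)  # amplitude 1 = 50x the noise SD
  ev <- detect_bursts(x, noise, 20)
  expect_equal(nrow(ev), 1L)
  # base at the foot of the rise: within a couple of frames after onset
  expect_gte(ev$base_frame, 30 * 20 + 1)
  expect_lte(ev$base_frame, 30 * 20 + 4)
  expect_gt(ev$peak_frame, ev$base_frame)
  expect_gt(ev$amplitude, 0.9)
  expect_equal(ev$position_s, (ev$base_frame - 1) / 20)
})

test_that("sub-threshold edges are rejected and the threshold scales with noise", {
  set.seed(3)
  noise_small <- rnorm(1200, sd = 0.001)
  noise_big <- rnorm(1200, sd = 1)
  x <- kernel_trace(30, amp = 0.05)
  expect_equal(nrow(detect_bursts(x, noise_small, 20)), 1L)
  expect_equal(nrow(detect_bursts(x, noise_big, 20)), 0L)
})

test_that("zero-variance noise traces fall back with a warning", {
  x <- kernel_trace(30)
  expect_warning(ev <- detect_bursts(x, rep(0, 1200), 20), "zero variance")
  expect_equal(nrow(ev), 1L)
})

test_that("events closer than the separation merge keeping the larger", {
  set.seed(4)
  noise <- rnorm(1200, sd = 0.005)
  x <- kernel_trace(30, amp = 0.4) + kernel_trace(30.3, amp = 1)
  ev <- detect_bursts(x, noise, 20,
                      detection_params(min_separation_s = 0.5))
  expect_equal(nrow(ev), 1L)
  ev2 <- detect_bursts(x, noise, 20,
                       detection_params(min_separation_s = 0))
  expect_gte(nrow(ev2), nrow(ev))
})

test_that("edge-guarded events near the record boundaries are dropped", {
  set.seed(5)
  # signal-trace wiggle well below the noise-trace threshold, as after
  # smoothing and PCA reconstruction
  x <- rnorm(1200, sd = 0.0002)
  spike <- function(at) {
    x[at - 1] <<- 0.1
    x[at:(at + 4)] <<- c(0, 0.5, 1, 0.6, 0.2)
  }
  spike(3)     # peak at frame 5, inside the leading guard
  spike(600)   # interior
  spike(1194)  # base at frame 1194 > 1190, inside the trailing guard
  noise <- rnorm(1200, sd = 0.002)
  ev <- detect_bursts(x, noise, 20, detection_params(edge_guard_s = 0.5))
  expect_equal(nrow(ev), 1L)  # only the interior transient clears the guards
  expect_lt(abs(ev$position_s - 30), 0.3)
  ev0 <- detect_bursts(x, noise, 20, detection_params(edge_guard_s = 0))
  expect_equal(nrow(ev0), 3L)
})

test_that("a transient truncated by the record end has no measurable peak", {
  set.seed(51)
  noise <- rnorm(1200, sd = 0.002)
  x <- kernel_trace(c(30, 59.9)) # second burst peaks past the record end
  ev <- detect_bursts(x, noise, 20, detection_params(edge_guard_s = 0))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$position_s - 30), 0.25)
})

mk_events <- function(...) {
  # list of per-ROI position vectors -> event data frame
  lst <- list(...)
  do.call(rbind, lapply(seq_along(lst), function(r) {
    if (length(lst[[r]]) == 0L) return(NULL)
    data.frame(roi_id = r, position_s = lst[[r]], amplitude = 1)
  }))
}

test_that("cataloging follows the greedy +/- window rule", {
  # one ROI, two separated events -> two singleton entries
  cat1 <- catalog_bursts(mk_events(c(5, 15)), n_rois = 1)
  expect_equal(nrow(cat1$entries), 2L)
  expect_equal(cat1$entries$support_count, c(1L, 1L))
  expect_equal(cat1$sequences[[1]], c(1L, 2L))
  # 10.0 and 10.4 within 1 s -> one entry supported by both, time = mean
  cat2 <- catalog_bursts(mk_events(10.0, 10.4), n_rois = 2)
  expect_equal(nrow(cat2$entries), 1L)
  expect_equal(cat2$entries$support_count, 2L)
  expect_equal(cat2$entries$time_s, 10.2)
  # 10.0 and 11.5 are 1.5 s apart -> two entries
  cat3 <- catalog_bursts(mk_events(10.0, 11.5), n_rois = 2)
  expect_equal(nrow(cat3$entries), 2L)
  # at most one event per ROI per entry: the nearest wins
  cat4 <- catalog_bursts(mk_events(c(9.8, 10.4), 9.9), n_rois = 2)
  expect_equal(nrow(cat4$entries), 2L)
  expect_equal(cat4$sequences[[1]], c(1L, 2L))
  expect_equal(cat4$entries$support_count, c(2L, 1L))
  expect_equal(catalog_bursts(NULL, n_rois = 3)$entries$catalog_id, integer(0))
})

test_that("every event lands in exactly one entry with increasing times", {
  set.seed(6)
  for (i in 1:10) {
    lst <- lapply(1:8, function(r) sort(runif(sample(0:12, 1), 0, 120)))
    ev <- do.call(mk_events, lst)
    if (is.null(ev)) next
    cat_ <- catalog_bursts(ev, n_rois = 8)
    expect_equal(nrow(cat_$assignments), nrow(ev))
    expect_true(all(cat_$assignments$catalog_id %in% cat_$entries$catalog_id))
    expect_lte(nrow(cat_$entries), nrow(ev))
    expect_true(all(diff(cat_$entries$time_s) > 0))
    # each ROI contributes at most once per entry
    tab <- table(cat_$assignments$roi_id, cat_$assignments$catalog_id)
    expect_true(all(tab <= 1))
    # within-ROI sequences have strictly increasing representative times
    for (s in cat_$sequences) {
      if (length(s) > 1) expect_true(all(diff(cat_$entries$time_s[s]) > 0))
    }
  }
})

test_that("the 4% support filter keeps 8/196 and drops 7/196", {
  ev <- rbind(
    data.frame(roi_id = 1:8, position_s = 10, amplitude = 1),
    data.frame(roi_id = 1:7, position_s = 50, amplitude = 1)
  )
  cat_ <- catalog_bursts(ev, n_rois = 196)
  expect_equal(nrow(cat_$entries), 2L)
  filt <- filter_catalog(cat_, min_support = 0.04)
  expect_equal(nrow(filt$entries), 1L)
  expect_equal(filt$entries$support_count, 8L)
  expect_equal(filt$entries$catalog_id, 1L)
  expect_equal(filt$sequences[[8]], 1L)
  expect_equal(filt$sequences[[1]], 1L)
})

test_that("filtering is idempotent and min_support = 0 is a no-op", {
  set.seed(7)
  lst <- lapply(1:10, function(r) sort(runif(sample(1:10, 1), 0, 100)))
  cat_ <- catalog_bursts(do.call(mk_events, lst), n_rois = 10)
  f0 <- filter_catalog(cat_, 0)
  expect_equal(f0$entries[, names(cat_$entries)], cat_$entries)
  f1 <- filter_catalog(cat_, 0.2)
  f2 <- filter_catalog(f1, 0.2)
  expect_equal(f1$entries, f2$entries)
  expect_equal(f1$sequences, f2$sequences)
  expect_warning(filter_catalog(cat_, 1), "below the support threshold")
})

test_that("detector recall degrades as noise rises, at fixed threshold", {
  recall_at <- function(noise_sd, seed) {
    cfg <- synth_config(n_frames = 1200L, height = 32L, width = 32L,
                        seed = seed, amplitude_mean = 0.05,
                        baseline = 30, noise_sd = noise_sd)
    out <- render_movie(cfg)
    res <- analyze_movie(out$movie, pipeline_config())
    true_t <- out$truth$schedules$time_s
    true_t <- true_t[true_t > 1 & true_t < 58]
    ev <- res$events
    # a true burst counts as recalled in an ROI when that ROI has an event
    # within 0.25 s of the onset (after the half-window filter lead)
    hits <- vapply(true_t, function(t0) {
      found <- abs(ev$position_s + 0.5 - t0) < 0.25
      length(unique(ev$roi_id[found]))
    }, numeric(1))
    mean(hits) / 9 # 9 ROIs on a 32x32 field
  }
  lo <- mean(vapply(1:4, function(s) recall_at(1, s), numeric(1)))
  hi <- mean(vapply(1:4, function(s) recall_at(25, s + 100), numeric(1)))
  expect_gt(lo, hi)
})
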