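test_that("ROI tiling reproduces the standard lattice sizes", {
  expect_equal(nrow(tile_rois(128, 128, 11, 9)$centers), 196L)
  expect_equal(nrow(tile_rois(11, 11, 11, 9)$centers), 1L)
  expect_equal(nrow(tile_rois(64, 64, 11, 9)$centers), 36L)
  expect_error(tile_rois(8, 8, 11, 9), "exceeds")
})

test_that("tiling matches brute-force placement enumeration", {
  brute <- function(h, w, s, sp) {
    n <- 0L
    for (top in seq(1, h, by = sp)) {
      for (left in seq(1, w, by = sp)) {
        if (top + s - 1 <= h && left + s - 1 <= w) n <- n + 1L
      }
    }
    n
  }
  set.seed(2)
  for (i in 1:20) {
    h <- sample(12:80, 1); w <- sample(12:80, 1)
    s <- sample(3:11, 1); sp <- sample(1:12, 1)
    g <- tile_rois(h, w, s, sp)
    expect_equal(nrow(g$centers), brute(h, w, s, sp))
    expect_true(all(g$centers$top + s - 1 <= h))
    expect_true(all(g$centers$left + s - 1 <= w))
  }
})

test_that("the oval footprint is the inscribed ellipse of the ROI square", {
  m <- oval_mask(11)
  expect_true(m[6, 6])          # center
  expect_true(m[1, 6] && m[6, 1]) # edge midpoints
  expect_false(m[1, 1] || m[11, 11]) # corners
  expect_identical(m, t(m))
  expect_identical(m, m[11:1, ])
})

test_that("trace extraction averages exactly the footprint pixels", {
  set.seed(3)
  frames <- array(sample(0:255, 20 * 30 * 30, replace = TRUE),
                  dim = c(20, 30, 30))
  movie <- movie_stack(frames, 20)
  grid <- tile_rois(30, 30, 11, 9)
  tr <- extract_traces(movie, grid)
  # brute-force loop oracle
  fp <- grid$footprint
  for (r in seq_len(nrow(grid$centers))) {
    top <- grid$centers$top[r]; left <- grid$centers$left[r]
    for (t in c(1, 10, 20)) {
      block <- frames[t, top:(top + 10), left:(left + 10)]
      expect_equal(tr$values[r, t], mean(block[fp]))
    }
  }
})

test_that("trace extraction is local and preserves constants", {
  frames <- array(100, dim = c(10, 32, 32))
  frames[5, 1:11, 1:11] <- 255
  movie <- movie_stack(frames, 20)
  grid <- tile_rois(32, 32, 11, 9)
  tr <- extract_traces(movie, grid)
  expect_true(all(abs(tr$values[, -5] - 100) < 1e-9))
  expect_gt(tr$values[1, 5], 100)    # ROI over the bright block
  far <- which(grid$centers$top > 12 & grid$centers$left > 12)
  expect_true(all(abs(tr$values[far, 5] - 100) < 1e-9))
})

test_that("loading resizes by area pooling and preserves constants", {
  d <- withr::local_tempdir()
  path <- file.path(d, "c.tif")
  pages <- lapply(1:3, function(i) matrix(100 / 255, 256, 256))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  m <- load_stack(path, fps = 20, target_size = 128)
  expect_identical(dim(m$frames), c(3L, 128L, 128L))
  expect_true(all(abs(m$frames - 100) < 1e-9))
  # integer-factor downscale equals block means
  set.seed(4)
  x <- matrix(runif(64 * 64, 0, 255), 64, 64)
  y <- circuitnet:::resize_frame(x, 32, 32)
  blocks <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    blocks[i, j] <- mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(y, blocks)
  # upscale keeps constants too
  expect_true(all(abs(circuitnet:::resize_frame(matrix(7, 16, 16), 40, 40) - 7) < 1e-9))
})

test_that("single-frame and color stacks are rejected", {
  d <- withr::local_tempdir()
  one <- file.path(d, "one.tif")
  tiff::writeTIFF(matrix(0.5, 16, 16), one, bits.per.sample = 8L)
  expect_error(load_stack(one), "single frame")
  rgb <- file.path(d, "rgb.tif")
  tiff::writeTIFF(list(array(0.5, c(8, 8, 3)), array(0.5, c(8, 8, 3))), rgb,
                  bits.per.sample = 8L)
  expect_error(load_stack(rgb), "grayscale")
})

test_that("running-mean smoothing matches hand-computed convolutions", {
  const <- trace_matrix(matrix(5, 1, 100), 20, "raw")
  expect_equal(smooth_traces(const, 1)$values, matrix(5, 1, 100))
  # unit impulse at frame 50, 20 fps, 1 s window -> 21-frame plateau of 1/21
  imp <- matrix(0, 1, 100); imp[1, 50] <- 1
  sm <- smooth_traces(trace_matrix(imp, 20, "raw"), 1)$values
  expect_equal(which(sm[1, ] > 0), 40:60)
  expect_equal(unique(round(sm[1, 40:60], 12)), 1 / 21)
  # alternating +/-1: interior values within 1/21 of zero
  alt <- matrix(rep(c(1, -1), 50), 1, 100)
  sma <- smooth_traces(trace_matrix(alt, 20, "raw"), 1)$values
  expect_true(all(abs(sma[1, 11:90]) <= 1 / 21 + 1e-12))
})

test_that("smoothing preserves the mean and never widens the range", {
  set.seed(6)
  for (i in 1:10) {
    x <- matrix(rnorm(3 * 200), 3, 200)
    sm <- smooth_traces(trace_matrix(x, 20, "raw"), 1)$values
    expect_true(all(sm <= max(x) + 1e-12) && all(sm >= min(x) - 1e-12))
    # interior mass is conserved; only the edge windows can shift the mean
    expect_lt(abs(mean(sm) - mean(x)), 0.05)
  }
  expect_error(smooth_traces(trace_matrix(matrix(0, 1, 10), 20, "raw"), 1),
               "longer")
})

test_that("delta-F/F is zero for constants, unit for doubling, scale-free", {
  const <- trace_matrix(matrix(7, 2, 50), 20, "smoothed")
  expect_true(all(dff(const)$values == 0))
  # 90% of frames at F0, 10% at 2*F0 -> 10th-percentile baseline F0, peaks 1
  x <- matrix(c(rep(10, 90), rep(20, 10)), 1, 100)
  d <- dff(trace_matrix(x, 20, "smoothed"))$values
  expect_equal(max(d), 1)
  expect_equal(min(d), 0)
  d3 <- dff(trace_matrix(3 * x, 20, "smoothed"))$values
  expect_equal(d3, d)
  bad <- trace_matrix(matrix(c(rep(0, 60), rep(1, 40)), 1, 100), 20, "smoothed")
  expect_error(dff(bad), "ROI")
})

test_that("PCA split reconstructs its input exactly", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:25, 1); t <- sample(30:120, 1)
    X <- matrix(rnorm(n * t), n, t)
    tr <- trace_matrix(X, 20, "dff")
    sp <- pca_split(tr)
    rel <- norm(X - (sp$signal + sp$noise), "F") / norm(X, "F")
    expect_lt(rel, 1e-8)
    expect_gte(sp$n_signal_components, 1L)
    expect_lte(sp$n_signal_components, n)
    expect_equal(order(sp$eigenvalues, decreasing = TRUE),
                 seq_along(sp$eigenvalues))
  }
})

test_that("rank-1 input is pure signal", {
  set.seed(9)
  w <- runif(10, 0.5, 2)
  base <- sin(seq(0, 8 * pi, length.out = 200)) + 2
  X <- outer(w, base)
  sp <- pca_split(trace_matrix(X, 20, "dff"))
  expect_lt(max(abs(sp$noise)), 1e-10)
  expect_equal(sp$signal, X, tolerance = 1e-10)
})

test_that("strong components survive the elbow+2 selection", {
  set.seed(10)
  t <- 400; n <- 30
  comps <- rbind(sin(seq_len(t) / 5), cos(seq_len(t) / 9),
                 sin(seq_len(t) / 23))
  W <- matrix(rnorm(n * 3), n, 3)
  noise <- matrix(rnorm(n * t, sd = 0.01), n, t)
  X <- W %*% comps + noise
  sp <- pca_split(trace_matrix(X, 20, "dff"))
  expect_gte(sp$n_signal_components, 3L)
  expect_lte(sum(sp$noise^2), 1.5 * sum(noise^2))
})

test_that("degenerate zero-variance input is handled with a warning", {
  X <- matrix(3, 5, 40)
  expect_warning(sp <- pca_split(trace_matrix(X, 20, "dff")), "zero-variance")
  expect_equal(sp$n_signal_components, 1L)
  expect_true(all(sp$noise == 0))
  expect_equal(sp$signal, X)
})

test_that("the trace chain is deterministic for a fixed movie", {
  out <- render_movie(tiny_config(seed = 55))
  run <- function() {
    g <- tile_rois(32, 32)
    dff(smooth_traces(extract_traces(out$movie, g), 1), 10)$values
  }
  expect_identical(run(), run())
})
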