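#' Analysis pipeline configuration
#'
#' Collects every tunable of the movie analysis chain. The defaults are the
#' standard operating point of the method: 11 px oval ROIs at 9 px spacing,
#' 1 s running-mean smoothing, 10th-percentile delta-F/F baseline, a
#' 1.96-sigma noise threshold, a +/- 1 s catalog window, a 4% catalog
#' support filter, 0.5 s event merging, a 0.2 rhythmicity cut, and
#' 20 frames/s acquisition.
#'
#' @param roi_size,spacing ROI side and lattice spacing in pixels.
#' @param smooth_s Running-mean window (s).
#' @param dff_percentile Baseline percentile for delta-F/F.
#' @param k_sigma Burst threshold in noise SDs.
#' @param window_s Catalog half-window (s).
#' @param min_support Catalog support filter fraction.
#' @param min_separation_s Event merge separation (s).
#' @param icv_threshold Rhythmic / non-rhythmic cut on the interval C.V.
#' @param n_boot Bootstrap resamples for median standard errors.
#' @param fps Frames per second.
#' @param seed Seed for stochastic steps (bootstrap).
#' @param mode `"network"` (lattice ROIs over the field of view) or
#'   `"cellular"` (caller-supplied per-cell traces).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(roi_size = 11, spacing = 9, smooth_s = 1,
                            dff_percentile = 10, k_sigma = 1.96,
                            window_s = 1, min_support = 0.04,
                            min_separation_s = 0.5, icv_threshold = 0.2,
                            n_boot = 1000L, fps = 20, seed = 1L,
                            mode = c("network", "cellular")) {
  mode <- match.arg(mode)
  structure(list(roi_size = roi_size, spacing = spacing, smooth_s = smooth_s,
                 dff_percentile = dff_percentile, k_sigma = k_sigma,
                 window_s = window_s, min_support = min_support,
                 min_separation_s = min_separation_s,
                 icv_threshold = icv_threshold, n_boot = as.integer(n_boot),
                 fps = fps, seed = as.integer(seed), mode = mode),
            class = "pipeline_config")
}

#' Analyze a movie end to end
#'
#' Runs the full chain on a movie stack: ROI tiling, trace extraction,
#' smoothing, delta-F/F, PCA signal/noise separation, per-ROI burst
#' detection, burst cataloging with the support filter, the directed
#' burst-sequence graph with its complexity score, per-ROI and network
#' burst-train metrics, and pairwise synchrony.
#'
#' @param movie A [movie_stack()] (or a path to a TIFF stack, loaded with
#'   [load_stack()] at its native size).
#' @param config A [pipeline_config()].
#' @return A list of class `"circuit_analysis"` with components `grid`,
#'   `traces_raw`, `traces_smoothed`, `traces_dff`, `split`, `events`,
#'   `catalog_raw`, `catalog`, `graph`, `complexity`, `roi_metrics`,
#'   `network_train`, `network_metrics`, `synchrony`, `config`, and a
#'   `counts` summary of every stage.
#' @export
analyze_movie <- function(movie, config = pipeline_config()) {
  if (is.character(movie)) {
    movie <- load_stack(movie, fps = config$fps, target_size = NULL)
  }
  stopifnot(inherits(movie, "movie_stack"), inherits(config, "pipeline_config"))
  d <- dim(movie$frames)
  duration <- d[1] / movie$fps
  grid <- tile_rois(d[2], d[3], config$roi_size, config$spacing)
  raw <- extract_traces(movie, grid)
  sm <- smooth_traces(raw, config$smooth_s)
  dd <- dff(sm, config$dff_percentile)
  split <- pca_split(dd)
  params <- detection_params(config$k_sigma, config$min_separation_s,
                             edge_guard_s = config$smooth_s / 2)
  events <- detect_bursts_all(split, movie$fps, params)
  n_rois <- nrow(grid$centers)
  catalog_raw <- catalog_bursts(events, n_rois, config$window_s)
  catalog <- filter_catalog(catalog_raw, config$min_support)
  graph <- build_graph(catalog$sequences)
  cx <- complexity_score(graph)
  # per-ROI metrics use the re-described (support-filtered) events: these are
  # the robust bursts; raw single-ROI noise calls are excluded
  rm_ <- roi_metrics(catalog$assignments, n_rois, duration,
                     config$icv_threshold)
  train <- network_burst_train(catalog, duration)
  icv <- interval_cv(train)
  amp <- amplitude_stats(train)
  network_metrics <- list(
    n_bursts = length(train$positions),
    frequency_bpm = burst_frequency(train),
    icv = icv,
    rhythmic = classify_rhythmic(icv, config$icv_threshold),
    amp_mean = amp$mean, amp_cv = amp$cv
  )
  sync <- pairwise_synchrony(dd)
  counts <- c(n_rois = n_rois, n_frames = d[1], n_events = nrow(events),
              n_catalog_raw = nrow(catalog_raw$entries),
              n_catalog = nrow(catalog$entries),
              n_nodes = length(graph$nodes), n_edges = nrow(graph$edges))
  structure(list(grid = grid, traces_raw = raw, traces_smoothed = sm,
                 traces_dff = dd, split = split, events = events,
                 catalog_raw = catalog_raw, catalog = catalog, graph = graph,
                 complexity = cx, roi_metrics = rm_, network_train = train,
                 network_metrics = network_metrics, synchrony = sync,
                 config = config, counts = counts),
            class = "circuit_analysis")
}

#' @export
print.circuit_analysis <- function(x, ...) {
  cat("<circuit_analysis>\n")
  cat(sprintf("  %d ROIs, %d events, %d/%d catalog entries (filtered/raw)\n",
              x$counts["n_rois"], x$counts["n_events"],
              x$counts["n_catalog"], x$counts["n_catalog_raw"]))
  cat(sprintf("  graph: %d nodes, %d edges; complexity score %s\n",
              x$counts["n_nodes"], x$counts["n_edges"],
              if (x$complexity$computable)
                sprintf("%.4f", x$complexity$score) else "not computable"))
  nm <- x$network_metrics
  cat(sprintf("  network: %.2f bursts/min, I.C.V. %s, mean synchrony %.3f\n",
              nm$frequency_bpm,
              if (is.na(nm$icv)) "NA" else sprintf("%.3f", nm$icv),
              x$synchrony$mean))
  invisible(x)
}

write_manifest <- function(path, config, counts, files, warnings = character(0)) {
  manifest <- list(
    package = "circuitnet",
    version = as.character(utils::packageVersion("circuitnet")),
    config = unclass(config),
    counts = as.list(counts),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    warnings = warnings
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a movie and write it with its ground truth
#'
#' Renders a synthetic movie, writes `movie.tif`, `schedules.csv`,
#' `partition.csv`, and a `manifest.json` with configuration, stage counts,
#' and file checksums. Identical configurations produce byte-identical
#' outputs.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of output paths, invisibly.
#' @export
run_simulate <- function(config = synth_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rendered <- render_movie(config)
  movie_path <- file.path(out_dir, "movie.tif")
  write_movie(rendered$movie, movie_path)
  gt <- write_ground_truth(rendered$truth, out_dir)
  files <- c(movie = movie_path, gt)
  counts <- c(n_frames = config$n_frames,
              n_bursts = nrow(rendered$truth$schedules),
              n_subnetworks = config$n_subnetworks)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, config, counts, files)
  invisible(c(files, manifest = manifest_path))
}

#' Analyze a movie and write all stage outputs
#'
#' Runs [analyze_movie()] and writes `traces_dff.csv`, `events.csv`,
#' `catalog.csv`, `sequences.csv`, `complexity.csv`, `metrics.csv`,
#' `synchrony.csv`, and `manifest.json` into `out_dir`.
#'
#' @param input A movie path or [movie_stack()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return The `"circuit_analysis"` object, invisibly.
#' @export
run_analyze <- function(input, config = pipeline_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- analyze_movie(input, config)
  dd <- res$traces_dff$values
  tdf <- data.frame(roi_id = seq_len(nrow(dd)), dd)
  names(tdf)[-1] <- sprintf("t_%.3f", (seq_len(ncol(dd)) - 1) / res$traces_dff$fps)
  seqs <- res$catalog$sequences
  seq_df <- do.call(rbind, lapply(seq_along(seqs), function(r) {
    if (length(seqs[[r]]) == 0L) return(NULL)
    data.frame(roi_id = r, position = seq_along(seqs[[r]]),
               catalog_id = seqs[[r]])
  }))
  if (is.null(seq_df)) {
    seq_df <- data.frame(roi_id = integer(0), position = integer(0),
                         catalog_id = integer(0))
  }
  cx <- res$complexity
  cx_df <- data.frame(n_nodes = cx$n_nodes, n_edges = cx$n_edges,
                      out_ratio = cx$out_ratio, in_ratio = cx$in_ratio,
                      score = cx$score, variant = cx$variant)
  files <- file.path(out_dir, c("traces_dff.csv", "events.csv", "catalog.csv",
                                "sequences.csv", "complexity.csv",
                                "metrics.csv", "synchrony.csv"))
  utils::write.csv(tdf, files[1], row.names = FALSE)
  utils::write.csv(res$events, files[2], row.names = FALSE)
  utils::write.csv(res$catalog$entries, files[3], row.names = FALSE)
  utils::write.csv(seq_df, files[4], row.names = FALSE)
  utils::write.csv(cx_df, files[5], row.names = FALSE)
  utils::write.csv(res$roi_metrics, files[6], row.names = FALSE)
  utils::write.csv(res$synchrony$matrix, files[7], row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, config, res$counts, as.list(files))
  invisible(res)
}

#' Compare two groups of per-movie metric values
#'
#' Applies the statistic appropriate to the metric: the two-sample
#' Kolmogorov-Smirnov test with bootstrap median standard errors for the
#' complexity score, a Student t-test (paired or unpaired) for all other
#' metrics.
#'
#' @param a,b Numeric vectors of per-movie values.
#' @param metric One of `"complexity"`, `"frequency"`, `"icv"`,
#'   `"amplitude"`, `"synchrony"`.
#' @param paired Paired t-test? (ignored for complexity).
#' @param n_boot,seed Bootstrap settings for the complexity medians.
#' @return A list with the test results and per-group summaries.
#' @export
run_compare <- function(a, b, metric = c("complexity", "frequency", "icv",
                                         "amplitude", "synchrony"),
                        paired = FALSE, n_boot = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  if (metric == "complexity") {
    ks <- compare_groups_ks(a, b)
    seed_b <- if (is.null(seed)) NULL else seed + 1L
    list(metric = metric, test = "ks",
         statistic = ks$statistic, p_value = ks$p_value, regime = ks$regime,
         group_a = bootstrap_median_se(a, n_boot, seed),
         group_b = bootstrap_median_se(b, n_boot, seed_b))
  } else {
    tt <- group_ttest(a, b, paired = paired)
    list(metric = metric, test = tt$method,
         statistic = tt$t, p_value = tt$p_value, df = tt$df,
         computable = tt$computable,
         group_a = list(mean = mean(a), sd = stats::sd(a), n = length(a)),
         group_b = list(mean = mean(b), sd = stats::sd(b), n = length(b)))
  }
}
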