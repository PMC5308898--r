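# Lazily built, cached fixtures shared across test files. All synthetic
# movies for routine tests use a 64x64 field (36 ROIs) over two minutes at
# 20 fps; a 32x32 one-minute "tiny" movie serves the cheapest smoke tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

rhythmic_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_frames = 2400L, height = 64L, width = 64L, seed = seed),
    list(...)
  )
  do.call(synth_config, args)
}

tiny_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_frames = 1200L, height = 32L, width = 32L, seed = seed),
    list(...)
  )
  do.call(synth_config, args)
}

rhythmic_render <- function() {
  fixture("rhythmic_render", function() render_movie(rhythmic_config()))
}

rhythmic_analysis <- function() {
  fixture("rhythmic_analysis", function() {
    analyze_movie(rhythmic_render()$movie, pipeline_config())
  })
}

irregular_render <- function() {
  fixture("irregular_render", function() {
    render_movie(rhythmic_config(seed = 12, period_jitter_cv = 0.5))
  })
}

irregular_analysis <- function() {
  fixture("irregular_analysis", function() {
    analyze_movie(irregular_render()$movie, pipeline_config())
  })
}

segmented_render <- function() {
  fixture("segmented_render", function() {
    render_movie(rhythmic_config(seed = 13, n_subnetworks = 2,
                                 period_jitter_cv = 0.5,
                                 shared_fraction = 0.3))
  })
}

# ROI -> subnetwork label for a stripe partition: label of the ROI center,
# NA for ROIs whose footprint straddles a stripe boundary
roi_subnetwork <- function(grid, partition) {
  vapply(seq_len(nrow(grid$centers)), function(r) {
    top <- grid$centers$top[r]; left <- grid$centers$left[r]
    s <- grid$roi_size
    labs <- unique(as.vector(partition[top:(top + s - 1),
                                       left:(left + s - 1)]))
    if (length(labs) == 1L) labs else NA_integer_
  }, integer(1))
}
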