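#' Build the directed burst-sequence graph
#'
#' Nodes are catalog entries; for every ROI, a directed edge joins each pair
#' of bursts that occurred adjacently in that ROI's sequence (no burst
#' between them), pointing forward in time. The edge set is deduplicated
#' across ROIs, so many ROIs sharing the same sequence contribute each edge
#' once.
#'
#' @param sequences List of per-ROI integer vectors of catalog ids in time
#'   order (e.g. the `sequences` of a filtered [catalog_bursts()]).
#' @return An object of class `"burst_graph"`: sorted `nodes` vector and an
#'   `edges` data frame (`from`, `to`).
#' @export
build_graph <- function(sequences) {
  if (inherits(sequences, "burst_catalog")) sequences <- sequences$sequences
  stopifnot(is.list(sequences))
  pairs <- lapply(sequences, function(s) {
    if (length(s) < 2L) return(NULL)
    cbind(from = s[-length(s)], to = s[-1])
  })
  pairs <- do.call(rbind, pairs)
  nodes <- sort(unique(unlist(sequences)))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0),
                                             to = integer(0))),
                     class = "burst_graph"))
  }
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(nodes = nodes,
                 edges = data.frame(from = pairs[, 1], to = pairs[, 2])),
            class = "burst_graph")
}

#' @export
print.burst_graph <- function(x, ...) {
  cat(sprintf("<burst_graph> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network complexity score of a burst graph
#'
#' Quantifies how far the ROI burst sequences deviate from one shared
#' sequence. Under the canonical `"degree_ratio"` definition,
#' `out_ratio = n_edges / #\{nodes with >= 1 outgoing edge\}` (the mean
#' out-degree among source nodes) and `in_ratio` likewise for incoming
#' edges; the score is their mean. A movie in which every ROI has the same
#' sequence yields a simple chain and scores exactly 1; sharing some but
#' not all bursts gives nodes more than one incoming or outgoing edge and
#' pushes the score above 1. The `"literal_fraction"` variant instead
#' reports the fraction of nodes with more than one outgoing (incoming)
#' edge; it is provided for comparison but scores 0, not 1, on a chain.
#'
#' @param graph A [build_graph()] result.
#' @param variant `"degree_ratio"` (canonical) or `"literal_fraction"`.
#' @return An object of class `"complexity_result"`: `score`, `out_ratio`,
#'   `in_ratio`, `n_nodes`, `n_edges`, `variant`, and `computable`. A graph
#'   with no edges is not scoreable: `score` is `NA` and `computable` is
#'   `FALSE`.
#' @export
complexity_score <- function(graph, variant = c("degree_ratio",
                                                "literal_fraction")) {
  stopifnot(inherits(graph, "burst_graph"))
  variant <- match.arg(variant)
  m <- nrow(graph$edges)
  n <- length(graph$nodes)
  if (m == 0L) {
    return(structure(list(score = NA_real_, out_ratio = NA_real_,
                          in_ratio = NA_real_, n_nodes = n, n_edges = 0L,
                          variant = variant, computable = FALSE),
                     class = "complexity_result"))
  }
  outdeg <- table(graph$edges$from)
  indeg <- table(graph$edges$to)
  if (variant == "degree_ratio") {
    out_ratio <- m / length(outdeg)
    in_ratio <- m / length(indeg)
  } else {
    out_ratio <- sum(outdeg > 1) / n
    in_ratio <- sum(indeg > 1) / n
  }
  structure(list(score = (out_ratio + in_ratio) / 2, out_ratio = out_ratio,
                 in_ratio = in_ratio, n_nodes = n, n_edges = m,
                 variant = variant, computable = TRUE),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  if (!x$computable) {
    cat("<complexity_result> not computable (no edges)\n")
  } else {
    cat(sprintf("<complexity_result> score %.4f (out %.4f, in %.4f; %d nodes, %d edges, %s)\n",
                x$score, x$out_ratio, x$in_ratio, x$n_nodes, x$n_edges,
                x$variant))
  }
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of score groups
#'
#' Two-sided two-sample KS test, the group comparison of choice for the
#' complexity score (non-normal, unequal variances). The exact p-value is
#' used when the combined sample size is at most 25, the asymptotic
#' approximation otherwise; the regime is reported.
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 2.
#' @return A list: `statistic` (D), `p_value`, `regime` (`"exact"` or
#'   `"asymptotic"`), `n_a`, `n_b`.
#' @export
compare_groups_ks <- function(scores_a, scores_b) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  exact <- (length(scores_a) + length(scores_b)) <= 25L
  kt <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = exact))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       regime = if (exact) "exact" else "asymptotic",
       n_a = length(scores_a), n_b = length(scores_b))
}

#' Bootstrap standard error of the median
#'
#' Resamples with replacement `n_boot` times and reports the standard
#' deviation of the resample medians.
#'
#' @param scores Numeric vector of length >= 2.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @return A list: `median`, `se`, `n_boot`.
#' @export
bootstrap_median_se <- function(scores, n_boot = 1000L, seed = NULL) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  stop_if_not_scalar_pos(n_boot, "n_boot")
  meds <- with_seed(seed, {
    res <- matrix(sample(scores, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(res, 1L, stats::median)
  })
  list(median = stats::median(scores), se = stats::sd(meds),
       n_boot = as.integer(n_boot))
}
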