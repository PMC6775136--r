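#' Randomized greedy agglomerative partitioning
#'
#' The stochastic base algorithm used to seed and refresh ensembles. Starting
#' from singleton communities it repeatedly samples `sample_size` communities
#' uniformly at random among those that still have neighbours, scans every
#' merge of a sampled community with one of its neighbouring communities, and
#' applies the merge with the largest modularity gain (ties broken by the
#' lowest community-id pair). Negative-gain merges are permitted so the
#' agglomeration completes; modularity is recorded at every level of the
#' resulting dendrogram and the partition at the best-scoring level (earliest
#' on ties) is returned. Communities in different connected components never
#' become neighbours and are therefore never merged, which cannot hurt: the
#' per-component partition always scores at least as well.
#'
#' @param graph A `reneel_graph` (or edge data frame) with positive total
#'   weight.
#' @param sample_size Number of communities sampled per merge step; the
#'   classic randomized greedy uses 2 (default).
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   consumed, so callers can manage reproducibility at a higher level.
#' @return A `reneel_partition`: canonical membership vector plus cached
#'   modularity `q`.
#' @examples
#' g <- ring_of_cliques(4, 5)$graph
#' randomized_greedy(g, seed = 1)
#' @export
randomized_greedy <- function(graph, sample_size = 2, seed = NULL) {
  graph <- as_reneel_graph(graph)
  if (graph$m <= 0) abort("graph has no edges.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- graph$edges
  res <- .rg_run(graph$n, e$from, e$to, e$weight, graph$m,
                 as.integer(sample_size))
  new_partition(graph, res$membership)
}

# Per-run seeds spawned from the current RNG stream. sample.int draws
# sequentially, so the first k seeds of a longer stream equal the shorter
# stream drawn under the same state (nested-ensemble monotonicity relies on
# this).
spawn_seeds <- function(k) {
  sample.int(2147483646L, k)
}

#' Generate an ensemble of base-algorithm partitions
#'
#' Runs the base partitioner `k` times with independently spawned seeds and
#' drops duplicate partitions (canonical-form equality), so the result holds
#' at most `k` distinct partitions.
#'
#' @inheritParams randomized_greedy
#' @param k Number of base runs.
#' @param base Optional base partitioner, any `function(graph)` returning a
#'   `reneel_partition`; defaults to [randomized_greedy()] with the given
#'   `sample_size`.
#' @return A list of distinct `reneel_partition` objects.
#' @export
make_ensemble <- function(graph, k, sample_size = 2, seed = NULL, base = NULL) {
  graph <- as_reneel_graph(graph)
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- base %||% function(g) randomized_greedy(g, sample_size = sample_size)
  seeds <- spawn_seeds(k)
  parts <- lapply(seeds, function(s) {
    set.seed(s)
    base(graph)
  })
  keys <- vapply(parts, function(p) p$key, "")
  parts[!duplicated(keys)]
}

#' Naive ensemble analysis: best of k base runs
#'
#' The conventional comparator scheme: run the base algorithm `k` times and
#' keep the partition with the largest modularity (earliest run on ties).
#' Seeds are spawned exactly as in [make_ensemble()], so for a fixed `seed`
#' the result is monotone non-decreasing in `k`.
#'
#' @inheritParams make_ensemble
#' @return The best `reneel_partition` found.
#' @export
naive_best <- function(graph, k, sample_size = 2, seed = NULL, base = NULL) {
  graph <- as_reneel_graph(graph)
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- base %||% function(g) randomized_greedy(g, sample_size = sample_size)
  seeds <- spawn_seeds(k)
  best <- NULL
  for (s in seeds) {
    set.seed(s)
    p <- base(graph)
    if (is.null(best) || p$q > best$q) best <- p
  }
  best
}
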