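#' Co-clustering matrix of a partition ensemble
#'
#' Entry \eqn{s_{ij}} is the fraction of partitions in which nodes `i` and
#' `j` share a community; the diagonal is 1 and entries equal to 1 off the
#' diagonal mark pairs inside one core group.
#'
#' @param partitions A non-empty list of partitions or membership vectors
#'   over a common node set.
#' @param labels Optional node labels for the dimnames.
#' @return A symmetric numeric matrix with entries in `[0, 1]`.
#' @examples
#' co_cluster_matrix(list(c(1, 1, 2), c(1, 2, 2)))
#' @export
co_cluster_matrix <- function(partitions, labels = NULL) {
  if (length(partitions) == 0) abort("need at least one partition.")
  membs <- lapply(partitions, function(p) {
    if (is_partition(p)) p$membership else as.integer(p)
  })
  n <- length(membs[[1]])
  if (!all(lengths(membs) == n)) abort("partitions cover different node sets.")
  s <- matrix(0, n, n)
  for (m in membs) s <- s + outer(m, m, "==")
  s <- s / length(membs)
  if (!is.null(labels)) dimnames(s) <- list(labels, labels)
  s
}

#' Seriation cost of a node order
#'
#' The cost (a "Hamiltonian") of displaying a co-clustering matrix in a given
#' node order: \eqn{H = \sum_{i<j} s_{ij} d_{ij}^\alpha}, where \eqn{d_{ij}}
#' is the circular distance between the positions of `i` and `j`,
#' `min(|p_i - p_j|, n - |p_i - p_j|)`. Low cost concentrates large
#' co-clustering values near the diagonal. `H` is invariant under rotations
#' and reflections of the circular order.
#'
#' @param s A co-clustering matrix.
#' @param order An integer permutation of `1..n`; `order[p]` is the node
#'   shown at position `p`.
#' @param alpha Exponent on the circular distance (default 3).
#' @return The cost, a non-negative number.
#' @export
seriation_cost <- function(s, order, alpha = 3) {
  n <- nrow(s)
  order <- as.integer(order)
  if (length(order) != n || !identical(sort(order), seq_len(n))) {
    abort("`order` must be a permutation of 1..n.")
  }
  pos <- integer(n)
  pos[order] <- seq_len(n)
  a <- abs(outer(pos, pos, "-"))
  d <- pmin(a, n - a)
  ut <- upper.tri(s)
  sum(s[ut] * d[ut]^alpha)
}

#' Anneal a node order for a co-clustering matrix
#'
#' Minimizes [seriation_cost()] by simulated annealing over random pair
#' swaps with Metropolis acceptance (Boltzmann factor `exp(-dH/T)`) and
#' geometric cooling, starting from the identity order at a temperature high
#' enough to randomize it. The best order seen anywhere in the run is
#' returned, so the result never costs more than the starting order.
#'
#' @inheritParams seriation_cost
#' @param t_start Initial temperature; `NULL` picks 10 times the standard
#'   deviation of the cost change over 100 random swap proposals.
#' @param cooling Geometric cooling factor per stage, in (0, 1).
#' @param sweeps Proposed swaps per temperature stage (default `n^2`, at
#'   least 100).
#' @param stall_stages Stop after this many consecutive stages with no
#'   accepted cost-changing move.
#' @param max_stages Hard cap on the number of stages.
#' @param groups Optional integer grouping of nodes restricting swaps to
#'   pairs within one group (a hook for hierarchy-constrained seriation).
#' @param seed Optional integer seed.
#' @return A `seriation_order`: list with the `order` permutation, its cost
#'   `h`, the starting cost `h_start`, the temperature used `t_start`, and
#'   the number of `stages` run.
#' @export
anneal_order <- function(s, alpha = 3, t_start = NULL, cooling = 0.98,
                         sweeps = NULL, stall_stages = 3, max_stages = 3000,
                         groups = NULL, seed = NULL) {
  n <- nrow(s)
  if (n < 2) abort("need at least two nodes to seriate.")
  if (!isTRUE(all.equal(s, t(s)))) abort("`s` must be symmetric.")
  if (cooling <= 0 || cooling >= 1) abort("`cooling` must be in (0, 1).")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sweeps <- sweeps %||% max(n^2, 100L)
  groups <- if (is.null(groups)) integer(0) else canonical_form(as.integer(groups))
  res <- .anneal_run(s, alpha, t_start %||% -1, cooling,
                     as.integer(sweeps), as.integer(stall_stages),
                     as.integer(max_stages), as.integer(groups))
  structure(
    list(order = res$order, h = res$h, h_start = res$h_start,
         t_start = res$t_start, stages = res$stages, alpha = alpha),
    class = "seriation_order"
  )
}

#' @export
print.seriation_order <- function(x, ...) {
  cat("Seriation of ", length(x$order), " nodes: H = ",
      format(x$h, digits = 8), " (start ", format(x$h_start, digits = 8),
      ", alpha = ", x$alpha, ", ", x$stages, " stages)\n", sep = "")
  invisible(x)
}

#' Heat-map of an ordered co-clustering matrix
#'
#' @param object A co-clustering matrix (as returned by
#'   [co_cluster_matrix()]).
#' @param order Optional node order, e.g. `anneal_order(s)$order`.
#' @return A ggplot object.
#' @export
plot_cocluster <- function(object, order = NULL) {
  n <- nrow(object)
  order <- order %||% seq_len(n)
  so <- object[order, order]
  df <- tibble(
    i = rep(seq_len(n), times = n),
    j = rep(seq_len(n), each = n),
    s = as.vector(so)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "s")
}

#' Write a co-clustering matrix as TSV
#'
#' @param s The matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cocluster <- function(s, path) {
  utils::write.table(s, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
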