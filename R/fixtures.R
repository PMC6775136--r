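#' Planted-partition random graph
#'
#' Generates a graph with `blocks` blocks of `block_size` nodes each;
#' within-block node pairs receive an edge independently with probability
#' `p_in`, cross-block pairs with probability `p_out < p_in`. The planted
#' block structure is returned alongside the graph and serves as ground
#' truth for recovery tests.
#'
#' @param blocks Number of blocks.
#' @param block_size Nodes per block.
#' @param p_in,p_out Within- and cross-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed Optional integer seed.
#' @param connected Regenerate until the graph is connected (up to
#'   `max_tries` attempts).
#' @param max_tries Attempt bound when `connected = TRUE`, and for drawing a
#'   non-empty graph.
#' @return A list with the `graph` and the planted `membership` vector.
#' @examples
#' pp <- planted_partition(4, 25, 0.3, 0.01, seed = 1)
#' pp$graph
#' @export
planted_partition <- function(blocks, block_size, p_in = 0.3, p_out = 0.01,
                              seed = NULL, connected = FALSE,
                              max_tries = 100) {
  stopifnot(blocks >= 1, block_size >= 1)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- blocks * block_size
  memb <- rep(seq_len(blocks), each = block_size)
  pairs_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pairs_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  p <- ifelse(memb[pairs_i] == memb[pairs_j], p_in, p_out)
  for (try in seq_len(max_tries)) {
    keep <- runif(length(p)) < p
    if (!any(keep)) next
    g <- new_graph(pairs_i[keep], pairs_j[keep], rep(1, sum(keep)),
                   labels = as.character(seq_len(n)))
    if (!connected || n_components(g) == 1) {
      return(list(graph = g, membership = memb))
    }
  }
  abort(paste0("failed to generate a suitable graph in ", max_tries,
               " tries; raise the edge probabilities."))
}

#' Ring of cliques
#'
#' `K` cliques of `c` nodes each, with one link joining consecutive cliques
#' around a ring (last node of one clique to the first node of the next). A
#' standard analytic test case: with equal cliques each clique has internal
#' weight `choose(c, 2)` and exactly two external links.
#'
#' @param K Number of cliques (at least 3).
#' @param c Clique size (at least 3).
#' @return A list with the `graph` and the clique `membership` vector.
#' @examples
#' rc <- ring_of_cliques(4, 5)
#' rc$graph$m # 4 * (choose(5, 2) + 1) = 44
#' @export
ring_of_cliques <- function(K, c) {
  stopifnot(K >= 3, c >= 3)
  n <- K * c
  from <- integer(0)
  to <- integer(0)
  pairs <- utils::combn(c, 2)
  for (k in seq_len(K)) {
    off <- (k - 1) * c
    from <- c(from, pairs[1, ] + off)
    to <- c(to, pairs[2, ] + off)
  }
  for (k in seq_len(K)) {
    from <- c(from, k * c) # last node of clique k
    to <- c(to, (k %% K) * c + 1) # first node of clique k+1 (wrapping)
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  g <- new_graph(a, b, rep(1, length(a)), labels = as.character(seq_len(n)))
  list(graph = g, membership = rep(seq_len(K), each = c))
}

# number of connected components (BFS over adjacency lists)
n_components <- function(graph) {
  n <- graph$n
  e <- graph$edges
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    f <- e$from[r]
    t <- e$to[r]
    if (f != t) {
      adj[[f]] <- c(adj[[f]], t)
      adj[[t]] <- c(adj[[t]], f)
    }
  }
  seen <- logical(n)
  comps <- 0L
  for (v in seq_len(n)) {
    if (seen[v]) next
    comps <- comps + 1L
    queue <- v
    seen[v] <- TRUE
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  comps
}
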