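# Partition container: canonical membership plus the cached modularity of the
# graph it was computed on. All cached Q values flow through modularity_q(),
# keeping exact floating-point comparisons between partitions meaningful.
new_partition <- function(graph, membership) {
  memb <- canonical_form(as.integer(membership))
  if (length(memb) != graph$n) {
    abort("membership length does not match the node count.")
  }
  structure(
    list(
      membership = memb,
      q = modularity_q(graph, memb),
      n_communities = max(memb),
      key = paste(memb, collapse = ",")
    ),
    class = "reneel_partition"
  )
}

is_partition <- function(x) inherits(x, "reneel_partition")

# Accepts a partition object or a bare vector; returns a validated dense
# integer membership vector of length n.
membership_vector <- function(x, n) {
  memb <- if (is_partition(x)) x$membership else as.integer(x)
  if (length(memb) != n) {
    abort(paste0("membership covers ", length(memb), " nodes; graph has ",
                 n, "."))
  }
  if (anyNA(memb)) abort("membership contains missing values.")
  memb
}

#' @export
print.reneel_partition <- function(x, ...) {
  cat("Partition: ", x$n_communities, " communities over ",
      length(x$membership), " nodes, Q = ", format(x$q, digits = 10), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn randomized_greedy Tidy a partition into a `node`, `community`
#'   tibble (labels are attached when the originating graph is supplied via
#'   `graph`).
#' @param x A `reneel_partition`.
#' @param graph Optionally, the graph the partition belongs to.
#' @param ... Unused.
#' @export
tidy.reneel_partition <- function(x, graph = NULL, ...) {
  node <- if (!is.null(graph)) graph$labels else seq_along(x$membership)
  tibble(node = node, community = x$membership)
}
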