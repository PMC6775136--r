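#' Core groups of an ensemble of partitions
#'
#' A core group is a maximal set of nodes found together in the same
#' community in every partition of the ensemble; the core grouping is the
#' meet (coarsest common refinement) of the partitions. Any node not
#' co-membered with some other node in every partition forms a singleton
#' group.
#'
#' @param partitions A non-empty list of partitions (or membership vectors)
#'   over a common node set.
#' @return A `core_grouping`: list with `group_of` (dense group id per node,
#'   numbered by first appearance), `groups` (list of node-index sets), and
#'   `n_groups`.
#' @examples
#' core_groups(list(c(1, 1, 2), c(1, 2, 2)))$n_groups # crossing: 3 singletons
#' @export
core_groups <- function(partitions) {
  if (length(partitions) == 0) abort("need at least one partition.")
  membs <- lapply(partitions, function(p) {
    if (is_partition(p)) p$membership else as.integer(p)
  })
  n <- length(membs[[1]])
  if (!all(lengths(membs) == n)) {
    abort("partitions cover different node sets.")
  }
  g <- canonical_form(membs[[1]])
  for (p in membs[-1]) {
    comb <- paste(g, p)
    g <- match(comb, unique(comb))
  }
  structure(
    list(
      group_of = g,
      groups = unname(split(seq_len(n), g)),
      n_groups = max(g)
    ),
    class = "core_grouping"
  )
}

#' @export
print.core_grouping <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("Core grouping: ", x$n_groups, " groups over ", length(x$group_of),
      " nodes (", sum(sizes == 1), " singletons, largest ", max(sizes),
      ")\n", sep = "")
  invisible(x)
}

#' Collapse core groups into a weighted reduced network
#'
#' Each group becomes one reduced node; weights of original links between two
#' groups are summed into a single link, and the total weight internal to a
#' group (including any pre-existing self-loops) becomes the reduced node's
#' self-loop. Total weight is preserved, which together with the self-loop
#' strength convention makes modularity of any reduced-graph partition equal
#' to the modularity of its expansion on the original graph.
#'
#' @param graph The original `reneel_graph`.
#' @param grouping A `core_grouping` covering the graph's nodes.
#' @return A `reduced_graph`: list with the reduced `graph`, the per-node
#'   `group_of` map, and the `groups` expansion (group id to original node
#'   indices).
#' @export
reduce_graph <- function(graph, grouping) {
  stopifnot(inherits(graph, "reneel_graph"))
  if (length(grouping$group_of) != graph$n) {
    abort("grouping does not cover the graph's nodes.")
  }
  e <- graph$edges
  gf <- grouping$group_of[e$from]
  gt <- grouping$group_of[e$to]
  a <- pmin(gf, gt)
  b <- pmax(gf, gt)
  agg <- rowsum(e$weight, paste(a, b), reorder = FALSE)
  keep <- !duplicated(paste(a, b))
  rg <- new_graph(a[keep], b[keep], agg[, 1],
                  labels = as.character(seq_len(grouping$n_groups)))
  structure(
    list(graph = rg, group_of = grouping$group_of, groups = grouping$groups),
    class = "reduced_graph"
  )
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat("Reduced network over ", x$graph$n, " core groups (original n = ",
      length(x$group_of), ")\n", sep = "")
  print(x$graph)
  invisible(x)
}

#' Expand a reduced-network partition onto the original graph
#'
#' Every original node inherits the community of its core group; the
#' partition's modularity is recomputed on the original graph (and equals the
#' reduced-graph value up to floating-point summation order).
#'
#' @param partition A partition of the reduced graph.
#' @param reduced The `reduced_graph` the partition belongs to.
#' @param graph The original graph.
#' @return A `reneel_partition` of the original graph.
#' @export
expand_partition <- function(partition, reduced, graph) {
  memb <- membership_vector(partition, reduced$graph$n)
  new_partition(graph, memb[reduced$group_of])
}

#' Bounded, Q-ordered partition ensemble
#'
#' Wraps a list of partitions of one graph as an ensemble: duplicates
#' (canonical form) are dropped and members are ordered by modularity,
#' best first.
#'
#' @param partitions A list of `reneel_partition` objects, e.g. from
#'   [make_ensemble()].
#' @param k_max Capacity of the ensemble.
#' @return A `reneel_ensemble`.
#' @export
partition_ensemble <- function(partitions, k_max = length(partitions)) {
  stopifnot(length(partitions) >= 1, k_max >= 1,
            all(vapply(partitions, is_partition, TRUE)))
  ens <- new_ensemble(partitions, k_max)
  if (length(ens$members) > k_max) {
    ens$members <- ens$members[seq_len(k_max)]
  }
  ens
}

# Bounded, Q-ordered ensemble of distinct partitions of the original graph.
new_ensemble <- function(partitions, k_max) {
  keys <- vapply(partitions, function(p) p$key, "")
  partitions <- partitions[!duplicated(keys)]
  qs <- vapply(partitions, function(p) p$q, 0)
  structure(
    list(members = partitions[order(-qs)], k_max = k_max),
    class = "reneel_ensemble"
  )
}

ensemble_qs <- function(ens) vapply(ens$members, function(p) p$q, 0)

#' Extremal update of a partition ensemble
#'
#' Applies one extremal-updating step with a candidate partition of the
#' original graph. If the candidate is already in the ensemble (canonical
#' form), the worst member is deleted (`"duplicate"`). Otherwise, if its
#' modularity strictly exceeds the worst member's, it is inserted in Q-order,
#' replacing the worst member when the ensemble is at capacity
#' (`"accepted"`). Otherwise the worst member is deleted (`"rejected"`). The
#' equality case counts as not better and follows the rejection branch.
#'
#' @param ensemble A `reneel_ensemble`, see [partition_ensemble()].
#' @param candidate A `reneel_partition` of the original graph.
#' @return A list with the updated `ensemble` and the `outcome` tag
#'   (`"duplicate"`, `"accepted"` or `"rejected"`).
#' @export
extremal_update <- function(ensemble, candidate) {
  stopifnot(inherits(ensemble, "reneel_ensemble"), is_partition(candidate))
  members <- ensemble$members
  k <- length(members)
  stopifnot(k >= 1)
  keys <- vapply(members, function(p) p$key, "")
  if (candidate$key %in% keys) {
    ensemble$members <- members[-k]
    return(list(ensemble = ensemble, outcome = "duplicate"))
  }
  qs <- vapply(members, function(p) p$q, 0)
  if (candidate$q > qs[k]) {
    pos <- sum(qs >= candidate$q)
    members <- append(members, list(candidate), after = pos)
    if (k == ensemble$k_max) members <- members[-(k + 1)]
    ensemble$members <- members
    return(list(ensemble = ensemble, outcome = "accepted"))
  }
  ensemble$members <- members[-k]
  list(ensemble = ensemble, outcome = "rejected")
}

#' @export
print.reneel_ensemble <- function(x, ...) {
  qs <- ensemble_qs(x)
  cat("Partition ensemble: k = ", length(qs), " (capacity ", x$k_max,
      "), Q in [", format(min(qs), digits = 8), ", ",
      format(max(qs), digits = 8), "]\n", sep = "")
  invisible(x)
}

#' Reduced network extremal ensemble learning
#'
#' Finds a high-modularity partition of an undirected network by extremal
#' ensemble learning. An ensemble of at most `k_max` distinct partitions is
#' produced by the base algorithm; then, until the ensemble reaches
#' consensus (size 1), each iteration (i) identifies the core groups shared
#' by every ensemble member, (ii) collapses them into a weighted reduced
#' network, (iii) partitions the reduced network `k_prime` times with the
#' base algorithm, and (iv) uses the best of those partitions, expanded back
#' to the original nodes, in an extremal update of the ensemble (see
#' [extremal_update()]). The surviving partition is the consensus estimate of
#' the modularity-maximizing partition.
#'
#' Acceptance into the ensemble requires strictly beating the worst member,
#' and the ensemble size is bounded, so the scheme always terminates. Core
#' groups can only coarsen from one iteration to the next: every new member
#' is a union of current core groups.
#'
#' @param x A `reneel_graph` or an edge data frame (see [as_reneel_graph()]).
#' @param k_max Ensemble capacity (default 100).
#' @param k_prime Number of reduced-network partitions generated per
#'   iteration (default 20).
#' @param sample_size Sample size of the default randomized greedy base.
#' @param seed Optional integer seed making the whole run deterministic.
#' @param base Optional base partitioner `function(graph) -> partition` used
#'   for the initial ensemble.
#' @param reduced_base Base partitioner for the reduced networks; defaults to
#'   `base`.
#' @param weighted,allow_self_loops Passed to [as_reneel_graph()] when `x` is
#'   an edge data frame.
#' @param diagnostics Keep the per-iteration core groupings in the fit (as
#'   `groupings`, a list of group-id vectors); used to inspect the
#'   agglomerative growth of core groups.
#' @return A `reneel_fit` with the consensus `partition`, its modularity `q`,
#'   the per-iteration `trace` tibble (`iteration`, `q_best`, `q_worst`,
#'   `q_candidate`, `n_reduced`, `k`), and run metadata. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' two_tri <- data.frame(
#'   from = c("a", "b", "a", "x", "y", "x"),
#'   to   = c("b", "c", "c", "y", "z", "z")
#' )
#' fit <- reneel(two_tri, k_max = 10, seed = 1)
#' glance(fit)
#' @export
reneel <- function(x, k_max = 100, k_prime = 20, sample_size = 2, seed = NULL,
                   base = NULL, reduced_base = NULL, weighted = NULL,
                   allow_self_loops = TRUE, diagnostics = FALSE) {
  graph <- as_reneel_graph(x, weighted = weighted,
                           allow_self_loops = allow_self_loops)
  stopifnot(k_max >= 1, k_prime >= 1)
  if (graph$m <= 0) abort("graph has no edges.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- base %||% function(g) randomized_greedy(g, sample_size = sample_size)
  reduced_base <- reduced_base %||% base

  ens <- new_ensemble(make_ensemble(graph, k_max, base = base), k_max)

  empty_trace <- tibble(
    iteration = integer(), q_best = numeric(), q_worst = numeric(),
    q_candidate = numeric(), n_reduced = integer(), k = integer()
  )
  rows <- list()
  groupings <- list()
  iter <- 0L
  final_groups <- NA_integer_

  # k_max = 1 (or an ensemble that deduplicated to one member): consensus
  # pre-exists, terminate before any iteration.
  while (length(ens$members) > 1) {
    iter <- iter + 1L
    cg <- core_groups(ens$members)
    red <- reduce_graph(graph, cg)
    final_groups <- cg$n_groups
    if (diagnostics) groupings[[iter]] <- cg$group_of

    prime_seeds <- spawn_seeds(k_prime)
    best_rp <- NULL
    for (s in prime_seeds) {
      set.seed(s)
      rp <- reduced_base(red$graph)
      if (is.null(best_rp) || rp$q > best_rp$q) best_rp <- rp
    }
    candidate <- expand_partition(best_rp, red, graph)
    # reduction/expansion must preserve modularity (P1)
    if (abs(candidate$q - best_rp$q) > 1e-12) {
      abort(paste0("internal error: reduced-network modularity ",
                   format(best_rp$q, digits = 17),
                   " does not match expanded value ",
                   format(candidate$q, digits = 17)))
    }

    qs <- ensemble_qs(ens)
    upd <- extremal_update(ens, candidate)
    ens <- upd$ensemble
    rows[[iter]] <- tibble(
      iteration = iter, q_best = qs[1], q_worst = qs[length(qs)],
      q_candidate = candidate$q, n_reduced = red$graph$n,
      k = length(ens$members)
    )
  }

  consensus <- ens$members[[1]]
  if (is.na(final_groups)) final_groups <- consensus$n_communities
  structure(
    list(
      partition = consensus,
      membership = consensus$membership,
      q = consensus$q,
      n_communities = consensus$n_communities,
      trace = if (iter > 0) dplyr::bind_rows(rows) else empty_trace,
      iterations = iter,
      final_core_groups = final_groups,
      k_max = k_max,
      k_prime = k_prime,
      seed = seed,
      graph = graph,
      groupings = if (diagnostics) groupings else NULL
    ),
    class = "reneel_fit"
  )
}

#' @export
print.reneel_fit <- function(x, ...) {
  cat("Extremal ensemble learning consensus\n")
  cat("  nodes: ", x$graph$n, ", total weight m = ", format(x$graph$m),
      "\n", sep = "")
  cat("  Q = ", format(x$q, digits = 10), " over ", x$n_communities,
      " communities\n", sep = "")
  cat("  ", x$iterations, " iterations (k_max = ", x$k_max, ", k' = ",
      x$k_prime, "), ", x$final_core_groups,
      " core groups at termination\n", sep = "")
  invisible(x)
}

#' @describeIn reneel Node-level results: tibble with `node` (original
#'   label) and `community`.
#' @param ... Unused.
#' @export
tidy.reneel_fit <- function(x, ...) {
  tibble(node = x$graph$labels, community = x$membership)
}

#' @describeIn reneel One-row run summary.
#' @export
glance.reneel_fit <- function(x, ...) {
  tibble(
    q = x$q, n_communities = x$n_communities, n_nodes = x$graph$n,
    m = x$graph$m, iterations = x$iterations,
    final_core_groups = x$final_core_groups, k_max = x$k_max,
    k_prime = x$k_prime
  )
}

#' @describeIn reneel Trace plot of the run: modularity of the best and worst
#'   ensemble members and of each candidate (`what = "modularity"`), the
#'   reduced-network size (`"size"`), or the ensemble size (`"ensemble"`),
#'   per iteration.
#' @param object A `reneel_fit`.
#' @param what Which trace panel to draw.
#' @export
autoplot.reneel_fit <- function(object,
                                what = c("modularity", "size", "ensemble"),
                                ...) {
  what <- match.arg(what)
  tr <- object$trace
  if (nrow(tr) == 0) abort("no iterations were run; nothing to plot.")
  if (what == "modularity") {
    long <- tidyr::pivot_longer(
      tr[, c("iteration", "q_best", "q_worst", "q_candidate")],
      cols = -"iteration", names_to = "series", values_to = "q"
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$q,
                                       colour = .data$series)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::geom_line(alpha = 0.5) +
      ggplot2::labs(x = "iteration", y = "modularity Q", colour = NULL)
  } else if (what == "size") {
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration,
                                     y = .data$n_reduced)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "reduced network size (core groups)")
  } else {
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$k)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "iteration", y = "ensemble size k")
  }
}

#' Write the per-iteration trace of a run
#'
#' @param fit A `reneel_fit`.
#' @param path Output TSV path (columns `iteration`, `q_best`, `q_worst`,
#'   `q_candidate`, `n_reduced`, `k`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "reneel_fit"))
  utils::write.table(fit$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
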