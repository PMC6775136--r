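#' Modularity of a partition
#'
#' Evaluates Newman-Girvan modularity
#' \deqn{Q = \sum_i \left[ \frac{m_i}{m} -
#'   \left(\frac{2 m_i + e_i}{2m}\right)^2 \right],}
#' where the sum runs over communities, \eqn{m_i} and \eqn{e_i} are the
#' internal and external weight of community \eqn{i}, and \eqn{m} is the total
#' weight of the graph. On weighted graphs all three are sums of link weights.
#' A self-loop counts once in \eqn{m} and \eqn{m_i} and twice in its node's
#' strength.
#'
#' All modularity values the package compares against each other come from
#' this one accumulation routine (community sums in sorted community order),
#' so exact floating-point comparisons between partitions of the same graph
#' are well defined.
#'
#' @param graph A `reneel_graph` with `m > 0`.
#' @param membership A partition object or an integer membership vector
#'   covering every node.
#' @return A single number in `[-1, 1)`.
#' @examples
#' tri <- as_reneel_graph(data.frame(a = c(1, 2, 1), b = c(2, 3, 3)))
#' modularity_q(tri, c(1, 1, 1)) # one community: 0
#' modularity_q(tri, c(1, 2, 3)) # singletons: -1/3
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(inherits(graph, "reneel_graph"))
  if (graph$m <= 0) abort("modularity is undefined on a graph with m = 0.")
  memb <- membership_vector(membership, graph$n)
  e <- graph$edges
  cf <- memb[e$from]
  ct <- memb[e$to]
  internal <- cf == ct
  s_c <- rowsum(graph$strength, memb) # one row per community, sorted ids
  m_c <- numeric(nrow(s_c))
  if (any(internal)) {
    mi <- rowsum(e$weight[internal], cf[internal])
    m_c[match(rownames(mi), rownames(s_c))] <- mi[, 1]
  }
  sum(m_c / graph$m - (s_c[, 1] / (2 * graph$m))^2)
}

#' Per-community weight census
#'
#' @param graph A `reneel_graph`.
#' @param membership A partition or membership vector.
#' @return A tibble with one row per community: internal weight `m_internal`,
#'   external weight `w_external`, total incident strength, and size.
#' @export
community_stats <- function(graph, membership) {
  memb <- membership_vector(membership, graph$n)
  e <- graph$edges
  cf <- memb[e$from]
  ct <- memb[e$to]
  internal <- cf == ct
  s_c <- rowsum(graph$strength, memb)
  ids <- as.integer(rownames(s_c))
  m_c <- numeric(length(ids))
  if (any(internal)) {
    mi <- rowsum(e$weight[internal], cf[internal])
    m_c[match(rownames(mi), rownames(s_c))] <- mi[, 1]
  }
  tibble(
    community = ids,
    size = as.integer(tabulate(memb)[ids]),
    m_internal = m_c,
    w_external = s_c[, 1] - 2 * m_c,
    strength = s_c[, 1]
  )
}

#' Modularity gain of merging two communities
#'
#' Returns `Q(after merge) - Q(before)` for joining communities `a` and `b`:
#' \deqn{\Delta Q = 2\left[\frac{w_{ab}}{2m} -
#'   \frac{s_a s_b}{(2m)^2}\right],}
#' with \eqn{w_{ab}} the total weight between the two communities and
#' \eqn{s_x} the total strength incident to community \eqn{x}. Consistent
#' with recomputing [modularity_q()] on the merged partition.
#'
#' @inheritParams modularity_q
#' @param a,b Distinct community ids present in `membership`.
#' @return The modularity difference.
#' @export
merge_delta <- function(graph, membership, a, b) {
  memb <- membership_vector(membership, graph$n)
  if (a == b) abort("`a` and `b` must be distinct communities.")
  in_a <- memb == a
  in_b <- memb == b
  if (!any(in_a)) abort(paste0("unknown community id: ", a))
  if (!any(in_b)) abort(paste0("unknown community id: ", b))
  s_a <- sum(graph$strength[in_a])
  s_b <- sum(graph$strength[in_b])
  e <- graph$edges
  cf <- memb[e$from]
  ct <- memb[e$to]
  cross <- (cf == a & ct == b) | (cf == b & ct == a)
  w_ab <- sum(e$weight[cross])
  two_m <- 2 * graph$m
  2 * (w_ab / two_m - s_a * s_b / two_m^2)
}

#' Canonical form of a membership vector
#'
#' Relabels community ids by order of first appearance over the nodes, so two
#' memberships describe the same partition if and only if their canonical
#' forms are identical.
#'
#' @param membership A partition or membership vector.
#' @return An integer vector with dense community ids starting at 1.
#' @examples
#' canonical_form(c(5, 5, 2)) # 1 1 2
#' identical(canonical_form(c(0, 1, 0)), canonical_form(c(7, 3, 7)))
#' @export
canonical_form <- function(membership) {
  memb <- if (is_partition(membership)) membership$membership else membership
  match(memb, unique(memb))
}

# hashable key for partition equality tests
partition_key <- function(membership) {
  paste(canonical_form(membership), collapse = ",")
}
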