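# Independent oracles used to check the implementation. They deliberately
# take different routes than the package code.

# Term-by-term modularity: loop over communities, count internal/external
# weight explicitly, sum m_i/m - ((2 m_i + e_i)/(2m))^2.
oracle_modularity <- function(graph, memb) {
  memb <- as.integer(memb)
  e <- graph$edges
  m <- graph$m
  q <- 0
  for (cm in unique(memb)) {
    mi <- 0
    ei <- 0
    for (r in seq_len(nrow(e))) {
      fin <- memb[e$from[r]] == cm
      tin <- memb[e$to[r]] == cm
      if (fin && tin) {
        mi <- mi + e$weight[r]
      } else if (fin || tin) {
        ei <- ei + e$weight[r]
      }
    }
    q <- q + mi / m - ((2 * mi + ei) / (2 * m))^2
  }
  q
}

# Matrix-form modularity Q = sum_ij [A_ij - k_i k_j / (2m)] delta(c_i, c_j)
# / (2m), with A_ii twice the self-loop weight. Used for fast brute-force
# maximization on tiny graphs.
oracle_b_matrix <- function(graph) {
  n <- graph$n
  A <- matrix(0, n, n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    f <- e$from[r]
    t <- e$to[r]
    w <- e$weight[r]
    if (f == t) {
      A[f, f] <- A[f, f] + 2 * w
    } else {
      A[f, t] <- A[f, t] + w
      A[t, f] <- A[t, f] + w
    }
  }
  k <- rowSums(A)
  (A - outer(k, k) / (2 * graph$m)) / (2 * graph$m)
}

# All set partitions of n elements as membership vectors (restricted growth
# strings); Bell(8) = 4140.
set_partitions <- function(n) {
  parts <- list(integer(0))
  for (v in seq_len(n)) {
    nxt <- vector("list", 0)
    for (p in parts) {
      k <- if (length(p)) max(p) else 0L
      for (cm in seq_len(k + 1L)) nxt[[length(nxt) + 1L]] <- c(p, cm)
    }
    parts <- nxt
  }
  parts
}

# Exhaustive maximum modularity over all set partitions (n <= 9 only).
brute_q_max <- function(graph) {
  B <- oracle_b_matrix(graph)
  best <- -Inf
  best_memb <- NULL
  for (p in set_partitions(graph$n)) {
    q <- sum(B[outer(p, p, "==")])
    if (q > best) {
      best <- q
      best_memb <- p
    }
  }
  list(q = best, membership = best_memb)
}

# Pairwise meet: nodes grouped iff co-membered in every partition.
oracle_meet <- function(membs) {
  n <- length(membs[[1]])
  together <- matrix(TRUE, n, n)
  for (mm in membs) together <- together & outer(mm, mm, "==")
  group <- integer(n)
  g <- 0L
  for (v in seq_len(n)) {
    if (group[v] == 0L) {
      g <- g + 1L
      group[together[v, ]] <- g
    }
  }
  group
}

# Erdos-Renyi random graph through the planted-partition generator
# (one block, no cross pairs).
random_graph <- function(n, p = 0.4, seed = NULL, connected = FALSE) {
  planted_partition(1, n, p_in = p, p_out = 0, seed = seed,
                    connected = connected)$graph
}

# Random weighted graph with self-loops permitted (duplicate pairs sum).
random_weighted_graph <- function(n, n_edges = 3 * n) {
  df <- data.frame(i = sample(n, n_edges, TRUE), j = sample(n, n_edges, TRUE),
                   w = runif(n_edges, 0.2, 2))
  # ensure all n nodes appear so the label map covers them
  df <- rbind(df, data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1L),
                             w = runif(n, 0.2, 2)))
  as_reneel_graph(df)
}

random_membership <- function(n, k) {
  sample(seq_len(k), n, replace = TRUE)
}

# all permutations of 1..n, one per row (n <= 7 in practice)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

# does grouping `now` coarsen grouping `prev` (every prev group inside one
# now group)?
coarsens <- function(now, prev) {
  length(unique(paste(prev, now))) == length(unique(prev))
}

two_triangles <- function() {
  as_reneel_graph(data.frame(
    from = c("a", "b", "a", "x", "y", "x"),
    to = c("b", "c", "c", "y", "z", "z")
  ))
}
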