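#' Build an undirected weighted graph from an edge table
#'
#' Constructs the graph container used throughout the package from a data
#' frame of edges. Node labels may be arbitrary strings or integers; they are
#' remapped internally to dense ids `1..n` (the label map is kept and used for
#' all output). Parallel edges are merged: in unweighted input duplicate pairs
#' collapse to a single edge of weight 1, in weighted input their weights sum.
#'
#' A self-loop of weight `w` contributes `w` to the total weight `m` and `2w`
#' to its node's strength. Under this convention collapsing node groups into
#' reduced nodes (see [reduce_graph()]) preserves modularity exactly.
#'
#' @param x A data frame whose first two columns are edge endpoints and whose
#'   optional third column holds positive edge weights.
#' @param weighted If `NULL` (default), edges are weighted when a third column
#'   is present. Set `TRUE`/`FALSE` to force the interpretation; unweighted
#'   input ignores any weight column and treats repeated pairs as redundant
#'   listings of one link.
#' @param allow_self_loops Keep self-loops (`TRUE`, default for programmatic
#'   construction) or reject them with an error.
#' @return An object of class `reneel_graph`: a list with node count `n`,
#'   merged edge tibble (`from`, `to`, `weight`, with `from <= to`), total
#'   weight `m`, per-node `strength`, and the original `labels`.
#' @examples
#' tri <- as_reneel_graph(data.frame(from = c(0, 1, 0), to = c(1, 2, 2)))
#' tri$m
#' tri$strength
#' @export
as_reneel_graph <- function(x, weighted = NULL, allow_self_loops = TRUE) {
  if (inherits(x, "reneel_graph")) {
    return(x)
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("`x` must be a data frame with at least two columns (edge endpoints).")
  }
  u <- as.character(x[[1]])
  v <- as.character(x[[2]])
  weighted <- weighted %||% (ncol(x) >= 3)
  w <- if (weighted && ncol(x) >= 3) as.numeric(x[[3]]) else rep(1, length(u))
  build_graph(u, v, w, weighted = weighted, allow_self_loops = allow_self_loops)
}

# Shared constructor: labels -> dense ids, duplicate merging, validation.
build_graph <- function(u, v, w, weighted, allow_self_loops,
                        labels = NULL, context = "edge input") {
  if (anyNA(u) || anyNA(v)) abort(paste0("missing endpoint in ", context, "."))
  if (anyNA(w)) abort(paste0("missing or non-numeric weight in ", context, "."))
  if (any(w <= 0)) {
    abort(paste0("non-positive edge weight in ", context,
                 "; all weights must be > 0."))
  }
  labels <- labels %||% unique(c(u, v))
  from <- match(u, labels)
  to <- match(v, labels)
  if (anyNA(from) || anyNA(to)) abort("edge endpoint outside the label set.")
  a <- pmin(from, to)
  b <- pmax(from, to)
  if (!allow_self_loops && any(a == b)) {
    abort(paste0("self-loop found in ", context,
                 "; pass allow_self_loops = TRUE to keep self-loops."))
  }
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    if (weighted) {
      tot <- rowsum(w, key, reorder = FALSE)
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]
      w <- tot[, 1]
    } else {
      n_dup <- sum(duplicated(key))
      rlang::inform(paste0("collapsed ", n_dup,
                           " duplicate unweighted edge line(s) to weight 1."))
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]; w <- w[keep]
    }
  }
  new_graph(a, b, w, labels)
}

# Lowest-level constructor; assumes merged edges with from <= to.
new_graph <- function(from, to, weight, labels) {
  n <- length(labels)
  strength <- numeric(n)
  add_from <- rowsum(weight, from)
  strength[as.integer(rownames(add_from))] <- add_from[, 1]
  add_to <- rowsum(weight, to)
  idx <- as.integer(rownames(add_to))
  strength[idx] <- strength[idx] + add_to[, 1]
  ord <- order(from, to)
  structure(
    list(
      n = n,
      edges = tibble(from = as.integer(from[ord]), to = as.integer(to[ord]),
                     weight = as.numeric(weight[ord])),
      m = sum(weight),
      strength = strength,
      labels = as.character(labels)
    ),
    class = "reneel_graph"
  )
}

#' @export
print.reneel_graph <- function(x, ...) {
  n_loops <- sum(x$edges$from == x$edges$to)
  cat("Undirected weighted graph: ", x$n, " nodes, ", nrow(x$edges),
      " edges (", n_loops, " self-loops), total weight m = ",
      format(x$m), "\n", sep = "")
  invisible(x)
}

#' Edge table of a graph
#'
#' @param graph A `reneel_graph`.
#' @param labelled Return original node labels (`TRUE`) or internal 1-based
#'   ids.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
graph_edges <- function(graph, labelled = TRUE) {
  stopifnot(inherits(graph, "reneel_graph"))
  e <- graph$edges
  if (labelled) {
    tibble(from = graph$labels[e$from], to = graph$labels[e$to],
           weight = e$weight)
  } else {
    e
  }
}

#' Read a whitespace-separated edge list
#'
#' Lines starting with `#` (or `%`) are comments. Each remaining line names an
#' edge by two node labels, with an optional third token holding a positive
#' weight when `weighted = TRUE`. Duplicate undirected pairs collapse to one
#' edge (weight 1 in unweighted input; weights sum in weighted input). The
#' benchmark networks this format is used for have no self-loops, so
#' self-loops are rejected unless `allow_self_loops = TRUE`.
#'
#' @param path Path to the edge-list file.
#' @param weighted Expect a third weight column.
#' @param allow_self_loops Permit self-loops.
#' @return A [as_reneel_graph()] graph.
#' @export
read_edge_list <- function(path, weighted = FALSE, allow_self_loops = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|%|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  want <- if (weighted) 3L else 2L
  nt <- lengths(toks)
  bad <- which(nt != want)
  if (length(bad) > 0) {
    abort(paste0("parse error at line ", idx[bad[1]], " of ", path,
                 ": expected ", want, " fields, found ", nt[bad[1]], "."))
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  w <- if (weighted) {
    wv <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
    if (anyNA(wv)) {
      abort(paste0("parse error at line ", idx[which(is.na(wv))[1]], " of ",
                   path, ": weight is not a number."))
    }
    wv
  } else {
    rep(1, length(u))
  }
  build_graph(u, v, w, weighted = weighted, allow_self_loops = allow_self_loops,
              context = paste0("'", path, "'"))
}

#' Read a METIS format graph
#'
#' Expects the header `n m [fmt]` followed by one 1-based adjacency line per
#' node; `fmt = 1` means each neighbour is followed by an edge weight. Every
#' undirected edge must be listed from both endpoints with consistent weight,
#' and the number of distinct edges must equal the declared `m`.
#'
#' @param path Path to the `.graph` file.
#' @return A graph with 0-based external labels `"0" .. "n-1"` mapped to
#'   internal ids.
#' @export
read_metis <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*%", lines)]
  if (length(lines) == 0) abort("empty METIS file.")
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2 || length(hdr) > 3 || anyNA(hdr)) {
    abort("METIS format error: header must be 'n m [fmt]'.")
  }
  n <- as.integer(hdr[1])
  m_decl <- as.integer(hdr[2])
  fmt <- if (length(hdr) == 3) as.integer(hdr[3]) else 0L
  if (!fmt %in% c(0L, 1L)) {
    abort(paste0("unsupported METIS fmt code ", fmt,
                 "; only 0 (unweighted) and 1 (edge weights) are handled."))
  }
  if (length(lines) - 1 != n) {
    abort(paste0("METIS format error: header declares ", n,
                 " nodes but file has ", length(lines) - 1,
                 " adjacency lines."))
  }
  srcs <- list()
  dsts <- list()
  wts <- list()
  for (i in seq_len(n)) {
    tk <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0) next
    vals <- suppressWarnings(as.numeric(tk))
    if (anyNA(vals)) {
      abort(paste0("METIS format error: non-numeric token on adjacency line ",
                   i, "."))
    }
    if (fmt == 1L) {
      if (length(vals) %% 2 != 0) {
        abort(paste0("METIS format error: odd token count on weighted ",
                     "adjacency line ", i, "."))
      }
      nbrs <- as.integer(vals[seq(1, length(vals), by = 2)])
      ws <- vals[seq(2, length(vals), by = 2)]
    } else {
      nbrs <- as.integer(vals)
      ws <- rep(1, length(nbrs))
    }
    if (any(nbrs < 1 | nbrs > n)) {
      abort(paste0("METIS format error: neighbour id out of range on line ",
                   i, "."))
    }
    srcs[[i]] <- rep(i, length(nbrs))
    dsts[[i]] <- nbrs
    wts[[i]] <- ws
  }
  src <- unlist(srcs) %||% integer(0)
  dst <- unlist(dsts) %||% integer(0)
  w <- unlist(wts) %||% numeric(0)
  fwd <- paste(src, dst, w)
  rev <- paste(dst, src, w)
  if (!all(rev %in% fwd)) {
    abort("METIS format error: adjacency is not symmetric with equal weights.")
  }
  keep <- src < dst
  loops <- src == dst
  a <- c(src[keep], src[loops])
  b <- c(dst[keep], dst[loops])
  ww <- c(w[keep], w[loops])
  kk <- paste(a, b)
  if (anyDuplicated(kk)) {
    abort("METIS format error: duplicate neighbour listing on one line.")
  }
  if (length(a) != m_decl) {
    abort(paste0("METIS format error: header declares m = ", m_decl,
                 " but file lists ", length(a), " distinct edges."))
  }
  new_graph(a, b, ww, labels = as.character(seq_len(n) - 1L))
}

#' Write a graph in METIS format
#'
#' Weighted graphs are written with `fmt = 1`. METIS has no self-loop
#' representation, so graphs with self-loops are rejected.
#'
#' @param graph A `reneel_graph` without self-loops.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metis <- function(graph, path) {
  stopifnot(inherits(graph, "reneel_graph"))
  e <- graph$edges
  if (any(e$from == e$to)) {
    abort("METIS format cannot represent self-loops.")
  }
  weighted <- any(e$weight != 1)
  src <- c(e$from, e$to)
  dst <- c(e$to, e$from)
  w <- c(e$weight, e$weight)
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]; w <- w[ord]
  body <- character(graph$n)
  sp <- split(seq_along(src), factor(src, levels = seq_len(graph$n)))
  for (i in seq_len(graph$n)) {
    ii <- sp[[i]]
    body[i] <- if (length(ii) == 0) {
      ""
    } else if (weighted) {
      paste(rbind(dst[ii], format(w[ii], trim = TRUE)), collapse = " ")
    } else {
      paste(dst[ii], collapse = " ")
    }
  }
  hdr <- paste(graph$n, nrow(e), if (weighted) "1" else NULL)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a node-membership table
#'
#' Writes a two-column TSV `node<TAB>community` using the graph's original
#' node labels; community ids are renumbered `0..r-1` by order of first
#' appearance over the node order.
#'
#' @param membership A partition (see [randomized_greedy()]) or an integer
#'   membership vector over the graph's nodes.
#' @param graph The graph the membership refers to (supplies labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, graph, path) {
  memb <- membership_vector(membership, graph$n)
  canon <- canonical_form(memb) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(graph$labels, canon, sep = "\t"), con)
  invisible(path)
}

#' Read a node-membership table
#'
#' Inverse of [write_membership()]: reads `node<TAB>community` and returns the
#' membership aligned with `graph`'s internal node order.
#'
#' @param path Path to the TSV file.
#' @param graph The graph the membership refers to.
#' @return An integer membership vector (dense ids starting at 1).
#' @export
read_membership <- function(path, graph) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer"))
  idx <- match(graph$labels, tab[[1]])
  if (anyNA(idx)) {
    abort("membership file does not cover every node of the graph.")
  }
  canonical_form(tab[[2]][idx])
}
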