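#!/usr/bin/env Rscript

# Downloads the classic community-detection benchmark networks into
# benchmarks/ at the repository root and normalizes each one to a plain
# two-column edge list (<name>.txt) readable by read_edge_list().
#
# This script needs network access and is never invoked by the test suite;
# the full-size benchmark check in the acceptance tests stays red until
# benchmarks/ is populated.
#
# Provenance (hosts current at the time of writing; mirrors move):
#   - Email, Jazz, Metabolic, PGPgc: A. Arenas' network data collection,
#     https://deim.urv.cat/~alexandre.arenas/data/welcome.htm
#   - Adjnoun, Polblog, Netscience, Power, Astro-ph, As-22july06,
#     Cond-mat-2005: M. Newman's collection (GML),
#     http://www-personal.umich.edu/~mejn/netdata/
#   - Memplus: SuiteSparse matrix collection, https://sparse.tamu.edu
#   - Smallworld, CAIDARouterLevel: 10th DIMACS implementation challenge
#     instance archive (METIS format),
#     https://www.cc.gatech.edu/dimacs10/downloads.shtml
#
# All of these graphs are treated as undirected, unweighted, simple graphs
# (duplicate links collapse, self-loops dropped), matching the node/link
# counts used for the published modularity values.

suppressPackageStartupMessages(library(igraph))

dest <- "benchmarks"
dir.create(dest, showWarnings = FALSE)

write_edges <- function(g, name) {
  g <- as_undirected(simplify(g, remove.multiple = TRUE, remove.loops = TRUE),
                     mode = "collapse")
  el <- as_edgelist(g, names = FALSE)
  writeLines(paste(el[, 1], el[, 2]), file.path(dest, paste0(name, ".txt")))
  cat(sprintf("%s: n = %d, m = %d\n", name, vcount(g), ecount(g)))
}

fetch <- function(url, file) {
  path <- file.path(tempdir(), file)
  utils::download.file(url, path, quiet = TRUE)
  path
}

## Newman collection (GML inside zip)
newman <- c(
  adjnoun = "http://www-personal.umich.edu/~mejn/netdata/adjnoun.zip",
  polblogs = "http://www-personal.umich.edu/~mejn/netdata/polblogs.zip",
  netscience = "http://www-personal.umich.edu/~mejn/netdata/netscience.zip",
  power = "http://www-personal.umich.edu/~mejn/netdata/power.zip",
  `astro-ph` = "http://www-personal.umich.edu/~mejn/netdata/astro-ph.zip",
  `as-22july06` = "http://www-personal.umich.edu/~mejn/netdata/as-22july06.zip",
  `cond-mat-2005` = "http://www-personal.umich.edu/~mejn/netdata/cond-mat-2005.zip"
)
for (nm in names(newman)) {
  ok <- tryCatch({
    zip <- fetch(newman[[nm]], paste0(nm, ".zip"))
    files <- utils::unzip(zip, exdir = tempdir())
    gml <- files[grepl("\\.gml$", files)][1]
    write_edges(read_graph(gml, format = "gml"), nm)
    TRUE
  }, error = function(e) {
    cat("skipping ", nm, ": ", conditionMessage(e), "\n", sep = "")
    FALSE
  })
}

## Arenas collection (plain/Pajek edge lists inside zip)
arenas <- c(
  email = "https://deim.urv.cat/~alexandre.arenas/data/xarxes/email.zip",
  jazz = "https://deim.urv.cat/~alexandre.arenas/data/xarxes/jazz.zip",
  metabolic = "https://deim.urv.cat/~alexandre.arenas/data/xarxes/celegans_metabolic.zip",
  pgpgc = "https://deim.urv.cat/~alexandre.arenas/data/xarxes/PGP.zip"
)
for (nm in names(arenas)) {
  ok <- tryCatch({
    zip <- fetch(arenas[[nm]], paste0(nm, ".zip"))
    files <- utils::unzip(zip, exdir = tempdir())
    src <- files[grepl("\\.(txt|net|dat)$", files, ignore.case = TRUE)][1]
    lines <- readLines(src, warn = FALSE)
    # tolerate Pajek headers and jazz-style preambles: keep lines that are
    # exactly two or three numeric tokens and use the first two
    toks <- strsplit(trimws(lines), "\\s+")
    keep <- vapply(toks, function(t) {
      length(t) %in% 2:3 && !anyNA(suppressWarnings(as.numeric(t)))
    }, TRUE)
    el <- do.call(rbind, lapply(toks[keep], function(t) as.numeric(t[1:2])))
    write_edges(graph_from_edgelist(apply(el, 2, as.character),
                                    directed = FALSE), nm)
    TRUE
  }, error = function(e) {
    cat("skipping ", nm, ": ", conditionMessage(e), "\n", sep = "")
    FALSE
  })
}

cat("\nDone. Networks are in ", normalizePath(dest), "\n", sep = "")
cat("Memplus (SuiteSparse) and the DIMACS METIS instances (Smallworld,\n")
cat("CAIDARouterLevel) are published as matrix/METIS files; download them\n")
cat("manually and convert with read_metis()/write_membership() as needed.\n")
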