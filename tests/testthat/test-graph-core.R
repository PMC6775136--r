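test_that("edge-list reader parses a triangle and remaps labels", {
  path <- withr::local_tempfile(lines = c("# comment", "0 1", "1 2", "0 2"))
  g <- read_edge_list(path)
  expect_equal(g$n, 3)
  expect_equal(g$m, 3)
  expect_equal(g$strength, rep(2, 3))
  expect_setequal(g$labels, c("0", "1", "2"))
})

test_that("duplicate undirected edges follow the documented merge rules", {
  path <- withr::local_tempfile(lines = c("a b", "b a"))
  expect_message(g <- read_edge_list(path), "duplicate")
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$m, 1)

  pathw <- withr::local_tempfile(lines = c("a b 1", "b a 1"))
  gw <- read_edge_list(pathw, weighted = TRUE)
  expect_equal(nrow(gw$edges), 1)
  expect_equal(gw$m, 2) # weighted dialect sums
})

test_that("malformed lines and bad weights are rejected with line numbers", {
  path <- withr::local_tempfile(lines = c("a b", "c"))
  expect_error(read_edge_list(path), "line 2")
  pathw <- withr::local_tempfile(lines = c("a b 1", "b c -2"))
  expect_error(read_edge_list(pathw, weighted = TRUE), "> 0")
  pathz <- withr::local_tempfile(lines = c("a b x"))
  expect_error(read_edge_list(pathz, weighted = TRUE), "not a number")
})

test_that("self-loops are rejected by default but can be permitted", {
  path <- withr::local_tempfile(lines = c("a b", "a a"))
  expect_error(read_edge_list(path), "self-loop")
  g <- read_edge_list(path, allow_self_loops = TRUE)
  expect_equal(g$m, 2)
  # self-loop of weight w adds 2w to its node's strength
  expect_equal(g$strength[match("a", g$labels)], 3)
})

test_that("strength sums to 2m on parsed graphs and ids are dense", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_weighted_graph(12)
    expect_lt(abs(sum(g$strength) - 2 * g$m), 1e-12)
    expect_true(all(c(g$edges$from, g$edges$to) %in% seq_len(g$n)))
  }
})

test_that("METIS reader handles the triangle and detects contract violations", {
  path <- withr::local_tempfile(lines = c("3 3", "2 3", "1 3", "1 2"))
  g <- read_metis(path)
  expect_equal(g$n, 3)
  expect_equal(g$m, 3)
  expect_equal(g$strength, rep(2, 3))

  # header declares m = 3 but file lists 4 distinct edges
  bad <- withr::local_tempfile(lines = c("4 3", "2 3 4", "1 3", "1 2", "1"))
  expect_error(read_metis(bad), "m = 3")

  # asymmetric adjacency
  asym <- withr::local_tempfile(lines = c("3 2", "2 3", "1", "1 2"))
  expect_error(read_metis(asym), "symmetric")

  # line-count mismatch
  short <- withr::local_tempfile(lines = c("3 1", "2"))
  expect_error(read_metis(short), "adjacency lines")
})

test_that("weighted METIS round-trips through write_metis", {
  set.seed(5)
  df <- data.frame(i = c(1, 1, 2, 3, 4), j = c(2, 3, 3, 4, 1),
                   w = c(1.5, 2, 0.5, 3, 1))
  g <- as_reneel_graph(df)
  path <- withr::local_tempfile()
  write_metis(g, path)
  g2 <- read_metis(path)
  expect_equal(g2$n, g$n)
  expect_equal(g2$edges$weight, g$edges$weight)
  expect_equal(g2$edges$from, g$edges$from)
  expect_equal(g2$edges$to, g$edges$to)
  # and an unweighted graph round-trips without a fmt flag
  gu <- two_triangles()
  write_metis(gu, path)
  gu2 <- read_metis(path)
  expect_equal(gu2$m, gu$m)
  expect_equal(gu2$strength, gu$strength)
})

test_that("membership TSV round-trips under canonical form", {
  g <- two_triangles()
  memb <- c(2, 2, 7, 7, 2, 7) # labels a b x y c z (first-appearance order)
  path <- withr::local_tempfile()
  write_membership(memb, g, path)
  lines <- readLines(path)
  expect_length(lines, 6)
  expect_match(lines[1], "^a\t0$")
  back <- read_membership(path, g)
  expect_identical(back, canonical_form(memb))

  # all-one-community triangle: three lines, all community 0
  tri <- as_reneel_graph(data.frame(a = c(1, 2, 1), b = c(2, 3, 3)))
  write_membership(rep(1, 3), tri, path)
  expect_identical(unique(sub(".*\t", "", readLines(path))), "0")
})
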