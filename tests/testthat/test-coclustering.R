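test_that("co-clustering matrix counts shared-community fractions", {
  # single partition: 0/1 blocks mirroring the partition
  memb <- c(1, 1, 2, 2)
  s1 <- co_cluster_matrix(list(memb))
  expect_true(all(s1 %in% c(0, 1)))
  expect_equal(s1, outer(memb, memb, function(a, b) (a == b) + 0))
  # identical partitions repeated change nothing
  expect_equal(co_cluster_matrix(rep(list(memb), 7)), s1)
  # {ab|c} and {a|bc}: s_ab = s_bc = 0.5, s_ac = 0
  s <- co_cluster_matrix(list(c(1, 1, 2), c(1, 2, 2)))
  expect_equal(s[1, 2], 0.5)
  expect_equal(s[2, 3], 0.5)
  expect_equal(s[1, 3], 0)
  expect_equal(diag(s), rep(1, 3))
  # pairs inside a core group sit at exactly 1
  parts <- make_ensemble(two_triangles(), 5, seed = 2)
  cg <- core_groups(parts)
  sm <- co_cluster_matrix(parts)
  for (grp in cg$groups) {
    if (length(grp) > 1) expect_true(all(sm[grp, grp] == 1))
  }
})

test_that("seriation cost matches its definition", {
  # zero off-diagonal: every order costs 0
  s0 <- diag(4)
  expect_equal(seriation_cost(s0, 1:4), 0)
  expect_equal(seriation_cost(s0, c(3, 1, 4, 2)), 0)
  # one unit pair placed adjacently at alpha = 3: H = 1
  s <- diag(4)
  s[1, 2] <- s[2, 1] <- 1
  expect_equal(seriation_cost(s, c(1, 2, 3, 4), alpha = 3), 1)
  # same pair placed opposite on the 4-cycle: d = 2, H = 8
  expect_equal(seriation_cost(s, c(1, 3, 2, 4), alpha = 3), 8)
  expect_error(seriation_cost(s, c(1, 1, 2, 3)), "permutation")
})

test_that("cost is invariant under rotation and reflection of the order", {
  set.seed(121)
  for (rep in 1:10) {
    membs <- lapply(1:5, function(i) random_membership(9, 3))
    s <- co_cluster_matrix(membs)
    ord <- sample(9)
    h <- seriation_cost(s, ord)
    rot <- c(ord[-1], ord[1])
    expect_equal(seriation_cost(s, rot), h)
    expect_equal(seriation_cost(s, rev(ord)), h)
  }
})

test_that("annealing solves two perfect blocks to the exhaustive optimum", {
  memb <- rep(1:2, each = 4)
  s <- co_cluster_matrix(list(memb))
  res <- anneal_order(s, alpha = 3, seed = 5)
  # rotation invariance: fixing the first slot, enumerate 7! orders
  perms <- all_permutations(7)
  hmin <- Inf
  for (r in seq_len(nrow(perms))) {
    hmin <- min(hmin, seriation_cost(s, c(1L, perms[r, ] + 1L)))
  }
  expect_equal(res$h, hmin)
  expect_equal(res$h, seriation_cost(s, res$order, alpha = 3))
})

test_that("annealing never loses to its starting order", {
  set.seed(131)
  for (rep in 1:5) {
    membs <- lapply(1:6, function(i) random_membership(20, 4))
    s <- co_cluster_matrix(membs)
    res <- anneal_order(s, seed = rep)
    expect_lte(res$h, res$h_start)
    expect_lte(res$h, seriation_cost(s, 1:20))
  }
})

test_that("grouped annealing only swaps nodes within a group", {
  set.seed(141)
  membs <- lapply(1:4, function(i) random_membership(12, 3))
  s <- co_cluster_matrix(membs)
  groups <- rep(1:3, each = 4)
  res <- anneal_order(s, groups = groups, seed = 3)
  pos <- integer(12)
  pos[res$order] <- seq_len(12)
  # the set of positions each group occupies is unchanged from identity
  for (g in unique(groups)) {
    expect_setequal(pos[groups == g], which(groups == g))
  }
})

test_that("two-node matrices seriate trivially", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  res <- anneal_order(s, seed = 1)
  expect_setequal(res$order, 1:2)
  expect_equal(res$h, 0.5)
})
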