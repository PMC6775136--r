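test_that("core groups reproduce the defining cases", {
  # meet of a single partition is that partition
  memb <- c(1, 1, 2, 3, 3)
  cg <- core_groups(list(memb))
  expect_identical(cg$group_of, canonical_form(memb))
  # crossing partitions {ab|c} and {a|bc} -> all singletons
  cg2 <- core_groups(list(c(1, 1, 2), c(1, 2, 2)))
  expect_equal(cg2$n_groups, 3)
  expect_error(core_groups(list(c(1, 1), c(1, 2, 2))), "different node sets")
})

test_that("core groups equal the pairwise brute-force meet", {
  set.seed(91)
  for (rep in 1:10) {
    membs <- lapply(1:20, function(i) random_membership(50, sample(2:6, 1)))
    cg <- core_groups(membs)
    expect_identical(canonical_form(cg$group_of),
                     canonical_form(oracle_meet(membs)))
  }
})

test_that("graph reduction preserves structure and total weight", {
  g <- two_triangles()
  # all-singleton grouping: identity reduction
  cg <- core_groups(list(seq_len(g$n)))
  red <- reduce_graph(g, cg)
  expect_equal(red$graph$n, g$n)
  expect_equal(red$graph$m, g$m)
  expect_equal(sort(red$graph$strength), sort(g$strength))

  # a collapsed triangle becomes one node with self-loop weight 3
  tri <- as_reneel_graph(data.frame(a = c(1, 2, 1), b = c(2, 3, 3)))
  red_tri <- reduce_graph(tri, core_groups(list(rep(1, 3))))
  expect_equal(red_tri$graph$n, 1)
  expect_equal(red_tri$graph$edges$weight, 3)
  expect_equal(red_tri$graph$m, 3)
  expect_equal(red_tri$graph$strength, 6)
})

test_that("five multi-node groups plus two singletons give 7 reduced nodes", {
  set.seed(101)
  g <- random_graph(22, p = 0.35, connected = TRUE)
  grouping <- c(rep(1:5, each = 4), 6, 7) # five groups of 4, two singletons
  red <- reduce_graph(g, core_groups(list(grouping)))
  expect_equal(red$graph$n, 7)
  expect_equal(red$graph$m, g$m)
})

test_that("expansion inverts reduction and preserves modularity", {
  set.seed(111)
  g <- random_weighted_graph(15)
  # identity reduction: expansion is the identity map
  red_id <- reduce_graph(g, core_groups(list(seq_len(g$n))))
  memb <- random_membership(g$n, 4)
  expect_identical(red_id$group_of, seq_len(g$n)) # reduced node i = node i
  p <- expand_partition(canonical_form(memb), red_id, g)
  expect_identical(p$membership, canonical_form(memb))

  # all reduced nodes in one community -> Q = 0 on the original graph
  parts <- make_ensemble(g, 5, seed = 2)
  red <- reduce_graph(g, core_groups(parts))
  one <- expand_partition(rep(1L, red$graph$n), red, g)
  expect_equal(one$q, 0)

  # P1: modularity(reduced, rp) == modularity(original, expand(rp))
  for (rep in 1:20) {
    rp <- random_membership(red$graph$n, 3)
    q_red <- modularity_q(red$graph, rp)
    q_exp <- expand_partition(rp, red, g)$q
    expect_lt(abs(q_red - q_exp), 1e-12)
  }
})

test_that("extremal update follows the three branches", {
  g <- planted_partition(3, 8, 0.6, 0.05, seed = 13)$graph
  parts <- make_ensemble(g, 12, seed = 4)
  # fabricate controlled members: use distinct partitions sorted by Q
  ens <- partition_ensemble(parts, k_max = length(parts))
  k <- length(ens$members)
  qs <- vapply(ens$members, function(p) p$q, 0)

  # duplicate candidate: worst member deleted regardless of its Q
  dup <- ens$members[[1]]
  out <- extremal_update(ens, dup)
  expect_equal(out$outcome, "duplicate")
  expect_length(out$ensemble$members, k - 1)

  # winning new candidate at capacity: size constant, min-Q strictly rises
  best_new <- reneel(g, k_max = 8, seed = 31)$partition
  if (!best_new$key %in% vapply(ens$members, function(p) p$key, "") &&
      best_new$q > min(qs)) {
    out2 <- extremal_update(ens, best_new)
    expect_equal(out2$outcome, "accepted")
    expect_length(out2$ensemble$members, k)
    expect_gt(min(vapply(out2$ensemble$members, function(p) p$q, 0)),
              min(qs))
  }

  # winning new candidate below capacity: size grows by one
  ens_small <- partition_ensemble(ens$members[seq_len(k - 1)], k_max = k + 5)
  if (!best_new$key %in%
        vapply(ens_small$members, function(p) p$key, "")) {
    out3 <- extremal_update(ens_small, best_new)
    expect_equal(out3$outcome, "accepted")
    expect_length(out3$ensemble$members, k)
  }

  # losing novel candidate: rejection deletes the worst member
  worst <- structure(
    list(membership = canonical_form(seq_len(g$n)),
         q = modularity_q(g, seq_len(g$n)),
         key = paste(seq_len(g$n), collapse = ",")),
    class = "reneel_partition"
  )
  out4 <- extremal_update(ens, worst)
  expect_equal(out4$outcome, "rejected")
  expect_length(out4$ensemble$members, k - 1)
})

test_that("consensus on two disconnected triangles is the optimum", {
  fit <- reneel(two_triangles(), k_max = 10, seed = 1)
  expect_equal(fit$q, 0.5)
  expect_equal(fit$n_communities, 2)
  expect_identical(canonical_form(fit$membership), c(1L, 1L, 2L, 2L, 1L, 2L))
})

test_that("k_max = 1 terminates before any iteration", {
  g <- planted_partition(3, 8, 0.5, 0.05, seed = 23)$graph
  fit <- reneel(g, k_max = 1, seed = 2)
  expect_equal(fit$iterations, 0)
  expect_equal(nrow(fit$trace), 0)
  # the consensus is the single base-algorithm partition
  set.seed(2)
  single <- make_ensemble(g, 1)
  expect_identical(fit$membership, single[[1]]$membership)
})

test_that("runs are deterministic given a seed and obey the monotonicity laws", {
  pp <- planted_partition(4, 15, 0.35, 0.02, seed = 37)
  f1 <- reneel(pp$graph, k_max = 30, k_prime = 10, seed = 9,
               diagnostics = TRUE)
  f2 <- reneel(pp$graph, k_max = 30, k_prime = 10, seed = 9)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$trace$q_candidate, f2$trace$q_candidate)

  tr <- f1$trace
  expect_gt(nrow(tr), 0)
  # P3: extremal monotonicity of the ensemble extremes
  expect_true(all(diff(tr$q_worst) >= 0))
  expect_true(all(diff(tr$q_best) >= 0))
  # reduced network size never grows
  expect_true(all(diff(tr$n_reduced) <= 0))
  # P2: every later core grouping coarsens every earlier one
  for (i in seq_along(f1$groupings)[-1]) {
    expect_true(coarsens(f1$groupings[[i]], f1$groupings[[i - 1]]))
  }
  # P5: consensus Q at least as good as every initial ensemble member
  expect_gte(f1$q, tr$q_best[1])
  expect_gte(f1$q, tr$q_worst[1])
})

test_that("fit methods expose tidy, glance and plots", {
  fit <- reneel(two_triangles(), k_max = 10, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("node", "community"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$q, 0.5)
  expect_equal(gl$n_communities, 2)

  fitp <- reneel(planted_partition(3, 8, 0.5, 0.05, seed = 3)$graph,
                 k_max = 15, seed = 4)
  if (fitp$iterations > 0) {
    expect_s3_class(autoplot(fitp), "ggplot")
    expect_s3_class(autoplot(fitp, what = "size"), "ggplot")
  }
  path <- withr::local_tempfile()
  write_trace(fitp, path)
  expect_equal(readLines(path)[1],
               "iteration\tq_best\tq_worst\tq_candidate\tn_reduced\tk")
})
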