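test_that("unbalanced solver handles degenerate and two-leaf trees", {
  tr <- ape::read.tree(text = "(a,b);")
  same <- cn_matrix(rbind(a = c(3, 1, 0, 2), b = c(3, 1, 0, 2)))
  r0 <- unbalanced_small_parsimony(tr, same)
  expect_equal(r0$score_l1, 0)
  q <- as.numeric(delta_map(c(3, 1, 0, 2)))
  for (v in seq_len(nrow(r0$labeling)))
    expect_equal(unname(r0$labeling[v, ]), q)
  two <- cn_matrix(rbind(a = c(2, 2, 2, 2), b = c(2, 3, 3, 2)))
  r1 <- unbalanced_small_parsimony(tr, two)
  expect_equal(r1$score_l1, 2)
  expect_equal(r1$score_events, 1)
})

test_that("unbalanced solver equals per-coordinate brute force on random trees", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    tr <- simulate_topology(n, seed = rep)
    X <- t(replicate(n, rand_profile(3, 2)))
    rownames(X) <- tr$tip.label
    cnm <- cn_matrix(X)
    res <- unbalanced_small_parsimony(tr, cnm)
    Qleaf <- res$labeling[seq_len(n), , drop = FALSE]
    expect_equal(res$score_l1, bf_unbalanced_score(res$tree, Qleaf))
    # the reported score matches the returned labeling
    expect_equal(parsimony_score(res$tree, res$labeling)$score_l1,
                 res$score_l1)
  }
})

test_that("discrepancy is zero on leaves and sums segment entries", {
  lab <- structure(rbind(c(0, 0, 0), c(1, 0, 0)),
                   seg = rep("chr1", 3), space = "delta")
  d <- vertex_discrepancy(lab)
  expect_equal(unname(d[, 1]), c(0, 1))
})

test_that("balancing repair fixes the right-boundary coordinate", {
  lab <- structure(rbind(c(1, 0, 0, 0), c(0, 2, 0, -2)),
                   seg = rep("chr1", 4), space = "delta")
  rep_lab <- repair_balancing(lab)
  expect_equal(unname(rep_lab[1, ]), c(1, 0, 0, -1))
  expect_equal(unname(rep_lab[2, ]), c(0, 2, 0, -2))  # balanced: unchanged
  expect_true(all(abs(vertex_discrepancy(rep_lab)) < 1e-9))
})

test_that("repair cost increase is bounded by the summed edge discrepancies", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 6
    sim <- simulate_evolution(simulate_topology(n, seed = rep),
                              simulation_config(n_bins = 10), seed = rep)
    ub <- unbalanced_small_parsimony(sim$tree, sim$matrix)
    disc <- rowSums(abs(vertex_discrepancy(ub$labeling)))
    repaired <- parsimony_score(ub$tree, repair_balancing(ub$labeling))
    E <- ub$tree$edge
    bound <- ub$score_l1 + sum(abs(disc[E[, 1]] - disc[E[, 2]]))
    expect_true(repaired$score_l1 <= bound + 1e-9)
    expect_true(repaired$score_l1 <= 2 * ub$score_l1 + 1e-9)
  }
})

test_that("two-approximation returns a feasible labeling within factor two", {
  tr <- ape::read.tree(text = "(a,b);")
  two <- cn_matrix(rbind(a = c(2, 2, 2, 2), b = c(2, 3, 3, 2)))
  r <- two_approx_small_parsimony(tr, two)
  expect_equal(r$score_events, 1)  # endpoint optimum already balanced
  expect_true(all(abs(vertex_discrepancy(r$labeling)) < 1e-9))
  same <- cn_matrix(rbind(a = c(2, 2, 2, 2), b = c(2, 2, 2, 2)))
  expect_equal(two_approx_small_parsimony(tr, same)$score_l1, 0)
})

test_that("any labeling scores at least its total discrepancy (lower bound)", {
  set.seed(29)
  for (rep in 1:10) {
    sim <- simulate_evolution(simulate_topology(6, seed = rep),
                              simulation_config(n_bins = 8), seed = rep + 100)
    ub <- unbalanced_small_parsimony(sim$tree, sim$matrix)
    sc <- parsimony_score(ub$tree, ub$labeling)
    expect_true(sc$score_l1 >= sc$lower_bound_disc - 1e-9)
  }
})

test_that("true simulated labelings cost at most twice the event count", {
  # each event changes the delta L1 along its edge by at most 2
  for (s in 1:5) {
    sim <- simulate_evolution(simulate_topology(6, seed = s),
                              simulation_config(n_bins = 12), seed = s)
    lab <- t(apply(sim$true_labeling, 1, delta_map, bins = sim$matrix$bins))
    lab <- structure(lab, seg = attr(delta_transform(sim$matrix), "seg"))
    sc <- parsimony_score(sim$tree, lab)
    expect_true(sc$score_l1 <= 2 * sum(sim$event_log$applied))
  }
})

test_that("polytomy resolution never increases the unbalanced optimum", {
  set.seed(31)
  poly <- ape::read.tree(text = "((a,b,c),(d,e),f);")
  X <- t(replicate(6, rand_profile(8, 3)))
  rownames(X) <- letters[1:6]
  cnm <- cn_matrix(X)
  # optimum over the multifurcating tree itself, by brute force
  Qleaf <- delta_transform(cnm)
  poly_opt <- bf_unbalanced_score(poly,
                                  Qleaf[match(poly$tip.label,
                                              rownames(Qleaf)), ])
  expect_true(unbalanced_small_parsimony(poly, cnm)$score_l1 <= poly_opt)
  for (rep in 1:5) {
    res <- ape::multi2di(poly, random = TRUE)
    expect_true(unbalanced_small_parsimony(res, cnm)$score_l1 <= poly_opt)
  }
})

test_that("canonical event decomposition replays parent to child", {
  expect_equal(nrow(canonical_event_decomposition(c(2, 2), c(2, 2))), 0)
  ev <- canonical_event_decomposition(c(2, 2, 2, 2), c(2, 3, 3, 2))
  expect_equal(nrow(ev), 1)
  expect_equal(unname(unlist(ev[1, c("s", "t", "b")])), c(2, 3, 1))
  ev2 <- canonical_event_decomposition(c(2, 2), c(1, 3))
  expect_equal(nrow(ev2), 2)
  expect_setequal(paste(ev2$s, ev2$t, ev2$b), c("1 1 -1", "2 2 1"))
  expect_equal(ev2$b[1], 1)  # amplifications scheduled first
  set.seed(37)
  for (rep in 1:40) {
    m <- sample(3:8, 1)
    p <- rand_profile(m, 4); q <- rand_profile(m, 4)
    ev <- canonical_event_decomposition(p, q)
    expect_equal(nrow(ev), zcnt_distance(p, q))
    cur <- p
    for (j in seq_len(nrow(ev)))
      cur <- apply_zcnt_event(cur, event_record(ev$chrom[j], ev$s[j],
                                                ev$t[j], ev$b[j]))
    expect_equal(cur, q)
  }
})

test_that("CNT-violation statistics count stretches and zero-amplifications", {
  # star with two leaves: force an ancestral profile by hand
  tr <- ape::read.tree(text = "(a,b);")
  lab_ok <- rbind(c(2, 1, 2), c(2, 1, 2), c(2, 1, 2))
  v0 <- cnt_violation_stats(tr, lab_ok)
  expect_equal(v0$negative_stretches, 0)
  expect_equal(v0$zero_amplifications, 0)
  expect_equal(v0$violating_score_fraction, 0)
  lab_neg <- rbind(c(1, 1, 2), c(1, 1, 2), c(1, -1, 2))
  expect_equal(cnt_violation_stats(tr, lab_neg)$negative_stretches, 1)
  expect_equal(cnt_violation_stats(tr, lab_neg)$min_ancestral_entry, -1)
  # parent (2,0,2) -> child (2,1,2): the single event amplifies a zero locus
  lab_amp <- rbind(c(2, 1, 2), c(2, 0, 2), c(2, 0, 2))
  tr1 <- ape::read.tree(text = "(a,b);")
  # vertices: tips a,b then root; edge root->a has the zero amplification
  v2 <- cnt_violation_stats(tr1, lab_amp)
  expect_equal(v2$zero_amplifications, 1)
  expect_equal(v2$zero_amplifications_per_edge, 0.5)
  expect_equal(v2$violating_score_fraction, 1)
})
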