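test_that("random topologies have binary-tree counts and are seeded", {
  t2 <- simulate_topology(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(nrow(t2$edge), 2)
  t10 <- simulate_topology(10, seed = 5)
  expect_equal(t10$Nnode, 9)
  expect_equal(nrow(t10$edge), 18)
  expect_true(ape::is.binary(t10) && ape::is.rooted(t10))
  expect_equal(ape::write.tree(simulate_topology(10, seed = 5)),
               ape::write.tree(t10))
  expect_error(simulate_topology(1), "at least 2")
})

test_that("zero event rate leaves every profile diploid", {
  sim <- simulate_evolution(simulate_topology(5, seed = 2),
                            simulation_config(events_per_edge_mean = 0),
                            seed = 2)
  expect_true(all(sim$matrix$X == 2))
  expect_true(all(zcnt_distance_matrix(sim$matrix) == 0))
})

test_that("replaying the event log reproduces every vertex profile", {
  for (s in 1:4) {
    sim <- simulate_evolution(simulate_topology(6, seed = s),
                              simulation_config(n_bins = 15,
                                                n_chromosomes = 2),
                              seed = s)
    bins <- sim$matrix$bins
    ntip <- ape::Ntip(sim$tree)
    prof <- matrix(NA_integer_, nrow(sim$true_labeling),
                   ncol(sim$true_labeling))
    prof[ntip + 1, ] <- 2L
    E <- reorder(sim$tree, "cladewise")$edge
    for (k in seq_len(nrow(E))) {
      u <- E[k, 1]; v <- E[k, 2]
      p <- prof[u, ]
      log_k <- sim$event_log[sim$event_log$parent == u &
                               sim$event_log$child == v & sim$event_log$applied,
                             , drop = FALSE]
      for (j in seq_len(nrow(log_k)))
        p <- apply_cnt_event(p, event_record(log_k$chrom[j], log_k$s[j],
                                             log_k$t[j], log_k$b[j]), bins)
      prof[v, ] <- p
    }
    expect_equal(prof, sim$true_labeling)
    expect_equal(prof[seq_len(ntip), ], unname(sim$matrix$X))
  }
})

test_that("per-edge ZCNT distance never exceeds the applied event count", {
  sim <- simulate_evolution(simulate_topology(8, seed = 9),
                            simulation_config(n_bins = 20), seed = 9)
  bins <- sim$matrix$bins
  for (k in seq_len(nrow(sim$tree$edge))) {
    u <- sim$tree$edge[k, 1]; v <- sim$tree$edge[k, 2]
    nev <- sum(sim$event_log$parent == u & sim$event_log$child == v &
                 sim$event_log$applied)
    expect_true(zcnt_distance(sim$true_labeling[u, ],
                              sim$true_labeling[v, ], bins) <= nev)
  }
})

test_that("simulated root-to-leaf transitions remain CNT-feasible", {
  sim <- simulate_evolution(simulate_topology(4, seed = 12),
                            simulation_config(n_bins = 4,
                                              events_per_edge_mean = 1),
                            seed = 12)
  ntip <- ape::Ntip(sim$tree)
  for (k in seq_len(nrow(sim$tree$edge))) {
    u <- sim$tree$edge[k, 1]; v <- sim$tree$edge[k, 2]
    d <- bfs_min_events(sim$true_labeling[u, ], sim$true_labeling[v, ],
                        "CNT", max_events = 8)
    expect_true(is.finite(d))
  }
})

test_that("mean leaf-pair distance is non-decreasing in the event rate", {
  rates <- c(0, 1, 3, 6)
  means <- vapply(rates, function(r) {
    mean(vapply(1:5, function(s) {
      tr <- simulate_topology(8, seed = 99 + s)
      sim <- simulate_evolution(tr,
                                simulation_config(n_bins = 60,
                                                  events_per_edge_mean = r),
                                seed = 99 + s)
      D <- zcnt_distance_matrix(sim$matrix)
      mean(D[upper.tri(D)])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("the max-copy cap rejects events that would exceed it", {
  sim <- simulate_evolution(simulate_topology(6, seed = 3),
                            simulation_config(n_bins = 10,
                                              events_per_edge_mean = 5,
                                              amplification_probability = 1,
                                              max_copy_cap = 3),
                            seed = 3)
  expect_true(max(sim$true_labeling) <= 3)
})

test_that("profile enumeration is complete and duplicate-free", {
  expect_equal(enumerate_profiles(1, 1), matrix(c(0L, 1L), ncol = 1))
  P <- enumerate_profiles(3, 3)
  expect_equal(nrow(P), 64)
  expect_equal(anyDuplicated(P), 0)
  expect_true(all(P[order(P[, 1], P[, 2], P[, 3]), ] == P))
  expect_error(enumerate_profiles(30, 9), "guard")
})
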