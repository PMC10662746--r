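test_that("neighbor joining recovers additive and simulated topologies", {
  # additive 4-taxon matrix from tree ((a:1,b:2):1,(c:1,d:3):1)
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:1,d:3):1);")
  D <- ape::cophenetic.phylo(tr)
  expect_equal(rf_distance(nj_tree(D), tr), 0)
  # 3 taxa: the unique unrooted topology
  expect_equal(ape::Ntip(nj_tree(matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3,
                                        dimnames = list(letters[1:3],
                                                        letters[1:3])))), 3)
  # one ZCNT event per pendant edge of a quartet
  X <- rbind(a = c(3, 2, 2, 2), b = c(2, 3, 2, 2),
             c = c(2, 2, 3, 2), d = c(2, 2, 2, 3))
  base <- rbind(a = c(3, 3, 2, 2), b = c(3, 3, 2, 2),
                c = c(2, 2, 3, 3), d = c(2, 2, 3, 3))
  # cells a,b share an amplified left half, c,d an amplified right half,
  # plus one private event each
  X2 <- base + rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0),
                     c(0, 0, 0, 1))
  njt <- nj_tree(zcnt_distance_matrix(cn_matrix(X2)))
  expect_equal(rf_distance(njt, ape::read.tree(text = "((a,b),(c,d));")), 0)
})

test_that("neighbor joining validates its input", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_error(nj_tree(D), "3 taxa")
  D3 <- matrix(0, 3, 3); D3[1, 2] <- 1
  expect_error(nj_tree(D3), "symmetric")
})

test_that("NNI neighborhoods have the right size and structure", {
  t4 <- ape::read.tree(text = "((a,b),(c,d));")
  ie <- internal_edges(t4)
  expect_length(ie, 1)
  nb <- nni_neighbors(t4, ie[1])
  expect_length(nb, 2)
  # with the original, all 3 quartet topologies are covered
  quartets <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  hits <- vapply(c(list(t4), nb), function(t)
    which(vapply(quartets, function(q)
      rf_distance(t, ape::read.tree(text = q)) == 0, logical(1))),
    integer(1))
  expect_setequal(hits, 1:3)
  for (n in c(5, 8)) {
    tr <- simulate_topology(n, seed = n)
    expect_length(internal_edges(tr), n - 3)
    expect_length(all_nni_neighbors(tr), 2 * (n - 3))
  }
  # involution: the original is among a neighbor's neighbors
  t8 <- simulate_topology(8, seed = 61)
  nb1 <- nni_neighbors(t8, internal_edges(t8)[2])[[1]]
  expect_true(any(vapply(all_nni_neighbors(nb1), function(t)
    rf_distance(t, t8) == 0, logical(1))))
  expect_error(nni_neighbors(t4, setdiff(seq_len(nrow(ape::unroot(t4)$edge)),
                                         ie)[1]), "pendant")
})

test_that("NNI neighbors agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  for (s in 1:3) {
    tr <- simulate_topology(7, seed = s)
    ours <- all_nni_neighbors(tr)
    ref <- ape::.uncompressTipLabel(phangorn::nni(ape::unroot(tr)))
    expect_equal(length(ours), length(ref))
    # every reference neighbor is matched by one of ours (RF = 0)
    for (r in ref) {
      expect_true(any(vapply(ours, function(t)
        rf_distance(t, r) == 0, logical(1))))
    }
  }
})

test_that("hill climbing is monotone, reproducible, and never worse than NJ", {
  sim <- simulate_evolution(simulate_topology(8, seed = 67),
                            simulation_config(n_bins = 60,
                                              events_per_edge_mean = 2),
                            seed = 67)
  njt <- nj_tree(zcnt_distance_matrix(sim$matrix))
  nj_score <- unbalanced_small_parsimony(njt, sim$matrix)$score_l1
  cfg <- search_config(seed = 2, max_rounds = 2)
  hc <- hill_climb(njt, sim$matrix, cfg)
  expect_true(all(diff(hc$trace) <= 0))
  expect_true(hc$score_l1 <= nj_score)
  expect_equal(hc$score_l1,
               unbalanced_small_parsimony(hc$tree, sim$matrix)$score_l1)
  hc2 <- hill_climb(njt, sim$matrix, cfg)
  expect_equal(hc2$trace, hc$trace)
  expect_equal(rf_distance(hc2$tree, hc$tree), 0)
  # starting at a local optimum with no perturbation returns it unchanged
  still <- hill_climb(hc$tree, sim$matrix,
                      search_config(seed = 2, max_rounds = 0,
                                    perturbation_strength = 0))
  expect_equal(rf_distance(still$tree, hc$tree), 0)
  expect_length(still$trace, 1)
})

test_that("the full fit pipeline returns a scored, balanced phylogeny", {
  sim <- simulate_evolution(simulate_topology(6, seed = 71),
                            simulation_config(n_bins = 40), seed = 71)
  fit <- zcnt_phylo(sim$matrix, search_config(max_rounds = 1))
  expect_s3_class(fit, "zcnt_phylo")
  expect_true(all(abs(vertex_discrepancy(fit$fit$labeling)) < 1e-9))
  expect_equal(fit$fit$score_l1,
               parsimony_score(fit$tree, fit$fit$labeling)$score_l1)
  expect_output(print(fit), "parsimony score")
  expect_output(print(summary(fit)), "CNT violations")
  anc <- ancestral_profiles(fit)
  expect_equal(ncol(anc), ncol(sim$matrix$X))
  # pinning the root at diploid cannot decrease the score
  fitr <- zcnt_phylo(sim$matrix, search_config(max_rounds = 1,
                                               root_at_diploid = TRUE))
  expect_true("diploid" %in% fitr$tree$tip.label)
  # the diploid pin is an added constraint: at least the unpinned optimum
  # of the same topology
  il <- exact_small_parsimony_ilp(ape::drop.tip(fitr$tree, "diploid"),
                                  sim$matrix)
  expect_true(fitr$fit$score_l1 >= il$score_l1 - 1e-6)
  # parametric resampling on the fitted topology
  rs <- simulate(fitr, nsim = 1, seed = 5)
  expect_equal(dim(rs[[1]]$matrix$X), dim(sim$matrix$X))
})
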