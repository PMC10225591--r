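test_that("benchmark generator plants exactly the control perturbation", {
  spec <- simulation_spec(K = 40, mean_degree = 4, m_control = 5)
  bench <- make_benchmark_multiplex(spec, seed = 8)
  mpx <- bench$multiplex
  expect_length(bench$control_set, 5L)
  w1 <- mpx$layers$layer1; w2 <- mpx$layers$layer2
  nbr <- function(w, v) names(which(w[v, ] > 0))
  # every control node has a fully different neighbor set, same degree
  for (cn in bench$control_set) {
    expect_length(intersect(nbr(w1, cn), nbr(w2, cn)), 0)
    expect_equal(length(nbr(w2, cn)), length(nbr(w1, cn)))
  }
  # the majority of non-control nodes keep identical rows
  noncontrol <- setdiff(mpx$node_ids, bench$control_set)
  identical_rows <- vapply(noncontrol, function(v) {
    isTRUE(all.equal(w1[v, ], w2[v, ]))
  }, logical(1L))
  expect_gte(sum(identical_rows), length(mpx$node_ids) - 2 * 5 * 6)
  # and every non-control node keeps at least one original neighbor
  for (v in noncontrol) {
    if (length(nbr(w1, v))) expect_gt(length(intersect(nbr(w1, v), nbr(w2, v))), 0)
  }
  # m_control = 0 means identical layers
  b0 <- make_benchmark_multiplex(simulation_spec(K = 20, m_control = 0), seed = 2)
  expect_equal(b0$multiplex$layers$layer1, b0$multiplex$layers$layer2)
  expect_error(simulation_spec(K = 10, m_control = 10), "m_control")
})

test_that("uniform noise is bounded, symmetric and zero-safe", {
  bench <- make_benchmark_multiplex(simulation_spec(K = 15, m_control = 2),
                                    seed = 3)
  noisy <- add_uniform_noise(bench$multiplex, 0.1, seed = 4)
  for (ly in names(noisy$layers)) {
    d <- noisy$layers[[ly]] - bench$multiplex$layers[[ly]]
    off <- d[upper.tri(d)]
    expect_true(all(off >= 0 & off <= 0.1))
    expect_equal(noisy$layers[[ly]], t(noisy$layers[[ly]]))
  }
  # zero amplitude is the identity
  same <- add_uniform_noise(bench$multiplex, 0, seed = 4)
  expect_identical(same$layers, bench$multiplex$layers)
  expect_error(add_uniform_noise(bench$multiplex, -1), "non-negative")
})

test_that("jaccard index follows set identities", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "a")), 1)  # set semantics
})

test_that("top-m detection sorts by distance with id tie-breaks", {
  dt <- data.frame(owner = "o", node = c("n1", "n2", "n3", "n4"),
                   distance = c(0.1, 0.9, 0.5, 0.5))
  class(dt) <- c("dynamics_table", "data.frame")
  expect_identical(detect_topm(dt, 1), "n2")
  expect_identical(detect_topm(dt, 2), c("n2", "n3"))  # tie n3 < n4
  expect_setequal(detect_topm(dt, 4), dt$node)
  expect_error(detect_topm(dt, 0), "positive")
  expect_error(detect_topm(dt, 5), "exceeds")
})

test_that("laplacian baseline is sign-alignment invariant and null-safe", {
  w <- random_adjacency(K = 12, p = 0.4, seed = 6)
  mpx <- build_multiplex(list(l1 = w, l2 = w))
  dt <- laplacian_baseline(mpx, n_eigvecs = 5)
  expect_true(all(dt$distance < 1e-8))   # identical layers -> no dynamics
  # flipping an eigenvector's sign in one layer is undone by alignment:
  # scaling a layer leaves the eigenvectors' directions unchanged
  mpx2 <- build_multiplex(list(l1 = w, l2 = w * 2))
  dt2 <- laplacian_baseline(mpx2, n_eigvecs = 5)
  expect_true(all(dt2$distance < 1e-6))
})

test_that("synthetic cohort has the promised marginal structure", {
  spec <- cohort_spec(n = 20, K = 10, coupling = 1, zero_inflation = 0.2)
  cohort <- make_synthetic_cohort(spec, seed = 5)
  tab <- cohort$table
  expect_equal(dim(tab), c(40L, 10L))
  # coupling 1: phenotype equals subgroup exactly
  meta <- tab$metadata
  sg <- cohort$truth$subgroup[meta$individual_id]
  expect_true(all((meta$phenotype == "B") == (sg == 2L)))
  # rewired taxa recorded
  expect_true(all(cohort$truth$rewired_taxa %in% colnames(tab$counts)))
  # empirical zero fraction in the ballpark of the structural zero rate
  zf <- mean(tab$counts == 0)
  expect_gt(zf, 0.1); expect_lt(zf, 0.55)
  # overdispersion: variance exceeds the mean for abundant taxa
  v <- apply(tab$counts, 2L, var); m <- colMeans(tab$counts)
  expect_gt(mean(v / pmax(m, 1) > 1.5), 0.7)
  # rewiring probability 0 -> both subgroups share structure across layers
  c0 <- make_synthetic_cohort(cohort_spec(n = 10, K = 10, rewire_prob = 0),
                              seed = 6)
  expect_length(c0$truth$rewired_taxa, 0)
})

test_that("benchmark runner sweeps methods x noise x replicates", {
  spec <- simulation_spec(K = 25, mean_degree = 4, m_control = 3,
                          noise_levels = c(exp(-6), exp(-3)))
  res <- run_benchmark(spec, n_replicates = 2, seed = 5,
                       config = ednn_config(epochs = 150, seed = 1),
                       walk_repeats = 50)
  expect_setequal(unique(res$method), c("mnda", "laplacian"))
  expect_equal(nrow(res), 2L * 3L * 2L)   # methods x (0 + 2 noise) x reps
  expect_true(all(res$jaccard >= 0 & res$jaccard <= 1))
  # reproducibility with the same seed
  res2 <- run_benchmark(spec, n_replicates = 2, seed = 5,
                        config = ednn_config(epochs = 150, seed = 1),
                        walk_repeats = 50)
  expect_identical(res, res2)
})
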