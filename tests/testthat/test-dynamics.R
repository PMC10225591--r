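test_that("cosine distance matches its definition and bounds", {
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(2, 3, 4), c(2, 3, 4)), 0)
  # scale invariance
  expect_equal(cosine_distance(c(1, 2), c(3, 6)), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    d <- cosine_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
    # oracle: direct angle computation
    expect_equal(d, 1 - cos(acos(pmin(pmax(
      sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))), tolerance = 1e-12)
  }
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("identical layers give zero dynamics for every node", {
  w <- random_adjacency(K = 6, p = 0.5, seed = 3)
  mpx <- build_multiplex(list(l1 = w, l2 = w))
  emb <- mnda_embed(mpx, config = quick_config(), walk_seed = 2)
  dt <- node_dynamics(emb)
  expect_s3_class(dt, "dynamics_table")
  expect_equal(nrow(dt), 6L)
  expect_true(all(dt$distance < 1e-12))
})

test_that("planted rewired nodes carry the largest distances", {
  bench <- make_benchmark_multiplex(
    simulation_spec(K = 30, mean_degree = 4, m_control = 4), seed = 11)
  dt <- ensemble_dynamics(bench$multiplex, config = quick_config(epochs = 300),
                          n_repeats = 3)
  top <- detect_topm(dt, 4)
  expect_gte(jaccard(top, bench$control_set), 0.6)
  # the co-clustering route agrees: matched pairs of rewired nodes land in
  # the same cluster least often, so low pair similarity flags the same set
  embs <- attr(dt, "embeddings")
  pts <- lapply(embs, `[[`, "vectors")
  idx <- embs[[1L]]$index
  cons <- consensus_cluster(pts, k_range = 2:4)$consensus
  i1 <- which(idx$layer == unique(idx$layer)[1L])
  i2 <- which(idx$layer == unique(idx$layer)[2L])
  i2 <- i2[match(idx$node[i1], idx$node[i2])]
  sim <- cons[cbind(i1, i2)]
  is_ctrl <- idx$node[i1] %in% bench$control_set
  expect_lt(mean(sim[is_ctrl]), mean(sim[!is_ctrl]))
})

test_that("ensemble dynamics stores repeats and their mean", {
  w <- random_adjacency(K = 5, p = 0.6, seed = 4)
  w2 <- random_adjacency(K = 5, p = 0.6, seed = 5)
  mpx <- build_multiplex(list(l1 = w, l2 = w2))
  dt <- ensemble_dynamics(mpx, config = quick_config(epochs = 50),
                          n_repeats = 3)
  per <- attr(dt, "per_repeat")
  expect_equal(dim(per), c(5L, 3L))
  expect_equal(dt$distance, rowMeans(per))
  # same seed twice -> identical columns
  dt2 <- ensemble_dynamics(mpx, config = quick_config(epochs = 50),
                           n_repeats = 2, seeds = c(7, 7))
  per2 <- attr(dt2, "per_repeat")
  expect_identical(per2[, 1L], per2[, 2L])
  expect_error(ensemble_dynamics(mpx, n_repeats = 1), ">= 2")
})

test_that("consensus clustering recovers well-separated blobs", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(40, 0), 20),
               matrix(rnorm(40, 6), 20))
  rownames(pts) <- paste0("it", 1:40)
  reps <- lapply(1:5, function(i) pts + rnorm(80, sd = 0.05))
  res <- consensus_cluster(reps, k_range = 2:4)
  expect_equal(res$k, 2L)
  truth <- rep(1:2, each = 20)
  expect_true(all(table(res$labels, truth) %in% c(0L, 20L)))
  # within-block consensus ~ 1, between ~ 0
  expect_gt(min(res$consensus[1:20, 1:20]), 0.99)
  expect_lt(max(res$consensus[1:20, 21:40]), 0.01)
  # identical repeats -> frequencies exactly 0 or 1
  res2 <- consensus_cluster(list(pts, pts, pts), k_range = 2:3)
  expect_true(all(res2$consensus %in% c(0, 1)))
  # symmetry, unit diagonal
  expect_equal(res2$consensus, t(res2$consensus))
  expect_equal(unname(diag(res2$consensus)), rep(1, 40))
  expect_error(consensus_cluster(list(pts), k_range = 2:3), "2 repeats")
})

test_that("cluster transitions are row-stochastic and count correctly", {
  labels <- data.frame(
    node = rep(paste0("t", 1:70), 2L),
    layer = rep(c("l1", "l2"), each = 70),
    cluster = c(rep(1L, 70), c(rep(1L, 60), rep(2L, 10))))
  tr <- cluster_transitions(labels)
  expect_equal(unname(tr$counts["1", ]), c(60, 10))
  expect_equal(unname(tr$probabilities["1", "1"]), 6 / 7)
  expect_equal(unname(rowSums(tr$probabilities)), 1)
  # identity when nothing moves
  labels$cluster <- rep(rep(1:2, 35), 2L)
  tr2 <- cluster_transitions(labels)
  expect_equal(unname(as.matrix(tr2$probabilities)), diag(2))
  labels2 <- labels[-1L, ]
  expect_error(cluster_transitions(labels2), "missing")
})

test_that("extreme-dynamics gap detection flags the obvious jump", {
  s <- c(a = 0.01, b = 0.02, c = 0.03, d = 0.9)
  res <- extreme_dynamics(s, q = 0.5)
  expect_identical(res$high_ids, "d")
  # disjoint flags
  expect_length(intersect(res$high_ids, res$low_ids), 0)
  # equally spaced scores: minimal sets (at most one node each end)
  u <- setNames(seq(0.1, 1, length.out = 10), letters[1:10])
  res_u <- extreme_dynamics(u, q = 0.3)
  expect_lte(length(res_u$high_ids), 1L)
  expect_lte(length(res_u$low_ids), 1L)
  expect_error(extreme_dynamics(s[1:3]), "at least 4")
})

test_that("feature matrices have the documented shapes and names", {
  spec <- cohort_spec(n = 8, K = 6, n_rewired = 2, module_size = 3)
  cohort <- make_synthetic_cohort(spec, seed = 2)
  clr <- clr_transform(cohort$table)
  node <- build_feature_matrix("node", abundance = clr)
  expect_equal(dim(node), c(8L, 12L))      # 2K columns
  expect_true(all(grepl("@t[12]$", colnames(node))))
  pipe <- build_cohort_multiplexes(clr, fallback_estimator("pearson_clr"))
  edge <- build_feature_matrix("edge", isns = pipe$isns)
  expect_equal(dim(edge), c(8L, 2L * choose(6, 2)))
  dt <- data.frame(owner = rep(pipe$individuals, each = 6),
                   node = rep(colnames(clr$counts), 8),
                   distance = runif(48))
  class(dt) <- c("dynamics_table", "data.frame")
  dyn <- build_feature_matrix("dynamic", dynamics = dt)
  expect_equal(dim(dyn), c(8L, 6L))        # K columns only
  expect_true(all(grepl("\\.dyn$", colnames(dyn))))
})
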