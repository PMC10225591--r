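test_that("chi-square comparison matches hand computation and permutes", {
  a <- rep(c("x", "y"), each = 10)
  b <- a
  # perfectly aligned 2x2 table (10,0;0,10): chi2 = n = 20 without correction
  res <- compare_clusterings(a, b, n_perm = 200, seed = 1)
  expect_equal(res$chi2, 20)
  expect_lte(res$p_perm, 2 / 201)
  expect_error(compare_clusterings(rep("x", 20), b), "2 clusters")
})

test_that("permutation p-values are calibrated under independent labels", {
  set.seed(42)
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(i) {
    a <- sample(rep(1:2, each = 15))
    b <- sample(rep(1:2, each = 15))
    compare_clusterings(a, b, n_perm = 99, seed = i)$p_perm
  }, numeric(1L))
  rej <- mean(pvals <= 0.05)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej - 0.05), 3 * se + 1e-9)
})

test_that("phylum aggregation normalizes by pair counts, self-loops adapted", {
  ids <- paste0("t", 1:7)
  tax <- data.frame(taxon_id = ids,
                    phylum = c(rep("P1", 3), rep("P2", 4)))
  w <- matrix(0, 7, 7, dimnames = list(ids, ids))
  # 6 inter-phylum edges out of 3*4=12 possible -> 0.5
  w["t1", "t4"] <- w["t1", "t5"] <- w["t2", "t6"] <- 1
  w["t3", "t7"] <- w["t2", "t4"] <- w["t3", "t5"] <- 1
  # 3 intra-P2 edges out of 4*3/2=6 possible -> 0.5
  w["t4", "t5"] <- w["t5", "t6"] <- w["t6", "t7"] <- 1
  w <- pmax(w, t(w))
  agg <- aggregate_phyla(global_network(w), tax, mode = "binary")
  expect_equal(agg$eta["P1", "P2"], 6)
  expect_equal(agg$eta_norm["P1", "P2"], 0.5)
  expect_equal(agg$eta["P2", "P2"], 3)
  expect_equal(agg$eta_norm["P2", "P2"], 0.5)
  expect_equal(agg$eta_norm["P1", "P1"], 0)
  # complete bipartite inter-connection -> exactly 1
  wf <- matrix(0, 7, 7, dimnames = list(ids, ids))
  wf[1:3, 4:7] <- 1; wf <- pmax(wf, t(wf))
  aggf <- aggregate_phyla(global_network(wf), tax, mode = "binary")
  expect_equal(aggf$eta_norm["P1", "P2"], 1)
  # binary eta_norm always within [0, 1]
  expect_true(all(aggf$eta_norm >= 0 & aggf$eta_norm <= 1))
  # weighted and binary agree when all weights are 1
  aggw <- aggregate_phyla(global_network(wf), tax, mode = "weighted")
  expect_equal(aggw$eta_norm, aggf$eta_norm)
  expect_error(aggregate_phyla(global_network(w), tax[-1, ], "binary"),
               "phylum annotation")
})

make_two_layer_isns <- function(seed = 3, n_ind = 5, K = 4) {
  tab <- toy_table(n_ind = n_ind, K = K, seed = seed, two_timepoints = TRUE)
  clr <- clr_transform(tab)
  build_cohort_multiplexes(clr, fallback_estimator("pearson_clr"))
}

test_that("difference networks subtract averaged layers around seeds", {
  pipe <- make_two_layer_isns()
  isns <- pipe$isns
  # identical layers -> zero differences
  same <- list(t1 = isns$t1, t2 = isns$t1)
  d0 <- difference_network(same, group_members = pipe$individuals)
  expect_true(all(abs(d0$difference) < 1e-12))
  # one individual per group: difference of that individual's two ISNs
  ind <- pipe$individuals[1L]
  d1 <- difference_network(isns, group_members = ind)
  expect_equal(d1$difference,
               isns$t2$networks[[ind]] - isns$t1$networks[[ind]])
  # antisymmetry under swapping the layer order
  d2 <- difference_network(isns, group_members = pipe$individuals)
  d2r <- difference_network(isns, group_members = pipe$individuals,
                            layer_pair = c("t2", "t1"))
  expect_equal(d2$difference, -d2r$difference)
  expect_error(difference_network(isns, character(0)), "empty group")
})

test_that("seed restriction keeps exactly seeds plus distance-1 neighbors", {
  ids <- c("a", "b", "c", "d")
  w1 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w1["a", "b"] <- w1["b", "a"] <- 1          # a - b; c - d separate
  w1["c", "d"] <- w1["d", "c"] <- 1
  w2 <- w1
  fake_set <- function(w) {
    structure(list(individual_ids = "i1", n_reference = 3L, node_ids = ids,
                   networks = list(i1 = w), abs_applied = TRUE),
              class = "isn_set")
  }
  d <- difference_network(list(l1 = fake_set(w1), l2 = fake_set(w2)),
                          group_members = "i1", seed_taxa = "a")
  expect_setequal(d$nodes, c("a", "b"))
})

test_that("filtration curves sweep thresholds with monotone edge counts", {
  ids <- c("a", "b", "c")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["a", "b"] <- w["b", "a"] <- 0.1
  w["b", "c"] <- w["c", "b"] <- 0.2
  w["a", "c"] <- w["c", "a"] <- 0.3
  fc <- filtration_curve(w, "edge_count")
  expect_equal(fc$threshold, c(0.1, 0.2, 0.3))
  expect_equal(fc$value, c(3, 2, 1))
  # value at threshold above the current max would be 0: approximated by
  # the curve being non-increasing and ending at the largest weight
  expect_true(all(diff(fc$value) <= 0))
  fw <- filtration_curve(w, "total_weight")
  expect_equal(fw$value, c(0.6, 0.5, 0.3))
  fn <- filtration_curve(w, "n_components")
  expect_equal(fn$value[1L], 1)       # triangle connected
  expect_equal(fn$value[3L], 2)       # only a-c left: b isolated
  expect_error(filtration_curve(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "empty")
})

test_that("discriminator ranking orders by pooled selection counts", {
  rep1 <- structure(list(selection_counts = c(a = 3, b = 1, c = 0),
                         auc = 0.7, mean_auc = 0.7, se_auc = 0,
                         n_repeats = 1, config = list()),
                    class = "prediction_report")
  rep2 <- structure(list(selection_counts = c(a = 1, b = 4, c = 0),
                         auc = 0.7, mean_auc = 0.7, se_auc = 0,
                         n_repeats = 1, config = list()),
                    class = "prediction_report")
  rk <- rank_discriminators(list(rep1, rep2))
  expect_equal(rk$feature, c("b", "a", "c"))
  expect_equal(rk$count, c(5, 4, 0))
  # never-selected feature ranks last with count 0
  expect_equal(rk$count[rk$feature == "c"], 0)
  expect_error(rank_discriminators(list()), "empty")
})

test_that("prediction is deterministic per seed and near chance on noise", {
  set.seed(8)
  n <- 24
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(paste0("i", 1:n), paste0("f", 1:5)))
  x[, 1] <- x[, 1] + rep(c(0, 2.5), each = n / 2)   # one strong feature
  y <- factor(rep(c("A", "B"), each = n / 2))
  r1 <- predict_phenotype(x, y, n_repeats = 2, seed = 4, max_features = 3)
  r2 <- predict_phenotype(x, y, n_repeats = 2, seed = 4, max_features = 3)
  expect_identical(r1$auc, r2$auc)
  expect_gt(r1$mean_auc, 0.85)
  expect_gt(r1$selection_counts[["f1"]], 0.8 * 2 * n)  # f1 selected nearly always
  # permuted labels: near chance
  set.seed(9)
  yp <- sample(y)
  rp <- predict_phenotype(x[, 2:5], yp, n_repeats = 2, seed = 4,
                          max_features = 3)
  expect_gt(rp$mean_auc, 0.2); expect_lt(rp$mean_auc, 0.8)
  expect_error(predict_phenotype(x, factor(rep("A", n))), "binary")
})
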