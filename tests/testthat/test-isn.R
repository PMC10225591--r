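# naive, independent re-computation of the leave-one-out perturbation for a
# correlation estimator: used as the oracle for lioness_isn
naive_lioness <- function(counts, ind_drop, all_inds, pseudocount = 0.5) {
  clr <- function(m) {
    lx <- log(m + pseudocount); lx - rowMeans(lx)
  }
  N <- length(all_inds)
  w_full <- cor(clr(counts))
  w_loo <- cor(clr(counts[rownames(counts) != paste0(ind_drop, "_t1"), ,
                          drop = FALSE]))
  out <- N * w_full - (N - 1) * w_loo
  diag(out) <- 0
  out
}

test_that("leave-one-out perturbation matches a brute-force recomputation", {
  tab <- toy_table(n_ind = 6, K = 4, seed = 3)
  est <- fallback_estimator("pearson_clr")
  isns <- lioness_isn(tab, est)
  expect_equal(isns$n_reference, 6L)
  for (ind in isns$individual_ids) {
    oracle <- naive_lioness(tab$counts, ind, isns$individual_ids)
    expect_equal(isns$networks[[ind]], oracle, tolerance = 1e-10)
  }
  # symmetry and zero diagonal
  for (m in isns$networks) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 4))
  }
})

test_that("homogeneous and negative-weight cases follow the formula", {
  # all LOO networks identical to the global network -> every ISN edge
  # equals the global weight (N*w - (N-1)*w = w)
  ids <- c("a", "b", "c")
  w_const <- matrix(0.5, 3, 3, dimnames = list(ids, ids)); diag(w_const) <- 0
  est_const <- function(table) global_network(w_const, "constant")
  tab <- toy_table(n_ind = 10, K = 3)
  colnames(tab$counts) <- ids
  isns <- lioness_isn(tab, est_const)
  for (m in isns$networks) expect_equal(m, w_const)

  # N=5, w=0.4, w_loo=0.6 -> 5*0.4 - 4*0.6 = -0.4
  w_g <- matrix(0.4, 3, 3, dimnames = list(ids, ids)); diag(w_g) <- 0
  w_l <- matrix(0.6, 3, 3, dimnames = list(ids, ids)); diag(w_l) <- 0
  est_split <- function(table) {
    if (nrow(table$counts) == 5L) global_network(w_g) else global_network(w_l)
  }
  tab5 <- toy_table(n_ind = 5, K = 3)
  colnames(tab5$counts) <- ids
  isns5 <- lioness_isn(tab5, est_split)
  expect_equal(isns5$networks[[1L]]["a", "b"], 5 * 0.4 - 4 * 0.6)
  expect_equal(isns5$networks[[1L]]["a", "b"], -0.4)
})

test_that("estimator invocation count is N + 1", {
  calls <- 0L
  est <- function(table) {
    calls <<- calls + 1L
    fallback_estimator("pearson_clr")(table)
  }
  tab <- toy_table(n_ind = 5, K = 3)
  lioness_isn(tab, est)
  expect_equal(calls, 6L)
  expect_error(lioness_isn(toy_table(n_ind = 2, K = 3),
                           fallback_estimator()), "at least 3")
})

test_that("absolute transform is explicit, flagged and idempotent", {
  tab <- toy_table(n_ind = 5, K = 4, seed = 9)
  isns <- lioness_isn(tab, fallback_estimator("pearson_clr"))
  expect_true(any(unlist(isns$networks) < 0))
  a1 <- absolute_weights(isns)
  expect_true(a1$abs_applied)
  expect_true(all(unlist(a1$networks) >= 0))
  expect_equal(a1$networks[[1L]], abs(isns$networks[[1L]]))
  expect_warning(a2 <- absolute_weights(a1), "already applied")
  expect_equal(a2$networks, a1$networks)
})

test_that("global network is the exact ISN average for a linear estimator", {
  # estimator linear in per-sample contributions: mean of centered products
  # (population covariance with fixed global centering)
  tab <- toy_table(n_ind = 8, K = 4, seed = 5)
  mu <- colMeans(tab$counts)
  est_linear <- function(table) {
    xc <- sweep(table$counts, 2L, mu)
    w <- crossprod(xc) / nrow(xc)
    diag(w) <- 0
    global_network(w, "mean-of-products")
  }
  isns <- lioness_isn(tab, est_linear)
  rep <- isn_average_check(isns)
  expect_lt(rep$max_abs_deviation, 1e-10)
  # nonlinear (Pearson) estimator: small but nonzero deviations
  isns_p <- lioness_isn(toy_table(n_ind = 30, K = 4, seed = 7),
                        fallback_estimator("pearson_clr"))
  rep_p <- isn_average_check(isns_p)
  expect_gt(rep_p$max_abs_deviation, 0)
  expect_lt(rep_p$max_abs_deviation, 0.5)
  expect_error(isn_average_check(absolute_weights(isns)), "absolute")
})

test_that("fallback estimator behaves on correlated, sparse and constant taxa", {
  set.seed(11)
  n <- 500
  x <- rnorm(n)
  counts <- cbind(a = exp(x), b = exp(x), c = exp(rnorm(n)), d = exp(rnorm(n)))
  counts <- counts / rowSums(counts) * 1e4   # compositional closure
  rownames(counts) <- paste0("s", 1:n)
  meta <- data.frame(sample_id = rownames(counts),
                     individual_id = paste0("i", 1:n), time_point = "t1")
  tab <- abundance_table(counts, meta)
  net <- fallback_estimator("pearson_clr")(tab)
  expect_gt(net$weights["a", "b"], 0.99)
  # independent taxa near zero
  expect_lt(abs(net$weights["c", "d"]), 0.2)
  # sparsification keeps at most half of the nonzero entries
  net5 <- fallback_estimator("pearson_clr", sparsify_quantile = 0.5)(tab)
  expect_lte(sum(net5$weights[upper.tri(net5$weights)] != 0),
             ceiling(sum(net$weights[upper.tri(net$weights)] != 0) / 2))
  # constant taxon -> zero weights with warning
  counts2 <- counts; counts2[, "d"] <- 5
  tab2 <- abundance_table(counts2, meta)
  expect_warning(net2 <- fallback_estimator("pearson_clr")(tab2), "constant")
  expect_true(all(net2$weights["d", ] == 0))
})

test_that("precomputed networks can be served from a directory", {
  tab <- toy_table(n_ind = 4, K = 3, seed = 2)
  dir <- withr::local_tempdir()
  est <- fallback_estimator("pearson_clr")
  write_network(est(tab), file.path(dir, "global.csv"))
  for (ind in unique(tab$metadata$individual_id)) {
    keep <- tab$metadata$individual_id != ind
    sub <- abundance_table(tab$counts[keep, , drop = FALSE],
                           tab$metadata[keep, , drop = FALSE])
    write_network(est(sub), file.path(dir, paste0("loo_", ind, ".csv")))
  }
  isns_dir <- lioness_isn(tab, estimator_from_dir(dir))
  isns_ref <- lioness_isn(tab, est)
  expect_equal(isns_dir$networks, isns_ref$networks, tolerance = 1e-6)
})
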