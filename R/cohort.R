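#' Consensus clustering of individuals by their neighborhood dynamics
#'
#' Individuals are represented by their dynamic-view feature vectors (one
#' cosine distance per taxon) and clustered with the same ensemble consensus
#' machinery used for taxa. When the dynamics table carries per-repeat
#' distances (from [ensemble_dynamics()]) each ensemble repeat supplies one
#' base partition; otherwise repeats differ only in k-means initialization.
#' Because the features summarize change *across* time points, the resulting
#' communities are time-invariant.
#'
#' @param dynamics_table a `dynamics_table` over individuals.
#' @param k_range candidate cluster counts (default `2:6`).
#' @param n_repeats base partitions when no per-repeat distances are stored.
#' @param seed RNG seed.
#' @return as [consensus_cluster()], with individual ids on the labels.
#' @export
cluster_individuals <- function(dynamics_table, k_range = 2:6, n_repeats = 20,
                                seed = 1) {
  stopifnot(inherits(dynamics_table, "dynamics_table"))
  inds <- unique(dynamics_table$owner)
  if (length(inds) < 4L) stop("need at least 4 individuals")
  per <- attr(dynamics_table, "per_repeat")
  mk_mat <- function(dist_vec) {
    dt <- dynamics_table
    dt$distance <- dist_vec
    build_feature_matrix("dynamic", dynamics = dt)
  }
  pts <- if (!is.null(per) && ncol(per) >= 2L) {
    lapply(seq_len(ncol(per)), function(r) mk_mat(per[, r]))
  } else {
    m <- mk_mat(dynamics_table$distance)
    replicate(n_repeats, m, simplify = FALSE)
  }
  res <- consensus_cluster(pts, k_range = k_range, base_seed = seed)
  names(res$labels) <- rownames(pts[[1L]])
  res
}

#' Chi-square comparison of two clusterings with a permutation p-value
#'
#' The chi-square statistic of the contingency table between two labelings
#' of the same individuals (no continuity correction), with significance
#' assessed by permuting one labeling: `p = (1 + #{chi2_perm >= chi2_obs}) /
#' (1 + n_perm)`.
#'
#' @param labels_a,labels_b labelings of the same individuals (vectors of
#'   equal length, each with >= 2 distinct values).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `chi2`, `p_perm`, `table`.
#' @export
compare_clusterings <- function(labels_a, labels_b, n_perm = 10000, seed = 1) {
  stopifnot(length(labels_a) == length(labels_b))
  a <- as.factor(labels_a); b <- as.factor(labels_b)
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("both labelings must have at least 2 clusters")
  }
  chi2_stat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- chi2_stat(a, b)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) chi2_stat(sample(a), b),
                 numeric(1L))
  list(chi2 = obs, p_perm = (1 + sum(perm >= obs)) / (1 + n_perm),
       table = table(a, b))
}

# Stratified fold assignment: each class split as evenly as possible.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_rbf_classifier <- function() {
  list(
    fit = function(x, y) e1071::svm(x, y, kernel = "radial", scale = FALSE,
                                    fitted = FALSE),
    score = function(model, x) {
      as.numeric(attr(stats::predict(model, x, decision.values = TRUE),
                      "decision.values"))
    }
  )
}

# Orient decision scores so larger means the second factor level, using the
# column header libsvm reports ("lev1/lev2" => positive favors lev1).
orient_scores <- function(model, x, y_levels) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- as.numeric(dv)
  hdr <- colnames(dv)[1L]
  if (identical(hdr, paste(y_levels[1L], y_levels[2L], sep = "/"))) -s else s
}

#' Phenotype prediction with LOOCV, undersampling and forward selection
#'
#' Outer leave-one-out cross-validation over individuals; within each
#' training fold the majority class is undersampled to the minority size,
#' features are chosen by greedy forward selection maximizing inner
#' stratified 5-fold CV AUC (stopping when no candidate improves, or at
#' `max_features`), an RBF-kernel SVM is fit, and the left-out individual is
#' scored. One ROC/AUC is computed per repeat from the pooled held-out
#' decision scores (one score per fold precludes per-fold AUCs); the report
#' aggregates AUC mean and standard error across repeats and accumulates how
#' often each feature was selected.
#'
#' @param feature_matrix individuals x features numeric matrix (one of the
#'   [build_feature_matrix()] views).
#' @param labels binary factor (or coercible) aligned with the rows.
#' @param classifier list with `fit(x, y)` and `score(model, x)`; default
#'   RBF-kernel SVM.
#' @param n_repeats repetitions of the whole LOOCV (default 10).
#' @param seed master seed; per-repeat streams are derived from it.
#' @param inner_folds folds of the inner selection CV (default 5).
#' @param max_features forward-selection cap (default 10).
#' @param min_improvement minimum inner-CV AUC gain a candidate must
#'   deliver to be added (default 0.005); guards the greedy search against
#'   chance-level improvements.
#' @param n_candidates optional per-fold pre-screen: only the
#'   `n_candidates` features with the largest absolute two-sample t
#'   statistic on the balanced training fold enter the greedy search
#'   (`NULL`, the default, searches all features).
#' @return object of class `prediction_report`: list with `auc` (per
#'   repeat), `mean_auc`, `se_auc`, `selection_counts`, `n_repeats`,
#'   `config`.
#' @export
predict_phenotype <- function(feature_matrix, labels, classifier = NULL,
                              n_repeats = 10, seed = 1, inner_folds = 5,
                              max_features = 10, min_improvement = 0.005,
                              n_candidates = NULL) {
  x <- as.matrix(feature_matrix)
  y <- as.factor(labels)
  if (nlevels(y) != 2L) stop("labels must be binary")
  if (min(table(y)) < 3L) stop("each class needs at least 3 members")
  stopifnot(nrow(x) == length(y))
  # scale once; constant features left untouched
  sds <- apply(x, 2L, stats::sd)
  x <- sweep(x, 2L, colMeans(x))
  x <- sweep(x, 2L, ifelse(sds > 0, sds, 1), `/`)
  n <- nrow(x); p <- ncol(x)
  use_default <- is.null(classifier)
  if (use_default) classifier <- svm_rbf_classifier()
  sel_counts <- stats::setNames(numeric(p), colnames(x))
  aucs <- numeric(n_repeats)
  cv_auc <- function(xtr, ytr, feats, fold) {
    sc <- numeric(length(ytr))
    for (f in unique(fold)) {
      tr <- fold != f
      if (length(unique(ytr[tr])) < 2L) return(NA_real_)
      m <- classifier$fit(xtr[tr, feats, drop = FALSE], ytr[tr])
      sc[!tr] <- if (use_default) {
        orient_scores(m, xtr[!tr, feats, drop = FALSE], levels(ytr))
      } else {
        classifier$score(m, xtr[!tr, feats, drop = FALSE])
      }
    }
    rank_auc(sc, ytr)
  }
  for (rep_i in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, rep_i))
    scores <- numeric(n)
    for (i in seq_len(n)) {
      ytr_all <- y[-i]; xtr_all <- x[-i, , drop = FALSE]
      # undersample the majority class inside the training fold only
      tabs <- table(ytr_all)
      nmin <- min(tabs)
      keep <- unlist(lapply(levels(ytr_all), function(cl) {
        idx <- which(ytr_all == cl)
        if (length(idx) > nmin) sample(idx, nmin) else idx
      }))
      xtr <- xtr_all[keep, , drop = FALSE]; ytr <- droplevels(ytr_all[keep])
      fold <- stratified_folds(ytr, min(inner_folds, nmin))
      pool <- seq_len(p)
      if (!is.null(n_candidates) && n_candidates < p) {
        g1 <- ytr == levels(ytr)[1L]
        tstat <- abs(colMeans(xtr[g1, , drop = FALSE]) -
                       colMeans(xtr[!g1, , drop = FALSE])) /
          sqrt(apply(xtr, 2L, stats::var) / nrow(xtr) + 1e-12)
        pool <- order(-tstat)[seq_len(n_candidates)]
      }
      selected <- integer(0)
      best_auc <- -Inf
      repeat {
        cand <- setdiff(pool, selected)
        if (length(cand) == 0L || length(selected) >= max_features) break
        cand_auc <- vapply(cand, function(f) {
          cv_auc(xtr, ytr, c(selected, f), fold)
        }, numeric(1L))
        if (all(is.na(cand_auc))) break
        j <- which.max(cand_auc)
        if (cand_auc[j] <= best_auc + min_improvement) break
        best_auc <- cand_auc[j]
        selected <- c(selected, cand[j])
      }
      if (length(selected) == 0L) selected <- seq_len(p)
      m <- classifier$fit(xtr[, selected, drop = FALSE], ytr)
      scores[i] <- if (use_default) {
        orient_scores(m, x[i, selected, drop = FALSE], levels(ytr))
      } else {
        classifier$score(m, x[i, selected, drop = FALSE])
      }
      sel_counts[selected] <- sel_counts[selected] + 1
    }
    aucs[rep_i] <- rank_auc(scores, y)
  }
  structure(list(auc = aucs, mean_auc = mean(aucs),
                 se_auc = stats::sd(aucs) / sqrt(n_repeats),
                 selection_counts = sel_counts, n_repeats = n_repeats,
                 config = list(classifier = if (use_default) "svm_rbf" else "custom",
                               balancing = "undersample-majority",
                               inner_folds = inner_folds,
                               max_features = max_features,
                               min_improvement = min_improvement,
                               n_candidates = n_candidates)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: mean AUC %.3f (se %.3f) over %d repeats\n",
              x$mean_auc, x$se_auc, x$n_repeats))
  top <- utils::head(sort(x$selection_counts, decreasing = TRUE), 5L)
  cat("  top selected features:",
      paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by how often forward selection chose them
#'
#' Higher selection counts across folds, repeats (and, when reports from
#' several embedding ensembles are pooled, across embeddings) indicate more
#' consistently discriminative taxa. Ties break lexicographically.
#'
#' @param report a `prediction_report`, or a list of them to pool.
#' @return data.frame with `feature` and `count`, in descending count order.
#' @export
rank_discriminators <- function(report) {
  reports <- if (inherits(report, "prediction_report")) list(report) else report
  if (length(reports) == 0L) stop("empty report")
  stopifnot(all(vapply(reports, inherits, logical(1L), "prediction_report")))
  counts <- Reduce(`+`, lapply(reports, `[[`, "selection_counts"))
  out <- data.frame(feature = names(counts), count = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$feature), , drop = FALSE]
}

#' Aggregate a taxon network to phylum-level meta-nodes
#'
#' Edges are pooled between (and within) phyla and normalized by the number
#' of possible pairs: `eta / (n1 * n2)` between phyla of sizes `n1` and
#' `n2`, and `eta / (n * (n - 1) / 2)` within a phylum (self-loop). In
#' binary mode `eta` counts nonzero edges and the normalized value is the
#' fraction of realized pairs, a percentage; in weighted mode `eta` sums
#' edge weights with the same normalizers.
#'
#' @param net a [global_network()] (or symmetric matrix).
#' @param taxonomy data.frame with `taxon_id` and `phylum` covering every
#'   node.
#' @param mode `"binary"` (count nonzero edges) or `"weighted"` (sum
#'   weights).
#' @return object of class `phylum_aggregate`: list with `phyla`, `sizes`,
#'   `eta`, `eta_norm` (symmetric matrices whose diagonal holds self-loop
#'   values).
#' @export
aggregate_phyla <- function(net, taxonomy, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- if (inherits(net, "global_network")) net$weights else as.matrix(net)
  ids <- rownames(w)
  ph <- taxonomy$phylum[match(ids, taxonomy$taxon_id)]
  if (anyNA(ph)) stop("taxon without phylum annotation: ",
                      paste(ids[is.na(ph)], collapse = ", "))
  phyla <- sort(unique(ph))
  sizes <- stats::setNames(as.numeric(table(factor(ph, levels = phyla))), phyla)
  a <- if (mode == "binary") (w != 0) * 1 else w
  P <- length(phyla)
  eta <- matrix(0, P, P, dimnames = list(phyla, phyla))
  for (i in seq_len(P)) for (j in i:P) {
    ri <- ph == phyla[i]; rj <- ph == phyla[j]
    block <- a[ri, rj, drop = FALSE]
    eta[i, j] <- eta[j, i] <- if (i == j) sum(block[upper.tri(block)]) else sum(block)
  }
  denom <- outer(sizes, sizes)
  diag(denom) <- sizes * (sizes - 1) / 2
  eta_norm <- ifelse(denom > 0, eta / denom, 0)
  structure(list(phyla = phyla, sizes = sizes, eta = eta,
                 eta_norm = eta_norm, mode = mode),
            class = "phylum_aggregate")
}

#' Group-averaged difference network around seed taxa
#'
#' Averages the individual-specific networks of a group of individuals per
#' layer, subtracts the earlier layer's averaged weights from the later
#' layer's, and restricts the result to the seed taxa plus their distance-1
#' neighbors in either averaged layer. Positive entries mean the association
#' strengthened over time in this group, negative that it weakened.
#'
#' @param isns named list of two `isn_set`s (names = layer labels, earlier
#'   first unless `layer_pair` says otherwise).
#' @param group_members individual ids to average over (non-empty).
#' @param seed_taxa taxa around which the subnetwork is extracted; `NULL`
#'   keeps all nodes.
#' @param layer_pair length-2 vector `(earlier, later)`; defaults to
#'   `names(isns)`.
#' @return list with `nodes`, `difference` (signed symmetric matrix over
#'   `nodes`), `group_members`, `layer_pair`.
#' @export
difference_network <- function(isns, group_members, seed_taxa = NULL,
                               layer_pair = NULL) {
  stopifnot(is.list(isns), length(isns) == 2L, !is.null(names(isns)))
  if (length(group_members) == 0L) stop("empty group")
  layer_pair <- layer_pair %||% names(isns)
  avg <- lapply(layer_pair, function(ly) {
    set <- isns[[ly]]
    missing_ind <- setdiff(group_members, set$individual_ids)
    if (length(missing_ind)) stop("individual(s) missing in layer ", ly, ": ",
                                  paste(missing_ind, collapse = ", "))
    Reduce(`+`, set$networks[group_members]) / length(group_members)
  })
  dmat <- avg[[2L]] - avg[[1L]]
  ids <- rownames(dmat)
  if (!is.null(seed_taxa)) {
    if (!all(seed_taxa %in% ids)) {
      stop("unknown seed taxa: ", paste(setdiff(seed_taxa, ids), collapse = ", "))
    }
    nb <- unique(unlist(lapply(seed_taxa, function(s) {
      ids[avg[[1L]][s, ] != 0 | avg[[2L]][s, ] != 0]
    })))
    keep <- ids[ids %in% union(seed_taxa, nb)]
    dmat <- dmat[keep, keep, drop = FALSE]
  }
  list(nodes = rownames(dmat), difference = dmat,
       group_members = group_members, layer_pair = layer_pair)
}

#' Graph filtration curve
#'
#' Evaluates a graph descriptor on the subgraph of edges with absolute
#' weight at or above each threshold, sweeping the sorted unique absolute
#' edge weights. The edge-count descriptor is non-increasing along the
#' sweep; connected components are counted on nodes incident to surviving
#' edges plus isolated nodes.
#'
#' @param net a [global_network()], a symmetric matrix, or a
#'   [difference_network()] result (its signed `difference` matrix is used
#'   via absolute values).
#' @param descriptor `"edge_count"`, `"total_weight"` (sum of surviving
#'   absolute weights) or `"n_components"`.
#' @return data.frame with `threshold` and `value`, class
#'   `filtration_curve`.
#' @export
filtration_curve <- function(net, descriptor = c("edge_count", "total_weight",
                                                 "n_components")) {
  descriptor <- match.arg(descriptor)
  w <- if (inherits(net, "global_network")) net$weights
       else if (is.list(net) && !is.null(net$difference)) net$difference
       else as.matrix(net)
  aw <- abs(w)
  vals <- aw[upper.tri(aw)]
  vals <- vals[vals > 0]
  if (length(vals) == 0L) stop("empty network")
  thresholds <- sort(unique(vals))
  value <- vapply(thresholds, function(t) {
    keep <- aw >= t & upper.tri(aw)
    switch(descriptor,
      edge_count = sum(keep),
      total_weight = sum(aw[keep]),
      n_components = {
        adj <- (aw >= t) * 1
        diag(adj) <- 0
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                                 weighted = NULL)
        igraph::components(g)$no
      })
  }, numeric(1L))
  out <- data.frame(threshold = thresholds, value = value)
  attr(out, "descriptor") <- descriptor
  class(out) <- c("filtration_curve", "data.frame")
  out
}
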