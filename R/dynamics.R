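#' Cosine distance between two embedding vectors
#'
#' `1 - A.B / (|A| |B|)`, the complement of cosine similarity; values lie in
#' `[0, 2]`, with 0 for collinear same-direction vectors and 2 for opposite
#' directions. Zero-norm vectors make the quantity undefined and raise an
#' error; callers that must handle rectifier dead units can use the bounded
#' convention of [node_dynamics()] instead.
#'
#' @param A,B equal-length numeric vectors with nonzero norm.
#' @return a number in `[0, 2]`.
#' @export
cosine_distance <- function(A, B) {
  stopifnot(length(A) == length(B), length(A) > 0)
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0) stop("cosine distance undefined for zero-norm vectors")
  d <- 1 - sum(A * B) / (na * nb)
  min(max(d, 0), 2)
}

# Bounded convention for possibly-zero vectors (ReLU embeddings can die):
# both zero -> identical neighborhoods -> 0; exactly one zero -> maximal
# displacement -> 2.
cosine_distance_safe <- function(A, B) {
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(2)
  min(max(1 - sum(A * B) / (na * nb), 0), 2)
}

#' Per-node neighborhood dynamics between two layers
#'
#' For every (owner, node), the cosine distance between the node's embedding
#' in the first and second layer of `layer_pair`: the displacement of the
#' taxon's local-neighborhood representation across time points.
#'
#' @param embeddings an `embedding_set` from [train_ednn()] / [mnda_embed()].
#' @param layer_pair length-2 vector of layer names; defaults to the first
#'   two layers present.
#' @return object of class `dynamics_table`: data.frame with columns
#'   `owner`, `node`, `distance`.
#' @export
node_dynamics <- function(embeddings, layer_pair = NULL) {
  stopifnot(inherits(embeddings, "embedding_set"))
  idx <- embeddings$index
  if (is.null(layer_pair)) layer_pair <- unique(idx$layer)[1:2]
  stopifnot(length(layer_pair) == 2L)
  a <- idx$layer == layer_pair[1L]
  b <- idx$layer == layer_pair[2L]
  if (!any(a) || !any(b)) stop("layer(s) not present in the embedding set")
  ka <- paste(idx$owner[a], idx$node[a], sep = "\r")
  kb <- paste(idx$owner[b], idx$node[b], sep = "\r")
  if (!setequal(ka, kb)) stop("owners/nodes not matched across the two layers")
  va <- embeddings$vectors[a, , drop = FALSE]
  vb <- embeddings$vectors[b, , drop = FALSE][match(ka, kb), , drop = FALSE]
  d <- vapply(seq_len(nrow(va)), function(i) {
    cosine_distance_safe(va[i, ], vb[i, ])
  }, numeric(1L))
  out <- data.frame(owner = idx$owner[a], node = idx$node[a], distance = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("dynamics_table", "data.frame")
  out
}

#' Ensemble neighborhood dynamics over repeated EDNN trainings
#'
#' Neural-network training is non-convex, so single runs differ between
#' seeds. The ensemble retrains the EDNN once per seed on the same walk
#' profiles and reports per-repeat cosine distances together with their
#' across-repeat mean — the robust per-taxon dynamics score used for ranking
#' and clustering.
#'
#' @param multiplexes list of [build_multiplex()] objects.
#' @param config base [ednn_config()]; its seed is replaced per repeat.
#' @param n_repeats number of EDNN retrainings (>= 2; default 50).
#' @param seeds optional explicit seed per repeat (length `n_repeats`);
#'   defaults to streams derived from `config$seed`.
#' @param profiles optional precomputed profiles (see [mnda_embed()]).
#' @param ... walk parameters forwarded to [mnda_embed()].
#' @return a `dynamics_table` whose `distance` column is the across-repeat
#'   mean; per-repeat distances in attribute `"per_repeat"` (matrix, one
#'   column per repeat), embeddings of the last repeat in `"last_embedding"`,
#'   and all per-repeat embedding sets in `"embeddings"`.
#' @export
ensemble_dynamics <- function(multiplexes, config = ednn_config(),
                              n_repeats = 50, seeds = NULL, profiles = NULL,
                              ...) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_repeats), function(i) derive_seed(config$seed, i),
                    numeric(1L))
  }
  stopifnot(length(seeds) == n_repeats)
  if (inherits(multiplexes, "multiplex_network")) multiplexes <- list(multiplexes)
  if (is.null(profiles)) {
    dots <- list(...)
    profiles <- lapply(seq_along(multiplexes), function(i) {
      do.call(walk_profiles, c(list(multiplexes[[i]],
                                    seed = derive_seed(config$seed, 1000L + i)),
                               dots))
    })
  }
  per <- NULL
  tab <- NULL
  embs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config; cfg$seed <- seeds[r]
    emb <- mnda_embed(multiplexes, config = cfg, profiles = profiles)
    dt <- node_dynamics(emb)
    if (is.null(per)) {
      per <- matrix(NA_real_, nrow(dt), n_repeats)
      tab <- dt
    }
    per[, r] <- dt$distance
    embs[[r]] <- emb
  }
  tab$distance <- rowMeans(per)
  attr(tab, "per_repeat") <- per
  attr(tab, "last_embedding") <- embs[[n_repeats]]
  attr(tab, "embeddings") <- embs
  tab
}

#' Ensemble consensus clustering
#'
#' Items (typically the (node, layer) points of the joint embedding space)
#' are partitioned once per ensemble repeat; the consensus matrix records
#' the fraction of repeats in which two items fall in the same cluster.
#' Final labels come from average-linkage hierarchical clustering of
#' `1 - consensus`, with the number of clusters chosen by silhouette over
#' `k_range`.
#'
#' @param per_repeat_points list (one element per repeat) of numeric
#'   matrices, rows = items (consistent order and row count across repeats).
#' @param k_range candidate cluster counts (default `2:6`).
#' @param base_seed seed for the per-repeat k-means starts.
#' @return list with `consensus` (items x items frequency matrix), `labels`
#'   (final integer labels), `k` (chosen cluster count), `per_repeat_labels`.
#' @export
consensus_cluster <- function(per_repeat_points, k_range = 2:6, base_seed = 1) {
  n_rep <- length(per_repeat_points)
  if (n_rep < 2L) stop("consensus clustering needs at least 2 repeats")
  n <- nrow(per_repeat_points[[1L]])
  if (n < max(k_range) + 1L) stop("too few items for the requested k_range")
  co <- matrix(0, n, n)
  per_labels <- matrix(NA_integer_, n, n_rep)
  for (r in seq_len(n_rep)) {
    pts <- per_repeat_points[[r]]
    if (nrow(pts) != n) stop("repeat ", r, " has a different item count")
    set.seed(derive_seed(base_seed, r))
    dmat <- stats::dist(pts)
    best <- NULL; best_sil <- -Inf
    for (k in k_range) {
      km <- tryCatch(stats::kmeans(pts, centers = k, nstart = 5L),
                     error = function(e) NULL)
      if (is.null(km)) next
      sil <- mean(cluster::silhouette(km$cluster, dmat)[, 3L])
      if (sil > best_sil) { best_sil <- sil; best <- km$cluster }
    }
    if (is.null(best)) stop("base clustering failed in repeat ", r)
    per_labels[, r] <- best
    co <- co + outer(best, best, `==`)
  }
  co <- co / n_rep
  rn <- rownames(per_repeat_points[[1L]])
  dimnames(co) <- list(rn, rn)
  hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
  dmat <- stats::as.dist(1 - co)
  best_lab <- NULL; best_sil <- -Inf; best_k <- NA_integer_
  for (k in k_range) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2L) next
    sil <- mean(cluster::silhouette(lab, dmat)[, 3L])
    if (sil > best_sil) { best_sil <- sil; best_lab <- lab; best_k <- k }
  }
  if (is.null(best_lab)) {
    warning("degenerate consensus: all items co-cluster; returning one cluster")
    best_lab <- rep.int(1L, n); best_k <- 1L
  }
  list(consensus = co, labels = best_lab, k = best_k,
       per_repeat_labels = per_labels)
}

#' Cluster-transition counts and probabilities between two layers
#'
#' Cross-tabulates per-node cluster labels at the first layer against those
#' at the second and row-normalizes: `P[i, j]` is the probability that a
#' node in cluster `i` at the first layer belongs to cluster `j` at the
#' second.
#'
#' @param labels data.frame with columns `node`, `layer`, `cluster`; every
#'   node must carry a label in both layers.
#' @param layer_pair length-2 vector of layer names (defaults to the first
#'   two present).
#' @return list with `counts` (contingency table) and `probabilities`
#'   (row-stochastic matrix).
#' @export
cluster_transitions <- function(labels, layer_pair = NULL) {
  stopifnot(all(c("node", "layer", "cluster") %in% names(labels)))
  if (is.null(layer_pair)) layer_pair <- unique(labels$layer)[1:2]
  a <- labels[labels$layer == layer_pair[1L], ]
  b <- labels[labels$layer == layer_pair[2L], ]
  if (!setequal(a$node, b$node)) stop("node(s) missing a layer label")
  b <- b[match(a$node, b$node), ]
  counts <- table(layer1 = a$cluster, layer2 = b$cluster)
  probs <- sweep(counts, 1L, rowSums(counts), `/`)
  list(counts = counts, probabilities = probs)
}

#' Detect taxa with extreme neighborhood dynamics
#'
#' Formalizes "the first larger jump at both extreme ends" of a sorted score
#' vector: within the top (and bottom) `q`-fraction of sorted scores, the
#' largest consecutive gap is located and the nodes beyond it are flagged as
#' high- (respectively low-) dynamics. When the largest gap ties, the gap
#' closest to the extreme end wins, keeping the flagged sets minimal.
#'
#' @param scores named numeric vector of per-node dynamics scores (e.g. mean
#'   cosine distance, or `1 -` co-clustering similarity); larger = more
#'   dynamic.
#' @param q fraction of each tail searched for the jump, in `(0, 0.5]`
#'   (default 0.25).
#' @return list with `high_ids` and `low_ids` (character vectors).
#' @export
extreme_dynamics <- function(scores, q = 0.25) {
  stopifnot(q > 0, q <= 0.5)
  n <- length(scores)
  if (n < 4L) stop("need at least 4 scores")
  if (is.null(names(scores))) names(scores) <- as.character(seq_len(n))
  ord <- order(scores, names(scores))      # ascending; ties by id
  s <- scores[ord]
  m <- floor(q * n)
  pick_high <- character(0)
  pick_low <- character(0)
  tie_tol <- 1e-8
  if (m >= 1L) {
    # top tail: gaps between the (n-m)th..nth sorted values
    hi <- s[(n - m):n]
    gaps <- diff(hi)
    if (length(gaps) && max(gaps) > 0) {
      # gaps within tolerance of the maximum count as tied; the tie breaks
      # toward the extreme end, keeping the flagged set minimal
      g <- max(which(gaps >= max(gaps) * (1 - tie_tol)))
      pick_high <- names(hi)[(g + 1L):length(hi)]
    }
    lo <- s[1:(m + 1L)]
    gaps <- diff(lo)
    if (length(gaps) && max(gaps) > 0) {
      g <- min(which(gaps >= max(gaps) * (1 - tie_tol)))
      pick_low <- names(lo)[seq_len(g)]
    }
  }
  list(high_ids = pick_high, low_ids = pick_low)
}

#' Individuals-by-features matrices for the three analysis views
#'
#' * `node`: CLR abundances of both layers (2K columns, `taxon@layer`);
#' * `edge`: individual-specific edge weights of both layers (2L columns,
#'   undirected edges enumerated once in lexicographic `(min, max)` order,
#'   `taxonA--taxonB@layer`);
#' * `dynamic`: per-taxon cosine distances across layers (K columns,
#'   `taxon.dyn`) — the only view whose width does not grow with the number
#'   of time points.
#'
#' @param mode one of `"node"`, `"edge"`, `"dynamic"`.
#' @param abundance for `node`: a CLR-transformed [abundance_table()]
#'   covering both time points.
#' @param isns for `edge`: named list of `isn_set`s, one per layer (names =
#'   layer labels).
#' @param dynamics for `dynamic`: a `dynamics_table` with per-individual
#'   owners.
#' @param individuals individuals (rows) to include; defaults to those
#'   common to all sources used.
#' @return numeric matrix, individuals in rows.
#' @export
build_feature_matrix <- function(mode = c("node", "edge", "dynamic"),
                                 abundance = NULL, isns = NULL,
                                 dynamics = NULL, individuals = NULL) {
  mode <- match.arg(mode)
  if (mode == "node") {
    stopifnot(inherits(abundance, "abundance_table"))
    meta <- abundance$metadata
    layers <- sort(unique(meta$time_point))
    inds <- individuals %||% Reduce(intersect, lapply(layers, function(tp) {
      meta$individual_id[meta$time_point == tp]
    }))
    blocks <- lapply(layers, function(tp) {
      sm <- meta[meta$time_point == tp, ]
      missing_ind <- setdiff(inds, sm$individual_id)
      if (length(missing_ind)) stop("individual(s) missing at time point ", tp,
                                    ": ", paste(missing_ind, collapse = ", "))
      m <- abundance$counts[sm$sample_id[match(inds, sm$individual_id)], ,
                            drop = FALSE]
      colnames(m) <- paste0(colnames(m), "@", tp)
      rownames(m) <- inds
      m
    })
    return(do.call(cbind, blocks))
  }
  if (mode == "edge") {
    stopifnot(is.list(isns), length(isns) >= 1L, !is.null(names(isns)))
    inds <- individuals %||% Reduce(intersect, lapply(isns, `[[`, "individual_ids"))
    ids <- isns[[1L]]$node_ids
    ut <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
    a <- ids[ut[, 1L]]; b <- ids[ut[, 2L]]
    lex <- order(pmin(a, b), pmax(a, b))
    enames <- paste0(pmin(a, b), "--", pmax(a, b))[lex]
    blocks <- lapply(names(isns), function(ly) {
      set <- isns[[ly]]
      missing_ind <- setdiff(inds, set$individual_ids)
      if (length(missing_ind)) stop("individual(s) missing in layer ", ly, ": ",
                                    paste(missing_ind, collapse = ", "))
      m <- t(vapply(inds, function(ind) {
        set$networks[[ind]][ut][lex]
      }, numeric(length(enames))))
      colnames(m) <- paste0(enames, "@", ly)
      rownames(m) <- inds
      m
    })
    return(do.call(cbind, blocks))
  }
  stopifnot(inherits(dynamics, "dynamics_table"))
  inds <- individuals %||% unique(dynamics$owner)
  nodes <- unique(dynamics$node)
  m <- matrix(NA_real_, length(inds), length(nodes),
              dimnames = list(inds, paste0(nodes, ".dyn")))
  for (i in seq_along(inds)) {
    sub <- dynamics[dynamics$owner == inds[i], ]
    if (nrow(sub) == 0L) stop("individual missing in dynamics table: ", inds[i])
    m[i, ] <- sub$distance[match(nodes, sub$node)]
  }
  if (anyNA(m)) stop("incomplete dynamics table")
  m
}
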