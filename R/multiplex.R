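#' Multiplex networks: matched layers over one node set
#'
#' A multiplex network stacks several symmetric, non-negative weighted
#' adjacency matrices ("layers", e.g. one per time point) over a shared,
#' identically ordered node set. Layers supplied with permuted node order are
#' aligned by node id.
#'
#' @param networks_by_layer named list of layers; each element a symmetric
#'   non-negative matrix with node-id dimnames, or a [global_network()].
#' @param owner label for the owning unit (an individual id, or `"global"`).
#' @return object of class `multiplex_network`: list with `node_ids`,
#'   `layers` (named list of matrices), `owner`.
#' @export
build_multiplex <- function(networks_by_layer, owner = "global") {
  if (length(networks_by_layer) < 2L) stop("a multiplex needs at least 2 layers")
  if (is.null(names(networks_by_layer)) || anyDuplicated(names(networks_by_layer))) {
    stop("layers must have unique names")
  }
  mats <- lapply(networks_by_layer, function(l) {
    if (inherits(l, "global_network")) l$weights else as.matrix(l)
  })
  ids <- rownames(mats[[1L]])
  if (is.null(ids)) stop("layers must carry node ids as dimnames")
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!setequal(rownames(m), ids)) {
      sd <- union(setdiff(rownames(m), ids), setdiff(ids, rownames(m)))
      stop("node-set mismatch in layer '", nm, "': ", paste(sd, collapse = ", "))
    }
    m <- m[ids, ids]
    check_square_symmetric(m, what = paste0("layer '", nm, "'"))
    if (any(m < 0)) {
      stop("negative weights in layer '", nm,
           "'; apply absolute_weights() to signed individual-specific networks first")
    }
    diag(m) <- 0
    mats[[nm]] <- m
  }
  structure(list(node_ids = ids, layers = mats, owner = owner),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("multiplex_network:", length(x$node_ids), "nodes,",
      length(x$layers), "layers (", paste(names(x$layers), collapse = ", "),
      ") owner:", x$owner, "\n")
  invisible(x)
}

#' Direct-neighbor vector of a node
#'
#' The encoder input of the embedding model: entry `j` holds the edge weight
#' between `node` and `j` (or 1 in binary mode) and 0 otherwise. Self-loops
#' are never represented — a node is not its own neighbor — which is what
#' lets the trained encoder generalize to unseen nodes.
#'
#' @param mpx a [build_multiplex()] object.
#' @param layer layer name or index.
#' @param node node id.
#' @param weighted `TRUE` for edge weights, `FALSE` for 0/1 indicators.
#' @return numeric vector of length K named by node ids.
#' @export
neighbor_vector <- function(mpx, layer, node, weighted = TRUE) {
  stopifnot(inherits(mpx, "multiplex_network"))
  if (!node %in% mpx$node_ids) stop("unknown node: ", node)
  v <- mpx$layers[[layer]][node, ]
  if (!weighted) v[] <- as.numeric(v > 0)
  v[node] <- 0
  v
}

# Row-normalized transition matrix; zero-degree rows become self-absorbing so
# that terminated walks keep their probability mass.
transition_matrix <- function(w) {
  deg <- rowSums(w)
  p <- w / ifelse(deg > 0, deg, 1)
  dead <- deg == 0
  if (any(dead)) p[cbind(which(dead), which(dead))] <- 1
  p
}

#' Random-walk reach profile of a node
#'
#' For a start node, the reach profile gives for every node `j` the
#' probability that a fixed-length random walk starting there visits `j` at
#' least once within `walk_length` steps. Transition probabilities are
#' proportional to edge weights (uniform over neighbors in binary mode); the
#' start position at step 0 does not count as a visit; a walk hitting a
#' zero-degree node terminates early and its visits still count.
#'
#' Two computation modes: `monte_carlo` simulates `n_repeats` walks and
#' reports visit fractions; `exact` computes first-visit probabilities by an
#' absorbing-chain recursion (removing the target node from the chain and
#' propagating avoidance probabilities), which is exact for any graph size.
#'
#' @param mpx a [build_multiplex()] object.
#' @param layer layer name or index.
#' @param node start node id.
#' @param walk_length number of steps (default 5).
#' @param n_repeats walks per start node in Monte-Carlo mode (default 100).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param mode `"monte_carlo"` or `"exact"`.
#' @param weighted weight-proportional (`TRUE`) or uniform transitions.
#' @return reach vector of length K named by node ids, entries in `[0, 1]`.
#' @export
walk_profile <- function(mpx, layer, node, walk_length = 5, n_repeats = 100,
                         seed = NULL, mode = c("monte_carlo", "exact"),
                         weighted = TRUE) {
  stopifnot(inherits(mpx, "multiplex_network"), walk_length >= 1)
  mode <- match.arg(mode)
  if (!node %in% mpx$node_ids) stop("unknown node: ", node)
  w <- mpx$layers[[layer]]
  if (!weighted) w <- (w > 0) * 1
  s <- match(node, mpx$node_ids)
  if (sum(w[s, ]) == 0) {
    warning("start node '", node, "' has zero degree; returning zero reach")
    return(stats::setNames(numeric(length(mpx$node_ids)), mpx$node_ids))
  }
  if (mode == "monte_carlo") {
    if (!is.null(seed)) {
      if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
        stop("invalid seed")
      }
      set.seed(as.integer(seed))
    }
    reach <- walk_reach_mc(w, s, walk_length, n_repeats)
  } else {
    reach <- walk_reach_exact(w, s, walk_length)
  }
  stats::setNames(reach, mpx$node_ids)
}

# Monte-Carlo reach: advance all walkers simultaneously, grouping walkers by
# current node so each step costs one multinomial draw per occupied node.
walk_reach_mc <- function(w, s, walk_length, n_repeats) {
  K <- nrow(w)
  nbrs <- lapply(seq_len(K), function(i) which(w[i, ] > 0))
  pos <- rep.int(s, n_repeats)
  visited <- matrix(FALSE, n_repeats, K)
  for (step in seq_len(walk_length)) {
    cur <- pos                                 # snapshot: one move per step
    for (u in unique(cur)) {
      nb <- nbrs[[u]]
      if (length(nb) == 0L) next               # terminated walkers stay put
      idx <- which(cur == u)
      nxt <- if (length(nb) == 1L) {
        rep.int(nb, length(idx))
      } else {
        nb[sample.int(length(nb), length(idx), replace = TRUE, prob = w[u, nb])]
      }
      visited[cbind(idx, nxt)] <- TRUE
      pos[idx] <- nxt
    }
  }
  colMeans(visited)
}

# Exact reach via avoidance probabilities: P(visit j within T | start s) =
# 1 - P(stay off j for T steps). The latter is computed in the chain with j's
# column removed (mass stepping onto j is lost, i.e. counted as visiting).
walk_reach_exact <- function(w, s, walk_length) {
  K <- nrow(w)
  p <- transition_matrix(w)
  reach <- numeric(K)
  for (j in seq_len(K)) {
    q <- p
    q[, j] <- 0
    # avoid[v] = P(not touching j in the next `t` steps | currently at v)
    avoid <- rep.int(1, K)
    if (j == s) {
      # first step leaves s; avoidance then runs for walk_length - 1 steps
      if (walk_length > 1L) {
        for (t in seq_len(walk_length - 1L)) avoid <- q %*% avoid
      }
      reach[j] <- 1 - sum(p[s, -j] * avoid[-j])
    } else {
      for (t in seq_len(walk_length)) avoid <- q %*% avoid
      reach[j] <- 1 - avoid[s]
    }
  }
  pmin(pmax(reach, 0), 1)
}

#' Walk-reach profiles for every node of every layer
#'
#' Per-node RNG streams are derived deterministically from `seed`, so a
#' node's Monte-Carlo profile does not depend on the order in which nodes are
#' processed.
#'
#' @inheritParams walk_profile
#' @param seed master seed for the per-(layer, node) streams.
#' @return object of class `walk_profile_set`: list with `index` (data.frame
#'   `layer`, `node`), `profiles` (matrix, one row per index row, K columns),
#'   and the walk parameters.
#' @export
walk_profiles <- function(mpx, walk_length = 5, n_repeats = 100, seed = 1,
                          mode = c("monte_carlo", "exact"), weighted = TRUE) {
  stopifnot(inherits(mpx, "multiplex_network"))
  mode <- match.arg(mode)
  K <- length(mpx$node_ids)
  layers <- names(mpx$layers)
  idx <- expand.grid(node = mpx$node_ids, layer = layers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- idx[, c("layer", "node")]
  prof <- matrix(0, nrow(idx), K, dimnames = list(NULL, mpx$node_ids))
  for (r in seq_len(nrow(idx))) {
    prof[r, ] <- suppressWarnings(walk_profile(
      mpx, idx$layer[r], idx$node[r], walk_length = walk_length,
      n_repeats = n_repeats, seed = derive_seed(seed, r), mode = mode,
      weighted = weighted))
  }
  structure(list(index = idx, profiles = prof, walk_length = walk_length,
                 n_repeats = n_repeats, mode = mode, weighted = weighted),
            class = "walk_profile_set")
}
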