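#' Benchmark specification for the planted-rewiring simulation
#'
#' The benchmark emulates sparse weighted microbial co-occurrence graphs: a
#' configuration-model graph with Poisson-like degrees around `mean_degree`
#' and edge weights drawn from a truncated folded normal, copied into a
#' second layer in which `m_control` randomly chosen "control" nodes have
#' their entire neighborhoods rewired (degree-preserving, partners re-drawn
#' among non-control nodes, weights re-sampled). Control nodes are the
#' planted truth a dynamics method should recover.
#'
#' @param K number of nodes (default 95).
#' @param mean_degree target mean degree (default 4).
#' @param m_control number of rewired control nodes (default 10).
#' @param weight_mean,weight_sd parameters of the folded-normal weight
#'   distribution truncated to `(0, 1]` (defaults 0.3, 0.15).
#' @param noise_levels noise amplitudes for robustness sweeps (default
#'   `exp(-(10:2))`).
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(K = 95, mean_degree = 4, m_control = 10,
                            weight_mean = 0.3, weight_sd = 0.15,
                            noise_levels = exp(-(10:2))) {
  stopifnot(m_control >= 0, m_control < K, mean_degree > 0,
            all(noise_levels >= 0))
  structure(list(K = as.integer(K), mean_degree = mean_degree,
                 m_control = as.integer(m_control),
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 noise_levels = noise_levels),
            class = "simulation_spec")
}

sample_weights <- function(n, mean, sd) {
  w <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- abs(stats::rnorm(length(need), mean, sd))
    ok <- cand > 0 & cand <= 1
    w[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  w
}

#' Generate a two-layer planted-rewiring benchmark multiplex
#'
#' Layer 1 is a sparse weighted graph; layer 2 is a copy in which each
#' control node's incident edges are deleted and replaced by the same number
#' of edges to uniformly re-drawn non-control partners with re-sampled
#' weights. Non-control neighborhoods change only where an edge touched a
#' control node.
#'
#' @param spec a [simulation_spec()].
#' @param seed RNG seed.
#' @return list with `multiplex` (a [build_multiplex()] object, layers
#'   `"layer1"`, `"layer2"`) and `control_set` (character node ids).
#' @export
make_benchmark_multiplex <- function(spec = simulation_spec(), seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(as.integer(seed))
  K <- spec$K
  if (spec$mean_degree >= K) stop("mean degree infeasible for K nodes")
  degs <- pmax(1L, stats::rpois(K, spec$mean_degree))
  if (sum(degs) %% 2L == 1L) degs[which.max(degs)] <- degs[which.max(degs)] + 1L
  g <- igraph::sample_degseq(degs, method = "configuration")
  g <- igraph::simplify(g)
  ids <- sprintf("taxon%02d", seq_len(K))
  adj1 <- matrix(0, K, K, dimnames = list(ids, ids))
  el <- igraph::as_edgelist(g, names = FALSE)
  wts <- sample_weights(nrow(el), spec$weight_mean, spec$weight_sd)
  adj1[el] <- wts
  adj1[el[, c(2, 1), drop = FALSE]] <- wts
  # The construction plants controls as the only nodes whose neighborhood
  # varies: reject control draws that would strip some non-control node of
  # its entire neighborhood (else that bystander's neighborhood would fully
  # change too and the planted truth would be ambiguous).
  control <- NULL
  for (try in seq_len(1000L)) {
    cand <- sort(sample.int(K, spec$m_control))
    bystanders <- setdiff(seq_len(K), cand)
    ok <- vapply(bystanders, function(v) {
      nb <- which(adj1[v, ] > 0)
      length(nb) == 0L || any(!(nb %in% cand))
    }, logical(1L))
    if (all(ok)) { control <- cand; break }
  }
  if (is.null(control)) stop("could not place ", spec$m_control,
                             " control nodes without isolating bystanders")
  adj2 <- adj1
  noncontrol <- setdiff(seq_len(K), control)
  old_partners <- unique(unlist(lapply(control, function(cn) which(adj1[cn, ] > 0))))
  for (cn in control) {
    old <- which(adj1[cn, ] > 0)   # original degree, so that an edge between
    deg <- length(old)             # two controls is replaced on both sides
    adj2[cn, ] <- 0; adj2[, cn] <- 0
    # re-drawn partners must give the control genuinely different
    # neighbors; avoiding every control's former partners also keeps any
    # single bystander from both losing and gaining control edges
    pool <- setdiff(noncontrol, c(cn, old_partners))
    newnb <- sample(pool, min(deg, length(pool)))
    nw <- sample_weights(length(newnb), spec$weight_mean, spec$weight_sd)
    adj2[cn, newnb] <- nw
    adj2[newnb, cn] <- nw
  }
  list(multiplex = build_multiplex(list(layer1 = adj1, layer2 = adj2),
                                   owner = "benchmark"),
       control_set = ids[control])
}

#' Add symmetric uniform noise to every layer of a multiplex
#'
#' Adds independent `Uniform(0, noise_max)` draws to each upper-triangle
#' entry of each layer's adjacency matrix, mirrored to preserve symmetry.
#' Zero entries are perturbed too: this is an operation on the adjacency
#' matrix and densifies the graph.
#'
#' @param mpx a [build_multiplex()] object.
#' @param noise_max noise amplitude (>= 0; 0 is the identity).
#' @param seed RNG seed.
#' @return a noisy `multiplex_network`.
#' @export
add_uniform_noise <- function(mpx, noise_max, seed = 1) {
  stopifnot(inherits(mpx, "multiplex_network"))
  if (noise_max < 0) stop("noise_max must be non-negative")
  if (noise_max == 0) return(mpx)
  set.seed(as.integer(seed))
  layers <- lapply(mpx$layers, function(w) {
    ut <- upper.tri(w)
    w[ut] <- w[ut] + stats::runif(sum(ut), 0, noise_max)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    w
  })
  build_multiplex(layers, owner = mpx$owner)
}

#' Jaccard index between two node sets
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both sets are empty.
#'
#' @param set_a,set_b vectors treated as sets.
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Select the m most dynamic nodes
#'
#' Nodes carrying the `m` largest dynamics scores; ties break
#' deterministically by node id.
#'
#' @param dynamics_table a `dynamics_table` (single owner).
#' @param m number of nodes to select (1..K).
#' @return character vector of node ids.
#' @export
detect_topm <- function(dynamics_table, m) {
  stopifnot(inherits(dynamics_table, "dynamics_table"))
  if (m <= 0) stop("m must be positive")
  if (length(unique(dynamics_table$owner)) != 1L) {
    stop("detect_topm expects a single-owner dynamics table")
  }
  if (m > nrow(dynamics_table)) stop("m exceeds the number of nodes")
  ord <- order(-dynamics_table$distance, dynamics_table$node)
  dynamics_table$node[ord][seq_len(m)]
}

#' Laplacian-eigenvector baseline for node dynamics
#'
#' The comparison method: each layer's nodes are represented by their rows
#' in the matrix of the `n_eigvecs` smallest-nontrivial eigenvectors of the
#' layer's combinatorial Laplacian `L = D - W` (eigenvalues below `1e-8`
#' are treated as trivial and skipped). Eigenvector signs are arbitrary, so
#' each layer-2 vector is flipped when its inner product with the matched
#' layer-1 vector is negative before per-node cosine distances are taken.
#'
#' @param mpx a two-layer [build_multiplex()] object.
#' @param n_eigvecs number of eigenvectors (default 10, matching the EDNN
#'   embedding dimension for a fair comparison).
#' @return a `dynamics_table` over the multiplex owner's nodes.
#' @export
laplacian_baseline <- function(mpx, n_eigvecs = 10) {
  stopifnot(inherits(mpx, "multiplex_network"), length(mpx$layers) == 2L)
  K <- length(mpx$node_ids)
  embed_layer <- function(w) {
    L <- diag(rowSums(w)) - w
    e <- eigen(L, symmetric = TRUE)
    ord <- order(e$values)           # ascending
    vals <- e$values[ord]
    nontrivial <- which(vals > 1e-8)
    take <- nontrivial[seq_len(min(n_eigvecs, length(nontrivial)))]
    e$vectors[, ord[take], drop = FALSE]
  }
  v1 <- embed_layer(mpx$layers[[1L]])
  v2 <- embed_layer(mpx$layers[[2L]])
  r <- min(ncol(v1), ncol(v2))
  v1 <- v1[, seq_len(r), drop = FALSE]
  v2 <- v2[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    if (sum(v1[, j] * v2[, j]) < 0) v2[, j] <- -v2[, j]
  }
  d <- vapply(seq_len(K), function(i) cosine_distance_safe(v1[i, ], v2[i, ]),
              numeric(1L))
  out <- data.frame(owner = mpx$owner, node = mpx$node_ids, distance = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("dynamics_table", "data.frame")
  out
}

# One MNDA pass on a benchmark multiplex: profiles + single EDNN training +
# per-node cosine distances.
mnda_benchmark_dynamics <- function(mpx, config = ednn_config(),
                                    walk_length = 5, n_repeats = 100,
                                    walk_mode = "monte_carlo") {
  emb <- mnda_embed(mpx, config = config, walk_length = walk_length,
                    n_repeats = n_repeats, walk_mode = walk_mode)
  node_dynamics(emb)
}

#' Run the planted-rewiring benchmark over noise levels and replicates
#'
#' Full factorial over `noise_levels x replicates x methods`. For each cell
#' a fresh benchmark multiplex is generated, noise is added, the method's
#' per-node dynamics are computed, the top-`m_control` nodes are detected,
#' and the Jaccard index against the planted control set is recorded.
#'
#' @param spec a [simulation_spec()]; its `noise_levels` (prepended with 0
#'   unless `include_zero = FALSE`) define the sweep.
#' @param methods subset of `c("mnda", "laplacian")`.
#' @param n_replicates replicates per noise level (default 5).
#' @param seed master seed; replicate streams derive from it.
#' @param config EDNN configuration for the MNDA runs.
#' @param include_zero prepend a zero-noise level (default `TRUE`).
#' @param walk_length,walk_repeats walk parameters for MNDA.
#' @return data.frame with `method`, `noise`, `replicate`, `jaccard`.
#' @export
run_benchmark <- function(spec = simulation_spec(),
                          methods = c("mnda", "laplacian"),
                          n_replicates = 5, seed = 1,
                          config = ednn_config(), include_zero = TRUE,
                          walk_length = 5, walk_repeats = 100) {
  methods <- match.arg(methods, several.ok = TRUE)
  noise <- spec$noise_levels
  if (include_zero) noise <- c(0, noise)
  out <- expand.grid(method = methods, noise = noise,
                     replicate = seq_len(n_replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$jaccard <- NA_real_
  for (rep_i in seq_len(n_replicates)) {
    bench <- make_benchmark_multiplex(spec, seed = derive_seed(seed, rep_i))
    for (nz in seq_along(noise)) {
      mpx <- add_uniform_noise(bench$multiplex, noise[nz],
                               seed = derive_seed(seed, 100L * rep_i + nz))
      for (meth in methods) {
        dt <- if (meth == "mnda") {
          cfg <- config
          cfg$seed <- derive_seed(seed, 10000L + 100L * rep_i + nz)
          mnda_benchmark_dynamics(mpx, config = cfg,
                                  walk_length = walk_length,
                                  n_repeats = walk_repeats)
        } else {
          laplacian_baseline(mpx, n_eigvecs = config$hidden_dim)
        }
        det <- detect_topm(dt, spec$m_control)
        sel <- out$method == meth & out$noise == noise[nz] &
          out$replicate == rep_i
        out$jaccard[sel] <- jaccard(det, bench$control_set)
      }
    }
  }
  out
}

#' Specification of the synthetic two-time-point cohort
#'
#' The generator emulates the structure the method targets: a cohort of
#' individuals sampled at two time points whose latent taxon-taxon
#' correlation structure is organized in modules, with a subgroup of
#' individuals whose module membership is rewired between the time points
#' for a set of target taxa. Counts are drawn with zero-inflated negative
#' binomial marginals over the latent Gaussian copula, scaled by per-sample
#' sequencing depths, reproducing the noisiness, compositionality and
#' sparseness of amplicon data. The binary phenotype equals the subgroup up
#' to label noise `1 - coupling`.
#'
#' @param n individuals (default 60, split into two equal subgroups).
#' @param K taxa (default 40).
#' @param module_size taxa per latent correlation module (default 5).
#' @param rho within-module latent correlation (default 0.8).
#' @param n_rewired taxa whose module membership changes between layers for
#'   subgroup 2 (default 10).
#' @param rewire_prob probability that each target taxon is actually
#'   rewired (default 1).
#' @param coupling probability that the phenotype label equals the subgroup
#'   (default 1).
#' @param bloom_shift optional latent-scale mean increase of the rewired
#'   taxa in subgroup 2 at the second time point (default 0), emulating
#'   abundance blooms accompanying a rewiring. Note that a mean shift also
#'   moves the mixed-population center used by correlation estimators, so
#'   it spreads into the co-occurrence structure of both subgroups rather
#'   than sharpening the contrast.
#' @param persistence within-individual temporal autocorrelation of the
#'   latent state between the two time points (default 1, the
#'   perturbed-copy principle: the second layer is the first individual
#'   state plus the planted changes plus fresh measurement noise, exactly as
#'   the planted-rewiring benchmark copies layer 1). Without persistence
#'   every individual's realization would be redrawn at the second time
#'   point and all taxa would show maximal neighborhood dynamics, leaving
#'   nothing for the planted rewiring to stand out from.
#' @param zero_inflation structural-zero probability (default 0.1).
#' @param dispersion negative binomial size parameter (default 8).
#' @param depth_range sequencing depth range (default `c(2e4, 6e4)`).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 60, K = 40, module_size = 5, rho = 0.8,
                        n_rewired = 10, rewire_prob = 1, coupling = 1,
                        bloom_shift = 0, persistence = 1,
                        zero_inflation = 0.1, dispersion = 8,
                        depth_range = c(2e4, 6e4)) {
  stopifnot(n >= 4, K >= module_size, rho >= 0, rho < 1,
            n_rewired <= K, coupling >= 0, coupling <= 1,
            persistence >= 0, persistence <= 1, bloom_shift >= 0,
            zero_inflation >= 0, zero_inflation < 1, dispersion > 0)
  structure(list(n = as.integer(n), K = as.integer(K),
                 module_size = as.integer(module_size), rho = rho,
                 n_rewired = as.integer(n_rewired),
                 rewire_prob = rewire_prob, coupling = coupling,
                 bloom_shift = bloom_shift, persistence = persistence,
                 zero_inflation = zero_inflation, dispersion = dispersion,
                 depth_range = depth_range),
            class = "cohort_spec")
}

#' Generate the synthetic two-time-point cohort
#'
#' Latent model: taxa belong to correlation modules (compound-symmetric
#' within-module correlation `rho`, always positive definite for
#' `rho < 1`); an individual's latent state — shared module factors plus
#' taxon-specific residuals — persists between the two time points with
#' autocorrelation `persistence`. For subgroup 2, each rewiring-target
#' taxon's latent coordinate at the second time point detaches from its old
#' module and re-attaches to a different one (with a fresh residual), so
#' its co-occurrence neighborhood changes while subgroup 1's stays put.
#' Observed counts are zero-inflated negative binomial marginals over the
#' latent Gaussian copula, scaled by uniformly drawn sequencing depths.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed.
#' @return list with `table` (an [abundance_table()]; metadata columns
#'   `individual_id`, `time_point` in `{"t1", "t2"}`, `phenotype` in
#'   `{"A", "B"}`), and `truth` (list with `subgroup` per individual,
#'   `rewired_taxa`, `modules_*`).
#' @export
make_synthetic_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n; K <- spec$K
  ids <- sprintf("ind%02d", seq_len(n))
  taxa <- sprintf("taxon%02d", seq_len(K))
  subgroup <- rep(1:2, length.out = n)
  n_modules <- ceiling(K / spec$module_size)
  modules1 <- rep(seq_len(n_modules), each = spec$module_size)[seq_len(K)]
  # subgroup 2, layer 2: rewired taxa move to a different module
  targets <- sample.int(K, spec$n_rewired)
  modules2 <- modules1
  for (t in targets) {
    if (stats::runif(1) <= spec$rewire_prob) {
      modules2[t] <- sample(setdiff(seq_len(n_modules), modules1[t]), 1L)
    }
  }
  rewired <- taxa[modules2 != modules1]
  base_abund <- stats::rlnorm(K, meanlog = 0, sdlog = 1)
  base_abund <- base_abund / sum(base_abund)
  phi <- spec$persistence
  rho <- spec$rho
  # per-individual latent state at t1: module factors f and residuals eps
  f1 <- matrix(stats::rnorm(n * n_modules), n)
  e1 <- matrix(stats::rnorm(n * K), n)
  # t2 state: AR(1) persistence of both factors and residuals
  f2 <- phi * f1 + sqrt(1 - phi^2) * matrix(stats::rnorm(n * n_modules), n)
  e2 <- phi * e1 + sqrt(1 - phi^2) * matrix(stats::rnorm(n * K), n)
  z1 <- sqrt(rho) * f1[, modules1, drop = FALSE] + sqrt(1 - rho) * e1
  z2 <- sqrt(rho) * f2[, modules1, drop = FALSE] + sqrt(1 - rho) * e2
  # subgroup 2's rewired taxa: re-attach to the new module with a fresh,
  # non-persistent residual (their neighborhood and trajectory both break),
  # accompanied by an abundance bloom so that every affected individual
  # actually expresses the rewiring in their own sample
  g2 <- subgroup == 2L
  for (t in which(modules2 != modules1)) {
    z2[g2, t] <- spec$bloom_shift + sqrt(rho) * f2[g2, modules2[t]] +
      sqrt(1 - rho) * stats::rnorm(sum(g2))
  }
  samples <- data.frame(
    sample_id = c(paste0(ids, "_t1"), paste0(ids, "_t2")),
    individual_id = rep(ids, 2L),
    time_point = rep(c("t1", "t2"), each = n),
    stringsAsFactors = FALSE)
  z <- rbind(z1, z2)
  depth <- stats::runif(2L * n, spec$depth_range[1L], spec$depth_range[2L])
  u <- stats::pnorm(z)
  counts <- matrix(0L, 2L * n, K)
  for (j in seq_len(K)) {
    mu <- base_abund[j] * depth
    adj <- (u[, j] - spec$zero_inflation) / (1 - spec$zero_inflation)
    pos <- adj > 0
    counts[pos, j] <- stats::qnbinom(pmin(adj[pos], 1 - 1e-12),
                                     size = spec$dispersion, mu = mu[pos])
  }
  dimnames(counts) <- list(samples$sample_id, taxa)
  flip <- stats::runif(n) > spec$coupling
  phen <- ifelse(xor(subgroup == 2L, flip), "B", "A")
  samples$phenotype <- rep(phen, 2L)
  list(
    table = abundance_table(counts, samples),
    truth = list(subgroup = stats::setNames(subgroup, ids),
                 rewired_taxa = rewired,
                 modules_layer1 = stats::setNames(modules1, taxa),
                 modules_layer2_subgroup2 = stats::setNames(modules2, taxa))
  )
}
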