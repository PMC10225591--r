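#' Individual-specific networks via leave-one-out perturbation
#'
#' The LIONESS scheme estimates the contribution of one individual to every
#' edge of a population-level association network: with `N` reference
#' individuals, global edge weights `w` and the leave-one-out weights
#' `w_bar[-n]` recomputed without individual `n`, the individual-specific
#' weight is
#'
#'     w_n = N * w - (N - 1) * w_bar[-n]
#'
#' Even when both population weights are positive the individual-specific
#' weight can be negative; this happens whenever `w < (N - 1) * w_bar[-n] / N`.
#'
#' @param table an [abundance_table()] holding exactly one sample per
#'   reference individual (a single time point or condition).
#' @param estimator a function `(abundance_table) -> global_network`; the
#'   association estimator applied to the full and each leave-one-out sample
#'   subset. See [fallback_estimator()] for a simple built-in.
#' @param individuals individuals to build networks for; defaults to the
#'   whole reference population.
#' @return an object of class `isn_set`: list with `individual_ids`,
#'   `n_reference`, `node_ids`, `networks` (named list of symmetric matrices),
#'   `global` (the full-population [global_network()]), `abs_applied`.
#' @export
lioness_isn <- function(table, estimator, individuals = NULL) {
  stopifnot(inherits(table, "abundance_table"), is.function(estimator))
  meta <- table$metadata
  if (anyDuplicated(meta$individual_id)) {
    stop("table must hold one sample per individual (single time point)")
  }
  ref <- as.character(meta$individual_id)
  N <- length(ref)
  if (N < 3L) stop("reference population must have at least 3 individuals")
  if (is.null(individuals)) individuals <- ref
  individuals <- as.character(individuals)
  if (!all(individuals %in% ref)) {
    stop("unknown individual(s): ",
         paste(setdiff(individuals, ref), collapse = ", "))
  }
  glob <- estimator(table)
  if (!inherits(glob, "global_network")) stop("estimator must return a global_network")
  if (!setequal(glob$node_ids, colnames(table$counts))) {
    stop("estimator output node set does not match the taxon set")
  }
  w <- glob$weights
  nets <- vector("list", length(individuals))
  names(nets) <- individuals
  for (ind in individuals) {
    keep <- meta$sample_id[meta$individual_id != ind]
    sub <- abundance_table(table$counts[keep, , drop = FALSE],
                           meta[meta$individual_id != ind, , drop = FALSE],
                           taxonomy = table$taxonomy, clr = table$clr)
    loo <- tryCatch(estimator(sub), error = function(e) {
      stop("estimator failed on leave-one-out subset for individual '",
           ind, "': ", conditionMessage(e))
    })
    wl <- loo$weights[rownames(w), colnames(w)]
    wn <- N * w - (N - 1) * wl
    diag(wn) <- 0
    nets[[ind]] <- wn
  }
  structure(list(individual_ids = individuals, n_reference = N,
                 node_ids = glob$node_ids, networks = nets, global = glob,
                 abs_applied = FALSE),
            class = "isn_set")
}

#' @export
print.isn_set <- function(x, ...) {
  cat("isn_set:", length(x$individual_ids), "individual networks over",
      length(x$node_ids), "nodes (N =", x$n_reference, "reference)\n")
  if (x$abs_applied) cat("  absolute-value transform applied\n")
  invisible(x)
}

#' Replace individual-specific edge weights by their absolute values
#'
#' Applied when only the unsigned strength of an association matters, e.g.
#' before stacking networks into multiplexes whose layers require
#' non-negative weights. A separate, explicit step: the sign of an
#' individual-specific weight is discarded knowingly, not silently.
#'
#' @param isns an `isn_set` from [lioness_isn()].
#' @return the `isn_set` with entrywise absolute values and
#'   `abs_applied = TRUE`. Re-applying warns and returns the input unchanged
#'   (the transform is idempotent).
#' @export
absolute_weights <- function(isns) {
  stopifnot(inherits(isns, "isn_set"))
  if (isns$abs_applied) {
    warning("absolute-value transform already applied; returning input")
    return(isns)
  }
  isns$networks <- lapply(isns$networks, abs)
  isns$abs_applied <- TRUE
  isns
}

#' Check the ISN-average identity against the global network
#'
#' The global network is a weighted average of the individual-specific
#' networks: when the estimator is linear in per-sample contributions the
#' edgewise mean of all ISNs equals the global weight exactly; for nonlinear
#' estimators (e.g. correlations) the identity holds approximately.
#'
#' @param isns an `isn_set` built over the full reference population, before
#'   the absolute-value transform.
#' @param global_net the [global_network()] the ISNs derive from; defaults to
#'   the one stored on the `isn_set`.
#' @return list with `max_abs_deviation`, `quantiles` (of per-edge absolute
#'   deviations) and the `deviation` matrix `mean_n(w_n) - w`.
#' @export
isn_average_check <- function(isns, global_net = NULL) {
  stopifnot(inherits(isns, "isn_set"))
  if (isns$abs_applied) stop("run the check before the absolute-value transform")
  global_net <- global_net %||% isns$global
  if (!setequal(global_net$node_ids, isns$node_ids)) stop("node set mismatch")
  if (length(isns$individual_ids) != isns$n_reference) {
    stop("ISNs must cover the full reference population")
  }
  avg <- Reduce(`+`, isns$networks) / length(isns$networks)
  dev <- avg - global_net$weights[rownames(avg), colnames(avg)]
  ut <- abs(dev[upper.tri(dev)])
  list(max_abs_deviation = max(ut),
       quantiles = stats::quantile(ut, c(0, 0.25, 0.5, 0.75, 0.9, 1)),
       deviation = dev)
}

#' Simple correlation-based association estimator
#'
#' A plain pairwise-association estimator for testing and demonstration:
#' CLR-transform (for `pearson_clr`) then correlate taxa, optionally zeroing
#' entries below a quantile of the absolute weights. This is NOT MAGMA and
#' not SparCC: it makes no attempt to model zero inflation, overdispersion or
#' indirect associations. Production analyses should supply networks from a
#' dedicated compositional inference tool via [read_network()] /
#' [estimator_from_dir()].
#'
#' @param method `"pearson_clr"` (Pearson on CLR-transformed counts) or
#'   `"spearman"` (rank correlation on raw counts).
#' @param sparsify_quantile in `[0, 1)`: entries with `|weight|` below this
#'   quantile of the nonzero absolute weights are set to zero. 0 disables
#'   sparsification.
#' @param pseudocount CLR pseudocount, see [clr_transform()].
#' @return an estimator function `(abundance_table) -> global_network`
#'   suitable for [lioness_isn()].
#' @export
fallback_estimator <- function(method = c("pearson_clr", "spearman"),
                               sparsify_quantile = 0, pseudocount = 0.5) {
  method <- match.arg(method)
  stopifnot(sparsify_quantile >= 0, sparsify_quantile < 1)
  function(table) {
    stopifnot(inherits(table, "abundance_table"))
    x <- if (method == "pearson_clr") {
      if (table$clr) table$counts else clr_transform(table, pseudocount)$counts
    } else {
      table$counts
    }
    # a taxon constant on the observed scale has no definable association,
    # even though CLR row-centering makes its transformed column vary
    const <- apply(table$counts, 2L, function(v) stats::sd(v) == 0)
    w <- if (method == "pearson_clr") {
      suppressWarnings(stats::cor(x))
    } else {
      suppressWarnings(stats::cor(x, method = "spearman"))
    }
    w[!is.finite(w)] <- 0
    if (any(const)) {
      warning("constant taxa set to zero association: ",
              paste(colnames(x)[const], collapse = ", "))
      w[const, ] <- 0
      w[, const] <- 0
    }
    diag(w) <- 0
    if (sparsify_quantile > 0) {
      nz <- abs(w[upper.tri(w)])
      nz <- nz[nz > 0]
      if (length(nz)) {
        thr <- stats::quantile(nz, sparsify_quantile)
        w[abs(w) < thr] <- 0
      }
    }
    global_network(w, provenance = sprintf(
      "fallback_estimator(%s, sparsify_quantile=%g) [NOT MAGMA/SparCC]",
      method, sparsify_quantile))
  }
}

#' Estimator reading precomputed networks from a directory
#'
#' Supports workflows where the global and leave-one-out networks were
#' inferred by an external tool (e.g. MAGMA or SparCC) and written to files:
#' the directory must contain `global.<ext>` and one `loo_<individual>.<ext>`
#' per individual, in either network dialect of [read_network()].
#'
#' @param dir directory holding the network files.
#' @param ext file extension, `"csv"` (matrix) or `"tsv"` (edge list).
#' @return an estimator function keyed on the sample subset it receives: the
#'   full table maps to `global`, a table missing exactly one individual maps
#'   to that individual's `loo_` file.
#' @export
estimator_from_dir <- function(dir, ext = c("csv", "tsv")) {
  ext <- match.arg(ext)
  force(dir)
  reference <- NULL
  function(table) {
    ids <- as.character(table$metadata$individual_id)
    if (is.null(reference)) reference <<- ids
    missing_ind <- setdiff(reference, ids)
    file <- if (length(missing_ind) == 0L) {
      file.path(dir, paste0("global.", ext))
    } else if (length(missing_ind) == 1L) {
      file.path(dir, paste0("loo_", missing_ind, ".", ext))
    } else {
      stop("subset differs from the reference by more than one individual")
    }
    if (!file.exists(file)) stop("missing network file: ", file)
    read_network(file, node_ids = colnames(table$counts),
                 provenance = paste("precomputed:", file))
  }
}
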