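#' Global association networks
#'
#' A `global_network` is a symmetric weighted association matrix over labeled
#' taxa with a zero diagonal, typically produced by an external co-occurrence
#' inference tool over a pooled reference population. Edge weights may be
#' signed.
#'
#' @param weights square numeric matrix with matching row/column names
#'   (taxon ids), symmetric within tolerance, zero diagonal.
#' @param provenance free-text description of the estimator and parameters.
#' @param tol relative symmetry tolerance (default 1e-8).
#' @param symmetrize if `TRUE`, an asymmetric matrix is replaced by
#'   `(w + t(w)) / 2` instead of raising an error.
#' @return an object of class `global_network`.
#' @export
global_network <- function(weights, provenance = "unspecified", tol = 1e-8,
                           symmetrize = FALSE) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) && !is.null(colnames(weights))) {
    rownames(weights) <- colnames(weights)
  }
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <- paste0("n", seq_len(nrow(weights)))
  }
  if (!identical(rownames(weights), colnames(weights))) {
    stop("row and column names must match")
  }
  if (symmetrize) {
    weights <- (weights + t(weights)) / 2
  }
  check_square_symmetric(weights, tol = tol, what = "global network")
  weights <- (weights + t(weights)) / 2   # remove numerical asymmetry
  diag(weights) <- 0
  structure(list(node_ids = rownames(weights), weights = weights,
                 provenance = provenance),
            class = "global_network")
}

#' @export
print.global_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("global_network:", length(x$node_ids), "nodes,", nz, "edges\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a network from square-matrix CSV or edge-list TSV
#'
#' Two dialects are supported: a square matrix CSV with a header row and a
#' leading node-id column, or a 3-column edge list (`node_a`, `node_b`,
#' `weight`) interpreted as an undirected graph. Edge-list nodes not listed
#' in `node_ids` raise an error; unlisted edges are zero.
#'
#' @param path file path.
#' @param format `"matrix"`, `"edgelist"`, or `"auto"` (guessed from the
#'   header).
#' @param node_ids required for the edge-list dialect when the file does not
#'   cover all nodes: full node set of the network.
#' @param provenance provenance string stored on the result.
#' @param symmetrize forwarded to [global_network()].
#' @return a [global_network()].
#' @export
read_network <- function(path, format = c("auto", "matrix", "edgelist"),
                         node_ids = NULL, provenance = NULL,
                         symmetrize = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    hdr <- strsplit(readLines(path, n = 1L), "[,\t]")[[1L]]
    format <- if (length(hdr) == 3L &&
                  all(tolower(hdr) %in% c("node_a", "node_b", "weight"))) {
      "edgelist"
    } else "matrix"
  }
  if (format == "matrix") {
    raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(raw[[1L]])
    w <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(w) <- "double"
    rownames(w) <- ids
    if (!identical(ids, colnames(w))) stop("matrix row/column ids differ in ", path)
    return(global_network(w, provenance = provenance %||% paste("matrix CSV:", path),
                          symmetrize = symmetrize))
  }
  el <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(el) != 3L) stop("edge list must have 3 columns (node_a, node_b, weight)")
  names(el) <- c("node_a", "node_b", "weight")
  el$node_a <- as.character(el$node_a)
  el$node_b <- as.character(el$node_b)
  if (is.null(node_ids)) node_ids <- sort(unique(c(el$node_a, el$node_b)))
  unknown <- setdiff(c(el$node_a, el$node_b), node_ids)
  if (length(unknown)) stop("unknown node(s) in edge list: ",
                            paste(unique(unknown), collapse = ", "))
  key <- paste(pmin(el$node_a, el$node_b), pmax(el$node_a, el$node_b))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      length(unique(el$weight[key == k])) > 1L
    }, logical(1L))
    if (any(conflicting)) {
      stop("edge(s) listed twice with conflicting weights: ",
           paste(unique(dup)[conflicting], collapse = "; "))
    }
    el <- el[!duplicated(key), , drop = FALSE]
  }
  K <- length(node_ids)
  w <- matrix(0, K, K, dimnames = list(node_ids, node_ids))
  ia <- match(el$node_a, node_ids); ib <- match(el$node_b, node_ids)
  w[cbind(ia, ib)] <- el$weight
  w[cbind(ib, ia)] <- el$weight
  global_network(w, provenance = provenance %||% paste("edge-list TSV:", path))
}

#' Write a network as square-matrix CSV or edge-list TSV
#'
#' The edge-list writer emits each undirected edge once with node ids in
#' lexicographic order, omitting zero-weight pairs.
#'
#' @param net a [global_network()] or a plain symmetric matrix.
#' @param path output file.
#' @param format `"matrix"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  w <- if (inherits(net, "global_network")) net$weights else as.matrix(net)
  if (format == "matrix") {
    df <- data.frame(node_id = rownames(w), w, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  a <- rownames(w)[idx[, 1L]]; b <- colnames(w)[idx[, 2L]]
  el <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                   weight = w[idx], stringsAsFactors = FALSE)
  el <- el[order(el$node_a, el$node_b), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
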