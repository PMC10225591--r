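#' Abundance tables with sample metadata
#'
#' An `abundance_table` bundles a samples-by-taxa count (or CLR-transformed)
#' matrix with per-sample metadata and optional per-taxon taxonomy. Metadata
#' must identify the individual and the time point of every sample, because
#' downstream individual-specific network construction pairs samples of the
#' same individual across time points.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns; finite and
#'   non-negative unless `clr = TRUE` (CLR values may be negative). Row names
#'   are sample ids, column names taxon ids.
#' @param metadata data.frame with one row per sample; must contain columns
#'   `sample_id`, `individual_id`, `time_point`; extra columns (phenotypes,
#'   diet codes, delivery mode, ...) are carried along.
#' @param taxonomy optional data.frame with column `taxon_id` plus rank
#'   columns such as `phylum`, `genus`, `species`.
#' @param clr logical; `TRUE` marks the matrix as CLR-transformed (negative
#'   values allowed).
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, metadata, taxonomy = NULL, clr = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample row names and taxon column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated sample ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicated taxon ids in counts")
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (!clr && any(counts < 0)) stop("counts must be non-negative")
  metadata <- as.data.frame(metadata)
  req <- c("sample_id", "individual_id", "time_point")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  if (!all(rownames(counts) %in% metadata$sample_id)) {
    stop("metadata rows missing for samples: ",
         paste(setdiff(rownames(counts), metadata$sample_id), collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, rownames(counts))
  if (length(extra)) {
    stop("metadata rows without matching samples: ", paste(extra, collapse = ", "))
  }
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- metadata$sample_id
  key <- paste(metadata$individual_id, metadata$time_point, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, time_point) pairs in metadata")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!"taxon_id" %in% names(taxonomy)) stop("taxonomy lacks column taxon_id")
    taxonomy$taxon_id <- as.character(taxonomy$taxon_id)
  }
  structure(
    list(counts = counts, metadata = metadata, taxonomy = taxonomy, clr = clr),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  time points:", paste(sort(unique(x$metadata$time_point)), collapse = ", "), "\n")
  cat("  individuals:", length(unique(x$metadata$individual_id)), "\n")
  if (x$clr) cat("  values: CLR-transformed\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Read an abundance table and its metadata from delimited text
#'
#' The abundance file is a TSV/CSV with a header row and a leading sample-id
#' column (taxa in columns). With `taxa_rows = TRUE` the matrix is read
#' transposed (taxa in rows). Metadata is a separate delimited file keyed by
#' `sample_id`.
#'
#' @param path abundance file.
#' @param metadata_path metadata file with columns `sample_id`,
#'   `individual_id`, `time_point`.
#' @param sep field separator; `NULL` guesses from the file extension
#'   (".csv" is comma, anything else tab).
#' @param taxa_rows logical; set `TRUE` when taxa are in rows.
#' @param taxonomy_path optional taxonomy file with a `taxon_id` column.
#' @param clr whether the stored values are already CLR-transformed.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, metadata_path, sep = NULL, taxa_rows = FALSE,
                           taxonomy_path = NULL, clr = FALSE) {
  gsep <- function(p, s) if (!is.null(s)) s else if (grepl("\\.csv$", p)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = gsep(path, sep),
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop("duplicated ids in first column of ", path)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (taxa_rows) m <- t(m)
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = gsep(metadata_path, sep),
                            check.names = FALSE, stringsAsFactors = FALSE)
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- utils::read.table(taxonomy_path, header = TRUE,
                             sep = gsep(taxonomy_path, sep),
                             check.names = FALSE, stringsAsFactors = FALSE)
  }
  abundance_table(m, meta, taxonomy = tax, clr = clr)
}

#' Write an abundance table (and its metadata) to delimited text
#'
#' @param table an [abundance_table()].
#' @param path abundance output file (samples in rows).
#' @param metadata_path optional metadata output file.
#' @param sep field separator; `NULL` guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, metadata_path = NULL, sep = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  gsep <- function(p, s) if (!is.null(s)) s else if (grepl("\\.csv$", p)) "," else "\t"
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = gsep(path, sep), row.names = FALSE,
                     quote = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(table$metadata, metadata_path,
                       sep = gsep(metadata_path, sep),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Centered log-ratio transform
#'
#' Applies the CLR transform per sample: `log(x + pseudocount)` centered by
#' the sample's mean log value, so each output row has mean zero. The
#' pseudocount guards against zeros in sparse count data; half a count is the
#' common convention.
#'
#' @param table an [abundance_table()] of non-negative values.
#' @param pseudocount positive value added before taking logs (default 0.5);
#'   may be 0 only if no sample contains a zero.
#' @return an [abundance_table()] with `clr = TRUE`.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$clr) stop("table is already CLR-transformed")
  x <- table$counts + pseudocount
  if (any(x <= 0)) stop("non-positive values after pseudocount; use pseudocount > 0")
  lx <- log(x)
  lx <- lx - rowMeans(lx)
  abundance_table(lx, table$metadata, taxonomy = table$taxonomy, clr = TRUE)
}

#' Taxon prevalence
#'
#' Fraction of samples with a strictly positive count per taxon.
#'
#' @param table an [abundance_table()].
#' @param samples optional character vector restricting to a sample subset.
#' @return named numeric vector over taxa.
#' @export
prevalence <- function(table, samples = NULL) {
  m <- table$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  colMeans(m > 0)
}

#' Prevalence filtering of taxa
#'
#' Retains taxa whose prevalence on the supplied (merged) sample set strictly
#' exceeds `threshold`; the 15% default mirrors common practice for sparse
#' amplicon data. Column order is preserved.
#'
#' @param table an [abundance_table()] of counts.
#' @param threshold prevalence threshold in `[0, 1]`; comparison is strict.
#' @return list with elements `table` (filtered), `kept_ids`, `dropped_ids`.
#' @export
prevalence_filter <- function(table, threshold = 0.15) {
  stopifnot(inherits(table, "abundance_table"),
            threshold >= 0, threshold <= 1)
  if (nrow(table$counts) == 0L || ncol(table$counts) == 0L) stop("empty table")
  prev <- prevalence(table)
  keep <- prev > threshold
  if (!any(keep)) stop("no taxon passes the prevalence threshold ", threshold)
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[tax$taxon_id %in% names(prev)[keep], , drop = FALSE]
  list(
    table = abundance_table(table$counts[, keep, drop = FALSE], table$metadata,
                            taxonomy = tax, clr = table$clr),
    kept_ids = names(prev)[keep],
    dropped_ids = names(prev)[!keep]
  )
}

#' Appearing and disappearing taxa between two time points
#'
#' A taxon is *appearing* when its prevalence exceeds the threshold among the
#' samples of the later time point but not on the merged sample set, and
#' *disappearing* when it exceeds the threshold only at the earlier time
#' point. These are exactly the taxa the joint-time-point prevalence filter
#' discards even though they are established at one of the two time points.
#'
#' @param table an [abundance_table()] whose metadata has exactly two time
#'   points.
#' @param threshold prevalence threshold (strict comparison), default 0.15.
#' @param time_order optional length-2 vector giving the earlier and later
#'   time point; defaults to the sorted unique values.
#' @return list with `appearing_ids` and `disappearing_ids`.
#' @export
appearing_disappearing <- function(table, threshold = 0.15, time_order = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  tps <- unique(table$metadata$time_point)
  if (length(tps) != 2L) stop("metadata must contain exactly two time points")
  if (is.null(time_order)) time_order <- sort(tps)
  if (!setequal(time_order, tps)) stop("time_order does not match the data")
  early <- table$metadata$sample_id[table$metadata$time_point == time_order[1L]]
  late <- table$metadata$sample_id[table$metadata$time_point == time_order[2L]]
  p_all <- prevalence(table)
  p_early <- prevalence(table, early)
  p_late <- prevalence(table, late)
  list(
    appearing_ids = names(p_all)[p_late > threshold & p_all <= threshold],
    disappearing_ids = names(p_all)[p_early > threshold & p_all <= threshold]
  )
}
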