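#' Build per-individual multiplexes from a two-time-point abundance table
#'
#' Convenience pipeline for cohort analyses: at each time point the samples
#' form an independent reference population from which individual-specific
#' networks are derived by leave-one-out perturbation; the signed weights
#' are replaced by absolute values and each individual's two networks are
#' stacked into a multiplex. Only individuals sampled at both time points
#' are retained.
#'
#' @param table an [abundance_table()] with exactly two time points.
#' @param estimator association estimator, see [lioness_isn()].
#' @param time_order optional length-2 vector (earlier, later).
#' @return list with `multiplexes` (named list per individual), `isns`
#'   (named list of the two absolute-valued `isn_set`s, keyed by time
#'   point), `isns_signed` (before the absolute transform), `individuals`.
#' @export
build_cohort_multiplexes <- function(table, estimator, time_order = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- table$metadata
  tps <- unique(meta$time_point)
  if (length(tps) != 2L) stop("table must contain exactly two time points")
  if (is.null(time_order)) time_order <- sort(tps)
  per_tp <- lapply(time_order, function(tp) {
    keep <- meta$sample_id[meta$time_point == tp]
    abundance_table(table$counts[keep, , drop = FALSE],
                    meta[meta$time_point == tp, , drop = FALSE],
                    taxonomy = table$taxonomy, clr = table$clr)
  })
  paired <- Reduce(intersect, lapply(per_tp, function(t) t$metadata$individual_id))
  if (length(paired) < 3L) stop("fewer than 3 individuals sampled at both time points")
  isns_signed <- lapply(per_tp, function(t) {
    lioness_isn(t, estimator, individuals = paired)
  })
  names(isns_signed) <- as.character(time_order)
  isns <- lapply(isns_signed, absolute_weights)
  multiplexes <- lapply(paired, function(ind) {
    build_multiplex(stats::setNames(lapply(isns, function(s) s$networks[[ind]]),
                                    names(isns)),
                    owner = ind)
  })
  names(multiplexes) <- paired
  list(multiplexes = multiplexes, isns = isns, isns_signed = isns_signed,
       individuals = paired)
}
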