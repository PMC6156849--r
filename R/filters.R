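#' Expression filters gating events into the analysis
#'
#' Sequencing: an event is retained only if every splice junction in its two
#' alternative paths reaches at least \code{min_junction_fpkm} (default 2
#' FPKM) in at least \code{min_samples} samples. Arrays: the alternative
#' paths' signals must strictly exceed the \code{array_quantile} (default
#' 0.25) quantile of all reference-path signals in at least one sample.
#'
#' @param min_junction_fpkm junction FPKM threshold (applied as >=).
#' @param array_quantile reference-signal quantile in [0, 1] (applied as >).
#' @param min_samples number of samples in which the threshold must be met.
#' @param quantile_type quantile convention (stats::quantile type, default 7,
#'   linear interpolation).
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(min_junction_fpkm = 2, array_quantile = 0.25,
                          min_samples = 1L, quantile_type = 7L) {
  stopifnot(min_junction_fpkm >= 0, array_quantile >= 0, array_quantile <= 1,
            min_samples >= 1)
  structure(list(min_junction_fpkm = min_junction_fpkm,
                 array_quantile = array_quantile,
                 min_samples = as.integer(min_samples),
                 quantile_type = as.integer(quantile_type)),
            class = "filter_config")
}

## junction edges of both alternative paths (real junctions, gap > 0)
.event_junction_edges <- function(event, graph) {
  ids <- c(event$path1, event$path2)
  e <- graph$edges[match(ids, graph$edges$edge_id), , drop = FALSE]
  e$edge_id[e$kind == "junction" & e$end > e$start]
}

#' Filter sequencing events on junction expression
#'
#' @param events a \code{splice_events} object.
#' @param graph its \code{splicing_graph}.
#' @param edge_fpkm matrix of per-edge FPKM (rownames = edge ids as
#'   characters, columns = samples).
#' @param cfg a [filter_config()].
#' @return the retained \code{splice_events} subset.
#' @export
filter_rnaseq_events <- function(events, graph, edge_fpkm,
                                 cfg = filter_config()) {
  keep <- vapply(unclass(events), function(ev) {
    jn <- .event_junction_edges(ev, graph)
    if (!length(jn)) return(TRUE)
    rows <- edge_fpkm[as.character(jn), , drop = FALSE]
    all(rowSums(rows >= cfg$min_junction_fpkm) >= cfg$min_samples)
  }, logical(1))
  structure(unclass(events)[keep], class = "splice_events",
            gene_id = attr(events, "gene_id"))
}

#' Filter array events on path signal
#'
#' The threshold is computed array-wide: the \code{array_quantile} quantile of
#' the reference-path signals of all events. An event is retained iff each
#' alternative path's signal strictly exceeds it in at least one sample.
#'
#' @param event_ids character vector of event ids.
#' @param S1,S2,SR signal matrices (events x samples, rows aligned with
#'   \code{event_ids}).
#' @param cfg a [filter_config()].
#' @return character vector of retained event ids.
#' @export
filter_array_events <- function(event_ids, S1, S2, SR,
                                cfg = filter_config()) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2); SR <- as.matrix(SR)
  if (length(SR) == 0L) stop("empty reference signal matrix")
  thr <- stats::quantile(as.numeric(SR), probs = cfg$array_quantile,
                         type = cfg$quantile_type, names = FALSE)
  keep <- apply(S1 > thr, 1, any) & apply(S2 > thr, 1, any)
  event_ids[keep]
}
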