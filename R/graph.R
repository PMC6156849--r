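#' Splicing graphs
#'
#' A splicing graph represents the exon/intron structure of one gene as a
#' directed acyclic graph. Every (sub)exonic segment contributes two boundary
#' nodes -- one for its start and one for its end position -- joined by an
#' exonic edge; splice junctions join the end node of one segment to the start
#' node of a downstream segment; a virtual source and sink flank the first and
#' last boundary of every transcript. Isoforms are source-to-sink paths.
#'
#' Coordinates are 0-based, half-open throughout; GTF input/output converts
#' from/to the 1-based inclusive convention. Graphs are laid out in genomic
#' (left-to-right) order regardless of strand; strand matters only when
#' classifying events (e.g. which side is the 5' splice site).
#'
#' @name splicing_graph
#' @keywords internal
NULL

new_splicing_graph <- function(gene_id, chrom, strand, nodes, edges,
                               isoform_edges) {
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         nodes = nodes, edges = edges, isoform_edges = isoform_edges),
    class = "splicing_graph"
  )
}

#' @export
print.splicing_graph <- function(x, ...) {
  kinds <- table(factor(x$edges$kind,
                        levels = c("exonic", "junction", "artificial")))
  cat("Splicing graph for gene '", x$gene_id, "' (", x$chrom, x$strand,
      ")\n", sep = "")
  cat("  ", nrow(x$nodes), " nodes (incl. virtual source/sink); ",
      kinds[["exonic"]], " exonic, ", kinds[["junction"]], " junction, ",
      kinds[["artificial"]], " artificial edges\n", sep = "")
  cat("  ", length(x$isoform_edges), " annotated isoform(s)\n", sep = "")
  invisible(x)
}

## Node bookkeeping -----------------------------------------------------------
## Nodes are kept sorted in topological (genomic) order: virtual source first,
## then boundaries by (position, side) with side "end" before "start" so that
## zero-gap adjacency edges (end@p -> start@p) respect the order, sink last.

.side_rank <- c(end = 0L, start = 1L)

.make_nodes <- function(positions, sides) {
  key <- paste(positions, sides)
  keep <- !duplicated(key)
  positions <- positions[keep]
  sides <- sides[keep]
  o <- order(positions, .side_rank[sides])
  data.frame(
    node_id = seq_len(length(positions) + 2L),
    position = c(-Inf, positions[o], Inf),
    side = c("source", sides[o], "sink"),
    virtual = c(TRUE, rep(FALSE, length(positions)), TRUE),
    stringsAsFactors = FALSE
  )
}

.node_lookup <- function(nodes) {
  ids <- nodes$node_id
  names(ids) <- paste(nodes$position, nodes$side)
  ids
}

## Segment decomposition: cut the union of all exons at every distinct exon
## boundary; a candidate slice is kept iff it lies inside at least one exon.
.decompose_segments <- function(starts, ends) {
  bounds <- sort(unique(c(starts, ends)))
  if (length(bounds) < 2L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  seg <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  covered <- vapply(seq_len(nrow(seg)), function(i) {
    any(starts <= seg$start[i] & ends >= seg$end[i])
  }, logical(1))
  seg[covered, , drop = FALSE]
}

## Edge construction helper: dedupe on (from, to, kind) and assign stable ids.
.finish_edges <- function(from, to, kind, start, end) {
  key <- paste(from, to, kind)
  keep <- !duplicated(key)
  edges <- data.frame(
    from = from[keep], to = to[keep], kind = kind[keep],
    start = start[keep], end = end[keep], stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to, edges$kind), , drop = FALSE]
  edges$edge_id <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  edges[, c("edge_id", "from", "to", "kind", "start", "end")]
}

.edge_key <- function(from, to, kind) paste(from, to, kind)

#' Build a splicing graph from an exon table
#'
#' Decomposes the exons of all isoforms of one gene into disjoint subexonic
#' segments at every distinct exon boundary, creates one start/end node pair
#' and one exonic edge per segment, junction edges between consecutive
#' segments of each isoform (zero-gap edges where two segments of the same
#' exon abut), and artificial source/sink edges at each transcript's first
#' and last boundary.
#'
#' @param exons data.frame with columns \code{transcript_id}, \code{start},
#'   \code{end} (0-based half-open).
#' @param gene_id,chrom,strand gene metadata; strand one of \code{"+"},
#'   \code{"-"}, \code{"."} (unstranded input is treated as \code{"+"}).
#' @return A \code{splicing_graph}.
#' @export
build_splicing_graph <- function(exons, gene_id = "gene", chrom = "chr1",
                                 strand = "+") {
  stopifnot(is.data.frame(exons),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  if (nrow(exons) == 0L) {
    stop("gene '", gene_id, "': no exons (transcripts with zero exons are rejected)")
  }
  bad <- exons$start >= exons$end
  if (any(bad)) {
    stop("gene '", gene_id, "': ", sum(bad),
         " exon(s) with start >= end rejected")
  }
  if (!strand %in% c("+", "-")) strand <- "+"

  seg <- .decompose_segments(exons$start, exons$end)
  nodes <- .make_nodes(
    positions = c(seg$start, seg$end),
    sides = rep(c("start", "end"), each = nrow(seg))
  )
  lut <- .node_lookup(nodes)
  source_id <- nodes$node_id[nodes$side == "source"]
  sink_id <- nodes$node_id[nodes$side == "sink"]

  e_from <- integer(0); e_to <- integer(0); e_kind <- character(0)
  e_start <- numeric(0); e_end <- numeric(0)
  add_edge <- function(from, to, kind, start, end) {
    e_from <<- c(e_from, from); e_to <<- c(e_to, to)
    e_kind <<- c(e_kind, kind)
    e_start <<- c(e_start, start); e_end <<- c(e_end, end)
  }
  # exonic edges, one per segment
  for (i in seq_len(nrow(seg))) {
    add_edge(lut[[paste(seg$start[i], "start")]],
             lut[[paste(seg$end[i], "end")]],
             "exonic", seg$start[i], seg$end[i])
  }

  # per-isoform chains
  iso_node_paths <- list()
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("transcript '", tx, "' has overlapping exons")
    }
    node_path <- source_id
    for (j in seq_len(nrow(ex))) {
      segs <- seg[seg$start >= ex$start[j] & seg$end <= ex$end[j], ,
                  drop = FALSE]
      segs <- segs[order(segs$start), , drop = FALSE]
      if (j > 1L) {
        # splice junction from previous exon end to this exon start
        add_edge(lut[[paste(ex$end[j - 1L], "end")]],
                 lut[[paste(ex$start[j], "start")]],
                 "junction", ex$end[j - 1L], ex$start[j])
      }
      for (k in seq_len(nrow(segs))) {
        if (k > 1L) {
          # adjacency between segments of one exon: zero-gap junction edge
          add_edge(lut[[paste(segs$start[k], "end")]],
                   lut[[paste(segs$start[k], "start")]],
                   "junction", segs$start[k], segs$start[k])
        }
        node_path <- c(node_path,
                       lut[[paste(segs$start[k], "start")]],
                       lut[[paste(segs$end[k], "end")]])
      }
    }
    node_path <- c(node_path, sink_id)
    add_edge(source_id, node_path[2L], "artificial", NA_real_, NA_real_)
    add_edge(node_path[length(node_path) - 1L], sink_id, "artificial",
             NA_real_, NA_real_)
    iso_node_paths[[tx]] <- node_path
  }

  edges <- .finish_edges(e_from, e_to, e_kind, e_start, e_end)
  ekey <- .edge_key(edges$from, edges$to, edges$kind)
  eid <- edges$edge_id
  names(eid) <- ekey

  isoform_edges <- lapply(iso_node_paths, function(np) {
    n <- length(np)
    ids <- integer(n - 1L)
    for (i in seq_len(n - 1L)) {
      from <- np[i]; to <- np[i + 1L]
      kind <- if (i == 1L || i == n - 1L) "artificial" else
        if (nodes$side[match(from, nodes$node_id)] == "start") "exonic"
        else "junction"
      ids[i] <- eid[[.edge_key(from, to, kind)]]
    }
    ids
  })

  new_splicing_graph(gene_id, chrom, strand, nodes, edges, isoform_edges)
}

#' Build splicing graphs from a parsed GTF annotation
#'
#' @param gene a gene record as returned by [read_gtf_annotation()]: a list
#'   with \code{gene_id}, \code{chrom}, \code{strand} and an \code{exons}
#'   data.frame (\code{transcript_id}, \code{start}, \code{end}; 0-based
#'   half-open after import).
#' @return A \code{splicing_graph}.
#' @seealso [read_gtf_annotation()], [build_graph_from_junctions()]
#' @export
build_graph_from_gtf <- function(gene) {
  stopifnot(is.list(gene), !is.null(gene$exons))
  build_splicing_graph(gene$exons, gene_id = gene$gene_id,
                       chrom = gene$chrom, strand = gene$strand)
}

#' FPKM for a splice junction
#'
#' Fragments per kilobase per million mapped reads, with the junction's
#' effective length standing in for the feature length: a junction is only
#' observable from reads spanning it, so its effective length defaults to
#' \code{read_length - 2 * min_anchor + 1}.
#'
#' @param count read count (vectorized).
#' @param library_size total mapped reads in the sample.
#' @param effective_length effective feature length in bp.
#' @return FPKM value(s): \code{count * 1e9 / (library_size * effective_length)}.
#' @export
junction_fpkm <- function(count, library_size, effective_length) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(effective_length <= 0)) stop("effective_length must be > 0")
  count * 1e9 / (library_size * effective_length)
}

#' Default effective length of a junction
#' @param read_length read length in bp.
#' @param min_anchor minimum anchor overhang in bp on each side.
#' @return Effective length in bp.
#' @export
junction_effective_length <- function(read_length = 100, min_anchor = 1) {
  read_length - 2 * min_anchor + 1
}

#' Build a data-driven splicing graph from junction and coverage tables
#'
#' Junctions with FPKM at or above \code{min_fpkm} in at least one sample
#' become junction edges; contiguous expressed coverage bins, cut at every
#' retained junction boundary, become exonic edges. Data-driven graphs carry
#' no isoform map; event enumeration then uses path enumeration instead.
#'
#' @param junctions data.frame: \code{chrom}, \code{start}, \code{end} (intron
#'   coordinates, 0-based half-open), \code{strand}, then one count column per
#'   sample.
#' @param coverage_bins analogous data.frame of exon-bin read counts.
#' @param library_sizes named numeric vector of total mapped reads per sample;
#'   names must match the count columns.
#' @param min_fpkm junction inclusion threshold (default 2 FPKM).
#' @param min_coverage_fpkm expressed-bin cutoff (default 0.5 FPKM).
#' @param read_length,min_anchor used for the junction effective length.
#' @param gene_id,strand metadata for the resulting graph.
#' @return A \code{splicing_graph} with empty \code{isoform_edges}.
#' @export
build_graph_from_junctions <- function(junctions, coverage_bins, library_sizes,
                                       min_fpkm = 2, min_coverage_fpkm = 0.5,
                                       read_length = 100, min_anchor = 1,
                                       gene_id = "gene", strand = "+") {
  samples <- names(library_sizes)
  stopifnot(length(samples) > 0,
            all(samples %in% names(junctions)),
            all(samples %in% names(coverage_bins)))
  chrom <- if (nrow(junctions)) junctions$chrom[1L] else coverage_bins$chrom[1L]

  eff_len <- junction_effective_length(read_length, min_anchor)
  jc <- as.matrix(junctions[, samples, drop = FALSE])
  jfpkm <- sweep(jc * 1e9 / eff_len, 2, library_sizes, "/")
  keep_j <- nrow(junctions) > 0 &
    apply(jfpkm, 1, function(r) any(r >= min_fpkm))
  jn <- junctions[keep_j, , drop = FALSE]

  bc <- as.matrix(coverage_bins[, samples, drop = FALSE])
  width <- coverage_bins$end - coverage_bins$start
  bfpkm <- sweep(bc * 1e9 / width, 2, library_sizes, "/")
  expressed <- apply(bfpkm, 1, function(r) any(r >= min_coverage_fpkm))
  bins <- coverage_bins[expressed, , drop = FALSE]

  # merge contiguous expressed bins into covered regions
  regions <- data.frame(start = numeric(0), end = numeric(0))
  if (nrow(bins)) {
    r <- IRanges::reduce(IRanges::IRanges(bins$start + 1L, bins$end))
    regions <- data.frame(start = IRanges::start(r) - 1L,
                          end = IRanges::end(r))
  }

  # cut covered regions at junction boundaries
  cuts <- sort(unique(c(jn$start, jn$end)))
  in_region <- function(p) {
    nrow(regions) > 0 && any(regions$start < p & p < regions$end)
  }
  at_region_edge <- function(p) {
    nrow(regions) > 0 && any(regions$start == p | regions$end == p)
  }
  orphan <- cuts[!vapply(cuts, function(p) in_region(p) || at_region_edge(p),
                         logical(1))]
  if (length(orphan)) {
    warning("junction boundary with no covered region at position(s) ",
            paste(orphan, collapse = ", "),
            "; kept as novel exon boundary")
  }

  seg_start <- numeric(0); seg_end <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    inner <- cuts[cuts > regions$start[i] & cuts < regions$end[i]]
    b <- c(regions$start[i], inner, regions$end[i])
    seg_start <- c(seg_start, b[-length(b)])
    seg_end <- c(seg_end, b[-1L])
  }
  seg <- data.frame(start = seg_start, end = seg_end)

  # nodes: segment boundaries plus orphan junction boundaries
  pos <- c(seg$start, seg$end, jn$start, jn$end)
  side <- c(rep("start", nrow(seg)), rep("end", nrow(seg)),
            rep("end", nrow(jn)), rep("start", nrow(jn)))
  nodes <- .make_nodes(pos, side)
  lut <- .node_lookup(nodes)
  source_id <- nodes$node_id[nodes$side == "source"]
  sink_id <- nodes$node_id[nodes$side == "sink"]

  e_from <- integer(0); e_to <- integer(0); e_kind <- character(0)
  e_start <- numeric(0); e_end <- numeric(0)
  add_edge <- function(from, to, kind, start, end) {
    e_from <<- c(e_from, from); e_to <<- c(e_to, to)
    e_kind <<- c(e_kind, kind)
    e_start <<- c(e_start, start); e_end <<- c(e_end, end)
  }
  for (i in seq_len(nrow(seg))) {
    add_edge(lut[[paste(seg$start[i], "start")]],
             lut[[paste(seg$end[i], "end")]],
             "exonic", seg$start[i], seg$end[i])
  }
  # adjacency between consecutive segments within one covered region
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      if (seg$end[i] == seg$start[i + 1L]) {
        add_edge(lut[[paste(seg$end[i], "end")]],
                 lut[[paste(seg$end[i], "start")]],
                 "junction", seg$end[i], seg$end[i])
      }
    }
  }
  for (i in seq_len(nrow(jn))) {
    add_edge(lut[[paste(jn$start[i], "end")]],
             lut[[paste(jn$end[i], "start")]],
             "junction", jn$start[i], jn$end[i])
  }
  edges <- .finish_edges(e_from, e_to, e_kind, e_start, e_end)

  # artificial edges at terminal boundaries
  non_art <- edges[edges$kind != "artificial", , drop = FALSE]
  real_nodes <- nodes$node_id[!nodes$virtual]
  no_in <- setdiff(real_nodes, non_art$to)
  no_out <- setdiff(real_nodes, non_art$from)
  # only start-side nodes can begin a path; end-side nodes can terminate one
  no_in <- no_in[nodes$side[match(no_in, nodes$node_id)] == "start"]
  no_out <- no_out[nodes$side[match(no_out, nodes$node_id)] == "end"]
  edges <- .finish_edges(
    c(edges$from, rep(source_id, length(no_in)), no_out),
    c(edges$to, no_in, rep(sink_id, length(no_out))),
    c(edges$kind, rep("artificial", length(no_in) + length(no_out))),
    c(edges$start, rep(NA_real_, length(no_in) + length(no_out))),
    c(edges$end, rep(NA_real_, length(no_in) + length(no_out)))
  )

  new_splicing_graph(gene_id, chrom, strand, nodes, edges,
                     isoform_edges = structure(list(), names = character(0)))
}

## Graph utilities ------------------------------------------------------------

#' Topological order check
#'
#' Nodes of a splicing graph are stored in genomic order, which is a valid
#' topological order by construction; this verifies every edge respects it.
#' @param graph a \code{splicing_graph}.
#' @return TRUE invisibly; errors if an edge violates the order.
#' @export
assert_dag <- function(graph) {
  idx <- match(graph$edges$from, graph$nodes$node_id)
  jdx <- match(graph$edges$to, graph$nodes$node_id)
  if (any(idx >= jdx)) stop("splicing graph is not a DAG under genomic order")
  invisible(TRUE)
}

## Node sequence of an isoform's edge path
.edge_path_nodes <- function(graph, edge_ids) {
  e <- graph$edges[match(edge_ids, graph$edges$edge_id), , drop = FALSE]
  c(e$from[1L], e$to)
}

#' Reconstruct the exonic intervals an isoform traverses
#' @param graph a \code{splicing_graph}.
#' @param transcript_id isoform identifier.
#' @return data.frame of merged exonic intervals (0-based half-open).
#' @export
isoform_exon_intervals <- function(graph, transcript_id) {
  ids <- graph$isoform_edges[[transcript_id]]
  if (is.null(ids)) stop("unknown transcript '", transcript_id, "'")
  e <- graph$edges[match(ids, graph$edges$edge_id), , drop = FALSE]
  e <- e[e$kind == "exonic", , drop = FALSE]
  r <- IRanges::reduce(IRanges::IRanges(e$start + 1, e$end))
  data.frame(start = IRanges::start(r) - 1, end = IRanges::end(r))
}
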