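#' Alternative splicing events
#'
#' An event is a local alternative in a splicing graph: two mutually exclusive
#' edge paths (Path 1 and Path 2) running between a divergence node s and its
#' earliest reconvergence node t, plus a shared reference path (the nearest
#' exonic edges flanking the bubble that all traversing isoforms share).
#' Isoforms through Path 1 never use Path 2 edges and vice versa.
#'
#' @name splice_events
#' @keywords internal
NULL

## isoform paths as node/edge index sequences; data-driven graphs (no isoform
## map) fall back to enumerating all source-to-sink edge paths.
.graph_paths <- function(graph, max_paths = 512L) {
  if (length(graph$isoform_edges)) {
    return(graph$isoform_edges)
  }
  edges <- graph$edges
  source_id <- graph$nodes$node_id[graph$nodes$side == "source"]
  sink_id <- graph$nodes$node_id[graph$nodes$side == "sink"]
  out <- split(edges$edge_id, edges$from)
  paths <- list()
  walk <- function(node, acc) {
    if (length(paths) >= max_paths) return(invisible(NULL))
    if (node == sink_id) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (eid in out[[as.character(node)]]) {
      walk(edges$to[match(eid, edges$edge_id)], c(acc, eid))
    }
  }
  walk(source_id, integer(0))
  if (length(paths) >= max_paths) {
    warning("path enumeration capped at ", max_paths, " paths for gene '",
            graph$gene_id, "'")
  }
  names(paths) <- paste0("path", seq_along(paths))
  paths
}

.order_bundles <- function(bundles, graph) {
  # Path1 = bundle with most member paths, then larger exonic content,
  # then lowest edge id (deterministic).
  exonic_len <- vapply(bundles, function(b) {
    e <- graph$edges[match(b$edges, graph$edges$edge_id), , drop = FALSE]
    sum((e$end - e$start)[e$kind == "exonic"])
  }, numeric(1))
  o <- order(-vapply(bundles, function(b) length(b$members), integer(1)),
             -exonic_len,
             vapply(bundles, function(b) as.numeric(min(b$edges)), numeric(1)))
  bundles[o]
}

#' Enumerate minimal binary splicing events in a splicing graph
#'
#' Scans every ordered pair of nodes (s, t) traversed by at least two isoform
#' paths. The subpaths between s and t are grouped into bundles (transitive
#' closure of edge sharing); a pair with two or more edge-disjoint bundles and
#' no interior node common to all traversing paths (the minimal-bubble
#' condition) yields one event. With exactly two bundles, these are Paths 1
#' and 2; with more, the largest bundle faces the union of the rest and the
#' event is labeled complex. Alternative first/last events arise at the
#' virtual source/sink.
#'
#' @param graph a \code{splicing_graph}.
#' @param max_paths cap on source-to-sink path enumeration for data-driven
#'   graphs (annotation-mode graphs use the isoform map).
#' @return An object of class \code{splice_events}: a list of events, each with
#'   \code{event_id}, \code{type}, \code{path1}, \code{path2}, \code{ref}
#'   (edge-id vectors), and \code{isoforms1}/\code{isoforms2}.
#' @export
enumerate_events <- function(graph, max_paths = 512L) {
  assert_dag(graph)
  paths <- .graph_paths(graph, max_paths)
  events <- list()
  if (length(paths) >= 2L) {
    node_paths <- lapply(paths, function(p) .edge_path_nodes(graph, p))
    all_nodes <- sort(unique(unlist(node_paths)))
    # node -> which paths contain it, and at which index
    pos <- lapply(node_paths, function(np) {
      v <- match(all_nodes, np)
      names(v) <- all_nodes
      v
    })
    seen <- character(0)
    for (si in seq_along(all_nodes)) {
      for (ti in seq(si + 1L, length.out = length(all_nodes) - si)) {
        s <- all_nodes[si]; t <- all_nodes[ti]
        trav <- which(vapply(pos, function(v) {
          !is.na(v[[as.character(s)]]) && !is.na(v[[as.character(t)]])
        }, logical(1)))
        if (length(trav) < 2L) next
        subs <- lapply(trav, function(i) {
          a <- pos[[i]][[as.character(s)]]
          b <- pos[[i]][[as.character(t)]]
          paths[[i]][a:(b - 1L)]
        })
        # minimality: no interior node shared by all traversing paths
        interior <- lapply(trav, function(i) {
          a <- pos[[i]][[as.character(s)]]
          b <- pos[[i]][[as.character(t)]]
          if (b - a < 2L) integer(0) else node_paths[[i]][(a + 1L):(b - 1L)]
        })
        common <- Reduce(intersect, interior)
        if (length(common)) next
        # bundles: union-find over subpaths sharing any edge
        comp <- seq_along(subs)
        for (i in seq_along(subs)) {
          for (j in seq_len(i - 1L)) {
            if (length(intersect(subs[[i]], subs[[j]]))) {
              comp[comp == comp[i]] <- comp[j]
            }
          }
        }
        k <- length(unique(comp))
        if (k < 2L) next
        bundles <- lapply(unique(comp), function(cid) {
          members <- which(comp == cid)
          list(members = names(paths)[trav[members]],
               edges = sort(unique(unlist(subs[members]))))
        })
        bundles <- .order_bundles(bundles, graph)
        if (k == 2L) {
          p1 <- bundles[[1L]]; p2 <- bundles[[2L]]
          forced_complex <- FALSE
        } else {
          p1 <- bundles[[1L]]
          p2 <- list(
            members = unlist(lapply(bundles[-1L], `[[`, "members")),
            edges = sort(unique(unlist(lapply(bundles[-1L], `[[`, "edges"))))
          )
          forced_complex <- TRUE
        }
        key <- paste(paste(sort(p1$edges), collapse = ","),
                     paste(sort(p2$edges), collapse = ","))
        key2 <- paste(paste(sort(p2$edges), collapse = ","),
                      paste(sort(p1$edges), collapse = ","))
        if (key %in% seen || key2 %in% seen) next
        seen <- c(seen, key)
        ref <- .reference_edges(graph, paths[trav], pos[trav], s, t)
        events[[length(events) + 1L]] <- list(
          gene_id = graph$gene_id, chrom = graph$chrom, strand = graph$strand,
          s = s, t = t,
          path1 = p1$edges, path2 = p2$edges, ref = ref,
          isoforms1 = p1$members, isoforms2 = p2$members,
          forced_complex = forced_complex
        )
      }
    }
  }
  for (i in seq_along(events)) {
    events[[i]]$type <- classify_event(events[[i]], graph)
    events[[i]]$event_id <- paste0(graph$gene_id, "_", i)
  }
  structure(events, class = "splice_events", gene_id = graph$gene_id)
}

## nearest exonic edge up/downstream of the bubble shared by all traversing
## paths (one per side where it exists)
.reference_edges <- function(graph, paths, pos, s, t) {
  kinds <- graph$edges$kind
  side_edges <- function(which_side) {
    per_path <- lapply(seq_along(paths), function(i) {
      a <- pos[[i]][[as.character(s)]]
      b <- pos[[i]][[as.character(t)]]
      p <- paths[[i]]
      if (which_side == "up") {
        ids <- if (a > 1L) rev(p[seq_len(a - 1L)]) else integer(0)
      } else {
        ids <- if (b <= length(p)) p[b:length(p)] else integer(0)
      }
      ids[kinds[match(ids, graph$edges$edge_id)] == "exonic"]
    })
    if (!length(per_path[[1L]])) return(integer(0))
    shared <- Reduce(intersect, per_path[-1L], per_path[[1L]])
    for (e in per_path[[1L]]) {        # nearest-first scan
      if (e %in% shared || length(per_path) == 1L) return(e)
    }
    integer(0)
  }
  sort(c(side_edges("up"), side_edges("down")))
}

## ordered edge chain + collapsed structural pattern ---------------------------

.path_chain <- function(graph, edge_ids) {
  e <- graph$edges[match(edge_ids, graph$edges$edge_id), , drop = FALSE]
  o <- order(match(e$from, graph$nodes$node_id))
  e[o, , drop = FALSE]
}

## pattern symbols: E exonic, J spliced junction (gap > 0), A abutting
## zero-gap junction, V artificial; runs of E/A collapse to one E.
.path_pattern <- function(graph, edge_ids) {
  e <- .path_chain(graph, edge_ids)
  sym <- ifelse(e$kind == "exonic", "E",
         ifelse(e$kind == "artificial", "V",
         ifelse(e$end > e$start, "J", "A")))
  sym <- sym[sym != "V"]
  if (!length(sym)) return(character(0))
  out <- character(0)
  i <- 1L
  while (i <= length(sym)) {
    if (sym[i] %in% c("E", "A")) {
      j <- i
      while (j < length(sym) && sym[j + 1L] %in% c("E", "A")) j <- j + 1L
      out <- c(out, if (any(sym[i:j] == "E")) "E" else "A")
      i <- j + 1L
    } else {
      out <- c(out, "J")
      i <- i + 1L
    }
  }
  out
}

#' Classify a splicing event
#'
#' Structural, strand-aware predicates over the two alternative paths:
#' cassette (junction-exon-junction vs. skipping junction), alternative 5'/3'
#' splice site (two junctions sharing one boundary, the longer path carrying
#' the exonic extension), mutually exclusive exons, intron retention (exonic
#' span vs. junction over the same interval), alternative first/last exon
#' (divergence at the virtual source / convergence at the sink), and complex
#' for everything else. Labels are invariant under swapping Path 1 and Path 2.
#'
#' @param event an event as produced by [enumerate_events()].
#' @param graph the \code{splicing_graph} it came from.
#' @return One of \code{"cassette"}, \code{"alt5"}, \code{"alt3"},
#'   \code{"mutually_exclusive"}, \code{"alt_first"}, \code{"alt_last"},
#'   \code{"intron_retention"}, \code{"complex"}.
#' @export
classify_event <- function(event, graph) {
  if (isTRUE(event$forced_complex)) return("complex")
  nodes <- graph$nodes
  s_virtual <- nodes$virtual[match(event$s, nodes$node_id)]
  t_virtual <- nodes$virtual[match(event$t, nodes$node_id)]
  minus <- identical(event$strand, "-")
  p1 <- .path_pattern(graph, event$path1)
  p2 <- .path_pattern(graph, event$path2)
  pat <- function(x) paste(x, collapse = "")
  pair <- sort(c(pat(p1), pat(p2)))

  if (s_virtual && t_virtual) return("complex")
  if (s_virtual || t_virtual) {
    terminal_ok <- function(p, at_source) {
      # path-specific terminal exon(s): alternating exon/junction runs,
      # exon-first when leaving the source, exon-last when entering the sink
      if (!length(p)) return(FALSE)
      expected <- if (at_source) rep(c("E", "J"), length.out = length(p))
                  else rep(c("J", "E"), length.out = length(p))
      if (at_source && p[length(p)] != "J") return(FALSE)
      if (!at_source && p[1L] != "J") return(FALSE)
      all(p == expected)
    }
    if (s_virtual) {
      if (terminal_ok(p1, TRUE) && terminal_ok(p2, TRUE)) {
        return(if (minus) "alt_last" else "alt_first")
      }
      return("complex")
    }
    if (terminal_ok(p1, FALSE) && terminal_ok(p2, FALSE)) {
      return(if (minus) "alt_first" else "alt_last")
    }
    return("complex")
  }

  if (identical(pair, c("E", "J"))) return("intron_retention")
  if (identical(pair, c("J", "JEJ"))) return("cassette")
  if (identical(pair, c("JEJ", "JEJ"))) return("mutually_exclusive")
  if (identical(pair, c("EJ", "J"))) {
    # extension on the upstream (left) side: the varying boundary is the
    # donor on + strand, the acceptor on - strand
    return(if (minus) "alt3" else "alt5")
  }
  if (identical(pair, c("J", "JE"))) {
    return(if (minus) "alt5" else "alt3")
  }
  "complex"
}

## footprints ------------------------------------------------------------------

.reduce_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- IRanges::reduce(IRanges::IRanges(start + 1, end))
  data.frame(start = IRanges::start(r) - 1, end = IRanges::end(r))
}

## genomic intervals of a path; junction anchors (two 1-bp intervals at donor
## and acceptor) are added for paths with no exonic content ("auto"), never,
## or always (GTF display)
path_intervals <- function(graph, edge_ids, anchors = c("auto", "always",
                                                        "never")) {
  anchors <- match.arg(anchors)
  e <- graph$edges[match(edge_ids, graph$edges$edge_id), , drop = FALSE]
  ex <- e[e$kind == "exonic", , drop = FALSE]
  jn <- e[e$kind == "junction" & e$end > e$start, , drop = FALSE]
  use_anchors <- anchors == "always" || (anchors == "auto" && nrow(ex) == 0L)
  s <- ex$start; en <- ex$end
  if (use_anchors && nrow(jn)) {
    s <- c(s, jn$start - 1, jn$end)
    en <- c(en, jn$start, jn$end + 1)
  }
  .reduce_intervals(s, en)
}

.transcriptomic_length <- function(graph, edge_ids) {
  e <- graph$edges[match(edge_ids, graph$edges$edge_id), , drop = FALSE]
  sum((e$end - e$start)[e$kind == "exonic"])
}

#' Genomic footprint of an event for cross-platform matching
#'
#' The path with the larger total transcriptomic (exonic) length is assigned
#' footprint A, the other B; ties are broken by genomic order of the leftmost
#' coordinate. Paths without exonic content are represented by 1-bp anchor
#' intervals at their junctions' donor and acceptor positions. R is the
#' reference-path footprint.
#'
#' @param event an event from [enumerate_events()].
#' @param graph its \code{splicing_graph}.
#' @return A list with \code{event_id}, \code{chrom}, \code{strand} and
#'   interval data.frames \code{A}, \code{B}, \code{R}.
#' @export
event_footprint <- function(event, graph) {
  f1 <- path_intervals(graph, event$path1)
  f2 <- path_intervals(graph, event$path2)
  l1 <- .transcriptomic_length(graph, event$path1)
  l2 <- .transcriptomic_length(graph, event$path2)
  first_is_a <- if (l1 != l2) l1 > l2 else {
    left1 <- if (nrow(f1)) min(f1$start) else Inf
    left2 <- if (nrow(f2)) min(f2$start) else Inf
    left1 <= left2
  }
  list(
    event_id = event$event_id, gene_id = event$gene_id,
    chrom = event$chrom, strand = event$strand,
    A = if (first_is_a) f1 else f2,
    B = if (first_is_a) f2 else f1,
    R = path_intervals(graph, event$ref, anchors = "never"),
    a_is_path1 = first_is_a
  )
}

## collection methods ----------------------------------------------------------

#' @export
print.splice_events <- function(x, ...) {
  cat(length(x), " splicing event(s) in gene '", attr(x, "gene_id"), "'\n",
      sep = "")
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.splice_events <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), path1 = character(0),
                      path2 = character(0), ref = character(0)))
  }
  do.call(rbind, lapply(unclass(x), function(ev) {
    data.frame(event_id = ev$event_id, gene_id = ev$gene_id,
               type = ev$type, chrom = ev$chrom, strand = ev$strand,
               path1 = paste(ev$path1, collapse = ","),
               path2 = paste(ev$path2, collapse = ","),
               ref = paste(ev$ref, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Write an event table
#'
#' TSV with event id, gene, type, location and semicolon-joined path
#' coordinates.
#' @param events a \code{splice_events} object.
#' @param graph its \code{splicing_graph}.
#' @param path output path.
#' @export
write_event_table <- function(events, graph, path) {
  ivl_str <- function(df) paste(sprintf("%d-%d", df$start, df$end),
                                collapse = ";")
  tab <- do.call(rbind, lapply(unclass(events), function(ev) {
    data.frame(
      event_id = ev$event_id, gene_id = ev$gene_id, type = ev$type,
      chrom = ev$chrom, strand = ev$strand,
      path1 = ivl_str(path_intervals(graph, ev$path1)),
      path2 = ivl_str(path_intervals(graph, ev$path2)),
      ref = ivl_str(path_intervals(graph, ev$ref, anchors = "never")),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(tab)) {
    tab <- data.frame(event_id = character(0), gene_id = character(0),
                      type = character(0), chrom = character(0),
                      strand = character(0), path1 = character(0),
                      path2 = character(0), ref = character(0))
  }
  write_eventscope_tsv(tab, path)
}

#' Export events as a GTF file for genome-browser inspection
#'
#' One transcript-like feature group per path (Path1/Path2/Ref) with exon
#' features at the path intervals (junction-only paths show their 1-bp donor
#' and acceptor anchors). Attributes carry the event id, type and path role.
#' Coordinates follow the 1-based inclusive GTF convention.
#'
#' @param events a \code{splice_events} object (may be empty).
#' @param graph its \code{splicing_graph}.
#' @param path output GTF path.
#' @export
write_event_gtf <- function(events, graph, path) {
  rows <- list()
  for (ev in unclass(events)) {
    for (role in c("Path1", "Path2", "Ref")) {
      edge_ids <- switch(role, Path1 = ev$path1, Path2 = ev$path2,
                         Ref = ev$ref)
      ivl <- path_intervals(graph, edge_ids,
                            anchors = if (role == "Ref") "never" else "always")
      if (!nrow(ivl)) next
      tx <- paste0(ev$event_id, "_", role)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ev$chrom,
        start = c(min(ivl$start), ivl$start) + 1L,
        end = c(max(ivl$end), ivl$end),
        type = c("transcript", rep("exon", nrow(ivl))),
        strand = ev$strand, gene_id = ev$gene_id, transcript_id = tx,
        event_id = ev$event_id, event_type = ev$type, path = role,
        stringsAsFactors = FALSE
      )
    }
  }
  header <- .provenance_header()
  if (!length(rows)) {
    writeLines(header, path)
    return(invisible(path))
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "eventscope", type = tab$type, gene_id = tab$gene_id,
    transcript_id = tab$transcript_id, event_id = tab$event_id,
    event_type = tab$event_type, path = tab$path
  )
  tmp <- tempfile(fileext = ".gtf")
  rtracklayer::export(gr, tmp, format = "gtf")
  writeLines(c(header, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}
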