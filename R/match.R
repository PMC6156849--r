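#' Cross-platform event matching
#'
#' Two events detected on different platforms match when their alternative
#' paths' genomic footprints are mutually compatible (one contained in the
#' other, A against A and B against B, or crossed A against B) and their
#' reference footprints overlap by at least one base. Footprints are the
#' possibly non-contiguous genomic projections of each path.
#'
#' @name event_matching
#' @keywords internal
NULL

.as_iranges <- function(x) {
  if (is.null(x) || nrow(x) == 0L) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(x$start + 1, x$end))
}

#' Is interval set x a subset of interval set y?
#'
#' TRUE iff every base covered by \code{x} is covered by the union of
#' \code{y}'s intervals. Interval sets are data.frames with \code{start},
#' \code{end} (0-based half-open) on one chromosome/strand; an empty \code{x}
#' is trivially contained.
#'
#' @param x,y interval-set data.frames.
#' @return logical.
#' @export
region_subset <- function(x, y) {
  ix <- .as_iranges(x)
  if (length(ix) == 0L) return(TRUE)
  sum(IRanges::width(IRanges::setdiff(ix, .as_iranges(y)))) == 0L
}

#' Do two interval sets overlap?
#'
#' TRUE iff some base lies in both unions.
#' @inheritParams region_subset
#' @return logical.
#' @export
regions_overlap <- function(x, y) {
  ix <- .as_iranges(x); iy <- .as_iranges(y)
  if (length(ix) == 0L || length(iy) == 0L) return(FALSE)
  sum(IRanges::width(IRanges::intersect(ix, iy))) > 0L
}

.compatible <- function(x, y) region_subset(x, y) || region_subset(y, x)

.footprint_span <- function(fp) {
  allv <- rbind(fp$A, fp$B, fp$R)
  c(min(allv$start), max(allv$end))
}

#' Match events between two platforms
#'
#' A pair matches directly when A-vs-A and B-vs-B footprints are compatible
#' and the references overlap, or in swapped form (A against B) when the
#' platforms assigned the path names in opposite length order. All matching
#' pairs are returned (many-to-many); \code{best_per_event} keeps, per event
#' of the first set, the pair with maximal reciprocal footprint overlap
#' (Jaccard index of the unions).
#'
#' @param set1,set2 lists of footprints from [event_footprint()].
#' @param best_per_event keep only the best pair per event of \code{set1}.
#' @return data.frame with \code{event_id_1}, \code{event_id_2}, \code{rule}
#'   (\code{"direct"} or \code{"swapped"}).
#' @export
match_events <- function(set1, set2, best_per_event = FALSE) {
  empty <- data.frame(event_id_1 = character(0), event_id_2 = character(0),
                      rule = character(0), stringsAsFactors = FALSE)
  if (!length(set1) || !length(set2)) return(empty)
  span2 <- lapply(set2, .footprint_span)
  rows <- list()
  for (f1 in set1) {
    sp1 <- .footprint_span(f1)
    for (j in seq_along(set2)) {
      f2 <- set2[[j]]
      if (!identical(f1$chrom, f2$chrom) ||
          !identical(f1$strand, f2$strand)) next
      if (sp1[1L] >= span2[[j]][2L] || span2[[j]][1L] >= sp1[2L]) next
      if (!regions_overlap(f1$R, f2$R)) next
      direct <- .compatible(f1$A, f2$A) && .compatible(f1$B, f2$B)
      swapped <- !direct &&
        .compatible(f1$A, f2$B) && .compatible(f1$B, f2$A)
      if (direct || swapped) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id_1 = f1$event_id, event_id_2 = f2$event_id,
          rule = if (direct) "direct" else "swapped",
          overlap = if (best_per_event) .reciprocal_overlap(f1, f2) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (best_per_event) {
    out <- out[order(out$event_id_1, -out$overlap), , drop = FALSE]
    out <- out[!duplicated(out$event_id_1), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[, c("event_id_1", "event_id_2", "rule")]
}

.reciprocal_overlap <- function(f1, f2) {
  u1 <- IRanges::reduce(c(.as_iranges(f1$A), .as_iranges(f1$B),
                          .as_iranges(f1$R)))
  u2 <- IRanges::reduce(c(.as_iranges(f2$A), .as_iranges(f2$B),
                          .as_iranges(f2$R)))
  inter <- sum(IRanges::width(IRanges::intersect(u1, u2)))
  uni <- sum(IRanges::width(IRanges::union(u1, u2)))
  if (uni == 0) 0 else inter / uni
}

#' Cross-tabulate significance classes of matched events
#'
#' @param pairs data.frame from [match_events()].
#' @param results1,results2 data.frames with \code{event_id} and
#'   \code{sig_class} per platform.
#' @return list with \code{table} (3x3 significance cross-tab over matched
#'   pairs, plus a "missing" margin when a matched event lacks a result) and
#'   \code{unmatched1}/\code{unmatched2} counts.
#' @export
crosstab_significance <- function(pairs, results1, results2) {
  classes <- c("significant", "inconclusive", "non_significant")
  cls <- function(results, ids) {
    v <- results$sig_class[match(ids, results$event_id)]
    if (anyNA(v)) {
      warning(sum(is.na(v)), " matched event(s) without a test result")
    }
    factor(ifelse(is.na(v), "missing", v), levels = c(classes, "missing"))
  }
  tab <- table(
    platform1 = cls(results1, pairs$event_id_1),
    platform2 = cls(results2, pairs$event_id_2)
  )
  list(
    table = tab,
    unmatched1 = sum(!results1$event_id %in% pairs$event_id_1),
    unmatched2 = sum(!results2$event_id %in% pairs$event_id_2)
  )
}
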