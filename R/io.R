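#' Read a GTF transcript annotation into per-gene records
#'
#' Uses rtracklayer to parse the GTF and regroups exon features by gene.
#' Coordinates are converted to the package's internal 0-based half-open
#' convention.
#'
#' @param path path to a GTF file.
#' @return Named list of gene records, each a list with \code{gene_id},
#'   \code{chrom}, \code{strand} and an \code{exons} data.frame
#'   (\code{transcript_id}, \code{start}, \code{end}).
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in '", path, "'")
  df <- data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  lapply(split(df, df$gene_id), function(g) {
    list(gene_id = g$gene_id[1L], chrom = g$chrom[1L], strand = g$strand[1L],
         exons = g[, c("transcript_id", "start", "end")])
  })
}

## Provenance-stamped TSV dialect ---------------------------------------------

.provenance_header <- function(seed = NULL, params = NULL) {
  lines <- c(
    paste0("# eventscope ", as.character(utils::packageVersion("eventscope"))),
    paste0("# written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )
  if (!is.null(seed)) lines <- c(lines, paste0("# seed: ", seed))
  if (!is.null(params) && length(params)) {
    lines <- c(lines, paste0("# params: ",
                             paste(names(params), unlist(params),
                                   sep = "=", collapse = " ")))
  }
  lines
}

#' Write a table in the package TSV dialect
#'
#' Tab-separated values with a commented provenance header (tool version,
#' optional seed and parameters).
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param seed,params optional provenance fields recorded in the header.
#' @export
write_eventscope_tsv <- function(x, path, seed = NULL, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.provenance_header(seed, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_eventscope_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_eventscope_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a junction (or coverage-bin) count table
#'
#' Expected columns: \code{chrom}, \code{start}, \code{end}, \code{strand},
#' then one count column per sample.
#' @param path input TSV path.
#' @return data.frame.
#' @export
read_junction_table <- function(path) {
  x <- read_eventscope_tsv(path)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(x))) {
    stop("junction table must have columns ", paste(need, collapse = ", "))
  }
  x
}

#' Read library sizes (sample -> total mapped reads)
#' @param path TSV with columns \code{sample}, \code{library_size}.
#' @return named numeric vector.
#' @export
read_library_sizes <- function(path) {
  x <- read_eventscope_tsv(path)
  stopifnot(all(c("sample", "library_size") %in% names(x)))
  stats::setNames(as.numeric(x$library_size), x$sample)
}
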