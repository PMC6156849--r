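# Fixture genes built in code (0-based half-open coordinates).

fig1_gene <- function(strand = "+") {
  # exons 6, 7, 8; isoform A includes exon 7, isoform B skips it
  list(gene_id = "fig1", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "A", "B", "B"),
         start = c(100, 300, 500, 100, 500),
         end = c(200, 400, 600, 200, 600)))
}

retained_intron_gene <- function(strand = "+") {
  list(gene_id = "ri", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "B"),
         start = c(0, 200, 0),
         end = c(100, 300, 300)))
}

alt_donor_gene <- function(strand = "+") {
  # isoform B extends the first exon's right boundary
  list(gene_id = "ad", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "B", "B"),
         start = c(0, 200, 0, 200),
         end = c(100, 300, 150, 300)))
}

alt_acceptor_gene <- function(strand = "+") {
  # isoform B extends the second exon's left boundary
  list(gene_id = "aa", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "B", "B"),
         start = c(0, 200, 0, 150),
         end = c(100, 300, 100, 300)))
}

mxe_gene <- function(strand = "+") {
  list(gene_id = "mxe", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "A", "B", "B", "B"),
         start = c(0, 200, 600, 0, 400, 600),
         end = c(100, 300, 700, 100, 500, 700)))
}

alt_first_gene <- function(strand = "+") {
  list(gene_id = "af", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "B", "B"),
         start = c(0, 400, 200, 400),
         end = c(100, 500, 300, 500)))
}

alt_last_gene <- function(strand = "+") {
  list(gene_id = "al", chrom = "chr1", strand = strand,
       exons = data.frame(
         transcript_id = c("A", "A", "B", "B"),
         start = c(0, 200, 0, 400),
         end = c(100, 300, 100, 500)))
}

graph_of <- function(gene) build_graph_from_gtf(gene)

event_list <- function(events) unclass(events)
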