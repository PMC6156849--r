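test_that("the cassette gene yields exactly the expected event", {
  g <- graph_of(fig1_gene())
  ev <- enumerate_events(g)
  expect_length(ev, 1L)
  e <- event_list(ev)[[1]]
  expect_equal(e$type, "cassette")
  edge_str <- function(ids) {
    x <- g$edges[match(ids, g$edges$edge_id), ]
    sort(paste(x$kind, x$start, x$end))
  }
  # inclusion path: junction in, cassette exon, junction out
  expect_setequal(edge_str(e$path1),
                  c("junction 200 300", "exonic 300 400", "junction 400 500"))
  expect_setequal(edge_str(e$path2), "junction 200 500")
  # reference: the two flanking exons
  expect_setequal(edge_str(e$ref), c("exonic 100 200", "exonic 500 600"))
  # mutual exclusivity in terms of isoforms
  expect_length(intersect(e$isoforms1, e$isoforms2), 0L)
  expect_length(intersect(e$path1, e$path2), 0L)
})

test_that("single-isoform genes yield no events", {
  g <- build_splicing_graph(data.frame(
    transcript_id = "t", start = c(0, 200, 400), end = c(100, 300, 500)))
  expect_length(enumerate_events(g), 0L)
})

test_that("event types are classified by structure, strand-aware", {
  type_of <- function(gene) {
    ev <- enumerate_events(graph_of(gene))
    expect_length(ev, 1L)
    event_list(ev)[[1]]$type
  }
  expect_equal(type_of(retained_intron_gene()), "intron_retention")
  expect_equal(type_of(mxe_gene()), "mutually_exclusive")
  expect_equal(type_of(alt_donor_gene()), "alt5")
  expect_equal(type_of(alt_donor_gene(strand = "-")), "alt3")
  expect_equal(type_of(alt_acceptor_gene()), "alt3")
  expect_equal(type_of(alt_acceptor_gene(strand = "-")), "alt5")
  expect_equal(type_of(alt_first_gene()), "alt_first")
  expect_equal(type_of(alt_first_gene(strand = "-")), "alt_last")
  expect_equal(type_of(alt_last_gene()), "alt_last")
  expect_equal(type_of(alt_last_gene(strand = "-")), "alt_first")
})

test_that("classification is invariant under swapping the two paths", {
  genes <- list(fig1_gene(), retained_intron_gene(), alt_donor_gene(),
                mxe_gene(), alt_first_gene(), alt_last_gene())
  for (gene in genes) {
    g <- graph_of(gene)
    e <- event_list(enumerate_events(g))[[1]]
    swapped <- e
    swapped$path1 <- e$path2
    swapped$path2 <- e$path1
    expect_equal(classify_event(swapped, g), classify_event(e, g))
  }
})

test_that("enumeration matches the exhaustive bipartition oracle on random genes", {
  set.seed(303)
  n_complex <- 0L
  for (rep in 1:60) {
    gene <- random_gene_annotation()
    g <- graph_of(gene)
    got <- enumerate_events(g)
    want <- enumerate_events_oracle(g)
    expect_setequal(event_pair_keys(event_list(got)), event_pair_keys(want))
    # invariants on every emitted event
    for (e in event_list(got)) {
      expect_length(intersect(e$path1, e$path2), 0L)
      expect_length(intersect(e$isoforms1, e$isoforms2), 0L)
      # every traversing isoform contains every reference edge
      for (iso in c(e$isoforms1, e$isoforms2)) {
        expect_true(all(e$ref %in% g$isoform_edges[[iso]]))
      }
      if (e$type == "complex") n_complex <- n_complex + 1L
    }
    # deduplication: no two events share the same unordered path pair
    keys <- event_pair_keys(event_list(got))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("footprint A is the longer path, B the shorter, with tie-break", {
  g <- graph_of(fig1_gene())
  e <- event_list(enumerate_events(g))[[1]]
  fp <- event_footprint(e, g)
  # A = the cassette exon; B = 1-bp anchors of the skipping junction
  expect_equal(fp$A, data.frame(start = 300, end = 400))
  expect_equal(fp$B, data.frame(start = c(199, 500), end = c(200, 501)))
  expect_equal(fp$R, data.frame(start = c(100, 500), end = c(200, 600)))
  # all intervals within the gene span
  allv <- rbind(fp$A, fp$B, fp$R)
  expect_true(all(allv$start >= 99 & allv$end <= 601))

  # tie: both paths pure junctions (equal transcriptomic length 0);
  # A must start leftmost
  g2 <- graph_of(mxe_gene())
  e2 <- event_list(enumerate_events(g2))[[1]]
  fp2 <- event_footprint(e2, g2)
  expect_true(sum(fp2$A$end - fp2$A$start) >= sum(fp2$B$end - fp2$B$start))
})

test_that("event tables and GTF export round-trip the path intervals", {
  g <- graph_of(fig1_gene())
  ev <- enumerate_events(g)
  tsv <- tempfile(fileext = ".tsv")
  write_event_table(ev, g, tsv)
  tab <- read_eventscope_tsv(tsv)
  expect_equal(tab$type, "cassette")
  expect_equal(tab$path1, "300-400")       # exon of the inclusion path
  expect_equal(tab$path2, "199-200;500-501")  # skipping-junction anchors
  gtf <- tempfile(fileext = ".gtf")
  write_event_gtf(ev, g, gtf)
  gr <- rtracklayer::import(gtf, format = "gtf")
  p1 <- gr[gr$path == "Path1" & gr$type == "exon"]
  # anchor convention: flank anchor, cassette exon, flank anchor
  expect_equal(length(p1), 3L)
  expect_equal(GenomicRanges::start(p1), c(200, 301, 501))
  expect_equal(GenomicRanges::end(p1), c(200, 400, 501))
  # empty event set still writes a valid commented file
  empty <- structure(list(), class = "splice_events", gene_id = "none")
  f2 <- tempfile(fileext = ".gtf")
  write_event_gtf(empty, g, f2)
  expect_true(all(grepl("^#", readLines(f2))))
})
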