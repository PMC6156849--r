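# eventscope

Cross-platform detection, quantification and differential analysis of
alternative splicing events.

## The problem

Alternative splicing is routinely profiled with RNA-seq and, historically,
with exon-junction microarrays. Comparing the two — or simply analyzing
either — benefits from an *event-based* view: instead of reconstructing whole
transcripts, one tests local alternatives directly. eventscope implements
that view end to end for both platforms:

1. **Splicing graphs.** Each gene becomes a DAG whose nodes are exon
   start/end boundaries and whose edges are exonic segments or splice
   junctions, built either from a GTF annotation or from observed junction
   and coverage tables.
2. **Events.** Minimal "bubbles" in the graph: two mutually exclusive edge
   paths (Path 1, Path 2) between a divergence and its earliest
   reconvergence, plus a shared reference path. Events are classified as
   cassette exon, alternative 5'/3' splice site, mutually exclusive exons,
   alternative first/last exon, intron retention, or complex.
3. **Ψ (percent spliced in).** The signal of each path is modeled as
   affinity × concentration, S_i = a_i·t_i, with t_R = t_1 + t_2 for the
   reference, so S_R = u·S_1 + v·S_2 with u = a_R/a_1, v = a_R/a_2. u and v
   are estimated by penalized non-negative least squares

       min ‖Ax − b‖₂  s.t. x ≥ 0,
       A = [S1 S2; λ −λ; λ 0; 0 λ],  b = [SR; 0; λ; λ]

   and Ψ_j = u·S1_j / (u·S1_j + v·S2_j) per sample. The relative residual
   ε = ‖u·S1 + v·S2 − SR‖₂ / ‖SR‖₂ flags events whose measurements are not
   coherent with the additive model.
4. **Statistics.** Counts go through voom; arrays enter as log2 signal. Each
   path is tested with a moderated linear-model contrast (limma); an event
   is *significant* when the two paths change in opposite directions with
   summarized p < 0.001, *non-significant* when the summarized p > 0.2, and
   *inconclusive* in between. π0 and q-values come from Storey's estimator;
   binomial thinning emulates shallower sequencing.
5. **Matching.** Events from two platforms match when their path footprints
   are mutually containing (directly, or with A/B names swapped) and their
   reference regions overlap; matched significance classes are
   cross-tabulated.

A seed-deterministic synthetic-data generator (annotation, junction counts,
path signals on two platforms with shared truth) makes the whole pipeline
testable without downloads.

## Worked example

A two-isoform gene where isoform `skp` skips the middle exon:

```r
library(eventscope)

exons <- data.frame(
  transcript_id = c("inc", "inc", "inc", "skp", "skp"),
  start = c(100, 300, 500, 100, 500),
  end   = c(200, 400, 600, 200, 600))
graph <- build_splicing_graph(exons, gene_id = "GENE1")
graph
#> Splicing graph for gene 'GENE1' (chr1+)
#>   8 nodes (incl. virtual source/sink); 3 exonic, 3 junction, 2 artificial edges
#>   2 annotated isoform(s)

enumerate_events(graph)
#> 1 splicing event(s) in gene 'GENE1'
#>   event_id gene_id     type chrom strand path1 path2 ref
#> 1  GENE1_1   GENE1 cassette  chr1      + 3,5,6     4 2,7
```

One cassette event: Path 1 is the inclusion route (junction, middle exon,
junction; edges 3, 5, 6), Path 2 the skipping junction (edge 4), and the
reference the two flanking exons (edges 2, 7).

Ψ estimation from path signals (here: inclusion drops between conditions):

```r
fit <- estimate_psi(S1 = c(30, 32, 9, 11), S2 = c(10, 11, 31, 29),
                    SR = c(41, 40, 42, 39),
                    condition = factor(c("ctl", "ctl", "trt", "trt")))
fit
#> PSI fit: 4 sample(s)
#>   u = 0.9542, v = 1.0324, lambda = 4.052, epsilon = 0.04243
#>   psi: 0.735 0.729 0.212 0.260
#>   delta_psi = -0.496
```

u and v land near 1 (comparable affinities), ε is small (the additive model
fits), Ψ falls from ~0.73 to ~0.24, and ΔΨ ≈ −0.50.

The full statistical pipeline on a synthetic cohort (500 events, two
conditions × 5 replicates, 30% differential with ΔΨ ≥ 0.3):

```r
co <- simulate_cohort(n_events = 500, seed = 1)
res <- test_splicing_events(co$counts$path1, co$counts$path2,
                            co$design, co$contrast, platform = "rnaseq",
                            library_sizes = co$library_sizes,
                            condition = co$condition)
head(as.data.frame(res)[, c("event_id", "logfc1", "logfc2", "p_summary",
                            "sig_class", "delta_psi")], 3)
#>   event_id logfc1 logfc2 p_summary   sig_class delta_psi
#> 1      ev1  1.743  -1.61  7.42e-11 significant     0.519
#> 2      ev2  1.683  -1.61  1.34e-10 significant     0.518
#> 3      ev3  0.937  -1.15  8.93e-04 significant     0.333

detection_rates(res, co$truth)
#> $power
#> [1] 0.96
#> $fpr
#> [1] 0
```

The opposite-sign fold changes on the two paths, the summarized p-value and
the recovered ΔΨ are shown per event; on this cohort 96% of the true
differential events are detected with no false positives at the
p < 0.001 rule.

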