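---
title: "Detecting and quantifying alternative splicing events with eventscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying alternative splicing events with eventscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventscope)
```

## Overview

eventscope detects local alternative-splicing events in per-gene splicing
graphs, estimates the percent spliced in (PSI) of each event per sample, tests
for differential splicing between conditions, and matches events detected on
two measurement platforms (for instance RNA-seq and exon-junction
microarrays). The same statistical machinery applies to both platforms; only
the way measurements enter differs (read counts versus linear-scale probe-set
signal).

## The splicing graph

Each gene is represented as a directed acyclic graph. Every (sub)exonic
segment is split into two boundary nodes, one at its start and one at its end
position, joined by an *exonic* edge. Splice junctions are edges from the end
node of one segment to the start node of a downstream segment. A virtual
source and sink flank the first and last boundary of every transcript, so
each annotated isoform is a single source-to-sink path. Overlapping exons
from different isoforms are decomposed into disjoint subexonic segments at
every distinct boundary, which makes the segments a partition of the exonic
sequence: alternative donor/acceptor structures appear as extra boundary
pairs rather than as overlapping intervals. Two segments of one exon that
abut are joined by a zero-length junction edge; classification distinguishes
these from real splice junctions by their genomic gap.

Graphs come from two sources. Annotation mode parses a GTF and retains the
isoform-to-edge map. Data mode builds the graph from observed junction and
coverage tables: junctions are kept when they reach at least 2 FPKM in one
sample (configurable), and contiguous coverage above 0.5 FPKM, cut at every
junction boundary, yields the exonic edges. Data-driven graphs carry no
isoform map; event enumeration then enumerates source-to-sink paths instead
(capped, with a warning, for safety on pathological graphs).

Coordinates are 0-based half-open internally; GTF input/output converts to
1-based inclusive. Graphs are laid out in genomic order regardless of strand;
strand enters only where biology requires it (deciding which side of a
variable boundary is the 5' splice site, and whether a source-side event is
an alternative *first* or *last* exon).

FPKM for a junction uses an effective length of
`read_length - 2 * min_anchor + 1` (99 bp at the 100-bp read length and 1-bp
anchor defaults): a junction is only observable from reads that span it.
This convention is exposed as configuration because junction-FPKM
conventions differ between tools.

## Events

An event is a pair of mutually exclusive edge paths (Path 1, Path 2) between
a divergence node s and its earliest reconvergence node t, plus a shared
reference path. Enumeration scans every traversed node pair; the subpaths
between s and t are grouped into *bundles* by transitive edge sharing, and a
pair with at least two edge-disjoint bundles and no interior node common to
all traversing isoforms (the minimal-bubble condition) yields one event.
Isoform mutual exclusivity then holds by construction. The reference path is
the nearest exonic edge on each side of the bubble shared by all traversing
isoforms; when flanking exons are themselves decomposed into segments this
nearest-shared rule picks the closest common segment.

When more than two bundles diverge at one node, the event is kept binary:
Path 1 is the largest bundle, Path 2 the union of the rest, and the event is
labeled complex. This is a design choice: the downstream statistics are
defined for two paths, and emitting one event per bundle pair would multiply
correlated tests. The classification is purely structural and invariant
under swapping the two paths: cassette (junction-exon-junction against a
skipping junction), intron retention (exonic span against a junction over
the same interval), alternative 5'/3' splice site (two junctions sharing one
boundary, strand-aware), mutually exclusive exons, alternative first/last
exon (divergence at the virtual source or convergence at the sink), and
complex for everything else.

## PSI estimation

The measured signal of a path is modeled as the product of an affinity (probe
affinity, or effective length for sequencing coverage) and the concentration
of the isoforms mapped to the path, S_i = a_i t_i. The reference path carries
all isoforms of the event, so t_R = t_1 + t_2 and

    S_R = u S_1 + v S_2,   u = a_R / a_1,   v = a_R / a_2.

u and v must be non-negative, and with comparable affinities they should be
similar and close to one. They are estimated by non-negative least squares
over the stacked per-sample rows with three penalty rows encoding exactly
those expectations:

    A = [ S1  S2 ]        b = [ SR ]
        [  l  -l ]            [  0 ]
        [  l   0 ]            [  l ]
        [  0   l ]            [  l ]

The problem is a strictly convex two-variable quadratic for penalty l > 0,
so the solver is exact: the unconstrained minimizer if it is feasible,
otherwise the best single-coordinate boundary solution. PSI then follows
without knowing the affinities themselves:

    PSI_j = u S1_j / (u S1_j + v S2_j),

`NA` where the denominator is zero. Signals enter on the linear scale
(FPKM or linearized array signal): the model is additive in concentrations,
so log-scale input would be wrong.

The penalty weight defaults to 0.1 times the root-mean-square reference
signal, making the penalty rows commensurate with the signal rows at any
overall expression level; PSI is then invariant under a common rescaling of
the three signals. When there is differential splicing the estimates are
insensitive to the choice; when PSI is constant across samples, u and v are
only weakly identified and the estimate depends more on the penalty — both
behaviors are asserted in the test suite. The relative residual error

    epsilon = ||u S1 + v S2 - SR||_2 / ||SR||_2

diagnoses events whose measurements are not internally coherent with the
additive model (for example bad-performing probe sets); events in the worse
epsilon half of a noisy simulation recover PSI measurably worse than the
better half. With all-zero signals the penalty rows dominate, u = v = 1 is
returned and the event is flagged degenerate; a zero reference signal makes
epsilon undefined (`NA` with a warning).

## Differential splicing

Sequencing counts are transformed with voom: log2 counts per million with
observation-level precision weights from the fitted mean-variance trend
(through limma). With fewer than 50 rows the trend is unstable, so the
transform falls back to unit weights with a warning. Array signals enter as
log2 values with unit weights. Each alternative path is fitted row-wise with
a weighted linear model (cell line and treatment as additive factors in the
motivating design, any full-rank design in general), the contrast of
interest is extracted, and residual variances are shrunk empirically
(limma's squeezeVar) to give moderated t statistics. Only the two
alternative paths are modeled; the reference path serves PSI estimation and
filtering, not the test.

An event is called significant when its two paths change in opposite
directions and the summarized p-value is below 0.001; non-significant when
the summarized p-value exceeds 0.2; inconclusive in between. The summarized
p-value defaults to the larger of the two per-path p-values — an
intersection-union reading under which both paths must move — with Fisher
and Irwin-Hall combiners available as configuration. Note that the maximum
of two null p-values is stochastically larger than uniform, so the Storey
pi0 estimate computed on summarized p-values is conservative (it
overestimates the null fraction); pi0 recovery is calibrated on per-test
p-values. The null proportion is estimated at the single evaluation point
p > 0.5, and q-values follow by step-up monotonization. Binomial thinning of
counts (with rescaled library sizes) reproduces shallower sequencing for
depth analyses.

## The synthetic cohort

The generator produces the study conditions the package is validated under:
two conditions with five replicates each; 500 events of which 30% are
differential with a true PSI shift of at least 0.3; true affinity fractions
u*, v* drawn uniformly from [0.7, 1.4]; reference concentrations log-normal
on the FPKM scale (median 50 FPKM, log-sd 0.7), reflecting well-expressed
events that pass the 2-FPKM junction filter with a realistic spread; library
size 2e7 reads (scaled-down bulk RNA-seq); Poisson counts by default with a
negative-binomial option; and 10% multiplicative log-normal noise on array
signals. Under these conditions the pipeline recovers at least 80% of true
differential events at the 0.001 rule with a false-positive rate at most
0.01, and detection power increases strictly across thinning fractions
0.1, 0.3, 1.0.

The generator emulates the features the estimators rely on — additive path
signals, affinity differences between paths, count noise at a given depth,
shared truth observed by two platforms with platform-specific affinities —
and deliberately not others: no read-level simulation (counts are drawn
directly), no positional coverage bias, no cross-hybridizing probes, no
correlated noise between paths, and isoform structures are modest (up to six
exons and four isoforms in the randomized tests, where enumeration is
checked against an exhaustive bipartition oracle). Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artifact of real libraries or arrays.

## Numerical choices and degenerate inputs

* Quantile for the array filter: type 7 (linear interpolation), exposed in
  `filter_config()`; the junction rule is applied as "at least" and the
  array rule as "strictly greater", following their respective wordings.
* Ties when assigning footprint A (equal transcriptomic path lengths) break
  by genomic order of the leftmost coordinate.
* Junction-only paths are represented for matching by two 1-bp anchor
  intervals at donor and acceptor, making containment well-defined for
  paths with no exonic content; paths with exonic content use only their
  exonic projection. GTF export always shows the anchors.
* Containment is evaluated on genomic projections on the same strand, not by
  sequence substring search; the two coincide except for pathological
  repeats.
* Events whose junctions fail the expression filter, or whose reference
  signal is zero, are excluded or flagged rather than silently estimated.
* Many-to-many matches are retained by default; `best_per_event` keeps the
  pair with maximal reciprocal footprint overlap.

## Problem sizes

The randomized validation uses 200 random genes for the enumeration oracle,
100 random instances for the NNLS grid oracle (grid step 1e-3 on [0, 5]^2,
evaluated exactly via the convexity of the objective), 50 random
two-platform sets for the matching oracle, a 2000-event null cohort for the
type-I error, and the 500-event cohort above for power; these sizes give
stable estimates while keeping the whole validation suite comfortably fast
on a laptop.

## Known limitations

* Data-driven graphs cannot recover boundaries that leave no junction or
  coverage trace (for example a transcript terminus inside another
  isoform's exon).
* The summarized p-value combiner is a documented choice, not a unique
  definition; results near the significance boundary can shift between
  combiners.
* No multi-way (more than two path) event statistics and no nested event
  decomposition; complex events are tested as binary largest-versus-rest.
* No bootstrap confidence intervals on PSI; no liftover between genome
  builds for matching (both platforms must share coordinates).
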