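---
title: "Copy-number aberration cladograms: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number aberration cladograms: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghclade)
```

## The analysis chain

`cghclade` takes per-sample segmented copy-number intervals (chromosome,
start, end, linear tumor/reference fold change), a gene annotation and a
clinical metadata table, and produces (i) gene-level aberration calls and
cohort frequency tables, (ii) a binary sample-by-aberration "polarity"
matrix, (iii) a rooted maximum-parsimony cladogram of the samples with
clade-level clinical summaries, and (iv) cohort summary statistics with
the classical group tests. This vignette records the model, the
conventions, and the design decisions that were genuinely open.

## Thresholds and coordinates

An interval is a **gain** iff its fold change is strictly above 1.2 and a
**loss** iff strictly below 0.8; values at the thresholds are discarded.
The inequalities are strict because the filter is defined by events lying
*above* and *below* the thresholds; with strictness, 1.2 and 0.8
themselves are non-events, which only matters for exactly-valued input
but must be fixed one way. A `log2_input` flag converts log2 ratios via
$2^x$ before classification.

All coordinates are zero-based half-open internally (BED-native), with
the two readers converting at the boundary; one-based inclusive input
(`read_interval_report(..., convention = "one_based_inclusive")`) is
shifted by one at the start. A single convention internally means a
single overlap arithmetic: intervals overlap a gene iff the intersection
length is at least `min_overlap_bp` (default 1 bp, i.e. any overlap —
whether the original pipeline required whole-gene containment is
unknowable, so the weaker and more common convention was chosen and is
configurable). Abutting half-open intervals have zero overlap. Strand is
ignored throughout: copy-number events are strandless. Chromosome labels
are normalized by stripping any `chr` prefix; only 1–22, X, Y are
accepted, since the analysis domain is the 24 nuclear chromosomes.
Genome build is treated as opaque metadata — the package never looks
coordinates up against a reference.

## Display conventions: truncation, not rounding

The cohort reporting style this package mirrors truncates fractional
digits instead of rounding: 764/30 = 25.466 prints as 25.46, 358/15 =
23.866 as 23.8, and a gene deleted in 16/30 samples prints "(53)" though
16/30 = 53.33 and 20/30 = 66.67 prints "(66)". Rounding would contradict
several of these printed values (47, 67), truncation reproduces all of
them; `trunc_dec()` and `percent_floor()` implement it, and exact values
are always retained alongside in machine-readable output. Clade
percentages likewise use floor: 14/22 right-sided reports 63%, 7/8
reports 87%.

Quantiles use the weighted-average-at-$(n+1)p$ convention
(`stats::quantile` type 6): it is the convention that reproduces the
reference cohort's published age quartiles (e.g. 51.5 and 66.7 for ages
{51, 69, 53, 60} after one-decimal truncation), where the common type-7
default would give 52.5. One published quartile (71 for the stable group,
computed 71.5) cannot be matched by any standard convention and is
treated as a printing discrepancy, documented here and not chased.

## The polarity matrix

Aberration identity is exact equality of (chromosome, start, end,
direction): pooling all samples' aberrations and "removing duplicates"
only has a well-defined meaning under exact matching, and gains and
losses at the same locus are kept as distinct characters (the
alternative — one character per locus — would conflate biologically
opposite events). Because real segmentations rarely agree to the base, a
merge tolerance is available (`build_union(..., merge_tolerance_bp)`),
implemented as single-linkage along the start-sorted order with merged
keys taking the union span; it is off by default and the generator's
`jitter_bp` option exists to stress-test it. All-zero rows
(aberration-free samples) are retained so every cohort sample appears as
a leaf. Matrices serialize to a relaxed PHYLIP discrete format (name,
whitespace, 0/1 string; strict 10-character names on request) plus a TSV
with full key headers.

## Maximum parsimony

**Character model.** Characters are unordered binary with free
reversibility — Wagner parsimony, scored with the Fitch bottom-up set
algorithm. The phrase "polarity" in this literature could also suggest
Camin–Sokal (irreversible) parsimony, where the derived state 1 can only
be gained; both readings are implemented, Wagner is the default, and
`mode = "camin_sokal"` switches to counting minimal 0→1 origins from an
all-zero root.

**Scoring.** Columns are compressed to unique patterns with multiplicity
weights. For the unrooted sample tree, binary columns with 0, 1, $n-1$ or
$n$ carriers are parsimony-uninformative and contribute a closed-form
constant (0, 1, 1, 0 respectively); when the all-zero ancestor is on the
tree (root placement, Camin–Sokal), columns with $n-1$ carriers become
informative and all-one columns cost exactly 1. The reported score always
refers to the full matrix and equals `fitch_score()` on the returned
topology.

**Search.** The heuristic is stepwise addition under random taxon
addition orders (10 by default), each followed by
nearest-neighbor-interchange hill-climbing; the climb may take a bounded
number of sideways (equal-score) steps across plateaus, with visited
topologies tracked so it cannot cycle. The best tree over all orders is
kept; among equally parsimonious candidates the lexicographically
smallest canonical Newick string (children sorted recursively) wins, so
results are deterministic given the seed. An exact branch-and-bound
search (`exhaustive_search()`) is provided for cohorts of at most 9
samples: depth-first stepwise insertion with partial-score pruning
(subtree score is monotone under taxon addition), seeded with a greedy
upper bound, returning the global optimum and *all* optimal topologies in
canonical order. It is both a user-facing tool for small cohorts and the
oracle against which the heuristic is tested.

**Rooting.** Cladograms are rooted on a hypothetical aberration-free
(all-zero) ancestor — consistent with treating presence as the derived
state — placed on the edge where attaching it costs fewest extra
changes. Rooting affects display and clade summaries only, never the
Wagner score. No branch lengths are estimated: the result is a cladogram.

**Degenerate inputs.** A matrix with no parsimony-informative characters
makes every topology equally parsimonious; the search warns and returns a
caterpillar topology (score equal to the uninformative constant, 0 for an
empty matrix). Duplicate rows are zero-distance taxa and end up as
sisters whenever the remaining signal resolves their neighborhood.

**Clade reports.** `summarize_clades()` reports clinical composition for
internal nodes down to a configurable depth (default 2) below the root,
using ape's stable node numbering. The MSI-H co-clustering rule had to be
fixed by decision: `msi_h_clustering_report()` scans every clade
(including single leaves), requires a clade's MSI-H *density* to strictly
exceed the cohort baseline (which excludes the trivial whole-cohort
clade but deliberately does not require an MSI-H majority), and among
qualifying clades flags the one containing most MSI-H samples, ties going
to the smallest clade. Under this rule a cohort whose MSI-H samples are
scattered as singletons reports 1/k, and a planted pure subgroup reports
k/k.

## Statistical tests

Numeric outcome vs 2 groups: two-sample Student t-test with equal
variances (the named test in this literature; Welch by flag). More than
2 groups: one-way ANOVA. Categorical vs categorical: Pearson chi-square
without continuity correction. p-values are kept at full precision, with
a one-decimal truncated display; no multiple-testing correction is
applied, matching the reporting style mirrored here. Zero within-group
variance is flagged as degenerate (p = 1 when means also coincide, rather
than an error, so property tests on constant data are well-defined).

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, with defaults
fixed once to the study conditions of the reference cohort: 30 samples,
5/30 MSI-H and 4/30 MSI-L; per-sample background aberration counts
Poisson with mean 27 for non-MSI-H (CIN) and 10 for MSI-H tumors (MSI-H
tumors carry fewer aberrations; the clustered MSI-H tumors in the
reference cohort carried fewer than 15); 5 signature aberrations shared
by every MSI-H sample and no other (the first a loss spanning an
annotated gene, so gene-level recovery is testable); a catalog of 40
recurrent regions confined to chromosomes 3/5/7/8/20/X from which each
background aberration is drawn with probability 0.5 (uniform background
otherwise); an X-chromosome gain planted with probability 10/15 in males
and 4/15 in females; gain folds uniform on (1.3, 3.0) and loss folds on
(0.3, 0.7), so every planted event survives the 1.2/0.8 filter by
construction. Where the emulated study pins no value, choices were made
once as field-realistic and documented here: interval lengths are
log-uniform between 50 kb and 5 Mb (no per-aberration size distribution
is published), and intervals live on a miniature genome of 24
chromosomes × 10 Mb to keep fixtures desk-scale (coordinates are
self-consistent; nothing depends on real chromosome lengths). A single
global seed drives one generator stream; identical configs are
byte-identical.

What the generator does *not* emulate: probe-level noise and
segmentation artifacts, partially overlapping segment boundaries across
samples (unless `jitter_bp` is enabled), allele-specific copy number,
and any correlation between clinical covariates and aberration content
beyond the MSI-H structure. Passing recovery tests on this generator
therefore demonstrates the correctness of the pipeline's logic — exact
key deduplication, matrix construction, search behavior under a planted
signal — not performance on real arrays, where aberration identity
across samples is itself uncertain.

## Problem sizes used in tests

The test suite verifies Fitch scoring against two independent oracles
(exhaustive internal-state assignment on all 15 five-taxon topologies,
and `phangorn::parsimony`), compares the heuristic against the exact
branch-and-bound optimum on 100 random 8-taxon × 20-character matrices
(at least 95 must match, and the heuristic may never undercut the exact
score), and checks planted-clade recovery on twenty 30-sample cohorts
(the MSI-H subgroup must come out monophyletic in at least 18). These
sizes keep the full suite around a couple of minutes of compute while
leaving each property enough replicates to be meaningful.

## Known limitations

- Exact-key aberration identity is brittle on real segmentations; the
  tolerance merge is single-linkage and can chain distinct events if the
  tolerance is set large.
- NNI-based hill-climbing with 10 addition orders is adequate at cohort
  scale (tens of samples) but offers no optimality guarantee; the exact
  search is capped at 9 taxa.
- The Camin–Sokal mode is provided for completeness and is less
  exercised by tests than the Wagner default.
- Association tests assume independent samples and use the classical
  parametric forms; with 4–5 samples per MSI subgroup their power is
  nominal, which is precisely why the reference comparisons are reported
  as non-significant.
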