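---
title: "Methods: repeat-driven genome compartmentalization and repeat-gene-methylation associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-driven genome compartmentalization and repeat-gene-methylation associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

# The problem

Plant genomes are dominated by repetitive DNA — LTR retrotransposons (Gypsy,
Copia), DNA transposons (autonomous and non-autonomous), LINEs, SINEs, simple
sequence repeats, endogenous viral elements and unclassified repeats. In a
fleshy-fruit species such as tomato, repeats are not inert filler: they carry
most of the cytosine methylation, they sit next to genes, and regions that
lose methylation during ripening (differentially methylated regions, DMRs)
overlap them preferentially. `repeatscape` implements, as reusable and tested
R functions, the chain of analyses needed to characterize this organisation:

1. a strict k-mer repeat layer merged with de novo annotation layers;
2. partitioning of the genome into repeat-rich (RR), intermediate (INT) and
   repeat-poor (RP) compartments from windowed coverage;
3. TE-gene filtering and gene/repeat/DMR/RIN-peak association mining;
4. enrichment statistics with the expected-count and contingency models,
   chi-square tests, Bonferroni correction, rank tests and Monte-Carlo
   placement nulls;
5. a seeded synthetic annotated-genome generator so that every stage is
   testable without any external download.

# Coordinates and distances

All internal coordinates are 0-based half-open `[start, end)`; GFF3 (1-based
inclusive) and BED are converted only at the I/O boundary. The distance
between two features is the number of bases strictly between their spans:
abutting features are at distance 0 and are distinct from overlapping
features, which carry an explicit overlap flag instead of a sentinel
distance. "Within 1 kb" is strict (`< 1000`). "Upstream" of a gene means the
5' side read from the gene's strand (genes without strand are treated as
`+`); this is the standard reading where the source analyses said only
"upstream", and the genomic-left alternative is obtained by setting the
strand column to `+` throughout.

# Repeat annotation layers

`find_kmer_repeats()` counts every k-mer (default k = 16) exactly across the
whole sequence set, keeps positions of k-mers occurring at least 10 times
genome-wide, merges them into maximal intervals, and drops fragments shorter
than 30 bp. Counting is forward-strand by default; a `canonical` flag pools
each k-mer with its reverse complement (whether the original strict-mapping
run collapsed strands is not documented, so both modes exist and forward is
the default). Ambiguous bases never match. The implementation is a rolling
base-4 encoding with a hash count, checked in the tests against a literal
dictionary-count oracle.

`merge_annotation_layers()` applies the layer rules: the primary de novo
annotation is kept whole; secondary-layer candidates contribute only their
bases *not included* in the primary footprint and must retain at least 50
novel bp (clipping to the novel portion is the default because the combined
annotation is reported in novel megabases; a `not_overlapping` policy keeps
or drops candidates whole); k-mer fragments are kept only when they share no
base with the de novo footprint and span at least 30 bp.

`gc_content()` is (G+C)/(A+C+G+T) with ambiguous bases excluded from both
numerator and denominator.

# Compartments

`compute_window_coverage()` slides 500 kb windows with 50 kb overlap (step
450 kb), flattens repeat copies to a footprint before counting, and measures
gene coverage from CDS parts, not whole gene spans. The last window of a
chromosome is truncated and normalized by its true width. `cluster_windows()`
runs `stats::kmeans` on the raw (gene coverage, repeat coverage) pairs —
both axes are already fractions in [0, 1], so no rescaling is applied — with
25 restarts under a fixed seed. `label_and_segment()` orders the clusters by
mean *repeat* coverage (the compartments are named by repeat content): the
highest becomes RR, the lowest RP, the rest INT. Because adjacent windows
share a 50 kb overlap, the boundary between two differently labelled windows
is placed at the midpoint of the overlap zone; this makes the segments an
exact partition of each chromosome, which the straddle-exclusion rule
(`assign_features_to_compartments()`: a feature intersecting two or more
segments is `EXCLUDED`) presupposes. A tie between cluster means is an
error, not an arbitrary ordering. `standardized_family_coverage()` z-scores
per-family coverage with the population standard deviation.

# Associations

* `flag_te_genes()`: a gene whose CDS footprint is covered strictly more
  than 50% by high-confidence repeats is a putative TE-gene and is excluded
  from downstream gene analyses.
* `closest_repeat()` reproduces a closest-feature scan with
  ignore-overlap/ignore-upstream/ignore-downstream semantics; ties break to
  the smaller start coordinate.
* `classify_gene_configuration()` counts repeats < 1 kb upstream, < 1 kb
  downstream, and overlapping introns; genes with exactly one non-zero count
  fall in an exclusive class, others are `multiple` and are excluded from
  configuration-stratified expression comparisons.
* `repeat_methylation_status()` flags a repeat methylated per context
  (CG/CHH/CWG) when at least `min_calls` (default 1; the source methods give
  no threshold) methylated calls fall inside its span.
* `link_dmrs_to_repeats()` classifies each DMR by its maximal-shared-bases
  repeat partner into partial overlap, DMR-inside-repeat (identical spans
  included) or repeat-inside-DMR (strictly smaller repeat); all overlapping
  pairs are retained in an auxiliary table.
* `associate_dmrs_with_genes()` keeps *all* qualifying (gene, DMR) pairs —
  a gene may associate with several repeat-linked DMRs and vice versa.
* `associate_rin_with_dmrs()` extends each binding peak by ±10 bp (overlap
  mode) and ±500 bp (adjacent mode), clamped at chromosome ends; every
  overlap-mode pair is by construction also adjacent.

# Enrichment statistics

The expected count of a gene category in a region is `EXP = OBS x REG /
TOT`; summed over regions partitioning the genome this conserves `OBS`
exactly, which the tests assert to 1e-9. Pairwise region comparisons are
2 x 2 chi-square tests (category vs not, region A vs region B) with the
Yates continuity correction — the default behaviour of the standard R
routine the original analysis called — and Bonferroni correction over the
categories tested in the same family; the multiplier is recorded in the
output. Multi-cell tables use no continuity correction.

For consensus-vs-regulation enrichment the printed description of the THEO
expectation is internally inconsistent (one symbol is glossed both as an
input and as the observed cell), so the implementation uses the standard
contingency expectation `row_total x column_total / grand_total` and
documents the choice rather than guessing the original arithmetic. A
(consensus, status) cell passes the filters when at least 10 of its observed
genes are *expressed* (RPKM > 0 at the later stage of the pair — the filter
phrase "genes expressed" is otherwise undefined), its fold
observed/expected is at least 2, and its Bonferroni-corrected p is below
0.001. Folds are binned 1–2.5 / 2.5–6 / 6–9 for reporting. The output also
carries `fold_vs_stable`, the per-gene placement-rate ratio against the
stable class: this is the direct, margin-free estimate of a planted
placement bias. The two estimators differ systematically: if a consensus is
planted at rate ratio $f$ upstream of up-regulated genes, the contingency
fold is diluted toward
$f N / (f n_{up} + n_{down} + n_{stable})$
by the pooled column margin (about 3.1–3.5 for $f = 4$ at the default 5%/5%/90%
up/down/stable split), while `fold_vs_stable` estimates $f$ itself. The
acceptance tests therefore detect the planted consensus through the filter
machinery and measure its effect size with `fold_vs_stable`.

`mann_whitney_u()` computes the rank-sum U with average ranks for ties and a
two-sided p by exact enumeration when both samples have at most 8
observations and no ties, otherwise by the normal approximation with
tie-corrected variance and 0.5 continuity correction (the
continuity-corrected behaviour of `wilcox.test`). Measured over all U values
at n = 8, the approximation deviates from exact enumeration by at most
0.011; the exact path is the default at those sizes.

`random_placement_expectation()` re-places every query feature uniformly on
its own chromosome (length preserved, no end-crossing; per-chromosome
placement keeps the chromosome composition of the null, since compartments
are chromosome-structured) and compares the observed associated count with
the mean over shuffles by a 2-cell goodness-of-fit chi-square. An analytic
mode computes the exact coverage-based overlap probability for
cross-validation; the Monte-Carlo estimate converges to it at the usual
$1/\sqrt{n_{shuffles}}$ rate.

# The synthetic genome: a stated world

`synthetic_spec()` fixes the emulated world once; the defaults are the
conditions the analysis reports or, where unreported, a realistic choice
documented here and not revisited:

* **Karyotype** — three 5 Mb chromosomes: large enough for 36 coverage
  windows and stable k-means, small enough for minute-scale runs.
* **Layout** — each chromosome is tiled RP–INT–RR–INT–RP: repeat-poor tips,
  repeat-rich pericentromere, intermediate transition zones. Segments must
  be at least two window lengths, which on 5 Mb chromosomes forces five
  equal 1 Mb segments; the desk-scale default therefore reproduces the
  *spatial ordering* of the compartments, not their genome-wide size ratio
  (485/161/113 Mb).
* **Repeat coverage targets** 0.85/0.50/0.15 and **gene densities**
  15/57/122 per Mb for RR/INT/RP — the reported compartment properties.
  Because random sequential placement jams near 75% coverage, background
  copies are placed into free gaps (sampled weighted by width) and a
  configurable fraction (default 10% of copies) of nested insertions is
  added inside existing elements, mirroring nested TEs in real annotations.
* **Family mixes** per compartment (Gypsy-dominated RR, Copia-enriched INT,
  Class-II/SSR-enriched RP) and **family G+C** (Gypsy 0.42 > Copia 0.39 >
  DNA 0.36 over a 0.35 background) follow the reported qualitative ordering.
* **Expression** — zero-inflated log-normal per compartment, parameterized
  so leaf medians are 0 (RR), ~1.34 (INT) and ~4.87 (RP): the zero fractions
  are 0.60/0.10/0.05 and the log-means are back-derived from the target
  medians given sdlog 1.2 (e.g. INT: median = exp(meanlog) x 0.845 at 10%
  zeros, so meanlog = log(1.59)).
* **Differential expression** — 5% up, 5% down between 17 and 52 d.p.a.
  (thousands of DE genes among ~34k in the source data, spread over stage
  pairs); up genes are forced to rise between the stages, down genes to
  fall.
* **Gene-proximal repeats** — 20 consensus families placed independently
  within 1 kb upstream of each gene at rate 0.15 (0.05 downstream). A
  planted enrichment multiplies the upstream rate for genes of one
  regulation status; because each gene receives at most one copy per
  consensus, the planted counts are binomial and the rate-ratio estimate of
  a 4-fold bias has a standard error of ~7%, comfortably inside a ±25%
  recovery band. The flank placement makes gene surroundings repeat-denser
  than in the real genome; configuration-class proportions are therefore
  not emulated quantitatively.
* **TE-genes** — planted per compartment at probabilities 0.30/0.12/0.02
  (RR/INT/RP; most TE-genes live in repeat-rich space) by covering the
  gene's span with a high-confidence repeat. High-confidence background
  copies that would touch the CDS of a non-TE-gene are demoted to low
  confidence, so the planted list is exactly the set a >50% CDS-coverage
  filter recovers — precision and recall 1 is a design property, and any
  deviation is an engine bug, not noise.
* **Methylome** — one call per kb on repeats (methylated with probability
  0.9/0.7/0.4 for CG/CWG/CHH) and 0.3 per kb of background (methylated at
  0.05). Calls are emitted directly; there is no bisulfite-read or
  methylation-spreading model (a spreading-distance parameter exists and
  defaults to 0 because the source gives no quantitative model).
* **DMRs** — 68 per Mb (the genome-wide density of the 52,095 reported
  DMRs), non-overlapping, 72.29% placed on repeats with the class mix
  normalized from the reported 18.65/54.57/0.80 breakdown (which itself
  sums to 74.02; the printed total is used as the target and the
  inconsistency recorded). Unassociated DMRs are rejection-sampled into
  repeat-free space, so the realized association fraction equals the target
  up to placement feasibility.
* **RIN peaks** — 5.4 per Mb, 12.4% placed within 500 bp of a DMR; far
  peaks are rejection-sampled outside the ±500 bp DMR neighbourhoods so the
  near/far ground truth is exact.

Everything derives from one integer seed; the same seed yields a
byte-identical emitted dataset.

## What a green test does and does not establish

The generator produces the co-location *structure* the pipeline assumes —
compartment-graded densities, family biases, gene-proximal copies,
repeat-borne methylation, DMR/repeat and RIN/DMR adjacency — with
independent placements and idealized boundaries. It does not model TE
sequence evolution (no LTR structure, no divergence), linkage between
neighbouring features, assembly gaps, or annotation noise. Green
parameter-recovery tests therefore establish that the engines measure
correctly in a world with known truth, not that the biological conclusions
of any particular genome are correct.

# Numerical choices and degenerate inputs

* K-mer codes use a base-4 rolling encoding in doubles (exact for k <= 26);
  `k` longer than every sequence yields an empty result with a warning.
* k-means requires at least k distinct coverage points and errors otherwise;
  a tie in cluster mean repeat coverage is an error naming the tie.
* Zero-variance family coverage yields all-zero z-scores with a warning.
* A chi-square expected cell of 0 is an error in the core routine; the
  compartment-enrichment wrapper reports NA for category/region pairs with
  an empty margin instead of aborting a whole run.
* Bonferroni caps at 1. Distance ties resolve to the smaller start.
* The DMR placer errors when non-overlapping placement is infeasible
  ("more DMRs than placeable"); associated placements that cannot find a
  suitable repeat are dropped silently (the association fraction is
  measured, not assumed).

# Reduced scales in the test suite

The unit suite runs the generator mostly on one 5 Mb chromosome and the
pipeline on a 1 x 3 Mb genome; the acceptance suite uses the full 3 x 5 Mb
default for parameter recovery and 100 one-chromosome genomes for the
type-I-error control, staying inside the stated per-criterion time budgets.
The acceptance script runs the complete pipeline (including sequence
generation and the k-mer layer) on the 3 x 5 Mb default under the seed it is
given.

# Known limitations

* The compartment size *ratios* of a real genome are not reproduced at desk
  scale (see Layout above).
* `fold_vs_stable` requires per-status gene counts; without them only the
  margin-diluted contingency fold is available.
* GFF3/BED parsing delegates to `rtracklayer`; malformed-line diagnostics
  are whatever that parser reports, plus package-level validation of
  coordinates, karyotype membership and vocabularies.
* The Mann-Whitney normal approximation's intrinsic deviation from exact
  enumeration at n = 8 reaches 0.011; use the (default) exact path for
  small samples.
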