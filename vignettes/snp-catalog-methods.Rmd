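---
title: "Constructing and validating a high-confidence SNP catalog from exome capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a high-confidence SNP catalog from exome capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprucesnp)
```

## The problem

Conifers such as Norway spruce have ~20 Gb, highly repetitive genomes for
which whole-genome resequencing is impractical. A standard way to build
population-genomic tools for such species is exome capture: probes designed
on a congener's transcriptome enrich the gene space, reads are assembled de
novo into contigs, and SNPs are called against those contigs. Because both
the assembly and the variant calls are noisy, reliable catalogs are built
by (i) pairing contigs back to the targeted transcripts under strict
identity and coverage gates, (ii) keeping only variants called
independently by two different callers, (iii) pushing the intersection
through a cascade of per-site quality filters, and (iv) validating a sample
of the catalog on a genotyping array. `sprucesnp` implements that full
workflow plus the downstream analyses: a depth-corrected SNP-abundance
statistic per gene and enrichment tests of functional categories among the
most polymorphic genes.

## Contig-to-target pairing

`filter_hits()` retains a contig-to-transcript hit iff identity ≥ 95%,
e-value < 1e-5, mean coverage within the closed window [25, 800], and
contig length > 500 bp. The bound conventions are deliberate: identity and
coverage are stated as inclusive thresholds ("95% of identity", "between 25
and 800") while the e-value bound is written strictly; both are applied
literally. When a contig matches several transcripts,
`pair_and_summarize()` assigns it to the single best gene by lowest
e-value, then highest identity, then lexicographically smallest gene id — a
deterministic rule chosen because unique gene matches are required but no
tie-break convention is standard.

## The consensus filter cascade

`intersect_callsets()` declares a site common when both callers report the
same contig, position, reference allele and alternative-allele list
(upper-cased). Duplicate (contig, position) keys within one set are input
errors. The first call set is the *annotation of record*: its quality
annotations and read counts feed the filters and the catalog statistics,
because the second (mapper-integrated) caller does not emit comparable
annotations; it contributes site confirmation only.

`apply_quality_filters()` is a pure conjunction of ten predicates —
MQ ≥ 20, MMLQ ≥ 10, QD ≥ 10, PP ≥ 20, SbPval ≥ 0.01, HapScore ≥ 15,
MGOF ≥ 20, SC ≥ 0.95, at least two alternative-allele reads (so singletons
are excluded by construction), and a single alternative allele — so the
result is order-independent, and the audit tallies every violated gate of
every rejected site. The MGOF gate is peculiar: the quantity is described
as a *maximum allowed* goodness-of-fit value, yet the threshold is printed
with ≥. We apply it exactly as printed and expose `mgof_invert = TRUE` to
flip it to ≤ rather than guessing the intent.

A related accounting subtlety: the count of SNPs "not in the intersection
but detected by either caller" equals, arithmetically, the union
|A| + |B| − |A∩B|. `union_size()` computes and reports that formula.

`extract_flanks()` uses 1-based, fully closed coordinates; flanks truncate
at contig ends, so their lengths are `min(100, distance to the end)`.

## Depth-corrected SNP abundance

The number of segregating sites discovered on a contig grows with read
depth roughly like the harmonic number H(D−1) — deeper sequencing samples
more chromosomes, in the manner of Watterson's estimator. The per-contig
abundance statistic

beta = [(S + 1) / L] / H(D − 1)

divides the (pseudo-counted) per-bp SNP count by that factor, making
contigs of different depths comparable. Average depth is rarely integral
and the formula's summation index must be: we truncate the harmonic sum at
`floor(D) − 1` by default (the conservative reading) and provide
`d_mode = "digamma"` (H(D−1) = digamma(D) + γ) for sensitivity analysis;
the two agree exactly at integer depths. Contigs with `floor(D) < 2` leave
the harmonic sum empty and are excluded (with a message) — the upstream
coverage gate of 25 makes this a synthetic-only edge case.

Genes assembled from multiple contigs get the length-weighted mean beta
(`gene_beta()`). `rank_genes()` orders genes by descending beta with a
deterministic tie-break (descending total SNP count, then gene id) and
flags the top `floor(0.10 N)` (at least one) as the most-SNPed decile;
"10%" comes without a rounding rule, and flooring is the stricter choice.

## Array design and genotyping QC

`select_candidates()` implements the three probe-design criteria: no other
variant within 50 bp on either side (checked, deliberately, against the
union of both callers' *raw* variant lists — any underlying polymorphism
can disturb probe annealing, whatever its filter status; a switch to a
filtered list is passing a different variant table), at least 20 bp from
both contig ends (`min(pos − 1, L − pos) ≥ 20`; distances come without an
open/closed convention, and the inclusive reading is the probe-safe one),
and a functionality score ≥ 0.60 consumed as an input column (the score
algorithm is proprietary). One SNP per gene is kept, by highest score,
then highest MAF, then lowest position.

For array QC, `marker_stats()` computes per-marker call rate, allele
frequency, observed and expected heterozygosity, and the
heterozygote-excess statistic `Fe = (Ho − He)/(1 − He)` (clamped at 0). No
standard closed form exists for Fe in this context; this form is 0 under
Hardy–Weinberg proportions and 1 for an obligate heterozygote — the
signature of a probe annealing to two fixed paralogous loci — and an
alternative `fe_mode = "ratio"` (Ho/He − 1) agreeing at both extremes is
provided. `classify_markers()` applies signal gates first (clustering
score ≥ 0.13, call rate ≥ 80%), then monomorphism (a single *homozygous*
class — an all-heterozygote marker is paralogous, not monomorphic), then
Fe ≥ 0.80, else valid: exhaustive and mutually exclusive, so validation
reports (`tpr_report()`) always conserve their row sums.

## The synthetic study generator

Real raw reads for such studies are rarely available, so every pipeline
input is emulated by seeded generators with known ground truth
(`synth_config()`, `generate_study()`). Defaults were fixed once to mirror
the study design the package models, scaled to run in seconds:

* 600 targeted genes, 900 contigs assigned to genes at random (~1.5 contigs
  per recovered gene, ~25% of genes never recovered), lengths 300–2500 bp,
  log-uniform mean depths 30–400 (right-skewed, like capture data);
* variant discovery coupled to depth as S ~ Poisson(θ·L·H(⌊D⌋−1)) with
  θ = 1.6e-3/bp, the Watterson-style expectation that beta inverts — this
  yields ~0.2 catalog SNPs per 100 bp after consensus and filtering;
* a caller-overlap Jaccard of 0.285 and a 9% planted filter-failure rate
  among intersection sites, each failing site violating exactly one named
  gate (including planted singletons and tri-allelic sites), so per-filter
  attribution is exactly testable;
* a 2,000-marker × 200-sample genotype matrix with marker classes in the
  proportions of a real validation panel (9% paralogous, 5.5% monomorphic,
  1.3% weak-signal, 1.6% controls), Hardy–Weinberg valid markers at MAF
  U(0.05, 0.5), paralogous markers as near-obligate heterozygotes
  (P(AB) = 0.95), a per-call error rate of 3e-4 and two replicate sample
  pairs;
* a 4-level GO DAG with multi-parent edges, ~40 gene families, orphan and
  conifer-specific flags, and one designated family plus one designated
  leaf term whose genes receive a 6× SNP-rate multiplier, planting them
  into the top beta decile.

Class-defining draws are rejection-sampled so the realised error-free data
actually exhibit each marker's class; this is what makes exact
confusion-matrix checks meaningful. The generator does *not* simulate
reads, capture thermodynamics, assembly artifacts, linkage between sites,
or allele-frequency spectra beyond the uniform-MAF choice — so green tests
demonstrate the correctness of the pipeline's logic on well-formed inputs,
not robustness to real-data pathologies such as mismapped paralogs in the
read data themselves.

## Enrichment testing

GO annotations are propagated to all ancestors (true-path rule,
`propagate_go()`; cyclic edge lists are rejected naming an offending
edge). Term tests are one-sided Fisher's exact tests (over-representation
only), with terms under 5 annotated genes skipped (`nodesize = 5`) and raw
p-values reported, as is conventional for hierarchy-aware GO testing. Two
methods are provided: `classic`, and `elim`, which processes terms
leaves-upward and removes the genes of children significant at
`alpha_elim = 0.01` from their ancestors before testing. The hybrid
`weight01` decorrelation is intricate and specific to one implementation;
we keep the algorithmic scope honest by providing the two well-defined
methods and labelling results with the method used. Family tests are
two-sided ("differential representation"), restricted to families with ≥ 2
members in the top decile, and Benjamini–Hochberg adjusted (a correction
method is required but not named; BH is the field default). Flag tests
(orphans, conifer-specific genes) are single two-sided 2×2 tests reporting
group proportions. The GO universe is the annotated genes only; family and
flag tests use all genes in the abundance table — the published convention,
exposed as arguments because the universes are not fully pinned down.

## Numerical and testing choices

Harmonic numbers are cumulative sums (exact for the integer arguments
used); Fisher p-values come from `stats::fisher.test` and are checked in
the test suite against an independent explicit hypergeometric tail
summation (`lchoose`), to 1e-10, over a sweep of tables up to N = 500.
The beta implementation is checked against a literal-loop oracle to 1e-12
over a grid of S ∈ {0..50}, seven lengths in [100, 5000] and ten depths in
[2, 500], with monotonicity asserted exhaustively on the grid. Calibration
suites use sizes chosen for statistical meaning rather than speed: the
null type-I error of term tests is measured over 1,000 simulated terms of
50–300 genes in a 2,000-gene universe (large enough that the discreteness
of the exact test does not bite), and planted-enrichment detection and the
depth-decorrelation property are each measured over 100 generator seeds.
A full synthetic study (default configuration) runs in a few seconds; the
complete test suite in about a minute.

## Known limitations

* The capture-efficiency figure upstream of pairing (pre-filter matching)
  involves criteria that are not printed; only the post-filter recovery
  accounting is reproduced.
* `elim` is implemented; `weight01` is not (see above).
* Depth and MAF of a catalog SNP come from the annotation-of-record only;
  no attempt is made to reconcile the two callers' read counts.
* Genotype-matrix QC consumes clustering-quality scores as inputs; the
  clustering algorithm itself is out of scope.
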