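---
title: "Methods: mitochondrial diversity metrics, segment detection and heteroplasmy calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial diversity metrics, segment detection and heteroplasmy calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodiv)
```

This vignette documents the models and conventions behind the package: what
each statistic assumes, which parameters matter, how degenerate inputs are
handled, and what the synthetic-data generators do and do not emulate.

## The analysis problem

Mitochondrial markers for population and individual identification are
usually drawn from the control region (CR), the most variable part of the
mitogenome. Marker design needs three maps: conserved segments (primer
sites), variable segments (discriminating sites) between individuals, and
the intra-individual (heteroplasmic) variation that can confound both. The
package computes these maps from three inputs it does not produce itself: a
gapped alignment of CR haplotypes, a gapped alignment of complete
mitogenomes (rotated to a common origin), and a read pileup over one
assembled mitogenome.

## Polymorphic sites and allele designation

A column of the alignment is polymorphic when it shows at least two
distinct alleles among `A, C, G, T, -`. Two conventions matter:

* **`N` is missing data**: `N` calls are removed from both the allele
  counts and the frequency denominator, and all-`N` columns are skipped.
* **The gap is an allele**: indel columns segregate like substitutions.
  The frequency denominator is the number of non-`N` sequences at the
  column. A switch (`gaps_as_alleles = FALSE`) instead drops gap calls like
  `N`, for comparison with tools that ignore indels; whether gap-only
  sequences belong in the denominator is genuinely convention-dependent,
  so both conventions are available.

Variant tables from naive callers include the reference allele among the
variants, inflating counts. Designation therefore picks exactly one
reference allele per site: frequency above 50% wins outright; a bi-allelic
50/50 site has a single variant (the site cannot have two variants — one
allele must be the reference); at tri- and tetra-allelic sites the most
frequent allele is the reference. The 50/50 tie (and any exact count tie)
is broken deterministically: the allele carried by the alignment's
coordinate-reference record wins, else the lexicographically smaller
allele. After designation no variant can exceed 50% — the package treats a
violation as an internal error rather than clamping it.

Adjacent gap columns are counted as independent sites; indel merging into
multi-base events happens only in the heteroplasmy module, where the caller
itself emits multi-base alleles. This matches how alignment-column
tabulations are conventionally counted.

Each site is typed by the reference/variant pairs it contains —
transition (A↔G, C↔T), transversion (purine↔pyrimidine), indel — and flags
combine at multi-allelic sites, so the categories
(transition-only, transversion-only, transition+transversion, indel-only,
indel+substitution) partition all sites.

## Variability index and weighted frequency bins

The variability index `VI = 100 * S / L` (polymorphic sites per bp,
percent) makes regions of different lengths comparable; by chance alone a
longer gene collects more polymorphic sites. VI is reported to 1 decimal in
segment tables and 2 decimals in per-gene tables.

Frequency spectra are summarized over left-open, right-closed percentage
bins `(0,10], (10,20], ..., (40,50]` (a frequency of exactly 10% falls in
the lowest bin). Each site carries total weight 1 split equally over its k
variant alleles; a tri-allelic site with variants at 4% and 13% adds 1/2 to
each of the first two bins. This weighting records every variant's
frequency without letting multi-allelic sites dominate the spectrum, and it
is why bin tables legitimately contain fractional entries (m/2, m/3). The
grand total of any bin table equals the number of contributing sites — an
invariant surfaced in the report footer and checked by the tests.

For a four-genome comparison the attainable variant frequencies are exactly
25% (a singleton) and 50% (a 2v2 split, which by the designation rules is a
single variant), so the per-gene table has exactly those two frequency
classes. Sites overlapping several annotations are counted in each with a
warning; sites in no annotation are tabulated as intergenic.

## Conserved segments and the window p-value

With the conservation threshold at its default C = 100, a column is
conserved only when all sequences carry the same unambiguous base — gaps
and `N` count as mismatches. (For C < 100, column conservation is the
fraction of sequences carrying the modal base, and a run qualifies when
every column reaches C; only C = 100 is exercised by the reference
analyses.) Maximal conserved runs of length at least `min_window` (default
20 columns) are candidate conserved segments.

Each run is scored with an exact null: if the alignment's S polymorphic
columns were placed uniformly at random among its L columns, the
probability that a fixed window of length w contains none of them is

P(w; S, L) = C(L − w, S) / C(L, S).

This hypergeometric window p-value is exact, monotonically decreasing in
both w and S, zero when S > L − w and one when S = 0; the tests verify it
against exhaustive enumeration of all C(L, S) placements for L ≤ 12. Runs
with p ≥ alpha (default 0.05) are discarded, except in the degenerate case
S = 0 (a fully conserved alignment), where the null is vacuous and the
single spanning segment is still reported. The widely used desktop
implementation of this analysis does not document its p-value formula; the
window null used here was chosen because it is exact and testable, and it
may therefore differ in detail from that tool. A Bonferroni option
(multiplying by the number of window placements, L − w + 1) is available
and off by default, matching the single-window convention.

Variable segments are the exact complement of the conserved segments
within the analyzed span, including leading and trailing stretches, so CS
and VS always tile the span — lengths are counted in alignment columns,
which is also the length entering VI (reference coordinates, mapped through
the ungapped reference record, are reported alongside and can differ from
the column count when other sequences carry insertions). GC content is
computed over non-gap characters of columns that are not indel-containing
sites, pooled across sequences.

## Hypervariable grouping

The per-VS polymorphic-count profile of a CR is typically bimodal. The
profile (optionally smoothed with a centered moving average; default none,
since the profiles involved have few points) is searched for local maxima —
a boundary point counts as a peak when it exceeds its single neighbour, an
interior point when it is at least as large as both neighbours and strictly
larger than one. With two or more peaks, the VS are split into two
contiguous groups at the minimum between the two largest peaks, the valley
segment opening the second group (profile 7, 19, 95, 18, 3, 26, 14 splits
into VS1–VS4 and VS5–VS7). A unimodal profile yields one group with a
warning, and an explicit split index overrides detection — useful when a
grouping is fixed a priori.

## Heteroplasmy calling

The caller consumes a samtools-style text pileup (the `-B` uncalibrated
dialect): `.`/`,` are reference calls, `ACGTacgt` substitutions,
`+n<seq>`/`-n<seq>` insertions/deletions anchored at the position,
`^q`/`$` read start/end markers are stripped, and `*` marks a base deleted
by an upstream deletion (a placeholder, not a call). Indels are reported in
anchored notation (insertion `C -> CA`, deletion `CA -> C`); multi-base
indels stay single variants.

Thresholds follow the VarScan-style contract: a variant needs at least
`min_var_reads = 4` supporting reads and frequency at least
`min_var_freq = 0` of the site coverage; at or above
`min_freq_for_hom = 0.5` it is a consensus call rather than a
heteroplasmic one. Zero-coverage sites are skipped. Each variant gets a
one-sided binomial tail p-value of its supporting reads against a per-base
error rate (default 0.01): this replaces the Fisher's-exact machinery of
read-level callers with a model that is deterministic, documented and
monotone in the supporting reads; variants with p at or above 0.05 are kept
in the output but flagged not-called and excluded from all summaries,
mirroring the "not called for any genotype" exclusion of annotation-track
review. Each indel is annotated with the length of the homopolymer run
around its position — A/T-run indels are the classic sequencing artifact —
but the annotation is never used for filtering, so counts remain
comparable with census-style tallies; downstream filtering can use it.

Per-gene summaries bin called variants into 10% frequency intervals,
compute the intra-individual VI, sort by VI descending, and classify each
gene's bin-occupancy pattern: `progressive` (occupied bins form a prefix
from the lowest interval — the signature of protein-coding genes, where
indels must accumulate at low frequency before rising), `lone_high` (a
single occupied bin above the lowest) and `gapped` (holes in the occupancy,
as in an rRNA with low-frequency variants plus one isolated high-frequency
call). Variants outside every annotation are excluded from the per-gene
table. One deposited tRNA length is an average over the two serine tRNA
genes; the bundled reference table keeps that average (68.5) while the
generator, which needs integer intervals, floors it.

## Distances, UPGMA and bootstrap

Pairwise distances use pairwise deletion: for each sequence pair, columns
where either carries a gap or `N` are dropped. Three models are provided:
p-distance; TN93 (separate purine and pyrimidine transition rates, unequal
base frequencies estimated from the pair); and T92 (GC-content based). The
gamma rate correction replaces each `-log(x)` term by `a (x^{-1/a} - 1)`
(continuous-gamma form, shape `a`; 0.18 is the conventional shape for a
hypervariable CR). Saturated pairs — any logarithm argument ≤ 0 — receive a
configurable ceiling distance (default 5) with a warning rather than
`NaN`, keeping clustering well-defined. The implementations follow the
standard published closed forms; they are not bit-for-bit replicas of any
particular desktop package, whose pairwise-deletion details differ — the
reproducible claim is tree topology, and the tests verify the closed forms
directly and against an independent implementation.

UPGMA joins the closest pair of clusters at height d/2 with size-weighted
average linkage; ties are broken toward the smallest index pair, making
output platform-independent. Trees are rooted, ultrametric (verified to
1e-9 in the tests) and serialized as Newick. Bootstrap support resamples
alignment columns with replacement, rebuilds the tree, and scores each
internal bipartition by the fraction of replicates containing it; a fixed
seed makes supports reproducible.

## The synthetic-data generators

The generators produce data with the statistical structure the analyses
assume, plus a complete serialized truth set, so every downstream test
reads only the truth, never generator internals.

* **CR haplotype panel** (default: 45 haplotypes, 7 CS of lengths
  40, 27, 23, 20, 27, 35, 24 alternating with 7 VS of lengths
  55, 89, 354, 110, 11, 130, 56 carrying 7, 19, 95, 18, 3, 26, 14 variant
  columns; site types 143/16/11/9/3 over the five categories; 111, 27, 13,
  13, 18 sites per 10% frequency bin). Frequencies are planted as exact
  counts `k` of `n` sequences — census ratios, not samples — because MSA
  frequencies are census ratios. Variant columns include each VS's first
  and last columns and are spread evenly, so no monomorphic run inside a
  VS reaches the window length and planted boundaries are recoverable
  exactly. The first haplotype carries no variants and anchors the
  coordinate system.
* **Genome quartet** (default: one region per published per-gene tally,
  212 sites at the 25%/50% classes on a 15,989 bp genome). Substitutions
  only, so the four genomes align column-wise; genome 1 stays unmutated.
* **Heteroplasmy pileup** (default: 186 variants over the published
  per-gene frequency tallies; event pool of 112 insertions / 72 deletions /
  2 transitions dominated by single T and A indels; negative-binomial
  coverage with mean 128.4 and SD 51.3). Planted fractions are drawn
  uniformly within each 10% bin (bounded below so variants stay
  detectable), and supporting reads are drawn binomially at the planted
  fraction — read support is stochastic even when the underlying fraction
  is fixed. Setting `sample_support = FALSE` and `depth_sd = 0` gives the
  noise-off validation mode in which every planted event is recovered
  exactly; the acceptance script uses that mode for the census-style
  composition quantities.

What the generators do **not** emulate: alignment uncertainty (columns are
planted, never mis-aligned), nuclear mitochondrial paralogs (NUMTs), PCR
and strand-bias artifacts, read-level base qualities, and phylogenetic
structure in the panel (variants are planted independently, so the
haplotype panel is star-like and bootstrap supports on it are legitimately
low). Passing tests on synthetic data therefore demonstrate correctness of
the computations under the stated models, not robustness to upstream
alignment or mapping errors.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere user-facing; wrapping genes
  on the circular genome are written `start > end` and never duplicated.
* Rotation to a common origin uses a deterministic anchor motif (first
  occurrence, forward then reverse complement, warning on multiple hits)
  rather than a maximal-rotation criterion: anchor rotation is auditable
  and sufficient once an origin convention exists.
* Circular spacing statistics include the wrap-around gap by default, so
  the mean gap is exactly L/n; a linear convention (no wrap) is available
  via `circular = FALSE`, since published spacing figures are sometimes
  computed that way — for 186 sites on 15,989 bp the circular mean is
  85.96 where a non-wrap figure of 85.9 may be printed.
* Reported VI rounding: 1 decimal for segment-style tables, 2 for
  per-gene tables; weighted counts to 1 decimal; an optional
  decimal-comma rendering matches regional table formatting.
* Problem sizes in the tests and acceptance script are the full study
  shapes (45 x ~1000 panel, 15,989 bp genomes, full-depth pileup); the
  bootstrap uses 100 replicates in the acceptance run, a size at which
  supports on these panels are stable to ~0.01.

## Known limitations

* The window p-value model is exact for its null but is not a re-derivation
  of the legacy desktop implementation; borderline segments near alpha may
  differ between the two.
* The binomial call p-value ignores read-level base quality; with the `-B`
  pileup dialect that information is deliberately uncalibrated anyway.
* Distances degrade to a ceiling under saturation instead of being dropped;
  for deeply diverged inputs a likelihood method should replace UPGMA.
* Heteroplasmy calls cannot distinguish true heteroplasmy from NUMT
  contamination or residual mapping error; the homopolymer annotation and
  invariable-region report are the provided levers for post-hoc scrutiny.
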