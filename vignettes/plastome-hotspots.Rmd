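---
title: "Comparative plastome structure and mutational-hotspot screening with plastomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome structure and mutational-hotspot screening with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## The problem

Plastid genomes (plastomes) of photosynthetic plants are circular molecules
of roughly 120-170 kb with a conserved quadripartite layout: two identical
inverted repeats (IRa, IRb) separating a large single-copy (LSC) and a small
single-copy (SSC) region. Two structural phenomena make plastomes
informative for comparative work. First, IR boundaries shift: in several
lineages (orchids prominently) the IR has expanded into the SSC, duplicating
genes such as ycf1 and rps15, and these expansions co-occur with the loss or
pseudogenization of the 11 plastid ndh genes (ndhA-ndhK). Second, the
non-coding fraction of the plastome — intergenic spacers and introns —
accumulates substitutions and indels at locus-specific rates, so a small set
of "mutational hotspots" carries most of the usable variation for
species-level phylogenetics and barcoding. Which loci are hotspots turns out
to be genus-specific, so hotspot screens must be repeated per genus.

`plastomics` implements that screen as a reusable, tested pipeline:
quadripartite structure detection, IR/SSC junction profiling relative to
ycf1, ndh status classification, extraction and synteny-grouping of
non-coding loci, perfect-SSR censusing, a pairwise sequence-variability
statistic with hotspot ranking, and the associated nonparametric tests. A
synthetic-genome generator with a planted-truth ledger makes every stage
verifiable without downloading data.

## The sequence-variability statistic

For each syntenic non-coding locus and each unordered pair of congeneric
species, the two locus copies are globally aligned and scored as

$$\mathrm{SV} = 100 \times \frac{M + I}{C + M + I}$$

where, over the alignment columns after discarding terminal gap runs,

* $M$ — columns where both rows carry bases and they differ (nucleotide
  mutations),
* $I$ — indel events, counted as one per maximal gap run regardless of its
  length (the event-counting convention of DnaSP),
* $C$ — columns with identical bases (conserved sites).

Terminal gap runs (any maximal run of gap characters touching the first or
last alignment column in either row) are excluded before counting, so length
differences at locus boundaries never inflate SV. Columns containing N are
excluded from $C$ and $M$; an N splits a gap run only if it interrupts the
gap characters themselves. SV is bounded in $[0, 100]$ and is zero exactly
when the pair shows no events.

Per genus, the pairwise SVs of each locus are summarized by their mean and
sample (n-1) standard deviation over all $\binom{k}{2}$ pairs of the $k$
genus members carrying the locus. Loci ranked by mean SV (ties broken by
locus key) give the hotspot table; the top 10 are reported by default.

## Alignment

Locus pairs are aligned with a deterministic global Needleman-Wunsch/Gotoh
aligner with affine gap penalties: match +2, mismatch −3, gap open −5, gap
extend −2 (a gap of length $L$ scores $-5 - 2L$). Traceback prefers
diagonal, then up, then left; the two inputs are ordered canonically before
alignment so `align_pair(a, b)` and `align_pair(b, a)` give row-swapped
identical columns. At the divergences relevant here (SV mostly below 15%),
pairwise alignment of homologous spacers is insensitive to the aligner
choice, and determinism is worth more than fidelity to any particular
external tool; the alignment contract (no all-gap columns, symmetric event
counts) is what downstream counting relies on, and any backend honouring it
could be substituted.

## Structure detection

`detect_inverted_repeats()` seeds 31-mers of the sequence against its
reverse complement, keeps one seed per anti-diagonal, and extends greedily.
An isolated mismatch is absorbed only when the following 10 positions match
and the running mismatch fraction stays within the tolerance (default
0.001); this absorbs the occasional SNP inside a real IR while guaranteeing
that exact planted repeats are recovered with exact coordinates (flanking
sequence cannot be glued on through a mismatch). The two gaps between the
repeats are labeled LSC/SSC by size, and the tiling identity
$2\,\mathrm{IR} + \mathrm{LSC} + \mathrm{SSC} = L$ is asserted on every
detection. Genomes without an inverted duplication of at least `min_ir` bp
(default 10 kb) return an explicit no-IR result, mirroring IR-less
plastomes such as those of pines.

The degree of IR expansion is measured as the distance from the strand-aware
5' end of ycf1 to the nearest IR/SSC junction; when several ycf1 annotations
exist (the IR fragment of ycf1 is commonly annotated too), the longest span
is used. ndh genes are classified `functional` when an annotated CDS is
present with length a multiple of 3, at least 50% of a reference length, and
no internal stop codon; `truncated` when annotated but failing a criterion;
`lost` when unannotated. The 50% cutoff is a conservative, configurable
choice — published descriptions say "truncated or lost" without giving one.

## Loci, synteny, and SSRs

Intergenic loci are maximal gaps between gene-level annotations around the
circle (gene-level, not CDS-level, so plastid annotation conventions without
UTRs do not create spurious spacers); intronic loci are gaps between
consecutive exons of a spliced feature, numbered in biological order. Loci
shorter than 150 bp are flagged and excluded. Loci are homologized across
plastomes purely by their canonical flank pair — the unordered,
strand-insensitive pair of flanking gene labels — and a locus duplicated by
the IR collapses to its IRa copy before grouping. tRNA labels keep their
anticodon (trnS-GCU vs trnS-GGA are distinct flanks), preventing false
synteny between paralogous tRNAs.

Perfect SSRs are scanned at motif periods 1-6 with unit thresholds 8
(mononucleotide) and 5 (multinucleotide). Only primitive motifs are
reported, each maximal run once from its leftmost start, truncated to whole
units. The per-genus census counts SSR *sites*: a site present in several
congeneric species, or varying in unit count among them (a polymorphic SSR),
counts once, with homologous sites matched by motif plus ordinal position
within the locus. The SC-vs-IR enrichment of SSR-containing loci is tested
with the two-sided Fisher exact test.

## Statistical tests

All three tests are implemented with exact small-sample behaviour because
the study design produces very small groups:

* **Mann-Whitney** (SC vs IR SV; IR length between ndh-status groups): U by
  midranks; for $n_A + n_B \le 20$ the two-sided p is
  $P(|U - n_A n_B/2| \ge |U_{obs} - n_A n_B/2|)$ under enumeration of all
  $\binom{n_A+n_B}{n_A}$ labelings; beyond that, a normal approximation with
  tie correction and continuity correction.
* **Fisher exact** (2×2): the sum of hypergeometric point probabilities not
  exceeding the observed one (tolerance factor $1+10^{-7}$); a zero margin
  gives p = 1 with a warning.
* **Spearman** (GC vs SV; cross-genus SV profiles): midrank rho; exact
  permutation p by full enumeration for $n \le 10$, t approximation above.

Per-genus p-values are reported raw and with Benjamini-Hochberg adjustment
across genera; the adjustment is modern reporting practice and does not
change any headline direction.

## The synthetic cohort generator

`simulate_cohort()` builds an annotated ancestral plastome and evolves
star-shaped congeneric cohorts from it, recording every planted event in a
truth ledger.

The default **quadripartite template** is a 26.6 kb miniature with the full
structural logic of a real plastome: LSC (9.5 kb, 16 genes including a
spliced rps16), IRs (4.3 kb each; ndhB, trnV, rrn16, trnI, rrn5, and the IR
fragment of ycf1), and SSC (8.5 kb; the remaining ndh genes, a spliced
ndhA, ccsA, psaC, rps15, and a ycf1 whose 5' 999 bp lie in the SSC so the
gene spans the IRb/SSC junction). IRb is assembled as the exact reverse
complement of IRa, so IR loci are co-mutated by construction. Spacers are
at least 150 bp, scrubbed of near-threshold tandem repeats so that the only
SSRs present are the planted ones, and one base at the SSC boundary is
adjusted so the maximal inverted repeat ends exactly at the planted
boundary. A lighter **sv_bench template** (marker genes alternating with 40
spacers on a single-copy circle) serves rate-calibration experiments where
quadripartite structure is irrelevant.

Species evolve independently from the ancestor: per non-coding locus,
substitutions are placed per-site Bernoulli($s$) (default $s = 0.01$) and
indel events Poisson($i$) per locus (default $i = 0.5$) with geometric
lengths ($p = 0.5$, capped at 8 bp). Events never touch the first/last base
of a locus and never overlap each other, which keeps the ledger arithmetic
exact: for any pair, the expected $(M, I, C)$ — and hence SV — can be
reconstructed combinatorially from the recorded events
(`truth_pair_sv()`). Coding regions receive only functionality-preserving
non-stop codon swaps (default per-codon rate 0.002), so ndh classification
and supermatrix construction stay well-defined. The
`ndh_loss_ir_expansion` scenario deletes 10 of the 11 ndh genes (retaining
ndhB) and moves the SSC tail containing rps15 and ycf1 into the IR by
duplication, reproducing the expanded-IR/reduced-SSC architecture.

What the generator does *not* emulate: phylogenetically correlated
divergence (cohorts are star-shaped), selection, rearrangements beyond the
single IR-expansion scenario, imperfect SSRs, and annotation error. Passing
tests therefore demonstrate the pipeline's correctness given faithful
annotations and tree-free congeneric divergence, not robustness to
misannotation or deep phylogenetic structure.

Loci that straddle region boundaries (including the spacer wrapping the
genome origin and junction-adjacent spacers merged by gene deletions) are
analyzed by the pipeline like any other locus but are excluded from
ledger-exactness comparisons (`clean = FALSE` in the ledger): their truth
would require modelling IR-mirror-merged event sets.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GenBank 1-based inclusive
  only at the I/O boundary. Origin-wrapping features are normalized at
  parse time into single logical intervals.
* Sequences are restricted to A, C, G, T, N; other ambiguity codes are not
  accepted, and N is excluded from GC and from conserved/mutated counts.
* Gene identity is matched case-insensitively.
* Synteny requires both flanks identical; the 150 bp filter is applied
  per instance.
* The Mann-Whitney exact/approximate switchover at combined n = 20 covers
  all group sizes arising in paper-scale cohorts with exact p-values.
* Supermatrix construction strips every column containing a gap or
  non-ACGT character in any taxon, then concatenates genes alphabetically
  (shared, functional, non-ndh CDSs) and emits RAxML-style and NEXUS
  partition definitions. Per-gene alignment is accepted pre-computed; the
  bundled center-star helper built on the pairwise aligner is intended for
  desk-scale fixtures, not production multiple alignment. Model selection
  and tree inference are explicitly out of scope.

## Validation problem sizes

The test suite validates each kernel against an independent oracle at sizes
chosen to be exhaustive where enumeration is feasible and seeded-random
elsewhere: the SSR scanner against a brute-force (start, period) scanner on
all 32,766 strings of length ≤ 14 over {A, T} plus 100 seeded 10 kb random
strings; event counting against a column classifier on all pairs of short
{A, C} strings plus 500 random pairs; the Fisher p against the
hypergeometric sum on every 2×2 table with total ≤ 40; the exact
Mann-Whitney against `wilcox.test` on all tie-free group sizes with
combined n ≤ 10. Parameter recovery runs 100 replicate genera (5 species,
40 loci, a 10-fold substitution-rate gradient, seeds 5001-5100) and checks
per-locus mean SV against the ledger expectation within 3 Monte-Carlo
standard errors, and gradient-rank recovery with Spearman rho ≥ 0.9; the
SC-vs-IR contrast is verified on 200 simulated genera at a planted 5× rate
ratio (seeds 7001-7200) and the GC-SV anticorrelation on 100 replicates
with GC planted against rate (seeds 8001-8100).

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 7, n_genera = 1, species_per_genus = 4)
cohort <- simulate_cohort(cfg)
res <- run_plastome_pipeline(
  cohort,
  pipeline_config(min_ir = 1000, ndh_reference = cohort$ledger$ndh_reference))
res$summary$pairs          # choose(4, 2) = 6 congeneric pairs
head(res$hotspots$GenusA)  # loci ranked by mean SV with SSR counts
res$tests                  # SC-vs-IR Mann-Whitney, GC-SV Spearman, Fisher
```

## Known limitations

* IR detection does not search across the sequence origin; plastome records
  conventionally start in the LSC, and the generator follows that
  convention.
* Trans-spliced genes (rps12) are treated as separate flank tokens.
* The SSR site-matching rule (motif + ordinal position) can over-merge
  sites when a locus gains a new upstream SSR of the same motif; with the
  planted densities used here this does not occur.
* Real-accession reproduction (published plastome lengths, IR lengths, GC
  values) requires the user to supply the GenBank records locally; the
  package performs no network access.
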