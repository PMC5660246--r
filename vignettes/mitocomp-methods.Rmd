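---
title: "Methods and design notes for mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` analyzes annotated insect mitochondrial genomes: composition and
strand skew, codon usage, gene-order rearrangement, gene overlaps and
non-coding architecture, substitution saturation, nonsynonymous divergence,
and phylogenetic dataset construction. This vignette records the methods, the
conventions where several were defensible, and the limits of what the test
suite demonstrates.

## Data model and coordinates

A genome is a circular J-strand sequence plus typed, stranded features.
Internally all coordinates are 0-based half-open on the J strand; conversion
to and from GenBank's 1-based inclusive convention happens only in the
GenBank reader/writer, so interval arithmetic on the circle never mixes
conventions. A feature that spans the origin carries two intervals in 5'→3'
J-strand order. Gene names are canonicalized through a bundled, editable
synonym table (`inst/extdata/gene_synonyms.tsv`); the two leucine and serine
tRNA copies are told apart by anticodon qualifier when the record has one,
otherwise by proximity to rrnL (trnL1) and nad3 (trnS1), flagged `inferred`.
Ambiguity codes other than N are mapped to N with a warning, because every
downstream statistic is defined over {A,C,G,T}.

## Composition and skew

AT skew = (A−T)/(A+T) and GC skew = (G−C)/(G+C); both are undefined (NA,
flagged) when the denominator is zero rather than silently 0. Per-region
profiles are computed on the J-strand slice for all genes, including N-strand
genes, so values are comparable across taxa regardless of which strand a gene
sits on; a `strand = "coding"` switch gives coding-strand profiles instead.
The "PCGs" region is the concatenation of the 13 CDS slices in genome order
with overlapping bases counted once per gene, as annotated — this matches how
per-region lengths are conventionally tabulated (the PCG total can exceed the
non-redundant footprint). Percentages print at one decimal, skews at three.

## Codon analysis

The genetic code is fixed to the invertebrate mitochondrial code
(transl_table 5, via `Biostrings::getGeneticCode("5")`): its only stops are
TAA and TAG, leaving 62 sense codons. Codons are read in frame from the
coding-sense CDS; the start codon is counted as its literal triplet; a
complete terminal stop is tallied separately and excluded from the total; an
incomplete stop is recognized purely from annotation arithmetic (CDS length
mod 3 ∈ {1,2} leaves a trailing `T`/`TA`), not by scanning for
polyadenylation signals. RSCU is computed over the concatenation of all 13
PCGs per genome — the genome-level convention — with RSCU 0 exactly for
unused codons and whole families flagged when their total usage is zero.
Whether start codons should be dropped from usage counts is genuinely open;
they are included by default with a `drop_first_codon` switch.

## Gene order and breakpoints

Gene order is the circular walk of the 37 genes (control region excluded) by
J-strand start, anchored at trnI; re-anchoring is a rotation. Two orders are
compared through strand-signed adjacencies: the adjacency (+a,+b) equals
(−b,−a) read on the other strand. The breakpoint count is the number of
observed adjacencies absent from the reference; it is symmetric, zero iff the
orders match up to rotation, and is checked against a brute-force adjacency
oracle in the tests. Differing blocks are maximal runs of genes incident to a
non-shared adjacency, which reports a rearranged cluster together with its
flanking genes; no rearrangement-scenario reconstruction (inversion/DCJ
sorting) is attempted, only the descriptive event. The reference arrangement
is the *Drosophila yakuba* order bundled as `inst/extdata/ancestral_order.tsv`.

## Junctions, control region, tandem repeats

Consecutive features around the circle either overlap (negative gap), abut,
or leave an intergenic spacer. Junctions involving the control region are
excluded from the spacer statistics and reported separately, since CR length
is tabulated on its own; with that convention, gene bp − overlap bp +
spacer bp + CR bp = genome length on a fully annotated genome (a conservation
law the tests check). An annotated control region takes precedence; otherwise
it is inferred as the span from rrnS end to trnI start (wrapping the origin
when needed), with a warning if a longer unannotated span exists elsewhere.

The tandem-repeat detector seeds candidate periods from exact k-mer matches
(k = 12 by default, shortened automatically for regions under 24 bp): two
occurrences of a k-mer at lag p propose period p. Around each seed the match
series s[i] = s[i+p] is extended to the maximal-scoring window (match +1,
mismatch −t/(1−t) for identity threshold t), which gives crisp boundaries
instead of creeping into flanking sequence. The window is then validated
against a per-column majority consensus; candidates whose period has a
divisor ≥ `min_period` that already explains the region are reduced to that
primitive period, so multiples are not reported; overlapping candidates are
resolved greedily by the score identity × copies × period, ties to the
smaller period. Defaults — min_period 10, min_copies 1.8, min_identity 0.80,
k 12 — approximate the defaults of the commonly used online repeat finder.
With k = 12, a random 1 kb sequence contains an exact repeated 12-mer only
rarely, which keeps the false-positive rate of the defaults below 5% (checked
over seeded trials); recovery of planted repeats with ≤5% per-base noise is
≥95% with the exact period (checked over 100 seeded plantings with period
20–300 and 2–5 copies). Fractional copies are reported rather than asserting
partial-copy boundaries, which are not well defined under noise.

## Distances and saturation

The p-distance uses pairwise deletion (columns with a gap or N in either
sequence are dropped), which maximizes usable sites in small taxon sets. The
GTR distance is the deterministic closed form: with F the symmetrized 4×4
matrix of site-pattern proportions and Π = diag of its marginals,
d = −tr(Π log(Π⁻¹F)). The matrix logarithm is taken by eigendecomposition of
the symmetric form Π^(−1/2) F Π^(−1/2), keeping everything in real
arithmetic; an eigenvalue at or below 1e−12 marks a saturated pair, returned
as a flagged NA, never an exception. When F is exactly JC-symmetric with
uniform frequencies the estimator reduces to −(3/4)·log(1 − (4/3)p) — the
tests verify this to 1e−6 — and on simulated GTR pairs it recovers the true
branch length with median relative error under 5% at 10 kb for t ∈ [0.05,
0.5]. No per-pair maximum-likelihood optimization is used: the closed form is
reproducible without an optimizer and is the standard pairwise GTR estimator.

Saturation is diagnosed per position class (codon positions pooled across all
PCGs; rRNAs pooled) by ordinary least squares of p-distance on GTR distance
with a free intercept — the common presentation for such plots; a
through-origin mode is available. The slope is the summary: near 1 at small
divergence, lower as observed differences plateau. Pairs with undefined GTR
distances are excluded and counted.

## Nonsynonymous divergence (Ka)

Ka follows Nei–Gojobori (1986) under transl_table 5. Per codon, the
synonymous site count at each position is the fraction of the three possible
changes that are synonymous, with mutations that create stop codons excluded
from the denominator (the original convention). Differences at codons with
2–3 changes are averaged over all orderings of single steps, excluding
pathways that pass through a stop codon (falling back to all pathways when
every ordering is blocked). pn = Nd/N is Jukes–Cantor corrected,
ka = −(3/4)·log(1 − (4/3)·pn), undefined at pn ≥ 3/4. Site and pathway
counts are verified against an independent exhaustive enumerator over all
codon pairs with ≤2 differences, and the statistic is symmetric in its
arguments. Ks and Ka/Ks are computed alongside but Ka is the headline value.
The helper `pair_pcg_concat()` concatenates the 13 PCGs of two genomes by
canonical name and requires equal per-gene lengths — real pairs should be
codon-aligned externally (multiple sequence alignment is deliberately outside
this package's scope).

## Datasets

`build_five_datasets()` produces P123 (13 PCGs, all codon positions), P12
(positions 1–2), P123R/P12R (rRNAs appended) and AA (translated). The
identities |P12| = (2/3)|P123|, |AA| = |P123|/3 and |P123R|−|P123| =
|P12R|−|P12| hold by construction and are asserted on arbitrary inputs.
Concatenation order is the order of the input list — phylogenetically
irrelevant but recorded in the charsets for reproducibility. Partition
schemes are written in two dialects: RAxML plain text (with `\3` stride
notation for codon positions) and a NEXUS SETS block. Model selection is out
of scope; partition files carry the scheme only. A permissive
`strip_gap_stop_columns()` removes all-gap and stop-bearing codon columns —
it is a simple cleaner, not a re-implementation of alignment-filtering tools.

## The simulator and what passing tests mean

`generate_genome()` realizes a declared architecture: the ancestral 37-gene
order (or any permutation), typical insect gene lengths, planted overlaps
(defaults: trnW–trnC 8 bp, atp8–atp6 7 bp, nad4–nad4l 7 bp), declared
start/stop codons (defaults: ATG with TTG for nad5; TAA stops with TAG for
nad5 and incomplete T for cox2 and nad1), a control region with a planted
tandem repeat (default 908 bp with a 239 bp unit at 657/239 ≈ 2.75 copies),
and composition targets (default A+T 0.78, AT skew +0.05, GC skew −0.20 on
the coding strand). Composition is met in expectation, not forced: CDS codons
are drawn from the 60 sense codons with probabilities proportional to
per-base frequencies, and those frequencies are inflated slightly (solved by
`uniroot`) to compensate for the A+T-rich stop codons being excluded —
without the compensation the realized genome runs about a point low. Planted
start/stop codons win inside overlap regions, and a repair pass mutates any
unlocked base whose planted neighbors would otherwise create an internal stop
in the partner gene's frame. All randomness flows from the spec's seed;
output is bit-reproducible.

CDS content is random stop-free codons — no real protein structure, no codon
bias beyond base composition, no indels (alignments are simulated gap-free),
no tRNA/rRNA secondary structure. Passing tests therefore demonstrate correct
bookkeeping, detection and estimation on data whose generating process is
known, not robustness to annotation errors, alignment artefacts or
compositional heterogeneity across a real tree.

`evolve_pair()`/`evolve_star()` simulate under an explicit GTR rate matrix
(six exchangeabilities, stationary frequencies, branch length in expected
substitutions/site, optional per-position rate multipliers such as (1,1,5)
for fast third positions). Descendants are drawn from exact transition
probabilities exp(Qt) computed by the reversible eigendecomposition — no
approximation in t. Codon mode rejects stop codons in ancestor and
descendant so output feeds Ka directly.

## Numerical choices and problem sizes

Eigenvalue positivity tolerance 1e−12; GTR distances need ≥4 comparable
sites; degenerate inputs (all-N regions, empty gene sets, ragged alignments,
overlaps longer than a gene) are hard errors with named genes. Test problem
sizes were chosen to make sampling error negligible relative to the asserted
tolerances while keeping the default suite quick: 10 kb pairs for
branch-length recovery, 3 kb star alignments for saturation ordering, 400 bp
pairs for the 1,000-pair correction-inequality sweep, 100 seeded plantings
for repeat recovery, full 15.4 kb genomes for architecture bookkeeping.

## Known limitations

* No de novo annotation: unannotated genes are not discovered, only an
  unannotated control region is inferred.
* Analyses that require multiple sequence alignment consume pre-aligned
  matrices; the bundled alignment script (mafft-based, no column filtering)
  approximates but does not reproduce pipelines that filter ambiguous blocks,
  so dataset column counts from public records match published ones only
  approximately.
* The breakpoint report is descriptive; it does not reconstruct the sequence
  of rearrangement events.
* The GTR distance assumes stationarity and reversibility; strongly
  non-stationary composition across taxa will bias it like any such
  estimator.
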