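---
title: "Methods: survey statistics for repeat-rich genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey statistics for repeat-rich genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesurvey)
```

genomesurvey characterizes large, repeat-rich genomes at the survey stage,
before (or instead of) a contiguous assembly: how big is the genome, how deep
was it sequenced, how much of it is repetitive, where are the tandem repeats
and nuclear mitochondrial insertions (NUMTs), which genes can be carried over
from a well-annotated relative, and how conserved is gene order against that
relative. The motivating use case is an orchid-bee-sized insect genome
(several Gb, mostly repeats) sequenced with short reads and annotated by
homology to the honey bee; every stage, however, is generic.

This vignette records the models behind each stage, the tunable parameters
with their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The k-mer survey

For reads of length $L$ and k-mer length $K$ (default $K = 25$), each read
contributes $L - K + 1$ k-mer observations. The frequency spectrum maps each
occurrence frequency $f$ to the number of distinct k-mers seen exactly $f$
times. K-mers are counted in canonical form (the lexicographic minimum of a
k-mer and its reverse complement): reads come from both strands, and without
strand collapsing the single-copy peak splits. Windows containing ambiguous
residues are skipped.

Genome size follows the read-mass identity

$$G = \frac{N\,(L - K + 1) - B}{D},$$

with $N$ the total read count, $B$ the k-mer observations at frequencies at
or below the error cutoff (default 3), and $D$ the k-mer depth. Two unit
conventions are possible for $B$; we count *observations*
($\sum_{f \le c} f \cdot n_f$), not distinct k-mers, because the numerator
$N(L-K+1)$ is in observation units. Mean per-base coverage is
$C = \sum_i R_i L_i / G$ over libraries $i$.

**Depth estimation.** $D$ is the primary non-error peak of the spectrum. Two
numerical details matter at survey scale:

* Adjacent k-mers share coverage windows almost entirely, so spectrum bins
  fluctuate far more than multinomial sampling would suggest (the effective
  number of independent depth draws is roughly genome length over
  $L - K + 1$). `estimate_depth()` therefore locates the peak on a
  triangularly smoothed spectrum (kernel half-width 2 by default;
  `smooth = 0` restores the raw argmax). Ties break toward the smaller
  frequency.
* The true per-copy depth $C\,(L-K+1)/L$ is generally not an integer (20x
  coverage with $L = 100$, $K = 25$ gives 15.2), and an integer divisor
  quantizes $G$ in steps of $\sim 1/D$. `estimate_genome_size()` therefore
  divides by a refined fractional depth: the observation-weighted mean
  frequency inside the peak window $[m/1.5,\ 1.5m]$, where $m$ is the integer
  mode. The refinement is insensitive to the mode flickering between
  adjacent frequencies and removes the quantization bias; both values are
  reported (`D`, `D_refined`).

**Spectrum repeat fraction.** The repetitive fraction is the share of
non-error observation mass at frequencies above `repeat_multiplier` times
$D$ (default 1.5, exposed as a flag): k-mers seen much more often than the
single-copy peak come from multi-copy sequence. The rule is deliberately
simple — no mixture fitting, no heterozygosity model — and is non-increasing
in the multiplier. Poisson tail mass from single-copy k-mers leaks above
$1.5D$ at survey depths, so the estimate carries an upward bias of a few
percentage points; recovery tests on planted-repeat genomes bound it at
under ten points.

The spectrum builder holds one 64-bit word per distinct k-mer
(hash map), comfortable for desk-scale inputs up to $\sim 10^8$ observations;
disk-backed counting is out of scope.

## Tandem repeats

Micro- (unit 1–6 bp) and minisatellites (unit 7 bp and up) are detected on
the *lag-u self-comparison*: position $j$ scores $+1$ if it equals position
$j - u$ and $-4$ otherwise, so a perfect repeat of total length $\ell$ and
unit $u$ scores $\ell - u$. A locus must span at least two units and reach
the minimum score 12. The reported locus set is defined greedily: repeatedly
accept the highest-scoring remaining candidate over all units, discarding
everything that overlaps it, with ties resolved toward the shorter unit, then
the smaller start, then the smaller end. The scanner implements this with
per-unit segment lists and a min-length-constrained maximum-subarray search;
an exhaustive oracle that scores every `(start, end, unit)` triple verifies
exact equivalence in the test suite.

Design choices:

* **Ungapped scoring.** A single-residue indel permanently shifts the phase
  of a fixed-lag comparison, so "gap" events are not expressible in this
  scoring without a different alignment recursion. The scan is mismatch-only
  and `n_gaps` is always 0; the gap penalty (−4) remains in the interface
  for compatibility with the conventional parameterization.
* **Harmonics.** A perfect dinucleotide array also scores at lags 4, 6, 8…
  Within one scan the greedy rule resolves this (the shortest unit scores
  highest); across class scans, a locus whose leading unit has a minimal
  period below the scanned range is suppressed, so the minisatellite run does
  not re-report microsatellites.
* **Unit bound.** The minisatellite upper bound defaults to 100 bp
  (configurable to 1000): cost grows with the number of lags, and units
  beyond 100 bp are vanishingly rare at survey scale.
* **Motifs** are normalized to the lexicographically minimal rotation, so
  rotated occurrences of one motif coalesce.
* Maximality is greedy-maximal: extending an accepted locus in either
  direction lowers its score.

Summaries merge overlapping loci before length accounting and exclude
ambiguous-residue stretches from the assembly denominator, matching the
usual reporting convention for repeat content tables.

## Gene-annotation decision rules

The package implements the decision layer of a homology-first annotation
pipeline; spliced alignment and ab initio prediction engines are inputs, not
components.

1. **Hit filtering** (`filter_protein_hits()`): a donor protein is carried
   forward iff it has a hit with E-value ≤ 1e−4 covering ≥ 50% of the
   protein. Both boundaries are inclusive.
2. **Two-round selection** (`select_homology_models()`): per query, the
   best-scoring candidate model with similarity ≥ 0.35; failing that, a
   relaxed round at ≥ 0.15; failing both, unannotated. Every query lands in
   exactly one class.
3. **Overlap resolution** (`resolve_overlaps()`): within each connected
   component of same-strand, span-overlapping models, one survivor — maximum
   score, ties to the longer span, then the lexicographic id. Opposite
   strands never compete.
4. **De novo complement** (`merge_denovo()`): predictions supported by both
   predictors (operationalized as reciprocal span overlap ≥ 0.5 on the same
   strand — the conventional reciprocal-overlap reading of "predicted by
   both programs"), minus pairs with coding-sequence identity ≥ 0.85
   (computed as $1 - \text{Levenshtein}/\max(\text{lengths})$, i.e. global
   alignment with unit costs), appended where they overlap no homology model
   on either strand. The similarity filter removes *both* members of a pair
   (its purpose is to purge unmasked transposon-derived predictions, and
   either member may be the offender); `keep_one = TRUE` keeps the longest
   coding sequence per similar group for users who prefer a representative.

## NUMTs and repeat content

NUMT scans are blastn-style hit tables filtered at E ≤ 1e−4; overlapping
hits on a scaffold merge into fragments, with fragment identity averaged
across merged hits weighted by hit length (unweighted averaging is a flag).
Reported: fragment count, scaffold count, total and mean length, mean
identity, and the fraction of the non-ambiguous assembly covered.

Repeat-element annotations aggregate into a per-class content table
(retrotransposons, DNA transposons, unclassified, with classified subtotal
and total): family counts from the catalog, element counts and
overlap-merged cumulative lengths from the annotations, percentages over the
non-ambiguous assembly length, family/element shares rounded to one decimal.
Class lengths are merged within class and summed across classes, so
classified + unclassified = total by construction.

The read-based repeat fraction treats each high-copy contig (a collapsed
repeat consensus) as representing $\ell_i d_i / C$ genomic base pairs, where
$\ell_i$ is contig length, $d_i$ its mean mapped depth and $C$ genome-wide
coverage; the fraction is the normalized sum over the estimated genome size.
Only contigs with $d_i \ge m C$ are counted, default $m = C$ — the
squared-coverage minimum frequency convention (400x at 20x coverage). The
normalization sentence this implements can also be read literally as
$d_i/(\ell_i C)$, which has inconsistent units; that variant is available
behind `literal_formula = TRUE` for comparison only.

## Synteny haplotype blocks

Inputs are gene placements on query scaffolds and an ortholog map to a
reference with linkage-group (LG) labels. Three filters apply, each
evaluated on the *original* map so the retained set is order-independent
(sequential re-evaluation would not be: removing an unknown-LG record can
"un-duplicate" a query): scaffolds ≥ 100 kb; genes homologous to multiple
locations in either species removed; unknown-LG records removed. On each
scaffold, maximal runs of adjacent retained genes sharing a target LG become
blocks spanning first-gene start to last-gene end (intergenic DNA included);
blocks need ≥ 2 genes and ≥ 1 kb. Genes removed by the filters are
transparent to adjacency; a retained gene targeting a different LG breaks
the run. Within-block collinearity and orientation are not enforced — the
procedure checks shared location, not gene order, matching its purpose of
measuring chromosome-scale conservation.

A scaffold's synteny fraction is block base pairs on the modal LG over total
block base pairs (ties: more genes, then lexicographic), syntenic iff
≥ 0.95, threshold inclusive. Gene-count or scaffold-length denominators are
plausible alternatives; block-bp was chosen because the blocks are the
objects the procedure constructs, and the summary reports total block bp
against filtered scaffold length separately.

## Mitogenome completeness

Transcript scaffolds are screened by hit tables at E ≤ 1e−12 (the stringent
cutoff conventional for blastx screens against a mitogenome). Gene order is
checked against a circular reference order: a scaffold is consistent iff its
genes, in positional order, form a contiguous subsequence of the reference
circle read in either direction with strands matching under that direction.
Completeness is annotated base pairs over the reference total length. The
reference length is a user input: the package default is the summed gene
lengths of the bundled reference order, a lower bound that ignores the
control region, and users with a species estimate should supply it. The
bundled `mito_gene_order_synthetic.tsv` is a constructed hymenopteran-like
37-gene order (13 protein-coding, 22 tRNA, 2 rRNA) with approximate lengths
— a synthetic stand-in sufficient for order and inventory checks, not a
curated annotation.

## The synthetic-data generator

Every stage is exercised end to end on generated data with exact ground
truth: a background genome of configurable length and GC (default 40%, a
bee-like value), interspersed repeat families (consensus plus binomially
substituted copies at the stated divergence), tandem arrays, NUMT fragments
drawn from a generated AT-rich mitogenome and mutated to a target identity
in 85–99%, and non-overlapping multi-exon gene models. Placement distributes
the free space uniformly over the gaps between features, so truth tables
describe the emitted sequence exactly. Reads are single-end with i.i.d.
substitution errors and no indels — the spectrum estimator treats errors
via low-frequency k-mers regardless of error type, and no stage here
consumes pairing or indel structure. The homologous-pair generator labels
every ortholog with a linkage group and injects translocations (single-gene
and two-gene segment), inversions, multi-homolog duplicates and unknown-LG
records, recording the implied true block decomposition.

What the generator does *not* emulate, and hence what passing tests do not
show about real data: position- and context-dependent sequencing error,
coverage biases (GC, mappability), heterozygosity, nested or diverged repeat
structures that defeat unique k-mer anchoring, assembly fragmentation, and
alignment-tool artifacts in the hit tables it fabricates.

## Problem sizes and determinism

The bundled tests and the acceptance script run genomes of 50–120 kb at 20x
coverage (1.5–2.4 million k-mer observations), 2 kb sequences against the
exhaustive tandem oracle, and 10-scaffold homolog pairs — sizes chosen so
the full suite completes in a few minutes on one core while leaving every
estimator in its intended operating regime (peak depth ≈ 15, hundreds of
independent coverage windows per scaffold). All generators take explicit
seeds and are bit-reproducible; the pipeline derives per-stage seeds from
one master seed.

## Known limitations

* The genome-size identity assumes one dominant single-copy peak; highly
  heterozygous or extremely repeat-dominated spectra (where the error and
  repeat mass swamp the peak) need model-based spectrum fitting, which is
  out of scope.
* The tandem scanner's greedy selection is locally optimal per conflict, not
  a global maximum-weight interval packing (the two differ only in
  contrived overlap chains); gapped repeat arrays are reported as split or
  truncated loci.
* Identity from `pident` columns inherits the emitting aligner's rounding.
* The circular order check treats gene names as atomic; duplicated gene
  names in a reference would need disambiguation.
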