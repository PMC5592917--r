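# genomesurvey

Survey-level characterization of large, repeat-rich genomes from short reads
and standard annotation tables — the statistics a genome report leans on
before a contiguous assembly exists. The package grew out of the survey
workflow for multi-gigabase, highly repetitive insect genomes (orchid bees
are the archetype: ~3 Gb, mostly repeats, annotated by homology to the honey
bee), but every stage is generic:

* **k-mer survey** — canonical k-mer frequency spectrum from reads; genome
  size by the read-mass identity `G = (N·(L−K+1) − B) / D`, where `N` is the
  read count, `L` the read length, `K` the k-mer length (default 25), `B`
  the error-attributed low-frequency observation mass (frequency ≤ 3) and
  `D` the k-mer depth at the spectrum's single-copy peak; mean coverage
  `C = Σ Ri·Li / G`; spectrum-based repeat fraction (observation mass above
  `1.5·D`).
* **tandem repeats** — Phobos-style micro/minisatellite scanner on the lag-u
  self-comparison (match +1, mismatch −4, minimum score 12; a perfect repeat
  of length ℓ and unit u scores ℓ − u), verified against an exhaustive
  oracle; merged-length summaries excluding ambiguous stretches.
* **gene annotation rules** — the decision layer of a homology-first
  pipeline: E ≤ 1e−4 with ≥ 50% query coverage, two-round similarity
  selection (0.35 then 0.15), same-strand overlap resolution, and a de novo
  complement with consensus-of-two-predictors and ≥ 85% pairwise-similarity
  purging.
* **NUMTs and repeat content** — merged nuclear-mitochondrial fragment
  summaries (E ≤ 1e−4), a per-class repeat content table, and the
  coverage-normalized read-based repeat fraction (`Σ ℓi·di/C / G` over
  contigs with depth ≥ C², the squared-coverage minimum frequency).
* **synteny** — haplotype blocks from ortholog gene order (scaffolds
  ≥ 100 kb, blocks ≥ 1 kb with ≥ 2 adjacent genes sharing a linkage group),
  per-scaffold synteny fractions with a 95% threshold.
* **mitogenome checks** — circular gene-order consistency and completeness
  against a reference gene order.
* **synthetic data** — generators for genomes with planted repeat families,
  tandem arrays, NUMT insertions, gene models, uniform-coverage reads, and
  homologous genome pairs with known rearrangements, all with exact ground
  truth, so the whole pipeline is testable end to end.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on spectra and content tables.

## Worked example

Generate a 100 kb genome that is 30% two-copy repeat with ten planted
(AG)₁₂ microsatellites, sequence it to 20x in silico, and survey it:

```r
library(genomesurvey)

spec <- genome_spec(
  genome_length   = 100000,
  repeat_families = tibble::tibble(family_id = "fam_1", unit_length = 15000,
                                   copy_number = 2, divergence = 0),
  tandem_specs    = tibble::tibble(motif = "AG", n_units = 12, n_loci = 10),
  seed = 1)
gen   <- generate_genome(spec)
reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 100, seed = 2)

kmer_survey(reads)
#> k-mer survey estimates (k = 25 )
#>   reads N = 20000, mean length L = 100.0
#>   error mass B = 33 (frequency <= 3)
#>   k-mer depth D = 15 (refined 15.45)
#>   genome size G = 98366 bp
#>   mean coverage C = 20.33 x
#>   spectrum repeat fraction = 0.326

loci <- find_tandem_repeats(gen$sequences, unit_range = c(1, 6))
summarize_tandem_repeats(loci, gen$sequences)
#> tandem-repeat summary
#> # A tibble: 2 × 3
#>   class n_loci total_bp
#>   <chr>  <int>    <dbl>
#> 1 micro     10      245
#> 2 mini       0        0
#>   combined 245 bp / 100000 non-ambiguous bp = 0.0024 (0.24%)
```

Reading the output: the reads contain 20,000 × 76 k-mer observations; the
single-copy peak sits at depth 15 (true k-mer depth is 20 × 76/100 = 15.2,
and the fractional refinement lands at 15.45), giving a genome size within
2% of the 100,000 bp truth. The spectrum repeat fraction (0.326) recovers
the planted 30% two-copy content plus a small Poisson-tail bias. All ten
planted microsatellite arrays are found, 245 bp after boundary-maximal
extension, 0.24% of the genome.

`run_survey(survey_config(seed = 1))` chains every stage on one synthetic
genome and returns a printable report; `write_survey_report()` emits it as
JSON plus TSV tables. A thin command-line front end ships in
`inst/scripts/survey.R` (`run`, `stats`, `kmer`, `tandem` subcommands).

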