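test_that("a featureless spec yields pure background and empty truth tables", {
  spec <- genome_spec(genome_length = 5000, seed = 42)
  gen <- generate_genome(spec)
  expect_equal(sum(nchar(as.character(gen$sequences))), 5000)
  expect_equal(nrow(gen$truth$repeats), 0)
  expect_equal(nrow(gen$truth$tandems), 0)
  expect_equal(nrow(gen$truth$numts), 0)
  expect_equal(nrow(gen$truth$genes), 0)
})

test_that("zero-divergence repeat copies are exact and retrievable by string search", {
  spec <- genome_spec(
    genome_length = 80000,
    repeat_families = tibble::tibble(family_id = "famA", unit_length = 500,
                                     copy_number = 100, divergence = 0),
    seed = 9)
  gen <- generate_genome(spec)
  truth <- gen$truth
  expect_equal(nrow(truth$repeats), 100)
  genome <- as.character(gen$sequences)[[1]]
  cons <- truth$consensus[["famA"]]
  copies <- substring(genome, truth$repeats$start + 1, truth$repeats$end)
  expect_true(all(copies == cons))
  # independent oracle: exact substring search over the emitted genome
  n_found <- Biostrings::countPattern(cons, Biostrings::DNAString(genome))
  expect_equal(n_found, 100)
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- genome_spec(
    genome_length = 30000,
    repeat_families = tibble::tibble(family_id = "f", unit_length = 200,
                                     copy_number = 10, divergence = 0.05),
    tandem_specs = tibble::tibble(motif = "AG", n_units = 10, n_loci = 5),
    numt_spec = list(mito_length = 3000, n_insertions = 3,
                     identity_range = c(0.85, 0.99)),
    gene_spec = list(n_genes = 5),
    seed = 77)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$truth$repeats, g2$truth$repeats)
  expect_identical(g1$truth$numts, g2$truth$numts)
})

test_that("truth tables exactly describe the emitted sequence", {
  spec <- genome_spec(
    genome_length = 40000,
    tandem_specs = tibble::tibble(motif = "ACG", n_units = 8, n_loci = 6),
    numt_spec = list(mito_length = 4000, n_insertions = 4,
                     identity_range = c(0.88, 0.98)),
    seed = 5)
  gen <- generate_genome(spec)
  genome <- as.character(gen$sequences)[[1]]
  # tandem placements contain the motif array
  for (i in seq_len(nrow(gen$truth$tandems))) {
    tr <- gen$truth$tandems[i, ]
    arr <- substring(genome, tr$start + 1, tr$end)
    expect_equal(nchar(arr), 24)
    expect_true(grepl("^(ACG|CGA|GAC)+$", arr))
  }
  # NUMT realized identity equals the recorded identity
  for (i in seq_len(nrow(gen$truth$numts))) {
    nm <- gen$truth$numts[i, ]
    frag <- substring(genome, nm$start + 1, nm$end)
    ref <- substring(gen$truth$mito_sequence, nm$mito_start + 1, nm$mito_end)
    mism <- sum(strsplit(frag, "")[[1]] != strsplit(ref, "")[[1]])
    expect_equal(1 - mism / nchar(ref), nm$identity, tolerance = 1e-12)
    expect_gte(nm$identity, 0.85)
  }
})

test_that("infeasible packing is rejected with a sizing message", {
  spec <- genome_spec(
    genome_length = 1000,
    repeat_families = tibble::tibble(family_id = "f", unit_length = 500,
                                     copy_number = 10, divergence = 0))
  expect_error(generate_genome(spec), "exceed genome length")
})

test_that("read count matches the coverage arithmetic", {
  gen <- generate_genome(genome_spec(genome_length = 10000, seed = 1))
  reads <- simulate_reads(gen$sequences, coverage = 10, read_length = 100,
                          seed = 2)
  expect_equal(nrow(reads), 1000)
})

test_that("error-free reads are exact substrings of their template", {
  gen <- generate_genome(genome_spec(genome_length = 20000, seed = 3))
  genome <- as.character(gen$sequences)[[1]]
  reads <- simulate_reads(gen$sequences, coverage = 5, read_length = 80,
                          error_rate = 0, seed = 4)
  templ <- substring(genome, reads$start + 1, reads$start + 80)
  expect_true(all(reads$sequence == templ))
})

test_that("injected substitution rate matches the binomial expectation", {
  gen <- generate_genome(genome_spec(genome_length = 50000, seed = 6))
  genome <- as.character(gen$sequences)[[1]]
  reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 100,
                          error_rate = 0.01, seed = 7)
  total <- sum(nchar(reads$sequence))
  expect_gte(total, 1e6)
  templ <- substring(genome, reads$start + 1, reads$start + 100)
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$sequence, templ))
  p_hat <- mism / total
  sd3 <- 3 * sqrt(0.01 * 0.99 / total)
  expect_lt(abs(p_hat - 0.01), sd3)
})

test_that("overlong reads are rejected naming the offending sequence", {
  expect_error(simulate_reads(c(tiny = "ACGTACGT"), coverage = 1,
                              read_length = 100),
               "tiny")
})

test_that("zero rearrangements give one truth block per scaffold spanning all genes", {
  pair <- generate_homolog_pair(n_scaffolds = 5, genes_per_scaffold = 6,
                                seed = 10)
  expect_equal(nrow(pair$truth_blocks), 5)
  expect_equal(unique(pair$truth_blocks$n_genes), 6)
  spans <- pair$genes_a |>
    dplyr::group_by(scaffold) |>
    dplyr::summarise(start = min(start), end = max(end), .groups = "drop")
  joined <- dplyr::inner_join(spans, pair$truth_blocks, by = "scaffold")
  expect_equal(joined$start.x, joined$start.y)
  expect_equal(joined$end.x, joined$end.y)
})

test_that("a translocated gene splits its scaffold's truth blocks per the run structure", {
  # hand-built 5-gene case: the middle gene moves to another linkage group,
  # leaving two 2-gene runs -> two truth blocks
  pair <- generate_homolog_pair(n_scaffolds = 2, genes_per_scaffold = 5,
                                seed = 11)
  orth <- pair$orthologs
  mid <- pair$genes_a |>
    dplyr::filter(scaffold == "scfA_01") |>
    dplyr::arrange(start) |>
    dplyr::slice(3) |>
    dplyr::pull(gene_id)
  orth$target_lg[orth$query_gene == mid] <- "LG2"
  orth$target_scaffold[orth$query_gene == mid] <- "LG2"
  f <- filter_synteny_inputs(pair$genes_a, orth, pair$scaffold_lengths,
                             min_scaffold_len = 50000)
  b <- build_blocks(f)
  expect_equal(sum(b$scaffold == "scfA_01"), 2)
  expect_equal(b$n_genes[b$scaffold == "scfA_01"], c(2, 2))

  # generator translocations: truth blocks per scaffold equal an independent
  # run-length recount of the retained target linkage groups
  pair2 <- generate_homolog_pair(n_scaffolds = 3, genes_per_scaffold = 5,
                                 rearrangements = list(n_translocations = 1),
                                 seed = 11)
  retained <- pair2$orthologs |>
    dplyr::group_by(query_gene) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::filter(target_lg != "unknown")
  placed <- pair2$genes_a |>
    dplyr::inner_join(retained, by = c(gene_id = "query_gene")) |>
    dplyr::arrange(scaffold, start)
  expected <- placed |>
    dplyr::group_by(scaffold) |>
    dplyr::summarise(n_blocks = sum(rle(target_lg)$lengths >= 2),
                     .groups = "drop")
  got <- dplyr::count(pair2$truth_blocks, scaffold, name = "n_blocks")
  merged <- dplyr::left_join(expected, got, by = "scaffold")
  expect_equal(tidyr::replace_na(merged$n_blocks.y, 0L), merged$n_blocks.x)
})

test_that("unknown-linkage-group labelling is exact bookkeeping", {
  pair <- generate_homolog_pair(rearrangements = list(n_unknown_lg = 4),
                                seed = 12)
  expect_equal(sum(pair$orthologs$target_lg == "unknown"), 4)
})

test_that("hit tables carry one record per true placement with identities in range", {
  spec <- genome_spec(genome_length = 60000,
                      numt_spec = list(mito_length = 5000, n_insertions = 5,
                                       identity_range = c(0.85, 0.99)),
                      seed = 13)
  gen <- generate_genome(spec)
  hits <- emit_hit_tables(gen$truth, seed = 14)
  expect_equal(nrow(hits$numt_hits), 5)
  expect_true(all(hits$numt_hits$pident >= 85 - 1 &
                    hits$numt_hits$pident <= 99 + 1))
  expect_true(all(hits$numt_hits$evalue <= 1e-30))
})

test_that("empty truth yields header-only hit tables", {
  gen <- generate_genome(genome_spec(genome_length = 2000, seed = 15))
  hits <- emit_hit_tables(gen$truth, seed = 16)
  expect_equal(nrow(hits$numt_hits), 0)
  expect_equal(nrow(hits$protein_hits), 0)
  expect_named(hits$numt_hits,
               c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore", "qcovs"))
})
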