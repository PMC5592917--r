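#' Survey pipeline configuration
#'
#' Collects every stage parameter with the survey defaults: k-mer length 25
#' with error-frequency cutoff 3 and repeat multiplier 1.5; tandem scoring
#' match +1 / mismatch -4 / gap -4 with minimum score 12, unit classes 1-6
#' and 7-100; annotation E-value cutoff 1e-4, minimum query coverage 0.5,
#' similarity rounds 0.35 and 0.15, de novo pairwise-similarity cutoff 0.85;
#' NUMT E-value cutoff 1e-4; mitogenome screen E-value cutoff 1e-12; synteny
#' scaffold/block minima 100 kb / 1 kb with syntenic threshold 0.95.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param ... Named overrides for any default listed above (see
#'   `survey_config_defaults()` in the source for the full set).
#' @return A `survey_config` list.
#' @export
survey_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = 120000, gc_fraction = 0.40,
    repeat_unit_length = 600, repeat_copy_number = 50, repeat_divergence = 0.02,
    tandem_motif = "AG", tandem_n_units = 15, tandem_n_loci = 20,
    mito_length = 8000, numt_insertions = 6, numt_identity = c(0.85, 0.95),
    numt_decoys = 8,
    n_genes = 25,
    coverage = 20, read_length = 100, error_rate = 0,
    k = 25, error_cutoff = 3, repeat_multiplier = 1.5,
    tandem_micro = c(1, 6), tandem_mini = c(7, 100),
    tandem_match = 1, tandem_mismatch = -4, tandem_gap = -4,
    tandem_min_score = 12,
    e_max = 1e-4, min_query_cov = 0.5, round1 = 0.35, round2 = 0.15,
    max_pairwise_similarity = 0.85,
    mito_e_max = 1e-12,
    min_scaffold_len = 100000, min_block_len = 1000,
    synteny_threshold = 0.95)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) abort(paste("unknown config fields:", paste(bad, collapse = ", ")))
  cfg[names(override)] <- override
  structure(cfg, class = "survey_config")
}

#' Run the full genome survey on a synthetic genome
#'
#' Generates a genome with known ground truth from the configuration,
#' simulates reads, and runs every survey stage in dependency order: assembly
#' statistics, the k-mer survey, tandem-repeat scan, gene-annotation decision
#' rules, NUMT summary, repeat-content aggregation with the read-based
#' repeat fraction, synteny haplotype blocks on a generated homologous
#' genome pair, and the mitogenome completeness check. Deterministic for a
#' fixed config seed.
#'
#' @param config A [survey_config()].
#' @return A `survey_report` list with one section per stage plus the truth
#'   tables used.
#' @export
run_survey <- function(config = survey_config()) {
  stopifnot(inherits(config, "survey_config"))
  seeds <- config$seed + seq_len(9)

  spec <- genome_spec(
    genome_length = config$genome_length, gc_fraction = config$gc_fraction,
    repeat_families = tibble(family_id = "fam_1",
                             unit_length = config$repeat_unit_length,
                             copy_number = config$repeat_copy_number,
                             divergence = config$repeat_divergence),
    tandem_specs = tibble(motif = config$tandem_motif,
                          n_units = config$tandem_n_units,
                          n_loci = config$tandem_n_loci),
    numt_spec = list(mito_length = config$mito_length,
                     n_insertions = config$numt_insertions,
                     identity_range = config$numt_identity),
    gene_spec = list(n_genes = config$n_genes),
    seed = seeds[1])
  gen <- generate_genome(spec)
  reads <- simulate_reads(gen$sequences, coverage = config$coverage,
                          read_length = config$read_length,
                          error_rate = config$error_rate, seed = seeds[2])

  stats <- assembly_stats(gen$sequences)
  survey <- kmer_survey(reads, k = config$k, error_cutoff = config$error_cutoff,
                        repeat_multiplier = config$repeat_multiplier)

  loci <- bind_rows(
    find_tandem_repeats(gen$sequences, unit_range = config$tandem_micro,
                        match = config$tandem_match,
                        mismatch = config$tandem_mismatch,
                        gap = config$tandem_gap,
                        min_score = config$tandem_min_score),
    find_tandem_repeats(gen$sequences, unit_range = config$tandem_mini,
                        match = config$tandem_match,
                        mismatch = config$tandem_mismatch,
                        gap = config$tandem_gap,
                        min_score = config$tandem_min_score))
  tandem <- summarize_tandem_repeats(loci, gen$sequences)

  hits <- emit_hit_tables(gen$truth,
                          noise = list(n_decoys = config$numt_decoys),
                          seed = seeds[3])
  candidates <- emit_candidate_models(gen$truth,
                                      similarity_range = c(0.1, 0.95),
                                      seed = seeds[4])
  retained <- filter_protein_hits(hits$protein_hits, e_max = config$e_max,
                                  min_query_cov = config$min_query_cov)
  selection <- select_homology_models(
    candidates[candidates$query %in% retained$query, , drop = FALSE],
    round1 = config$round1, round2 = config$round2)
  accepted <- selection[!is.na(selection$model_id), , drop = FALSE]
  homology <- resolve_overlaps(accepted)
  ogs <- merge_denovo(
    denovo_predictions(gen, n = 4, seed = seeds[5], jitter = 0),
    denovo_predictions(gen, n = 4, seed = seeds[5], jitter = 25),
    homology,
    min_reciprocal_overlap = 0.5,
    max_pairwise_similarity = config$max_pairwise_similarity)
  annotation <- list(
    n_queries = nrow(candidates) |> max(0L),
    n_retained = nrow(retained),
    selection = selection,
    stats = ogs_stats(ogs, donor_set_size = config$n_genes))

  numt <- summarize_numts(hits$numt_hits, gen$sequences, e_max = config$e_max)

  fam_catalog <- tibble(family_id = "fam_1", class = "unclassified")
  repeat_table <- aggregate_repeat_annotations(
    gen$truth$repeats |> mutate(family_id = .data$family_id),
    fam_catalog, gen$sequences)
  profiles <- repeat_profiles_from_truth(gen$truth, coverage = survey$C,
                                         seed = seeds[6])
  read_repeat_fraction <- estimate_read_repeat_fraction(
    profiles, mean_coverage = survey$C, genome_size = gen$truth$genome_length)

  pair <- generate_homolog_pair(
    rearrangements = list(n_translocations = 1, n_multi_homologs = 2,
                          n_unknown_lg = 2),
    seed = seeds[7])
  filtered <- filter_synteny_inputs(pair$genes_a, pair$orthologs,
                                    pair$scaffold_lengths,
                                    min_scaffold_len = config$min_scaffold_len)
  blocks <- build_blocks(filtered, min_block_len = config$min_block_len)
  reports <- score_scaffold_synteny(blocks,
                                    threshold = config$synteny_threshold)
  synteny <- list(blocks = blocks, reports = reports,
                  summary = summarize_synteny(
                    reports,
                    pair$scaffold_lengths[
                      pair$scaffold_lengths$length >= config$min_scaffold_len, ]))

  reference <- read_mito_reference()
  mito_ann <- mito_transcript_annotations(reference, n_scaffolds = 4,
                                          target_completeness = 0.75)
  mito <- mito_completeness(mito_ann, reference)

  structure(
    list(config = config, truth = gen$truth, assembly = stats,
         kmer = survey, tandem = tandem, annotation = annotation,
         numt = numt, repeats = list(table = repeat_table,
                                     read_repeat_fraction = read_repeat_fraction),
         synteny = synteny, mito = mito),
    class = "survey_report")
}

# Collapsed repeat-contig depth profiles implied by the truth tables: one
# contig per repeat family (the consensus), depth = coverage x copy number
# with Poisson counting noise, plus one single-copy background contig.
repeat_profiles_from_truth <- function(truth, coverage, seed = 1L) {
  set.seed(seed)
  fams <- unique(truth$repeats$family_id)
  rows <- lapply(fams, function(f) {
    sub <- truth$repeats[truth$repeats$family_id == f, ]
    unit <- round(mean(sub$end - sub$start))
    copies <- nrow(sub)
    bases <- stats::rpois(1, coverage * copies * unit)
    tibble(contig = f, length = unit, mean_depth = bases / unit)
  })
  bind_rows(
    bind_rows(rows),
    tibble(contig = "background", length = 5000,
           mean_depth = stats::rpois(1, coverage * 5000) / 5000))
}

# Deterministic transcript-scaffold annotations: the circular reference is
# cut into n_scaffolds contiguous runs and genes are dropped from the tail
# of each run until roughly target_completeness of the reference gene bases
# remain.
mito_transcript_annotations <- function(reference, n_scaffolds = 4,
                                        target_completeness = 0.75) {
  n <- nrow(reference)
  bounds <- floor(seq(0, n, length.out = n_scaffolds + 1))
  rows <- list()
  for (s in seq_len(n_scaffolds)) {
    idx <- (bounds[s] + 1):bounds[s + 1]
    rows[[s]] <- reference[idx, , drop = FALSE] |>
      mutate(scaffold = sprintf("transcript_%d", s))
  }
  ann <- bind_rows(rows)
  total <- sum(reference$length)
  # trim genes from scaffold run ends (keeping each run contiguous in the
  # circular order) until ~target_completeness of reference bases remain
  repeat {
    if (sum(ann$length) <= target_completeness * total) break
    by_scf <- split(seq_len(nrow(ann)), ann$scaffold)
    by_scf <- by_scf[vapply(by_scf, length, integer(1)) > 1]
    if (length(by_scf) == 0) break
    tot <- vapply(by_scf, function(i) sum(ann$length[i]), numeric(1))
    drop_idx <- by_scf[[which.max(tot)]]
    ann <- ann[-drop_idx[length(drop_idx)], , drop = FALSE]
  }
  ann |>
    group_by(.data$scaffold) |>
    mutate(start = cumsum(dplyr::lag(.data$length, default = 0L)),
           end = .data$start + .data$length) |>
    ungroup() |>
    select("scaffold", "gene", "start", "end", "strand")
}

# paired de novo gene predictions derived from truth genes plus TE-like
# decoy pairs with near-identical coding sequence in gene-free space
denovo_predictions <- function(gen, n = 4, seed = 1L, jitter = 0) {
  set.seed(seed)
  truth <- gen$truth
  genome <- as.character(gen$sequences)[[1]]
  genes <- head(truth$genes, n)
  cds <- substr(genome, genes$start + 1L, genes$start + 150L)
  tibble(gene_id = paste0("pred_", genes$gene_id),
         scaffold = genes$scaffold, strand = genes$strand,
         start = pmax(genes$start - jitter, 0L), end = genes$end + jitter,
         cds = cds)
}

#' @export
print.survey_report <- function(x, ...) {
  cat("== genome survey report (seed", x$config$seed, ") ==\n\n")
  cat("assembly:\n"); print(x$assembly)
  cat("\nk-mer survey:\n"); print(x$kmer)
  cat("\ntandem repeats:\n"); print(x$tandem)
  cat("\nannotation:\n"); print(x$annotation$stats)
  cat("\nNUMTs:\n"); print(x$numt)
  cat("\nrepeat content:\n"); print(x$repeats$table)
  cat(sprintf("read-based repeat fraction: %.3f\n",
              x$repeats$read_repeat_fraction))
  cat("\nsynteny:\n"); print(x$synteny$summary)
  cat("\nmitogenome:\n"); print(x$mito)
  invisible(x)
}

#' Write a survey report to disk
#'
#' Emits a flat JSON summary (every percentage accompanied by the counts it
#' derives from) plus per-stage TSV tables.
#'
#' @param report A `survey_report` from [run_survey()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the JSON summary.
#' @export
write_survey_report <- function(report, dir) {
  stopifnot(inherits(report, "survey_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    seed = report$config$seed,
    assembly = as.list(report$assembly),
    kmer = as.list(glance(report$kmer)),
    tandem = as.list(glance(report$tandem)),
    annotation = as.list(report$annotation$stats),
    numt = as.list(glance(report$numt)),
    read_repeat_fraction = report$repeats$read_repeat_fraction,
    synteny = as.list(report$synteny$summary),
    mito = as.list(glance(report$mito)))
  json_path <- file.path(dir, "survey_report.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  readr::write_tsv(report$repeats$table, file.path(dir, "repeat_content.tsv"))
  readr::write_tsv(report$synteny$blocks, file.path(dir, "synteny_blocks.tsv"))
  readr::write_tsv(as_tibble(report$kmer$spectrum),
                   file.path(dir, "kmer_spectrum.tsv"))
  invisible(json_path)
}
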