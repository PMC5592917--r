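#' Filter gene placements and ortholog records for synteny analysis
#'
#' Applies the three synteny input filters in one pass, each evaluated on the
#' original ortholog map so the retained set does not depend on application
#' order: (1) query scaffolds shorter than `min_scaffold_len` are dropped;
#' (2) genes homologous to multiple genomic locations in either species
#' (query gene with several target records, or target gene hit by several
#' queries) are dropped; (3) records whose target linkage group is
#' `"unknown"` are dropped. The result is a one-to-one query-target mapping.
#'
#' @param placements Query gene placements: `gene_id`, `scaffold`, `start`,
#'   `end`, `strand`.
#' @param orthologs Ortholog map: `query_gene`, `target_gene`,
#'   `target_scaffold`, `target_lg`.
#' @param scaffold_lengths Named vector or `scaffold`/`length` data frame of
#'   query scaffold lengths.
#' @param min_scaffold_len Minimum query scaffold length in bases (default
#'   100000).
#' @return Tibble with one row per retained gene: placement columns plus
#'   `target_gene`, `target_scaffold`, `target_lg`.
#' @export
filter_synteny_inputs <- function(placements, orthologs, scaffold_lengths,
                                  min_scaffold_len = 100000) {
  placements <- as_tibble(placements)
  orthologs <- as_tibble(orthologs)
  if (is.data.frame(scaffold_lengths)) {
    scaffold_lengths <- setNames(scaffold_lengths$length,
                                 scaffold_lengths$scaffold)
  }
  bad <- setdiff(placements$scaffold, names(scaffold_lengths))
  if (length(bad)) {
    abort(sprintf("placement on unknown scaffold '%s'", bad[1]))
  }

  dup_query <- orthologs$query_gene[duplicated(orthologs$query_gene)]
  dup_target <- orthologs$target_gene[duplicated(orthologs$target_gene)]
  keep_map <- !(orthologs$query_gene %in% dup_query) &
    !(orthologs$target_gene %in% dup_target) &
    orthologs$target_lg != "unknown"
  map <- orthologs[keep_map, , drop = FALSE]

  long_enough <- names(scaffold_lengths)[scaffold_lengths >= min_scaffold_len]
  placements |>
    filter(.data$scaffold %in% long_enough) |>
    inner_join(map, by = c(gene_id = "query_gene")) |>
    arrange(.data$scaffold, .data$start)
}

#' Build synteny haplotype blocks from ortholog gene order
#'
#' On each query scaffold, retained genes are sorted by start; every maximal
#' run of consecutive genes whose targets share one linkage group becomes a
#' block spanning from the first gene's start to the last gene's end
#' (intergenic DNA included). Blocks with fewer than two genes or spanning
#' less than `min_block_len` are suppressed.
#'
#' @param filtered Output of [filter_synteny_inputs()].
#' @param min_block_len Minimum block span in bases (default 1000).
#' @return Tibble of blocks: `scaffold`, `start`, `end`, `target_lg`,
#'   `n_genes`, `length`.
#' @export
build_blocks <- function(filtered, min_block_len = 1000) {
  filtered <- as_tibble(filtered)
  need <- c("gene_id", "scaffold", "start", "end", "target_lg")
  stopifnot(all(need %in% names(filtered)))
  if (nrow(filtered) == 0) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  target_lg = character(), n_genes = integer(),
                  length = integer()))
  }
  filtered |>
    group_by(.data$scaffold) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(run = cumsum(c(1L, .data$target_lg[-1] != .data$target_lg[-n()]))) |>
    group_by(.data$scaffold, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              target_lg = first(.data$target_lg), n_genes = n(),
              .groups = "drop") |>
    mutate(length = .data$end - .data$start) |>
    filter(.data$n_genes >= 2, .data$length >= min_block_len) |>
    select(-"run") |>
    arrange(.data$scaffold, .data$start)
}

#' Score per-scaffold synteny against the reference
#'
#' For each query scaffold with blocks, computes the fraction of block base
#' pairs assigned to the modal (most-represented, by block bp) target
#' linkage group; ties toward the linkage group with more genes, then
#' lexicographic. A scaffold is flagged syntenic when the fraction reaches
#' `threshold` (inclusive). Scaffolds without blocks yield no report row.
#'
#' @param blocks Block tibble from [build_blocks()].
#' @param threshold Syntenic fraction cutoff (default 0.95).
#' @return Tibble: `scaffold`, `total_block_bp`, `modal_lg`,
#'   `fraction_to_modal`, `syntenic`.
#' @export
score_scaffold_synteny <- function(blocks, threshold = 0.95) {
  blocks <- as_tibble(blocks)
  if (nrow(blocks) == 0) {
    return(tibble(scaffold = character(), total_block_bp = double(),
                  modal_lg = character(), fraction_to_modal = double(),
                  syntenic = logical()))
  }
  blocks |>
    group_by(.data$scaffold, .data$target_lg) |>
    summarise(bp = sum(.data$length), genes = sum(.data$n_genes),
              .groups = "drop_last") |>
    mutate(total_block_bp = sum(.data$bp)) |>
    arrange(desc(.data$bp), desc(.data$genes), .data$target_lg,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    transmute(scaffold = .data$scaffold,
              total_block_bp = .data$total_block_bp,
              modal_lg = .data$target_lg,
              fraction_to_modal = .data$bp / .data$total_block_bp,
              syntenic = .data$fraction_to_modal >= threshold) |>
    arrange(.data$scaffold)
}

#' Summarize genome-wide synteny
#'
#' @param reports Per-scaffold reports from [score_scaffold_synteny()].
#' @param scaffold_lengths Lengths of the filtered scaffolds (named vector or
#'   `scaffold`/`length` data frame); the denominator for the block-coverage
#'   percentage.
#' @return One-row tibble: `n_scaffolds`, `n_syntenic`, `pct_syntenic`
#'   (integer-rounded), `total_block_bp`, `pct_scaffold_length`
#'   (integer-rounded percent of summed filtered scaffold length covered by
#'   blocks).
#' @export
summarize_synteny <- function(reports, scaffold_lengths) {
  reports <- as_tibble(reports)
  if (is.data.frame(scaffold_lengths)) {
    scaffold_lengths <- setNames(scaffold_lengths$length,
                                 scaffold_lengths$scaffold)
  }
  if (nrow(reports) == 0) {
    return(tibble(n_scaffolds = 0L, n_syntenic = 0L, pct_syntenic = 0,
                  total_block_bp = 0, pct_scaffold_length = 0))
  }
  total_bp <- sum(reports$total_block_bp)
  denom <- sum(scaffold_lengths)
  tibble(n_scaffolds = nrow(reports),
         n_syntenic = sum(reports$syntenic),
         pct_syntenic = round(100 * sum(reports$syntenic) / nrow(reports)),
         total_block_bp = total_bp,
         pct_scaffold_length = if (denom > 0) round(100 * total_bp / denom) else 0)
}
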