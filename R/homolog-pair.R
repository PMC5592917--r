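#' Generate a pair of homologous genomes with known ortholog structure
#'
#' Builds genome A (query: `n_scaffolds` scaffolds, each carrying
#' `genes_per_scaffold` genes) and genome B (reference: one scaffold per
#' linkage group, baseline one linkage group per A scaffold), then injects the
#' requested rearrangements into the ortholog map:
#'
#' * `n_translocations`: an interior gene's ortholog is moved to a different
#'   linkage group, splitting the surrounding block run.
#' * `n_inversions`: a run of reference genes is reversed in place (order and
#'   strand); linkage-group membership is unchanged, so blocks are unaffected
#'   under location-based (non-collinear) block rules.
#' * `n_multi_homologs`: a query gene receives a second target location
#'   (removed by the downstream multiplicity filter).
#' * `n_unknown_lg`: an ortholog record's linkage group is relabelled
#'   `"unknown"` (removed by the downstream filter).
#' * `n_segment_translocations`: two adjacent interior genes move together to
#'   one other linkage group, forming a genuine foreign block on their
#'   scaffold (this is what can push a scaffold below the syntenic
#'   threshold; a single-gene translocation only breaks a run).
#'
#' The true block decomposition implied by the surviving records is computed
#' directly from the placements and recorded in `truth_blocks`.
#'
#' @param n_scaffolds Number of query scaffolds (= baseline linkage groups).
#' @param genes_per_scaffold Genes per query scaffold (>= 2).
#' @param gene_length,intergenic_length Gene span and intergenic spacing in
#'   bases; the defaults give >100 kb scaffolds that pass the synteny length
#'   filter.
#' @param rearrangements List with integer fields `n_translocations`,
#'   `n_inversions`, `n_multi_homologs`, `n_unknown_lg`,
#'   `n_segment_translocations` (all default 0).
#' @param min_block_len Minimum truth-block span in bases (default 1000).
#' @param seed Integer seed.
#' @return List with `genes_a`, `genes_b` (gene placements), `orthologs`
#'   (query_gene, target_gene, target_scaffold, target_lg), `scaffold_lengths`
#'   (tibble scaffold/length for genome A), `truth_blocks`, and the affected
#'   gene ids per rearrangement class.
#' @export
generate_homolog_pair <- function(n_scaffolds = 10, genes_per_scaffold = 8,
                                  gene_length = 2000, intergenic_length = 12000,
                                  rearrangements = list(), min_block_len = 1000,
                                  seed = 1L) {
  if (genes_per_scaffold < 2) abort("need at least 2 genes per scaffold")
  re <- list(n_translocations = 0L, n_inversions = 0L,
             n_multi_homologs = 0L, n_unknown_lg = 0L,
             n_segment_translocations = 0L)
  bad <- setdiff(names(rearrangements), names(re))
  if (length(bad)) abort(paste("unknown rearrangement:", bad[1]))
  re[names(rearrangements)] <- rearrangements
  set.seed(seed)

  scaffolds <- sprintf("scfA_%02d", seq_len(n_scaffolds))
  lgs <- sprintf("LG%d", seq_len(n_scaffolds))

  rows_a <- list(); rows_b <- list(); orth <- list()
  for (s in seq_len(n_scaffolds)) {
    pos <- 0L
    for (g in seq_len(genes_per_scaffold)) {
      gap <- intergenic_length + sample.int(2000L, 1L)
      start <- pos + gap
      gid <- sprintf("geneA_%02d_%02d", s, g)
      tid <- sprintf("geneB_%02d_%02d", s, g)
      rows_a[[length(rows_a) + 1L]] <- tibble(
        gene_id = gid, scaffold = scaffolds[s], start = start,
        end = start + gene_length, strand = sample(c("+", "-"), 1L))
      rows_b[[length(rows_b) + 1L]] <- tibble(
        gene_id = tid, scaffold = lgs[s], start = start,
        end = start + gene_length, strand = "+")
      orth[[length(orth) + 1L]] <- tibble(
        query_gene = gid, target_gene = tid, target_scaffold = lgs[s],
        target_lg = lgs[s])
      pos <- start + gene_length
    }
  }
  genes_a <- bind_rows(rows_a)
  genes_b <- bind_rows(rows_b)
  orthologs <- bind_rows(orth)
  scaffold_lengths <- genes_a |>
    group_by(scaffold) |>
    summarise(length = max(.data$end) + 5000L, .groups = "drop")

  n_rearr <- re$n_translocations + re$n_multi_homologs + re$n_unknown_lg
  interior <- genes_a |>
    group_by(scaffold) |>
    filter(row_number() > 1, row_number() < n()) |>
    pull(.data$gene_id)
  if (n_rearr > length(interior)) {
    abort("more rearrangements requested than available interior genes")
  }
  picks <- sample(interior, n_rearr)
  transloc <- utils::head(picks, re$n_translocations)
  multi <- picks[seq_len(re$n_multi_homologs) + re$n_translocations]
  unknown <- picks[seq_len(re$n_unknown_lg) + re$n_translocations +
                     re$n_multi_homologs]

  for (g in transloc) {
    cur_lg <- orthologs$target_lg[orthologs$query_gene == g]
    new_lg <- sample(setdiff(lgs, cur_lg), 1L)
    orthologs$target_lg[orthologs$query_gene == g] <- new_lg
    orthologs$target_scaffold[orthologs$query_gene == g] <- new_lg
  }
  if (re$n_multi_homologs > 0) {
    extra <- lapply(multi, function(g) {
      rec <- orthologs[orthologs$query_gene == g, ]
      rec$target_gene <- paste0(rec$target_gene, "_dup")
      rec$target_lg <- sample(lgs, 1L)
      rec$target_scaffold <- rec$target_lg
      rec
    })
    orthologs <- bind_rows(orthologs, bind_rows(extra))
  }
  orthologs$target_lg[orthologs$query_gene %in% unknown] <- "unknown"

  # segment translocations: a run of adjacent genes moves together to one
  # other linkage group, so the receiving run forms a real foreign block and
  # can push its scaffold below the syntenic threshold
  seg_transloc <- character()
  if (re$n_segment_translocations > 0) {
    used <- unique(genes_a$scaffold[genes_a$gene_id %in% picks])
    free_scf <- setdiff(scaffolds, used)
    if (length(free_scf) < re$n_segment_translocations) {
      abort("not enough unaffected scaffolds for segment translocations")
    }
    for (i in seq_len(re$n_segment_translocations)) {
      scf <- free_scf[i]
      on_scf <- genes_a$gene_id[genes_a$scaffold == scf]
      seg <- on_scf[2:3]  # two adjacent interior genes
      cur_lg <- lgs[match(scf, scaffolds)]
      new_lg <- sample(setdiff(lgs, cur_lg), 1L)
      sel <- orthologs$query_gene %in% seg
      orthologs$target_lg[sel] <- new_lg
      orthologs$target_scaffold[sel] <- new_lg
      seg_transloc <- c(seg_transloc, seg)
    }
  }

  if (re$n_inversions > 0) {
    for (i in seq_len(re$n_inversions)) {
      lg <- sample(lgs, 1L)
      on_lg <- which(genes_b$scaffold == lg)
      if (length(on_lg) >= 2) {
        k <- sample(2:length(on_lg), 1L)
        run <- sort(sample(on_lg, k))
        genes_b$strand[run] <- rev(ifelse(genes_b$strand[run] == "+", "-", "+"))
        sp <- genes_b$end[run] - genes_b$start[run]
        starts <- rev(genes_b$start[run])  # swap order within the span
        genes_b$start[run] <- starts
        genes_b$end[run] <- starts + sp
      }
    }
  }

  # truth blocks: retained records (not multi-homologous, known LG), runs of
  # adjacent genes sharing a target LG, >= 2 genes, span >= min_block_len
  retained <- orthologs |>
    group_by(.data$query_gene) |>
    filter(n() == 1) |>
    ungroup() |>
    filter(.data$target_lg != "unknown")
  placed <- genes_a |>
    inner_join(retained, by = c(gene_id = "query_gene")) |>
    arrange(.data$scaffold, .data$start)
  blocks <- list()
  for (scf in unique(placed$scaffold)) {
    sub <- placed[placed$scaffold == scf, ]
    run_id <- cumsum(c(1L, sub$target_lg[-1] != sub$target_lg[-nrow(sub)]))
    for (r in unique(run_id)) {
      rs <- sub[run_id == r, ]
      if (nrow(rs) >= 2 && (max(rs$end) - min(rs$start)) >= min_block_len) {
        blocks[[length(blocks) + 1L]] <- tibble(
          scaffold = scf, start = min(rs$start), end = max(rs$end),
          target_lg = rs$target_lg[1], n_genes = nrow(rs))
      }
    }
  }
  truth_blocks <- if (length(blocks)) {
    bind_rows(blocks) |> mutate(length = .data$end - .data$start)
  } else {
    tibble(scaffold = character(), start = integer(), end = integer(),
           target_lg = character(), n_genes = integer(), length = integer())
  }

  list(genes_a = genes_a, genes_b = genes_b, orthologs = orthologs,
       scaffold_lengths = scaffold_lengths, truth_blocks = truth_blocks,
       translocated = transloc, multi_homolog = multi, unknown_lg = unknown,
       segment_translocated = seg_transloc)
}
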