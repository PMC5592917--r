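#' Load a mitochondrial reference gene order
#'
#' Reads a TSV with columns `gene`, `class` (`protein_coding`, `trna`,
#' `rrna`), `strand`, `length` describing the circular reference gene order.
#' The package ships a constructed hymenopteran-like 37-gene order
#' (13 protein-coding, 22 tRNA, 2 rRNA) in
#' `inst/extdata/mito_gene_order_synthetic.tsv`; it is a synthetic stand-in
#' with approximate gene lengths, not a curated annotation.
#'
#' @param path Path to the TSV; defaults to the bundled synthetic order.
#' @return Tibble with the reference order (rows in circular order).
#' @export
read_mito_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mito_gene_order_synthetic.tsv",
                        package = "genomesurvey")
  }
  ref <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "class", "strand", "length")
  if (!all(need %in% names(ref))) {
    abort(paste("mito reference needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ref$gene)) abort("reference gene names must be unique")
  ref
}

#' Identify candidate mitochondrial scaffolds from a hit table
#'
#' Scaffolds with at least one hit at `evalue <= e_max` (default 1e-12, the
#' conventional stringent cutoff for blastx screens against a mitogenome
#' query) are returned.
#'
#' @param hits Hit table with `sseqid` and `evalue`.
#' @param e_max E-value cutoff (default 1e-12).
#' @return Tibble with one column `scaffold` (unique, sorted).
#' @export
identify_mito_scaffolds <- function(hits, e_max = 1e-12) {
  hits <- as_tibble(hits)
  stopifnot(all(c("sseqid", "evalue") %in% names(hits)))
  tibble(scaffold = sort(unique(hits$sseqid[hits$evalue <= e_max])))
}

# does `genes`/`strands` match the circular reference contiguously forward?
matches_forward <- function(genes, strands, ref_genes, ref_strands) {
  n <- length(ref_genes)
  m <- length(genes)
  if (m > n) return(FALSE)
  dg <- c(ref_genes, ref_genes)
  ds <- c(ref_strands, ref_strands)
  for (r in seq_len(n)) {
    idx <- r:(r + m - 1)
    if (all(dg[idx] == genes) && all(ds[idx] == strands)) return(TRUE)
  }
  FALSE
}

#' Check mitochondrial gene order and orientation per scaffold
#'
#' A scaffold is order-consistent when its genes, sorted by position, form a
#' contiguous subsequence of the circular reference order read in either
#' direction, with strands matching under that direction (reading the
#' molecule backwards flips every strand). The molecule is treated as
#' circular and each scaffold may come from either strand.
#'
#' @param annotations Tibble: `scaffold`, `gene`, `start`, `end`, `strand`.
#' @param reference Reference order from [read_mito_reference()].
#' @return Tibble: `scaffold`, `n_genes`, `order_consistent`.
#' @export
check_gene_order <- function(annotations, reference) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("scaffold", "gene", "start", "strand") %in%
                  names(annotations)))
  unknown <- setdiff(annotations$gene, reference$gene)
  if (length(unknown)) {
    abort(sprintf("annotation names unknown gene '%s'", unknown[1]))
  }
  flip <- function(s) ifelse(s == "+", "-", "+")
  annotations |>
    group_by(.data$scaffold) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      n_genes = n(),
      order_consistent =
        matches_forward(.data$gene, .data$strand,
                        reference$gene, reference$strand) ||
        matches_forward(rev(.data$gene), flip(rev(.data$strand)),
                        reference$gene, reference$strand),
      .groups = "drop")
}

#' Mitochondrial genome completeness report
#'
#' Tallies the annotated gene inventory against the reference: counts of
#' complete and partial protein-coding genes (partial when the summed
#' annotated length is below the reference gene length; more than 10% above
#' it is rejected as a suspect annotation), tRNA and rRNA counts, total
#' annotated base pairs, completeness as annotated bp over the reference
#' total length, and per-scaffold gene-order consistency flags.
#'
#' @param annotations Tibble: `scaffold`, `gene`, `start`, `end`, `strand`.
#' @param reference Reference order from [read_mito_reference()].
#' @param reference_length Reference mitogenome total length in bases;
#'   defaults to the summed reference gene lengths (a lower bound that
#'   ignores intergenic and control regions -- supply the species estimate
#'   when known).
#' @return A `mito_report` list.
#' @export
mito_completeness <- function(annotations, reference,
                              reference_length = sum(reference$length)) {
  annotations <- as_tibble(annotations)
  stopifnot(all(c("scaffold", "gene", "start", "end", "strand") %in%
                  names(annotations)))
  unknown <- setdiff(annotations$gene, reference$gene)
  if (length(unknown)) {
    abort(sprintf("annotation names unknown gene '%s'", unknown[1]))
  }
  per_gene <- annotations |>
    group_by(.data$gene) |>
    summarise(annotated_bp = sum(.data$end - .data$start), .groups = "drop") |>
    left_join(reference, by = "gene")
  too_long <- per_gene$annotated_bp > 1.1 * per_gene$length
  if (any(too_long)) {
    abort(sprintf("annotated length of '%s' exceeds its reference length by >10%%",
                  per_gene$gene[which(too_long)[1]]))
  }
  per_gene <- mutate(per_gene, complete = .data$annotated_bp >= .data$length)

  counts <- function(cls) {
    sub <- per_gene[per_gene$class == cls, , drop = FALSE]
    c(complete = sum(sub$complete), partial = sum(!sub$complete))
  }
  pcg <- counts("protein_coding")
  total_bp <- sum(per_gene$annotated_bp)
  structure(
    list(n_protein_coding_complete = unname(pcg["complete"]),
         n_protein_coding_partial = unname(pcg["partial"]),
         n_trna = sum(per_gene$class == "trna"),
         n_rrna = sum(per_gene$class == "rrna"),
         total_annotated_bp = total_bp,
         reference_length = reference_length,
         completeness = total_bp / reference_length,
         per_gene = per_gene,
         order_consistency = check_gene_order(annotations, reference)),
    class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat("mitogenome completeness report\n")
  cat(sprintf("  protein-coding: %d complete, %d partial; tRNA: %d; rRNA: %d\n",
              x$n_protein_coding_complete, x$n_protein_coding_partial,
              x$n_trna, x$n_rrna))
  cat(sprintf("  %d bp annotated of %d bp reference = %.1f%% complete\n",
              x$total_annotated_bp, x$reference_length, 100 * x$completeness))
  cat(sprintf("  gene order consistent on %d of %d scaffolds\n",
              sum(x$order_consistency$order_consistent),
              nrow(x$order_consistency)))
  invisible(x)
}

#' @export
glance.mito_report <- function(x, ...) {
  tibble(n_protein_coding_complete = x$n_protein_coding_complete,
         n_protein_coding_partial = x$n_protein_coding_partial,
         n_trna = x$n_trna, n_rrna = x$n_rrna,
         total_annotated_bp = x$total_annotated_bp,
         reference_length = x$reference_length,
         completeness = x$completeness,
         n_scaffolds_order_consistent = sum(x$order_consistency$order_consistent),
         n_scaffolds = nrow(x$order_consistency))
}
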