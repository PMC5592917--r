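#' Summarize nuclear-mitochondrial insertions (NUMTs) from blastn-style hits
#'
#' Retains hits with `evalue <= e_max`, merges overlapping hits on the same
#' scaffold into fragments (identity averaged across merged hits, weighted by
#' hit length by default), and reports fragment counts, lengths and
#' identities plus the fraction of the assembly covered, with ambiguous
#' residues excluded from the denominator.
#'
#' @param hits Outfmt-6 style hit table (`sseqid`, `sstart`, `send`,
#'   `pident`, `evalue`; BLAST 1-based inclusive subject coordinates, either
#'   orientation).
#' @param assembly Assembly sequences.
#' @param e_max E-value cutoff (default 1e-4).
#' @param identity_weighting `"length"` (default) or `"unweighted"` averaging
#'   of identities, both when merging hits into fragments and across
#'   fragments.
#' @return A `numt_summary` list: `n_scaffolds_with_hits`, `n_fragments`,
#'   `total_bp`, `mean_fragment_length`, `mean_identity` (proportion),
#'   `assembly_fraction`, `fragments` (per-fragment tibble) and
#'   `per_scaffold` (scaffold, n_fragments, concatenated_bp).
#' @export
summarize_numts <- function(hits, assembly, e_max = 1e-4,
                            identity_weighting = c("length", "unweighted")) {
  identity_weighting <- match.arg(identity_weighting)
  hits <- as_tibble(hits)
  seqs <- as_sequence_vector(assembly, arg = "assembly")
  lens <- nchar(seqs)
  assembly_bp <- non_ambiguous_length(seqs)

  empty <- structure(
    list(n_scaffolds_with_hits = 0L, n_fragments = 0L, total_bp = 0,
         mean_fragment_length = NA_real_, mean_identity = NA_real_,
         assembly_fraction = 0,
         fragments = tibble(scaffold = character(), start = integer(),
                            end = integer(), identity = double()),
         per_scaffold = tibble(scaffold = character(), n_fragments = integer(),
                               concatenated_bp = double())),
    class = "numt_summary")
  if (nrow(hits) == 0) return(empty)

  keep <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(keep) == 0) return(empty)
  start0 <- pmin(keep$sstart, keep$send) - 1L
  end0 <- pmax(keep$sstart, keep$send)
  bad_scf <- setdiff(keep$sseqid, names(seqs))
  if (length(bad_scf)) abort(sprintf("hit scaffold '%s' not in assembly", bad_scf[1]))
  if (any(end0 > lens[keep$sseqid]) || any(start0 < 0)) {
    abort("hit beyond scaffold bounds")
  }

  frag_rows <- lapply(split(seq_len(nrow(keep)), keep$sseqid), function(idx) {
    ir <- IRanges::IRanges(start = start0[idx] + 1L, end = end0[idx])
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    ident <- vapply(seq_along(red), function(i) {
      sub <- idx[revmap[[i]]]
      w <- if (identity_weighting == "length") {
        end0[sub] - start0[sub]
      } else rep(1, length(sub))
      weighted.mean(keep$pident[sub] / 100, w)
    }, numeric(1))
    tibble(scaffold = keep$sseqid[idx[1]],
           start = IRanges::start(red) - 1L, end = IRanges::end(red),
           identity = ident)
  })
  fragments <- bind_rows(frag_rows) |> arrange(.data$scaffold, .data$start)
  flen <- fragments$end - fragments$start
  w <- if (identity_weighting == "length") flen else rep(1, nrow(fragments))
  per_scaffold <- fragments |>
    group_by(.data$scaffold) |>
    summarise(n_fragments = n(),
              concatenated_bp = sum(.data$end - .data$start),
              .groups = "drop")
  structure(
    list(n_scaffolds_with_hits = nrow(per_scaffold),
         n_fragments = nrow(fragments),
         total_bp = sum(flen),
         mean_fragment_length = mean(flen),
         mean_identity = weighted.mean(fragments$identity, w),
         assembly_fraction = if (assembly_bp > 0) sum(flen) / assembly_bp else 0,
         fragments = fragments, per_scaffold = per_scaffold),
    class = "numt_summary")
}

#' @export
print.numt_summary <- function(x, ...) {
  cat("NUMT summary\n")
  cat(sprintf("  %d fragments on %d scaffolds, %.0f bp total\n",
              x$n_fragments, x$n_scaffolds_with_hits, x$total_bp))
  if (x$n_fragments > 0) {
    cat(sprintf("  mean fragment length %.1f bp, mean identity %.1f%%\n",
                x$mean_fragment_length, 100 * x$mean_identity))
    cat(sprintf("  %.4f%% of the non-ambiguous assembly\n",
                100 * x$assembly_fraction))
  }
  invisible(x)
}

#' @export
glance.numt_summary <- function(x, ...) {
  tibble(n_scaffolds_with_hits = x$n_scaffolds_with_hits,
         n_fragments = x$n_fragments, total_bp = x$total_bp,
         mean_fragment_length = x$mean_fragment_length,
         mean_identity = x$mean_identity,
         assembly_fraction = x$assembly_fraction)
}

#' Aggregate repeat-element annotations into a per-class content table
#'
#' Builds the classic repeat-content report: per repeat class
#' (retrotransposons, DNA transposons, unclassified) the number of families,
#' the number of annotated elements, the overlap-merged cumulative length,
#' and percentages -- family/element shares rounded to one decimal, assembly
#' percentages computed over the non-ambiguous assembly length. Classified
#' subtotal and grand total rows are included; their lengths are sums over
#' the per-class merged lengths so that classified + unclassified = total.
#'
#' @param annotations Tibble of element placements: `scaffold`, `start`,
#'   `end` (0-based half-open), `family_id`.
#' @param families Family catalog: `family_id`, `class` with class one of
#'   `"retrotransposon"`, `"dna_transposon"`, `"unclassified"`.
#' @param assembly Assembly sequences (for the non-ambiguous denominator).
#' @return A `repeat_content_table` tibble: one row per class plus
#'   `classified_total` and `total`, columns `n_families`, `family_pct`,
#'   `n_elements`, `element_pct`, `cumulative_bp`, `assembly_pct`.
#' @export
aggregate_repeat_annotations <- function(annotations, families, assembly) {
  annotations <- as_tibble(annotations)
  families <- as_tibble(families)
  stopifnot(all(c("family_id", "class") %in% names(families)))
  ok_classes <- c("retrotransposon", "dna_transposon", "unclassified")
  if (!all(families$class %in% ok_classes)) {
    abort(paste("family classes must be one of:", paste(ok_classes, collapse = ", ")))
  }
  unknown <- setdiff(annotations$family_id, families$family_id)
  if (length(unknown)) {
    abort(sprintf("annotation cites unknown family '%s'", unknown[1]))
  }
  assembly_bp <- non_ambiguous_length(assembly)

  ann <- left_join(annotations, families, by = "family_id")
  class_bp <- function(cls) {
    sub <- ann[ann$class %in% cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(0)
    sum(vapply(split(sub, sub$scaffold), function(x) {
      m <- merge_intervals(x$start, x$end)
      sum(m$end - m$start)
    }, numeric(1)))
  }
  row_for <- function(label, cls) {
    nf <- sum(families$class %in% cls)
    ne <- sum(ann$class %in% cls)
    bp <- if (length(cls) == 1L) class_bp(cls) else
      sum(vapply(cls, class_bp, numeric(1)))
    tibble(class = label, n_families = nf, n_elements = ne, cumulative_bp = bp)
  }
  out <- bind_rows(
    row_for("retrotransposon", "retrotransposon"),
    row_for("dna_transposon", "dna_transposon"),
    row_for("classified_total", c("retrotransposon", "dna_transposon")),
    row_for("unclassified", "unclassified"),
    row_for("total", ok_classes))
  tot_f <- out$n_families[out$class == "total"]
  tot_e <- out$n_elements[out$class == "total"]
  out <- out |>
    mutate(family_pct = round(100 * .data$n_families / tot_f, 1),
           element_pct = round(100 * .data$n_elements / max(tot_e, 1), 1),
           assembly_pct = round(100 * .data$cumulative_bp /
                                  max(assembly_bp, 1), 1)) |>
    select("class", "n_families", "family_pct", "n_elements", "element_pct",
           "cumulative_bp", "assembly_pct")
  class(out) <- c("repeat_content_table", class(out))
  attr(out, "assembly_bp") <- assembly_bp
  out
}

#' Coverage-normalized read-based repeat fraction
#'
#' Treats each highly repetitive contig (e.g. a de novo repeat assembly) as a
#' collapsed representation of its genomic copies: a contig of length
#' \eqn{l_i} with mean mapped depth \eqn{d_i} represents
#' \eqn{l_i \cdot d_i / C} genomic base pairs at mean genome coverage C. Only
#' contigs with \eqn{d_i \ge m \cdot C} are counted (default multiplier
#' `m = C`, i.e. minimum repeat frequency equal to the squared mean
#' coverage). The repeat fraction is the summed normalized base pairs over
#' the genome size G.
#'
#' @param profiles Tibble with `contig`, `length`, `mean_depth`.
#' @param mean_coverage Mean genome-wide coverage C (> 0).
#' @param genome_size Estimated genome size G in bases (> 0).
#' @param min_freq_multiplier Depth-threshold multiplier m (default
#'   `mean_coverage`, giving the squared-coverage cutoff).
#' @param literal_formula Use the literal normalization
#'   \eqn{d_i / (l_i C)} instead of \eqn{l_i d_i / C} (for comparison only;
#'   the default has consistent base-pair units).
#' @return Proportion of the genome attributed to high-copy repeats.
#' @export
estimate_read_repeat_fraction <- function(profiles, mean_coverage, genome_size,
                                          min_freq_multiplier = mean_coverage,
                                          literal_formula = FALSE) {
  profiles <- as_tibble(profiles)
  stopifnot(all(c("length", "mean_depth") %in% names(profiles)))
  if (!is.numeric(mean_coverage) || mean_coverage <= 0) abort("`mean_coverage` must be > 0")
  if (!is.numeric(genome_size) || genome_size <= 0) abort("`genome_size` must be > 0")
  keep <- profiles$mean_depth >= min_freq_multiplier * mean_coverage
  if (!any(keep)) return(0)
  p <- profiles[keep, , drop = FALSE]
  normalized_bp <- if (literal_formula) {
    p$mean_depth / (p$length * mean_coverage)
  } else {
    p$length * p$mean_depth / mean_coverage
  }
  sum(normalized_bp) / genome_size
}
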