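#' Filter protein-to-genome hits for homology annotation
#'
#' A query protein is retained when it has at least one hit with
#' `evalue <= e_max` and query coverage `>= min_query_cov` (boundaries
#' inclusive: coverage exactly at the threshold passes). Coverage is taken
#' from a `query_coverage` column (proportion), else from a BLAST-style
#' `qcovs` column (percent), else derived as `(qend - qstart + 1) /
#' query_length` from `query_lengths`.
#'
#' @param hits Hit table (outfmt-6 style tibble; needs `qseqid`, `evalue`,
#'   and one coverage source).
#' @param e_max E-value cutoff (default 1e-4).
#' @param min_query_cov Minimum query coverage proportion (default 0.5).
#' @param query_lengths Optional named vector or `query`/`length` data frame
#'   of query protein lengths, used when coverage must be derived.
#' @return Tibble with one column `query`: the retained query ids, sorted.
#' @export
filter_protein_hits <- function(hits, e_max = 1e-4, min_query_cov = 0.5,
                                query_lengths = NULL) {
  hits <- as_tibble(hits)
  stopifnot(all(c("qseqid", "evalue") %in% names(hits)))
  if ("query_coverage" %in% names(hits)) {
    cov <- hits$query_coverage
  } else if ("qcovs" %in% names(hits)) {
    cov <- hits$qcovs / 100
  } else {
    if (is.null(query_lengths)) {
      abort("no `query_coverage`/`qcovs` column and no `query_lengths` given")
    }
    if (is.data.frame(query_lengths)) {
      query_lengths <- setNames(query_lengths$length, query_lengths$query)
    }
    qlen <- query_lengths[hits$qseqid]
    if (anyNA(qlen)) {
      abort(sprintf("missing query length for '%s'",
                    hits$qseqid[which(is.na(qlen))[1]]))
    }
    cov <- (hits$qend - hits$qstart + 1) / qlen
  }
  keep <- hits$evalue <= e_max & cov >= min_query_cov
  tibble(query = sort(unique(hits$qseqid[keep])))
}

#' Two-round homology model selection
#'
#' Per retained query, accept the best-scoring candidate model whose
#' similarity (fraction of the optimal alignment score) reaches `round1`
#' (default 0.35). Queries with no such model are retried at the relaxed
#' `round2` threshold (default 0.15); queries failing both remain
#' unannotated. Score ties resolve by higher similarity, then model id.
#'
#' @param candidates Tibble with columns `query`, `model_id`, `similarity`,
#'   `score` (extra columns are carried through).
#' @param round1,round2 Similarity thresholds for the two rounds.
#' @return One row per query: the accepted model's columns plus `round` (1 or
#'   2); unannotated queries have `model_id = NA` and `round = NA`.
#' @export
select_homology_models <- function(candidates, round1 = 0.35, round2 = 0.15) {
  candidates <- as_tibble(candidates)
  stopifnot(all(c("query", "model_id", "similarity", "score") %in%
                  names(candidates)))
  pick <- function(df) {
    df |>
      arrange(desc(.data$score), desc(.data$similarity), .data$model_id) |>
      slice(1)
  }
  result <- candidates |>
    group_by(.data$query) |>
    group_modify(function(df, key) {
      r1 <- df[df$similarity >= round1, , drop = FALSE]
      if (nrow(r1) > 0) return(mutate(pick(r1), round = 1L))
      r2 <- df[df$similarity >= round2, , drop = FALSE]
      if (nrow(r2) > 0) return(mutate(pick(r2), round = 2L))
      out <- df[1, , drop = FALSE]
      out[, setdiff(names(out), "query")] <- NA
      mutate(out, round = NA_integer_)
    }) |>
    ungroup() |>
    arrange(.data$query)
  result
}

#' Resolve same-strand overlapping gene models
#'
#' Within each connected component of same-strand, span-overlapping models
#' (overlap is transitive through chains), exactly one model survives: the
#' maximum score, ties broken by longer span, then lexicographic model id.
#' Opposite-strand overlaps are left untouched.
#'
#' @param models Tibble with `model_id`, `scaffold`, `strand`, `start`,
#'   `end`, `score` (0-based half-open spans).
#' @return The surviving rows, ordered by scaffold and start.
#' @export
resolve_overlaps <- function(models) {
  models <- as_tibble(models)
  need <- c("model_id", "scaffold", "strand", "start", "end", "score")
  stopifnot(all(need %in% names(models)))
  models |>
    group_by(.data$scaffold, .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(component = cumsum(
      .data$start >= cummax(dplyr::lag(.data$end, default = first(.data$start))))) |>
    group_by(.data$scaffold, .data$strand, .data$component) |>
    arrange(desc(.data$score), desc(.data$end - .data$start), .data$model_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-"component") |>
    arrange(.data$scaffold, .data$start, .data$model_id)
}

# global identity over the aligned coding sequences: unit-cost end-to-end
# alignment (Levenshtein), identity = 1 - distance / max length
cds_identity_matrix <- function(cds) {
  n <- length(cds)
  if (n == 0L) return(matrix(numeric(), 0, 0))
  d <- adist(cds)
  len <- outer(nchar(cds), nchar(cds), pmax)
  ident <- 1 - d / pmax(len, 1L)
  diag(ident) <- 1
  ident
}

#' Build the de novo complement of the official gene set
#'
#' Three steps: (1) consensus -- keep predictions from set A that have a
#' same-scaffold, same-strand partner in set B with reciprocal span overlap
#' of at least `min_reciprocal_overlap` (both directions); (2) discard
#' putative transposable-element-derived predictions -- any pair of consensus
#' predictions with coding-sequence identity `>= max_pairwise_similarity` is
#' removed, both members by default (`keep_one = TRUE` instead keeps the
#' longest coding sequence per similarity component, ties by id); (3) append
#' survivors that overlap no homology model on either strand of their
#' scaffold as `source = "denovo"`.
#'
#' @param predictions_a,predictions_b Prediction tibbles with `gene_id`,
#'   `scaffold`, `strand`, `start`, `end`, `cds`.
#' @param homology_models Finalized homology model tibble (`scaffold`,
#'   `start`, `end`; strand is ignored for the exclusion test).
#' @param min_reciprocal_overlap Reciprocal span-overlap threshold (default
#'   0.5).
#' @param max_pairwise_similarity Coding-sequence identity at or above which
#'   a pair is discarded (default 0.85).
#' @param keep_one Keep one representative per similar group instead of
#'   dropping both members (default `FALSE`).
#' @return The official gene set: homology rows with `source = "homology"`
#'   plus appended de novo rows with `source = "denovo"`.
#' @export
merge_denovo <- function(predictions_a, predictions_b, homology_models,
                         min_reciprocal_overlap = 0.5,
                         max_pairwise_similarity = 0.85, keep_one = FALSE) {
  pa <- as_tibble(predictions_a)
  pb <- as_tibble(predictions_b)
  need <- c("gene_id", "scaffold", "strand", "start", "end", "cds")
  stopifnot(all(need %in% names(pa)), all(need %in% names(pb)))
  bad <- c(which(pa$end <= pa$start | !nzchar(pa$cds)),
           which(pb$end <= pb$start | !nzchar(pb$cds)))
  if (length(bad)) abort("malformed prediction: empty span or coding sequence")

  # (1) consensus by reciprocal overlap
  pairs <- inner_join(pa, pb, by = c("scaffold", "strand"),
                      suffix = c("_a", "_b"), relationship = "many-to-many")
  if (nrow(pairs) > 0) {
    ov <- pmax(0, pmin(pairs$end_a, pairs$end_b) -
                 pmax(pairs$start_a, pairs$start_b))
    ok <- ov / (pairs$end_a - pairs$start_a) >= min_reciprocal_overlap &
      ov / (pairs$end_b - pairs$start_b) >= min_reciprocal_overlap
    consensus_ids <- unique(pairs$gene_id_a[ok])
  } else {
    consensus_ids <- character()
  }
  consensus <- pa[pa$gene_id %in% consensus_ids, , drop = FALSE]

  # (2) pairwise coding-sequence similarity filter
  if (nrow(consensus) > 1) {
    ident <- cds_identity_matrix(consensus$cds)
    diag(ident) <- 0
    similar <- ident >= max_pairwise_similarity
    if (keep_one) {
      g <- igraph_components(similar)
      keep <- vapply(split(seq_len(nrow(consensus)), g), function(idx) {
        idx[order(-nchar(consensus$cds[idx]), consensus$gene_id[idx])][1]
      }, integer(1))
      consensus <- consensus[sort(keep), , drop = FALSE]
    } else {
      drop <- rowSums(similar) > 0
      consensus <- consensus[!drop, , drop = FALSE]
    }
  }

  # (3) append survivors not overlapping any homology model (either strand)
  hm <- as_tibble(homology_models)
  overlaps_homology <- vapply(seq_len(nrow(consensus)), function(i) {
    any(hm$scaffold == consensus$scaffold[i] &
          hm$start < consensus$end[i] & consensus$start[i] < hm$end)
  }, logical(1))
  denovo <- consensus[!overlaps_homology, , drop = FALSE]

  bind_rows(
    mutate(hm, source = "homology"),
    if (nrow(denovo) > 0) mutate(denovo, source = "denovo") else NULL
  )
}

# connected-component labels from a logical adjacency matrix
igraph_components <- function(adj) {
  n <- nrow(adj)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(labels[c(i, nb)])
        if (any(labels[c(i, nb)] != m)) {
          labels[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

#' Official-gene-set statistics
#'
#' @param ogs Official gene set tibble with a `source` column
#'   (`"homology"`/`"denovo"`), e.g. from [merge_denovo()].
#' @param donor_set_size Number of donor (reference species) genes used for
#'   homology annotation.
#' @return One-row tibble: `n_total`, `n_homology`, `n_denovo_added`,
#'   `donor_set_size`, `homology_percentage` (rounded to the nearest
#'   integer percent of the donor set).
#' @export
ogs_stats <- function(ogs, donor_set_size) {
  if (!is.numeric(donor_set_size) || donor_set_size <= 0) {
    abort("`donor_set_size` must be > 0")
  }
  stopifnot("source" %in% names(ogs))
  n_hom <- sum(ogs$source == "homology")
  n_de <- sum(ogs$source == "denovo")
  tibble(n_total = n_hom + n_de, n_homology = n_hom, n_denovo_added = n_de,
         donor_set_size = as.numeric(donor_set_size),
         homology_percentage = round(100 * n_hom / donor_set_size))
}
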