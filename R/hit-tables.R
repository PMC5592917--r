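outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore", "qcovs")

empty_hit_table <- function() {
  tibble(qseqid = character(), sseqid = character(), pident = double(),
         length = integer(), mismatch = integer(), gapopen = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = double(), bitscore = double(),
         qcovs = double())
}

log_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

#' Emit BLAST-style alignment-hit tables from synthetic truth
#'
#' Produces tab-table records (outfmt-6 column order plus a `qcovs`
#' query-coverage column, coordinates 1-based inclusive as in BLAST output)
#' with one hit per true placement, plus configurable decoy hits whose
#' E-values lie above the downstream cutoffs so that the filters can be
#' exercised against known truth.
#'
#' @param truth A `survey_truth` object from [generate_genome()].
#' @param noise List of optional fields: `true_evalue_range` (default
#'   `c(1e-180, 1e-30)`), `decoy_evalue_range` (default `c(2e-4, 10)`, i.e.
#'   above the 1e-4 cutoff), `n_decoys` (default 0), `identity_jitter`
#'   (additive percent-identity jitter s.d. for protein hits, default 0).
#' @param seed Integer seed.
#' @return List with `numt_hits` (mitogenome query vs nuclear scaffolds) and
#'   `protein_hits` (one donor protein per true gene), both outfmt-6 tibbles.
#' @export
emit_hit_tables <- function(truth, noise = list(), seed = 1L) {
  stopifnot(inherits(truth, "survey_truth"))
  nz <- list(true_evalue_range = c(1e-180, 1e-30),
             decoy_evalue_range = c(2e-4, 10),
             n_decoys = 0L, identity_jitter = 0)
  nz[names(noise)] <- noise
  set.seed(seed)

  numt_hits <- empty_hit_table()
  if (nrow(truth$numts) > 0) {
    nm <- truth$numts
    len <- nm$end - nm$start
    numt_hits <- tibble(
      qseqid = "mitogenome", sseqid = nm$scaffold,
      pident = round(nm$identity * 100, 2),
      length = as.integer(len),
      mismatch = as.integer(round((1 - nm$identity) * len)),
      gapopen = 0L,
      qstart = nm$mito_start + 1L, qend = nm$mito_end,
      sstart = nm$start + 1L, send = nm$end,
      evalue = log_uniform(nrow(nm), nz$true_evalue_range),
      bitscore = round(2 * len * nm$identity, 1),
      qcovs = round(100 * len / nchar(truth$mito_sequence), 1))
  }
  if (nz$n_decoys > 0) {
    dlen <- sample(60:400, nz$n_decoys, replace = TRUE)
    dstart <- sample.int(max(truth$genome_length - max(dlen), 1L),
                         nz$n_decoys, replace = TRUE)
    decoys <- tibble(
      qseqid = "mitogenome", sseqid = "scf_1",
      pident = round(runif(nz$n_decoys, 70, 85), 2),
      length = as.integer(dlen), mismatch = as.integer(round(0.2 * dlen)),
      gapopen = 0L,
      qstart = 1L, qend = as.integer(dlen),
      sstart = as.integer(dstart), send = as.integer(dstart + dlen - 1L),
      evalue = log_uniform(nz$n_decoys, nz$decoy_evalue_range),
      bitscore = round(runif(nz$n_decoys, 30, 50), 1),
      qcovs = round(100 * dlen / max(nchar(truth$mito_sequence %||% "A"), 1), 1))
    numt_hits <- bind_rows(numt_hits, decoys)
  }

  protein_hits <- empty_hit_table()
  if (nrow(truth$genes) > 0) {
    gn <- truth$genes
    len <- gn$end - gn$start
    qlen <- pmax(round(len / 3), 50L)
    pid <- pmin(pmax(round(runif(nrow(gn), 75, 98) +
                             stats::rnorm(nrow(gn), 0, nz$identity_jitter), 2),
                     50), 100)
    protein_hits <- tibble(
      qseqid = paste0("prot_", gn$gene_id), sseqid = gn$scaffold,
      pident = pid, length = as.integer(qlen),
      mismatch = as.integer(round((1 - pid / 100) * qlen)), gapopen = 0L,
      qstart = 1L, qend = as.integer(qlen),
      sstart = gn$start + 1L, send = gn$end,
      evalue = log_uniform(nrow(gn), nz$true_evalue_range),
      bitscore = round(2 * qlen * pid / 100, 1),
      qcovs = round(runif(nrow(gn), 60, 100), 1))
  }

  list(numt_hits = numt_hits, protein_hits = protein_hits)
}

#' Emit candidate homology gene models from synthetic truth
#'
#' Produces one or more candidate spliced-alignment models per true gene with
#' an injected similarity value (fraction of the optimal alignment score), so
#' the round-1/round-2 homology selection rules can be tested against known
#' per-gene similarities.
#'
#' @param truth A `survey_truth` object.
#' @param similarity_range Range the per-gene best similarity is drawn from.
#' @param n_models_per_gene Candidate models per gene; extra models get lower
#'   similarity and score than the best one.
#' @param seed Integer seed.
#' @return Tibble with columns `query`, `model_id`, `scaffold`, `strand`,
#'   `start`, `end`, `similarity`, `score`.
#' @export
emit_candidate_models <- function(truth, similarity_range = c(0.1, 0.95),
                                  n_models_per_gene = 1L, seed = 1L) {
  stopifnot(inherits(truth, "survey_truth"))
  set.seed(seed)
  gn <- truth$genes
  if (nrow(gn) == 0) {
    return(tibble(query = character(), model_id = character(),
                  scaffold = character(), strand = character(),
                  start = integer(), end = integer(), similarity = double(),
                  score = double()))
  }
  rows <- lapply(seq_len(nrow(gn)), function(i) {
    best <- runif(1, similarity_range[1], similarity_range[2])
    sims <- c(best, best * runif(n_models_per_gene - 1L, 0.3, 0.9))
    tibble(query = paste0("prot_", gn$gene_id[i]),
           model_id = sprintf("%s_m%d", gn$gene_id[i],
                              seq_len(n_models_per_gene)),
           scaffold = gn$scaffold[i], strand = gn$strand[i],
           start = gn$start[i], end = gn$end[i],
           similarity = round(sims, 3),
           score = round(1000 * sims + runif(n_models_per_gene, 0, 10), 1))
  })
  bind_rows(rows)
}
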