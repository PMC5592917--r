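#' Read and write sequence and table formats
#'
#' Thin wrappers over Biostrings, rtracklayer and readr for the formats the
#' survey consumes and emits. Coordinates in package tibbles are 0-based
#' half-open; GFF3 emission converts to 1-based inclusive.
#'
#' @param path File path.
#' @name survey-io
NULL

#' @rdname survey-io
#' @param sequences Sequences to write (`DNAStringSet`, named character, or
#'   `scaffold`/`sequence` data frame).
#' @export
write_fasta <- function(sequences, path) {
  seqs <- Biostrings::DNAStringSet(as_sequence_vector(sequences))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname survey-io
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname survey-io
#' @param reads Read tibble from [simulate_reads()].
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  dss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname survey-io
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(dss), sequence = unname(as.character(dss)))
}

#' @rdname survey-io
#' @param hits Outfmt-6 hit tibble.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, intersect(outfmt6_cols, names(hits))], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname survey-io
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, col_names = outfmt6_cols, show_col_types = FALSE)
}

#' @rdname survey-io
#' @param spectrum A `kmer_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(as_tibble(spectrum), path)
  invisible(path)
}

#' @rdname survey-io
#' @param k K-mer length recorded with the spectrum.
#' @export
read_spectrum <- function(path, k = 25) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  new_kmer_spectrum(df, k)
}

#' @rdname survey-io
#' @param models Gene model tibble (`gene_id`/`model_id`, `scaffold`,
#'   `strand`, `start`, `end`, optional `source`).
#' @export
write_gene_models_gff3 <- function(models, path) {
  models <- as_tibble(models)
  id_col <- if ("gene_id" %in% names(models)) "gene_id" else "model_id"
  gr <- GenomicRanges::GRanges(
    seqnames = models$scaffold,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand)
  S4Vectors::mcols(gr)$ID <- models[[id_col]]
  S4Vectors::mcols(gr)$type <- "gene"
  if ("source" %in% names(models)) {
    S4Vectors::mcols(gr)$source_tag <- models$source
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname survey-io
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(gene_id = as.character(S4Vectors::mcols(gr)$ID),
         scaffold = as.character(GenomicRanges::seqnames(gr)),
         strand = as.character(GenomicRanges::strand(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}
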