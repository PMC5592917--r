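#' Assembly summary statistics
#'
#' N-statistics by the cumulative-walk definition: Nx is the length of the
#' shortest scaffold among the longest scaffolds that jointly contain x% of
#' the assembly bases (so N25 >= N50). GC is computed over unambiguous
#' residues only.
#'
#' @param sequences Assembly sequences (`DNAStringSet`, named character
#'   vector, or `scaffold`/`sequence` data frame).
#' @return One-row tibble: `n_scaffolds`, `total_length`, `longest`, `n50`,
#'   `n25`, `gc_fraction`.
#' @export
assembly_stats <- function(sequences) {
  seqs <- as_sequence_vector(sequences)
  if (length(seqs) == 0L) abort("empty assembly")
  lens <- sort(unname(nchar(seqs)), decreasing = TRUE)
  total <- sum(lens)
  nx <- function(x) lens[which(cumsum(lens) >= x / 100 * total)[1]]
  dss <- Biostrings::DNAStringSet(seqs)
  acgt <- sum(Biostrings::letterFrequency(dss, "ACGT"))
  gc <- sum(Biostrings::letterFrequency(dss, "GC"))
  tibble(n_scaffolds = length(seqs), total_length = total,
         longest = lens[1], n50 = nx(50), n25 = nx(25),
         gc_fraction = if (acgt > 0) gc / acgt else NA_real_)
}
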