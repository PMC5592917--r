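#' Simulate uniform-coverage single-end reads
#'
#' Draws reads uniformly from the input sequences (scaffolds weighted by
#' length) so that total read bases equal `coverage` times the total sequence
#' length, up to rounding to a whole read. Substitution errors are injected
#' i.i.d. at `error_rate`, always to a different base; no indels are
#' simulated. Deterministic for a fixed `seed`.
#'
#' @param sequences Template sequences: a `DNAStringSet`, named character
#'   vector, or data frame with `scaffold`/`sequence` columns.
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length in bases; must not exceed the shortest
#'   template sequence.
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer seed.
#' @return A tibble with columns `read_id`, `scaffold`, `start` (0-based
#'   template offset) and `sequence`.
#' @export
simulate_reads <- function(sequences, coverage = 20, read_length = 100,
                           error_rate = 0, seed = 1L) {
  seqs <- as_sequence_vector(sequences)
  if (length(seqs) == 0L) abort("at least one template sequence is required")
  check_scalar_number(coverage, "coverage", min = .Machine$double.eps)
  check_scalar_number(read_length, "read_length", min = 1)
  if (error_rate < 0 || error_rate >= 0.25) {
    abort("`error_rate` must be in [0, 0.25)")
  }
  lens <- nchar(seqs)
  short <- which(lens < read_length)
  if (length(short) > 0L) {
    abort(sprintf("read_length %d exceeds length of sequence '%s' (%d bp)",
                  read_length, names(seqs)[short[1]], lens[short[1]]))
  }

  set.seed(seed)
  total <- sum(lens)
  n_reads <- round(coverage * total / read_length)
  scaff_idx <- sample.int(length(seqs), n_reads, replace = TRUE,
                          prob = lens / total)
  starts <- floor(runif(n_reads) * (lens[scaff_idx] - read_length + 1))
  reads <- substr(rep(seqs[scaff_idx], 1L), starts + 1L, starts + read_length)

  if (error_rate > 0) {
    total_bases <- n_reads * read_length
    n_err <- rbinom(1L, total_bases, error_rate)
    if (n_err > 0L) {
      pos <- sample(total_bases, n_err)
      read_i <- ((pos - 1L) %/% read_length) + 1L
      off <- ((pos - 1L) %% read_length) + 1L
      bases <- c("A", "C", "G", "T")
      for (e in seq_len(n_err)) {
        r <- read_i[e]; o <- off[e]
        cur <- substr(reads[r], o, o)
        alt <- setdiff(bases, cur)
        substr(reads[r], o, o) <- alt[sample.int(length(alt), 1L)]
      }
    }
  }

  tibble(read_id = sprintf("read_%06d", seq_len(n_reads)),
         scaffold = names(seqs)[scaff_idx],
         start = as.integer(starts),
         sequence = unname(reads))
}

#' Per-library read statistics
#'
#' Builds the library table consumed by [estimate_genome_size()] and
#' [estimate_coverage()]: one row per sequencing library with its read count
#' and mean read length.
#'
#' @param reads Optional read set (tibble/character/DNAStringSet); when given,
#'   a single-library table is derived from it.
#' @param n_reads,read_length Alternatively, per-library vectors of read
#'   counts and mean read lengths.
#' @return A tibble with columns `library`, `n_reads`, `mean_read_length`.
#' @export
library_stats <- function(reads = NULL, n_reads = NULL, read_length = NULL) {
  if (!is.null(reads)) {
    rv <- as_read_vector(reads)
    return(tibble(library = "lib_1", n_reads = length(rv),
                  mean_read_length = mean(nchar(rv))))
  }
  if (is.null(n_reads) || is.null(read_length)) {
    abort("supply either `reads` or both `n_reads` and `read_length`")
  }
  if (length(n_reads) != length(read_length)) {
    abort("`n_reads` and `read_length` must have the same length")
  }
  tibble(library = paste0("lib_", seq_along(n_reads)),
         n_reads = as.numeric(n_reads),
         mean_read_length = as.numeric(read_length))
}
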