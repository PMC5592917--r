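# shared internal helpers

# Accept a DNAStringSet, a named character vector, or a tibble with
# scaffold/sequence columns; return a named character vector of sequences.
as_sequence_vector <- function(sequences, arg = "sequences") {
  if (methods::is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
    if (is.null(names(out))) names(out) <- paste0("seq_", seq_along(out))
    return(out)
  }
  if (is.data.frame(sequences)) {
    if (!all(c("scaffold", "sequence") %in% names(sequences))) {
      abort(sprintf("`%s` data frame needs `scaffold` and `sequence` columns", arg))
    }
    return(setNames(as.character(sequences$sequence), sequences$scaffold))
  }
  if (is.character(sequences)) {
    if (length(sequences) > 0L && is.null(names(sequences))) {
      names(sequences) <- paste0("seq_", seq_along(sequences))
    }
    return(sequences)
  }
  abort(sprintf("`%s` must be a DNAStringSet, named character vector, or data frame", arg))
}

# Extract read sequences from a tibble (sequence column), character vector, or
# DNAStringSet.
as_read_vector <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.data.frame(reads)) {
    if (!"sequence" %in% names(reads)) {
      abort("`reads` data frame needs a `sequence` column")
    }
    return(as.character(reads$sequence))
  }
  if (is.character(reads)) return(reads)
  abort("`reads` must be a data frame with a `sequence` column, a character vector, or a DNAStringSet")
}

random_dna <- function(n, gc_fraction = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Substitute bases i.i.d. at `rate`, always to a different base.
# Returns list(sequence, n_substitutions).
mutate_sequence <- function(x, rate) {
  n <- nchar(x)
  if (n == 0L || rate <= 0) return(list(sequence = x, n_substitutions = 0L))
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(list(sequence = x, n_substitutions = 0L))
  pos <- sample.int(n, k)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  list(sequence = paste(chars, collapse = ""), n_substitutions = k)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# lexicographically minimal rotation (motif normalization)
min_rotation <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(x, i, n), substr(x, 1L, i - 1L))
  }, character(1))
  sort(rots)[1L]
}

# smallest p dividing nchar(x) such that x is a repetition of its first p
# characters
minimal_period <- function(x) {
  u <- nchar(x)
  for (p in seq_len(u)) {
    if (u %% p == 0L && strrep(substr(x, 1L, p), u %/% p) == x) return(p)
  }
  u
}

# non-ambiguous (A/C/G/T) length of a sequence set
non_ambiguous_length <- function(sequences) {
  seqs <- as_sequence_vector(sequences)
  dss <- Biostrings::DNAStringSet(seqs)
  sum(Biostrings::letterFrequency(dss, "ACGT"))
}

# merge 0-based half-open intervals; returns tibble(start, end)
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(tibble(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s", name, format(min)))
  invisible(x)
}
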