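#' Detect micro- and minisatellites by lag-u self-comparison
#'
#' Scores every candidate locus on the comparison of each position with the
#' position one repeat unit earlier: +1 per match, `mismatch` (default -4)
#' per mismatch; a perfect repeat of total length l and unit u scores l - u.
#' Loci must span at least two units and reach `min_score` (default 12).
#' The reported set is greedy-optimal: repeatedly the highest-scoring
#' remaining candidate over all unit lengths is accepted and everything
#' overlapping it discarded, ties resolved toward the shorter unit, then the
#' smaller start, then the smaller end. The scan is ungapped, so `n_gaps` is
#' always 0; the `gap` penalty is kept in the interface for compatibility
#' with the conventional parameterization. Stretches of ambiguous residues
#' are never crossed.
#'
#' @param sequences `DNAStringSet`, named character vector, or data frame
#'   with `scaffold`/`sequence` columns.
#' @param unit_range Length-2 integer range of repeat unit lengths, within
#'   `[1, 1000]`. Microsatellites: `c(1, 6)`; minisatellites: `c(7, 100)`.
#' @param match,mismatch,gap,min_score Scoring parameters (defaults +1, -4,
#'   -4, 12).
#' @return A `tandem_loci` tibble: `scaffold`, `start`, `end` (0-based
#'   half-open), `motif` (lexicographically minimal rotation of the leading
#'   unit), `unit_length`, `score`, `n_mismatches`, `n_gaps`.
#' @export
find_tandem_repeats <- function(sequences, unit_range = c(1, 6), match = 1,
                                mismatch = -4, gap = -4, min_score = 12) {
  seqs <- as_sequence_vector(sequences)
  if (any(nchar(seqs) == 0L)) abort("sequences must be non-empty")
  unit_range <- as.integer(unit_range)
  if (length(unit_range) != 2L || unit_range[1] < 1L ||
      unit_range[2] > 1000L || unit_range[1] > unit_range[2]) {
    abort("`unit_range` must be an increasing pair within [1, 1000]")
  }
  units <- seq(unit_range[1], unit_range[2])
  out <- lapply(names(seqs), function(scf) {
    s <- toupper(seqs[[scf]])
    df <- tandem_scan_cpp(s, units, match, mismatch, min_score)
    if (nrow(df) == 0L) return(NULL)
    unit_str <- substr(rep(s, nrow(df)), df$start + 1L,
                       df$start + df$unit_length)
    # a locus whose leading unit has a shorter minimal period belongs to the
    # smaller unit class; drop such harmonic matches when scanning a class
    # that excludes that period
    keep <- vapply(unit_str, minimal_period, integer(1)) >= unit_range[1]
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0L) return(NULL)
    motif <- vapply(seq_len(nrow(df)), function(i) {
      min_rotation(substr(s, df$start[i] + 1L, df$start[i] + df$unit_length[i]))
    }, character(1))
    tibble(scaffold = scf, start = df$start, end = df$end, motif = motif,
           unit_length = df$unit_length, score = df$score,
           n_mismatches = df$n_mismatches, n_gaps = 0L)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(scaffold = character(), start = integer(), end = integer(),
                  motif = character(), unit_length = integer(),
                  score = double(), n_mismatches = integer(), n_gaps = integer())
  }
  res <- arrange(res, .data$scaffold, .data$start)
  class(res) <- c("tandem_loci", class(res))
  res
}

#' Summarize tandem-repeat content of an assembly
#'
#' Classifies loci into microsatellites (unit 1-6 bp) and minisatellites
#' (unit >= 7 bp), reports per-class locus counts and cumulative lengths with
#' overlapping loci merged before length accounting, and the combined
#' fraction of the assembly with stretches of ambiguous residues excluded
#' from the denominator.
#'
#' @param loci A `tandem_loci` tibble (or compatible data frame).
#' @param assembly Assembly sequences (`DNAStringSet`, named character, or
#'   `scaffold`/`sequence` data frame).
#' @return A `tandem_summary` list: `per_class` tibble (class, n_loci,
#'   total_bp), `combined_bp`, `assembly_bp` (non-ambiguous), `fraction`.
#' @export
summarize_tandem_repeats <- function(loci, assembly) {
  seqs <- as_sequence_vector(assembly, arg = "assembly")
  lens <- nchar(seqs)
  if (nrow(loci) > 0) {
    bad_scf <- setdiff(loci$scaffold, names(seqs))
    if (length(bad_scf)) {
      abort(sprintf("locus scaffold '%s' not in assembly", bad_scf[1]))
    }
    over <- loci$end > lens[loci$scaffold]
    if (any(over)) {
      abort(sprintf("locus beyond scaffold end on '%s'",
                    loci$scaffold[which(over)[1]]))
    }
  }
  cls <- ifelse(loci$unit_length <= 6, "micro", "mini")
  merged_bp <- function(sub) {
    if (nrow(sub) == 0L) return(0)
    sum(vapply(split(sub, sub$scaffold), function(x) {
      m <- merge_intervals(x$start, x$end)
      sum(m$end - m$start)
    }, numeric(1)))
  }
  per_class <- tibble(
    class = c("micro", "mini"),
    n_loci = c(sum(cls == "micro"), sum(cls == "mini")),
    total_bp = c(merged_bp(loci[cls == "micro", , drop = FALSE]),
                 merged_bp(loci[cls == "mini", , drop = FALSE])))
  combined_bp <- merged_bp(loci)
  assembly_bp <- non_ambiguous_length(seqs)
  structure(
    list(per_class = per_class, combined_bp = combined_bp,
         assembly_bp = assembly_bp,
         fraction = if (assembly_bp > 0) combined_bp / assembly_bp else 0),
    class = "tandem_summary")
}

#' @export
print.tandem_summary <- function(x, ...) {
  cat("tandem-repeat summary\n")
  print(x$per_class)
  cat(sprintf("  combined %d bp / %d non-ambiguous bp = %.4f (%.2f%%)\n",
              x$combined_bp, x$assembly_bp, x$fraction, 100 * x$fraction))
  invisible(x)
}

#' @export
glance.tandem_summary <- function(x, ...) {
  tibble(n_micro = x$per_class$n_loci[x$per_class$class == "micro"],
         micro_bp = x$per_class$total_bp[x$per_class$class == "micro"],
         n_mini = x$per_class$n_loci[x$per_class$class == "mini"],
         mini_bp = x$per_class$total_bp[x$per_class$class == "mini"],
         combined_bp = x$combined_bp, assembly_bp = x$assembly_bp,
         fraction = x$fraction)
}
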