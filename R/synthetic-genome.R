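#' Specify a synthetic genome
#'
#' Builds the parameter object consumed by [generate_genome()]. The defaults
#' describe a small, desk-scale genome with the qualitative features of a
#' repeat-rich bee genome: moderate GC, interspersed repeat families at
#' configurable copy number and divergence, micro-/minisatellite arrays, NUMT
#' insertions derived from an AT-rich mitogenome at 85-99% identity, and
#' multi-exon gene models.
#'
#' @param genome_length Total scaffold length in bases.
#' @param gc_fraction Background GC proportion in `[0, 1]`.
#' @param repeat_families Data frame with columns `family_id`, `unit_length`
#'   (bases), `copy_number`, `divergence` (per-base substitution proportion of
#'   each copy relative to the family consensus), or `NULL` for none.
#' @param tandem_specs Data frame with columns `motif`, `n_units`, `n_loci`,
#'   or `NULL` for none.
#' @param numt_spec List with `mito_length` (bases), `n_insertions`,
#'   `identity_range` (length-2 proportions) and optionally
#'   `fragment_length_range` (bases, default 300-1500), or `NULL`.
#' @param gene_spec List with `n_genes`, `exons_per_gene` (length-2 integer
#'   range), `exon_length` and `intron_length` (length-2 base ranges), or
#'   `NULL`.
#' @param seed Integer seed; every generator draw derives from it.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(genome_length = 100000, gc_fraction = 0.40,
                        repeat_families = NULL, tandem_specs = NULL,
                        numt_spec = NULL, gene_spec = NULL, seed = 1L) {
  check_scalar_number(genome_length, "genome_length", min = 1)
  check_scalar_number(gc_fraction, "gc_fraction", min = 0)
  if (gc_fraction > 1) abort("`gc_fraction` must be in [0, 1]")

  if (!is.null(repeat_families)) {
    repeat_families <- as_tibble(repeat_families)
    need <- c("family_id", "unit_length", "copy_number", "divergence")
    if (!all(need %in% names(repeat_families))) {
      abort(paste("`repeat_families` needs columns:", paste(need, collapse = ", ")))
    }
    if (any(repeat_families$divergence < 0 | repeat_families$divergence > 1)) {
      abort("repeat family `divergence` must be in [0, 1]")
    }
  }
  if (!is.null(tandem_specs)) {
    tandem_specs <- as_tibble(tandem_specs)
    need <- c("motif", "n_units", "n_loci")
    if (!all(need %in% names(tandem_specs))) {
      abort(paste("`tandem_specs` needs columns:", paste(need, collapse = ", ")))
    }
  }
  if (!is.null(numt_spec)) {
    need <- c("mito_length", "n_insertions", "identity_range")
    if (!all(need %in% names(numt_spec))) {
      abort(paste("`numt_spec` needs fields:", paste(need, collapse = ", ")))
    }
    if (any(numt_spec$identity_range < 0 | numt_spec$identity_range > 1)) {
      abort("`identity_range` proportions must be in [0, 1]")
    }
    numt_spec$fragment_length_range <-
      numt_spec$fragment_length_range %||% c(300, 1500)
  }
  if (!is.null(gene_spec)) {
    need <- c("n_genes")
    if (!all(need %in% names(gene_spec))) abort("`gene_spec` needs field `n_genes`")
    gene_spec$exons_per_gene <- gene_spec$exons_per_gene %||% c(2L, 6L)
    gene_spec$exon_length <- gene_spec$exon_length %||% c(100L, 400L)
    gene_spec$intron_length <- gene_spec$intron_length %||% c(50L, 300L)
  }

  structure(
    list(genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction,
         repeat_families = repeat_families,
         tandem_specs = tandem_specs,
         numt_spec = numt_spec,
         gene_spec = gene_spec,
         seed = as.integer(seed)),
    class = "genome_spec")
}

empty_truth_tables <- function(scaffold = character()) {
  list(
    repeats = tibble(family_id = character(), scaffold = character(),
                     start = integer(), end = integer()),
    tandems = tibble(motif = character(), scaffold = character(),
                     start = integer(), end = integer()),
    numts = tibble(scaffold = character(), start = integer(), end = integer(),
                   identity = double(), mito_start = integer(),
                   mito_end = integer()),
    genes = tibble(gene_id = character(), scaffold = character(),
                   strand = character(), start = integer(), end = integer()),
    exons = tibble(gene_id = character(), exon_rank = integer(),
                   start = integer(), end = integer())
  )
}

#' Generate a synthetic genome with known ground truth
#'
#' Emits one scaffold of the requested length: an i.i.d. background sequence
#' at the requested GC into which repeat-family copies, tandem arrays, NUMT
#' fragments and gene spans are placed without overlap at uniformly random
#' positions. Every placement is recorded in the returned truth tables
#' (0-based half-open coordinates), which exactly describe the emitted
#' sequence. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [genome_spec()].
#' @return A list with `sequences` (a named [Biostrings::DNAStringSet] of one
#'   scaffold, `"scf_1"`), and `truth`, an object of class `survey_truth`:
#'   tibbles `repeats`, `tandems`, `numts`, `genes`, `exons`, plus the family
#'   consensus sequences, the mitogenome sequence (when a `numt_spec` is
#'   given) and the spec itself.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  G <- spec$genome_length

  features <- list()  # each: list(kind, length, payload)

  consensus <- character()
  if (!is.null(spec$repeat_families)) {
    for (i in seq_len(nrow(spec$repeat_families))) {
      fam <- spec$repeat_families[i, ]
      cons <- random_dna(fam$unit_length, spec$gc_fraction)
      consensus[[fam$family_id]] <- cons
      for (j in seq_len(fam$copy_number)) {
        copy <- mutate_sequence(cons, fam$divergence)
        features[[length(features) + 1L]] <- list(
          kind = "repeat", sequence = copy$sequence,
          payload = list(family_id = fam$family_id))
      }
    }
  }

  if (!is.null(spec$tandem_specs)) {
    for (i in seq_len(nrow(spec$tandem_specs))) {
      ts <- spec$tandem_specs[i, ]
      arr <- strrep(ts$motif, ts$n_units)
      for (j in seq_len(ts$n_loci)) {
        features[[length(features) + 1L]] <- list(
          kind = "tandem", sequence = arr,
          payload = list(motif = min_rotation(ts$motif)))
      }
    }
  }

  mito_seq <- NULL
  if (!is.null(spec$numt_spec)) {
    ns <- spec$numt_spec
    mito_seq <- random_dna(ns$mito_length, gc_fraction = 0.15)  # AT-rich mitogenome
    for (j in seq_len(ns$n_insertions)) {
      flen <- sample(seq(ns$fragment_length_range[1],
                         min(ns$fragment_length_range[2], ns$mito_length)), 1L)
      fstart <- sample.int(ns$mito_length - flen + 1L, 1L) - 1L
      frag <- substr(mito_seq, fstart + 1L, fstart + flen)
      target_ident <- runif(1L, ns$identity_range[1], ns$identity_range[2])
      mut <- mutate_sequence(frag, 1 - target_ident)
      features[[length(features) + 1L]] <- list(
        kind = "numt", sequence = mut$sequence,
        payload = list(identity = 1 - mut$n_substitutions / flen,
                       mito_start = fstart, mito_end = fstart + flen))
    }
  }

  if (!is.null(spec$gene_spec)) {
    gs <- spec$gene_spec
    for (j in seq_len(gs$n_genes)) {
      n_ex <- sample(seq(gs$exons_per_gene[1], gs$exons_per_gene[2]), 1L)
      ex_len <- sample(seq(gs$exon_length[1], gs$exon_length[2]), n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1L) {
        sample(seq(gs$intron_length[1], gs$intron_length[2]), n_ex - 1L,
               replace = TRUE)
      } else integer()
      strand <- sample(c("+", "-"), 1L)
      features[[length(features) + 1L]] <- list(
        kind = "gene", sequence = NULL,  # genes keep the background sequence
        length = sum(ex_len) + sum(in_len),
        payload = list(gene_id = sprintf("gene_%03d", j), strand = strand,
                       exon_lengths = ex_len, intron_lengths = in_len))
    }
  }

  lens <- vapply(features, function(f) {
    if (!is.null(f$sequence)) nchar(f$sequence) else f$length
  }, numeric(1))
  if (sum(lens) > G) {
    abort(sprintf(paste("features exceed genome length: %d feature bases do",
                        "not fit in %d; enlarge `genome_length` or reduce",
                        "feature content"), sum(lens), G))
  }

  # non-overlapping placement: distribute the free space over the gaps
  # between features (stick-breaking), features in random order
  scaffold <- "scf_1"
  truth <- empty_truth_tables()
  nfeat <- length(features)
  genome <- strsplit(random_dna(G, spec$gc_fraction), "", fixed = TRUE)[[1]]

  if (nfeat > 0L) {
    ord <- sample.int(nfeat)
    features <- features[ord]
    lens <- lens[ord]
    free <- G - sum(lens)
    cuts <- sort(sample.int(free + 1L, nfeat, replace = TRUE) - 1L)
    starts <- cuts + c(0, cumsum(lens))[seq_len(nfeat)]

    rep_rows <- list(); tan_rows <- list(); numt_rows <- list()
    gene_rows <- list(); exon_rows <- list()
    for (i in seq_len(nfeat)) {
      f <- features[[i]]
      s0 <- starts[i]; e0 <- s0 + lens[i]
      if (!is.null(f$sequence)) {
        genome[(s0 + 1L):e0] <- strsplit(f$sequence, "", fixed = TRUE)[[1]]
      }
      if (f$kind == "repeat") {
        rep_rows[[length(rep_rows) + 1L]] <- tibble(
          family_id = f$payload$family_id, scaffold = scaffold,
          start = s0, end = e0)
      } else if (f$kind == "tandem") {
        tan_rows[[length(tan_rows) + 1L]] <- tibble(
          motif = f$payload$motif, scaffold = scaffold, start = s0, end = e0)
      } else if (f$kind == "numt") {
        numt_rows[[length(numt_rows) + 1L]] <- tibble(
          scaffold = scaffold, start = s0, end = e0,
          identity = f$payload$identity,
          mito_start = f$payload$mito_start, mito_end = f$payload$mito_end)
      } else if (f$kind == "gene") {
        p <- f$payload
        ex_starts <- s0 + c(0, cumsum(p$exon_lengths[-length(p$exon_lengths)] +
                                        p$intron_lengths))
        gene_rows[[length(gene_rows) + 1L]] <- tibble(
          gene_id = p$gene_id, scaffold = scaffold, strand = p$strand,
          start = s0, end = e0)
        exon_rows[[length(exon_rows) + 1L]] <- tibble(
          gene_id = p$gene_id, exon_rank = seq_along(p$exon_lengths),
          start = as.integer(ex_starts),
          end = as.integer(ex_starts + p$exon_lengths))
      }
    }
    if (length(rep_rows)) truth$repeats <- bind_rows(rep_rows)
    if (length(tan_rows)) truth$tandems <- bind_rows(tan_rows)
    if (length(numt_rows)) truth$numts <- bind_rows(numt_rows)
    if (length(gene_rows)) truth$genes <- bind_rows(gene_rows)
    if (length(exon_rows)) truth$exons <- bind_rows(exon_rows)
  }

  truth$consensus <- consensus
  truth$mito_sequence <- mito_seq
  truth$genome_length <- G
  truth$seed <- spec$seed
  truth$spec <- spec
  class(truth) <- "survey_truth"

  sequences <- Biostrings::DNAStringSet(setNames(paste(genome, collapse = ""),
                                                 scaffold))
  list(sequences = sequences, truth = truth)
}

#' Ground-truth interspersed-repeat fraction of a synthetic genome
#'
#' Sum of repeat-copy lengths over genome length, computed exactly from the
#' truth tables.
#'
#' @param truth A `survey_truth` object from [generate_genome()].
#' @return A proportion in `[0, 1]`.
#' @export
truth_repeat_fraction <- function(truth) {
  stopifnot(inherits(truth, "survey_truth"))
  sum(truth$repeats$end - truth$repeats$start) / truth$genome_length
}
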