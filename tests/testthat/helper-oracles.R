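# independent oracles and fixture builders used across the suite

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# naive dictionary k-mer spectrum: hash every window, canonicalize by string
# comparison, tabulate counts of counts
naive_spectrum <- function(reads, k) {
  kmers <- unlist(lapply(reads, function(r) {
    L <- nchar(r)
    if (L < k) return(character())
    starts <- seq_len(L - k + 1)
    substring(r, starts, starts + k - 1)
  }))
  kmers <- toupper(kmers)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  canon <- pmin(kmers, rc_string(kmers))
  counts <- table(canon)
  freq_tab <- table(as.integer(counts))
  tibble::tibble(frequency = as.integer(names(freq_tab)),
                 n_kmers = as.numeric(freq_tab))
}

# exhaustive tandem-repeat oracle: scores every (start, end, unit) triple on
# the lag-u self-comparison via prefix sums, then reports the greedy
# non-overlapping selection (score desc, unit asc, start asc, end asc).
# Sequences must be ambiguity-free. Coordinates 0-based half-open.
oracle_tandem <- function(seq, unit_range = c(1, 6), match = 1,
                          mismatch = -4, min_score = 12) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  cands <- list()
  for (u in seq(unit_range[1], unit_range[2])) {
    if (n < 2 * u) next
    y <- ifelse(s[(u + 1):n] == s[1:(n - u)], match, mismatch)
    P <- c(0, cumsum(y))  # P[t+1] = sum of first t comparisons
    # locus [a, b): score = P[b - u + 1] - P[a + 1]; b - a >= 2u
    A <- 0:(n - 2 * u)
    B <- (2 * u):n
    M <- outer(P[A + 1], P[B - u + 1], function(pa, pb) pb - pa)
    M[lower.tri(M)] <- -Inf  # row i, col j valid iff j >= i (b - a >= 2u)
    hit <- which(M >= min_score, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      cands[[length(cands) + 1]] <- tibble::tibble(
        unit_length = u, start = A[hit[, 1]], end = B[hit[, 2]],
        score = M[hit])
    }
  }
  accepted <- tibble::tibble(start = integer(), end = integer(),
                             unit_length = integer(), score = double())
  if (length(cands) == 0) return(accepted)
  all_c <- dplyr::arrange(dplyr::bind_rows(cands),
                          dplyr::desc(score), unit_length, start, end)
  for (i in seq_len(nrow(all_c))) {
    ci <- all_c[i, ]
    if (nrow(accepted) == 0 ||
        all(ci$end <= accepted$start | ci$start >= accepted$end)) {
      accepted <- dplyr::bind_rows(accepted, ci)
    }
  }
  dplyr::arrange(accepted[, c("start", "end", "unit_length", "score")], start)
}

# brute-force same-strand overlap resolution: enumerate connected components
# by repeated expansion, keep max score (ties: longer span, then id)
brute_resolve <- function(models) {
  keep <- logical(nrow(models))
  for (key in unique(paste(models$scaffold, models$strand))) {
    idx <- which(paste(models$scaffold, models$strand) == key)
    adj <- outer(seq_along(idx), seq_along(idx), function(i, j) {
      models$start[idx[i]] < models$end[idx[j]] &
        models$start[idx[j]] < models$end[idx[i]]
    })
    comp <- seq_along(idx)
    repeat {
      new_comp <- comp
      for (i in seq_along(idx)) new_comp[i] <- min(comp[adj[i, ]])
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      ord <- order(-models$score[members],
                   -(models$end[members] - models$start[members]),
                   models$model_id[members])
      keep[members[ord[1]]] <- TRUE
    }
  }
  models[keep, , drop = FALSE]
}

# sort-and-scan Nx oracle
nx_oracle <- function(lengths, x) {
  lens <- sort(lengths, decreasing = TRUE)
  lens[which(cumsum(lens) >= x / 100 * sum(lens))[1]]
}

# repeat-family catalog and annotation table whose marginal counts are the
# published-style worked example: 566 families (36 retro, 106 DNA
# transposon, 424 unclassified), 597,369 elements of which 74,513 from
# classified families
table2_fixture <- function() {
  families <- tibble::tibble(
    family_id = sprintf("fam_%03d", 1:566),
    class = c(rep("retrotransposon", 36), rep("dna_transposon", 106),
              rep("unclassified", 424)))
  n_retro <- 12989
  n_dna <- 74513 - n_retro
  n_uncl <- 597369 - 74513
  fam_of <- c(sample(families$family_id[1:36], n_retro, replace = TRUE),
              sample(families$family_id[37:142], n_dna, replace = TRUE),
              sample(families$family_id[143:566], n_uncl, replace = TRUE))
  n <- length(fam_of)
  annotations <- tibble::tibble(
    scaffold = "scf_big",
    start = seq(0L, by = 20L, length.out = n),
    end = seq(10L, by = 20L, length.out = n),
    family_id = fam_of)
  list(families = families, annotations = annotations)
}
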