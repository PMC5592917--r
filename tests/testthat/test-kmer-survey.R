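test_that("windowed observation count and small-case spectra are exact", {
  sp <- count_kmer_spectrum("ACGTACGT", k = 4)
  expect_equal(attr(sp, "total_observations"), 5)
  # ACGT occurs at positions 1 and 5; its canonical form also absorbs the
  # reverse-complement windows
  expect_equal(sum(sp$frequency * sp$n_kmers), 5)
})

test_that("a read and its reverse complement count like the read twice", {
  set.seed(21)
  r <- rand_seq(200)
  sp_rc <- count_kmer_spectrum(c(r, rc_string(r)), k = 25)
  sp_2x <- count_kmer_spectrum(c(r, r), k = 25)
  expect_equal(as.data.frame(sp_rc), as.data.frame(sp_2x))
})

test_that("spectrum equals a naive dictionary count on tiling reads", {
  set.seed(22)
  base <- rand_seq(1000)
  # duplicate a 200 bp slice to create genuine multi-copy k-mers
  seq <- paste0(base, substr(base, 101, 300))
  starts <- seq_len(nchar(seq) - 100 + 1)
  reads <- substring(seq, starts, starts + 99)  # every position tiled
  got <- count_kmer_spectrum(reads, k = 25)
  want <- naive_spectrum(reads, k = 25)
  expect_equal(as.data.frame(got)[, c("frequency", "n_kmers")],
               as.data.frame(want), ignore_attr = TRUE)
})

test_that("ambiguous residues are skipped and k beyond read length errors", {
  sp <- count_kmer_spectrum("ACGTNACGT", k = 4)
  expect_equal(attr(sp, "total_observations"), 2)  # two clean windows per side, canonical-collapsed observations still counted per window
  expect_error(count_kmer_spectrum("ACG", k = 25), "larger than every read")
})

test_that("depth is the spectrum mode above the error cutoff with ties toward smaller", {
  expect_equal(estimate_depth(kmer_spectrum(c(1, 20, 21), c(1e6, 5e4, 4e4))), 20)
  expect_equal(estimate_depth(kmer_spectrum(c(5, 7), c(100, 100))), 5)
  expect_error(estimate_depth(kmer_spectrum(c(1, 2, 3), c(10, 10, 10))),
               "look like errors")
})

test_that("depth recovered from simulated error-free reads matches the k-mer coverage", {
  gen <- generate_genome(genome_spec(genome_length = 50000, seed = 23))
  reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 500,
                          seed = 24)
  sp <- count_kmer_spectrum(reads, k = 25)
  # a read of length L covers each k-mer with L - K + 1 of its L positions,
  # so the k-mer depth of 20x reads is 20 * 476 / 500 = 19.04
  expect_lte(abs(estimate_depth(sp) - 19), 1)
})

test_that("the genome-size identity holds on constructed spectra", {
  # 100 reads, L = K = 25: one k-mer per read, all distinct
  sp <- kmer_spectrum(frequency = 1, n_kmers = 100, k = 25)
  ls <- library_stats(n_reads = 100, read_length = 25)
  est <- estimate_genome_size(sp, ls, error_cutoff = 0)
  expect_equal(est$B, 0)
  expect_equal(est$D, 1)
  expect_equal(est$G, 100)
  # B equal to all observations is degenerate
  expect_error(estimate_genome_size(sp, ls, error_cutoff = 3),
               "look like errors|non-positive")
})

test_that("genome size is recovered within 5% from error-free 20x reads", {
  gen <- generate_genome(genome_spec(genome_length = 100000, seed = 25))
  reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 100,
                          error_rate = 0, seed = 26)
  est <- estimate_genome_size(count_kmer_spectrum(reads, k = 25),
                              library_stats(reads = reads))
  expect_lt(abs(est$G - 100000) / 100000, 0.05)
})

test_that("substitution errors populate B and degrade recovery by less than 10%", {
  gen <- generate_genome(genome_spec(genome_length = 100000, seed = 27))
  reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 100,
                          error_rate = 0.005, seed = 28)
  est <- estimate_genome_size(count_kmer_spectrum(reads, k = 25),
                              library_stats(reads = reads))
  expect_gt(est$B, 0)
  expect_lt(abs(est$G - 100000) / 100000, 0.10)
})

test_that("repeat fraction behaves on constructed spectra and is monotone in the multiplier", {
  # pure single-copy peak: nothing above 1.5 x depth
  sp <- kmer_spectrum(frequency = c(1, 15), n_kmers = c(1000, 5000))
  expect_equal(estimate_repeat_fraction(sp), 0)
  # two-copy mass at 2D
  sp2 <- kmer_spectrum(frequency = c(1, 15, 30), n_kmers = c(1000, 7000, 1500))
  f <- estimate_repeat_fraction(sp2)
  expect_equal(f, (30 * 1500) / (15 * 7000 + 30 * 1500))
  mults <- c(1.5, 2.5, 5, 50)
  fr <- vapply(mults, function(m) {
    estimate_repeat_fraction(sp2, repeat_multiplier = m)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[length(fr)], 0)
})

test_that("a 30% two-copy repeat genome yields a spectrum repeat fraction near 0.30", {
  spec <- genome_spec(
    genome_length = 100000,
    repeat_families = tibble::tibble(family_id = "two_copy",
                                     unit_length = 15000, copy_number = 2,
                                     divergence = 0),
    seed = 29)
  gen <- generate_genome(spec)
  expect_equal(truth_repeat_fraction(gen$truth), 0.30)
  reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 100,
                          seed = 30)
  est <- kmer_survey(reads)
  expect_lt(abs(est$spectrum_repeat_fraction - 0.30), 0.10)
})

test_that("coverage follows the per-library sum", {
  expect_equal(estimate_coverage(library_stats(n_reads = 1000,
                                               read_length = 100), 10000), 10)
  expect_equal(estimate_coverage(library_stats(n_reads = c(500, 250),
                                               read_length = c(100, 200)),
                                 10000), 10)
  expect_error(estimate_coverage(library_stats(n_reads = 10,
                                               read_length = 100), 0),
               "G")
})

test_that("simulated 20x coverage is recovered within 1% given the true genome size", {
  gen <- generate_genome(genome_spec(genome_length = 40000, seed = 31))
  reads <- simulate_reads(gen$sequences, coverage = 20, read_length = 100,
                          seed = 32)
  C <- estimate_coverage(library_stats(reads = reads), 40000)
  expect_lt(abs(C - 20) / 20, 0.01)
})

test_that("spectrum conservation holds exactly across random read sets", {
  set.seed(33)
  for (i in 1:5) {
    reads <- vapply(sample(30:120, 20, replace = TRUE), rand_seq, character(1))
    k <- sample(c(5, 11, 25), 1)
    reads <- reads[nchar(reads) >= k]
    sp <- count_kmer_spectrum(reads, k = k)
    expect_equal(attr(sp, "total_observations"),
                 sum(pmax(nchar(reads) - k + 1, 0)))
  }
})

test_that("tidy and glance expose the survey estimates", {
  gen <- generate_genome(genome_spec(genome_length = 20000, seed = 34))
  reads <- simulate_reads(gen$sequences, coverage = 15, read_length = 100,
                          seed = 35)
  est <- kmer_survey(reads)
  td <- tidy(est)
  expect_true(all(c("G", "D", "C") %in% td$term))
  gl <- glance(est)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$G, est$G)
})
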