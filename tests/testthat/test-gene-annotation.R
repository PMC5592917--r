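test_that("protein-hit filtering applies the E-value and coverage rules inclusively", {
  hits <- tibble::tibble(
    qseqid = c("p1", "p2", "p3", "p4"),
    evalue = c(1e-5, 1e-3, 1e-6, 1e-10),
    query_coverage = c(0.6, 0.9, 0.5, 0.49))
  kept <- filter_protein_hits(hits)
  expect_equal(kept$query, c("p1", "p3"))  # boundary coverage 0.5 passes
})

test_that("coverage can be derived from alignment coordinates and query lengths", {
  hits <- tibble::tibble(qseqid = c("p1", "p2"), evalue = c(1e-6, 1e-6),
                         qstart = c(1, 1), qend = c(60, 20))
  lens <- c(p1 = 100, p2 = 100)
  expect_equal(filter_protein_hits(hits, query_lengths = lens)$query, "p1")
  expect_error(filter_protein_hits(hits, query_lengths = c(p1 = 100)),
               "p2")
})

test_that("sub-threshold queries are dropped with exact bookkeeping", {
  set.seed(51)
  good <- tibble::tibble(qseqid = sprintf("q%03d", 1:60),
                         evalue = 10^runif(60, -50, -5),
                         query_coverage = runif(60, 0.5, 1))
  bad <- tibble::tibble(qseqid = sprintf("q%03d", 61:100),
                        evalue = c(10^runif(20, -3, 0), 10^runif(20, -50, -5)),
                        query_coverage = c(runif(20, 0.5, 1), runif(20, 0, 0.49)))
  kept <- filter_protein_hits(dplyr::bind_rows(good, bad))
  expect_equal(nrow(kept), 60)
  expect_setequal(kept$query, good$qseqid)
})

test_that("two-round selection classifies every query exactly once", {
  candidates <- tibble::tibble(
    query = c("a", "a", "b", "c"),
    model_id = c("a_m1", "a_m2", "b_m1", "c_m1"),
    similarity = c(0.50, 0.40, 0.20, 0.10),
    score = c(500, 510, 200, 100))
  sel <- select_homology_models(candidates)
  expect_equal(nrow(sel), 3)
  # round 1: best score among models passing 0.35
  a <- sel[sel$query == "a", ]
  expect_equal(a$model_id, "a_m2")
  expect_equal(a$round, 1L)
  # round 2 rescue at 0.15
  expect_equal(sel$round[sel$query == "b"], 2L)
  # below both thresholds: unannotated
  expect_true(is.na(sel$model_id[sel$query == "c"]))
  # partition property: each query in exactly one class
  classes <- ifelse(is.na(sel$round), "none", paste0("round", sel$round))
  expect_equal(unname(table(classes)[c("round1", "round2", "none")]),
               c(1L, 1L, 1L), ignore_attr = TRUE)
})

test_that("same-strand overlap resolution keeps the single best model per component", {
  m <- tibble::tibble(
    model_id = c("A", "B"), scaffold = "s", strand = "+",
    start = c(0, 50), end = c(100, 150), score = c(80, 95))
  expect_equal(resolve_overlaps(m)$model_id, "B")
  # opposite strands are untouched
  m2 <- dplyr::mutate(m, strand = c("+", "-"))
  expect_equal(sort(resolve_overlaps(m2)$model_id), c("A", "B"))
  # chain A-B, B-C with A and C disjoint: one survivor for the component
  m3 <- tibble::tibble(
    model_id = c("A", "B", "C"), scaffold = "s", strand = "+",
    start = c(0, 80, 160), end = c(100, 200, 260), score = c(10, 20, 15))
  expect_equal(resolve_overlaps(m3)$model_id, "B")
})

test_that("overlap resolution matches brute-force component enumeration", {
  set.seed(52)
  for (rep in 1:6) {
    n <- 10
    start <- sample(0:500, n)
    m <- tibble::tibble(
      model_id = sprintf("m%02d", 1:n),
      scaffold = sample(c("s1", "s2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = start, end = start + sample(30:150, n, replace = TRUE),
      score = sample(1:100, n))
    got <- resolve_overlaps(m)
    want <- brute_resolve(m)
    expect_setequal(got$model_id, want$model_id)
    # no same-strand overlapping pair survives
    for (i in seq_len(nrow(got))) {
      for (j in seq_len(nrow(got))) {
        if (i < j && got$scaffold[i] == got$scaffold[j] &&
            got$strand[i] == got$strand[j]) {
          expect_false(got$start[i] < got$end[j] &&
                         got$start[j] < got$end[i])
        }
      }
    }
  }
})

make_pred <- function(id, scaffold, strand, start, end, cds) {
  tibble::tibble(gene_id = id, scaffold = scaffold, strand = strand,
                 start = start, end = end, cds = cds)
}

test_that("the de novo merge applies consensus, similarity and homology rules", {
  set.seed(53)
  cds1 <- rand_seq(120)
  cds2 <- cds1
  substr(cds2, 1, 10) <- paste(rep("A", 10), collapse = "")  # ~92% identical
  cds3 <- rand_seq(120)
  cds4 <- rand_seq(120)
  a <- dplyr::bind_rows(
    make_pred("a1", "s1", "+", 1000, 2000, cds1),   # similar pair member
    make_pred("a2", "s1", "+", 5000, 6000, cds2),   # similar pair member
    make_pred("a3", "s2", "+", 1000, 2000, cds3),   # survivor, gene-free scaffold
    make_pred("a4", "s1", "+", 9000, 10000, cds4),  # overlaps homology model
    make_pred("a5", "s3", "+", 1000, 2000, rand_seq(120)))  # no B counterpart
  b <- dplyr::bind_rows(
    make_pred("b1", "s1", "+", 1100, 2100, cds1),
    make_pred("b2", "s1", "+", 5000, 6000, cds2),
    make_pred("b3", "s2", "+", 900, 1900, cds3),
    make_pred("b4", "s1", "+", 9000, 10000, cds4))
  homology <- tibble::tibble(
    model_id = "h1", scaffold = "s1", strand = "-", start = 9100, end = 9900,
    score = 100)
  ogs <- merge_denovo(a, b, homology)
  denovo <- ogs[ogs$source == "denovo", ]
  # a5 fails consensus; a1/a2 removed as a >=85% pair (both members);
  # a4 overlaps homology (opposite strand still excludes); a3 appended
  expect_equal(denovo$gene_id, "a3")
  expect_equal(sum(ogs$source == "homology"), 1)
})

test_that("keep-one mode retains a single representative of a similar group", {
  set.seed(54)
  cds <- rand_seq(150)
  cds_b <- cds
  substr(cds_b, 1, 12) <- strrep("T", 12)
  a <- dplyr::bind_rows(
    make_pred("x1", "s1", "+", 100, 260, cds),
    make_pred("x2", "s1", "+", 5000, 5160, cds_b))
  ogs <- merge_denovo(a, a, homology_models = a[0, ], keep_one = TRUE)
  expect_equal(nrow(ogs[ogs$source == "denovo", ]), 1)
  ogs_both <- merge_denovo(a, a, homology_models = a[0, ])
  expect_equal(nrow(ogs_both[ogs_both$source == "denovo", ]), 0)
})

test_that("the merge is idempotent on its own surviving de novo set", {
  set.seed(55)
  a <- dplyr::bind_rows(
    make_pred("g1", "s1", "+", 100, 300, rand_seq(90)),
    make_pred("g2", "s1", "+", 1000, 1200, rand_seq(90)),
    make_pred("g3", "s2", "-", 100, 300, rand_seq(90)))
  no_hom <- a[0, ]
  ogs1 <- merge_denovo(a, a, no_hom)
  denovo1 <- dplyr::select(ogs1[ogs1$source == "denovo", ], -"source")
  ogs2 <- merge_denovo(denovo1, denovo1, no_hom)
  denovo2 <- dplyr::select(ogs2[ogs2$source == "denovo", ], -"source")
  expect_equal(as.data.frame(denovo1), as.data.frame(denovo2))
})

test_that("malformed predictions are rejected", {
  bad <- make_pred("z", "s", "+", 100, 100, "ACGT")
  expect_error(merge_denovo(bad, bad, bad[0, ]), "malformed")
})

test_that("official-gene-set statistics reproduce the donor-set percentage", {
  ogs <- tibble::tibble(source = c(rep("homology", 11139),
                                   rep("denovo", 4765)))
  st <- ogs_stats(ogs, donor_set_size = 15314)
  expect_equal(st$n_total, 15904)
  expect_equal(st$homology_percentage, 73)
  expect_equal(ogs_stats(tibble::tibble(source = character()), 100)$homology_percentage, 0)
  ogs_all <- tibble::tibble(source = rep("homology", 50))
  expect_equal(ogs_stats(ogs_all, 50)$homology_percentage, 100)
  expect_error(ogs_stats(ogs_all, 0), "donor_set_size")
})
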