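test_that("annotated sequences validate residues and feature bounds", {
  s <- annotated_seq("x", "acgtn")
  expect_equal(s$residues, "ACGTN")
  expect_error(annotated_seq("x", ""), "non-empty")
  expect_error(annotated_seq("x", "ACGU"), "outside")
  expect_error(
    annotated_seq("x", "ACGT", feats = features("CDS", 1, 10)),
    "beyond"
  )
  expect_error(features("exonish", 1, 5), "unknown feature kind")
})

test_that("FASTA round-trips through Biostrings wrappers", {
  tf <- tempfile(fileext = ".fa")
  seqs <- c(a = "ACGTACGTAA", b = strrep("ACGT", 40))
  write_fasta(seqs, tf)
  expect_equal(read_fasta(tf), seqs)
})

test_that("GFF3 features convert to internal 1-based coordinates with intron ranks", {
  tf <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t10\t30\t.\t+\t.\tID=cds1;gene=ops1",
    "chr1\ttest\tintron\t31\t60\t.\t+\t.\tID=i1;gene=ops1",
    "chr1\ttest\tintron\t81\t120\t.\t+\t.\tID=i2;gene=ops1"
  ), tf)
  ft <- read_features(tf)
  expect_equal(ft$kind, c("CDS", "intron", "intron"))
  expect_equal(ft$start, c(10L, 31L, 81L))
  expect_equal(ft$rank[ft$kind == "intron"], c(1L, 2L))
})

test_that("BED export is 0-based half-open", {
  tf <- tempfile(fileext = ".bed")
  write_bed(data.frame(id = "e1", start = 11L, end = 20L), tf, seqname = "s")
  expect_equal(readLines(tf), "s\t10\t20\te1")
})

test_that("p-distance counts comparable columns and excludes gaps, N and masks", {
  expect_equal(p_distance(pairwise_alignment("AAAA", "AAAA"))$p, 0)
  expect_equal(p_distance(pairwise_alignment("AAAA", "AAAT"))$p, 0.25)
  est <- p_distance(pairwise_alignment("AA-A", "AACA"))
  expect_equal(est$p, 0)
  expect_equal(est$n_comparable, 3L)
  ## N in either row is non-comparable, not a difference
  est <- p_distance(pairwise_alignment("ANAA", "AAAT"))
  expect_equal(est$n_comparable, 3L)
  expect_equal(est$p, 1 / 3)
  ## masking
  est <- p_distance(pairwise_alignment("AAAT", "AAAA"), mask = 4L)
  expect_equal(est$p, 0)
  expect_error(p_distance(pairwise_alignment("NNN", "AAA")), "no comparable")
})

test_that("p-distance is invariant to swapping rows", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_sequence(60)
    b <- evolve_sequence(a, 0.3)
    aln <- pairwise_alignment(a, b)
    rev_aln <- pairwise_alignment(b, a)
    expect_equal(p_distance(aln)$p, p_distance(rev_aln)$p)
  }
})

test_that("JC69 correction matches the closed form and is increasing", {
  expect_equal(jc69_distance(0), 0)
  expect_equal(jc69_distance(0.25), 0.3040988, tolerance = 1e-6)
  expect_equal(jc69_distance(0.10), 0.1073256, tolerance = 1e-6)
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jc69_distance(p)) > 0))
  expect_true(all(jc69_distance(p[p > 0]) > p[p > 0]))
  expect_gt(jc69_distance(0.749999), 10)  # blow-up toward saturation
  expect_error(jc69_distance(0.75), "saturation")
  expect_error(jc69_distance(0.9), "saturation")
})

test_that("intron masking drops first introns and 6-bp edges", {
  ft <- features("intron", 1, 100, rank = 1)
  expect_equal(intron_interior_mask(ft), 1:100)
  ft <- features("intron", 101, 120, rank = 2)
  m <- intron_interior_mask(ft)
  expect_length(m, 12L)
  expect_equal(m, c(101:106, 115:120))
  ## degenerate short intron: wholly excluded
  ft <- features("intron", 1, 10, rank = 2)
  expect_equal(intron_interior_mask(ft), 1:10)
  expect_error(intron_interior_mask(features("intron", 1, 10)), "rank")
})

test_that("region divergence applies masks and reports missing regions as NA", {
  a <- strrep("A", 120)
  aln <- pairwise_alignment(a, a)
  ft <- features("CDS", 1, 50)
  expect_equal(region_divergence(aln, ft)$Dxy, 0)

  ## 2 mismatches over a 50-site CDS
  b <- paste0("TT", strrep("A", 118))
  rd <- region_divergence(pairwise_alignment(a, b), ft)
  expect_equal(rd$p, 0.04)
  expect_equal(rd$Dxy, jc69_distance(0.04))
  expect_equal(rd$n_comparable, 50L)

  ## feature entirely opposite a gap run: missing, not zero
  b <- paste0(strrep("-", 50), strrep("A", 70))
  rd <- region_divergence(pairwise_alignment(a, b), ft)
  expect_true(is.na(rd$p))
  expect_true(is.na(rd$Dxy))
})

test_that("region divergence pools as a weighted mean of per-feature p", {
  set.seed(42)
  a <- random_sequence(300)
  b <- evolve_sequence(a, 0.2)
  aln <- pairwise_alignment(a, b)
  ft <- features(c("CNE", "CNE", "CNE"), c(1, 101, 201), c(100, 200, 300))
  per <- region_divergence(aln, ft)
  whole <- region_divergence(aln, features("CNE", 1, 300))
  expect_equal(whole$p,
               sum(per$p * per$n_comparable) / sum(per$n_comparable))
})

test_that("log t-test matches the textbook pooled formula", {
  expect_error(log_ttest(c(0.1, -0.2, 0.3), c(0.1, 0.2, 0.3)), "positive")
  expect_error(log_ttest(0.1, c(0.2, 0.3)), "at least two")
  g <- c(0.01, 0.02, 0.04)
  res <- log_ttest(g, g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(log_ttest(c(0.01, 0.01, 0.01), c(0.1, 0.1, 0.1)),
               "degenerate")
  set.seed(7)
  for (i in 1:5) {
    a <- rlnorm(10, -3, 0.5)
    b <- rlnorm(10, -2.5, 0.5)
    got <- log_ttest(a, b)
    ora <- oracle_pooled_t(log10(a), log10(b))
    expect_equal(got$t, ora$t, tolerance = 1e-10)
    expect_equal(got$df, 18)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
  }
})

test_that("aligned FASTA round-trips and the aligner recovers an indel", {
  tf <- tempfile(fileext = ".fa")
  write_fasta(c(on = "ACGT-ACGT", mz = "ACGTTACGT"), tf)
  aln <- read_pairwise_alignment(tf)
  expect_equal(ungap(aln, "A"), "ACGTACGT")
  expect_equal(ungap(aln, "B"), "ACGTTACGT")
  expect_equal(aln$mapA[5], NA_integer_)

  a <- paste0(strrep("ACGT", 10), strrep("TTAC", 10))
  b <- paste0(strrep("ACGT", 10), "GGGG", strrep("TTAC", 10))
  aln <- align_pair(a, b)
  expect_equal(ungap(aln, "A"), a)
  expect_equal(ungap(aln, "B"), b)
  expect_equal(sum(is.na(aln$mapA)), 4L)
})
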