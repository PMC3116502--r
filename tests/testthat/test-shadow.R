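mk_hits <- function(factor, start, strand = "+", La = 12, width = 12L) {
  data.frame(factor = factor, accession = factor,
             start = as.integer(start),
             end = as.integer(start) + width - 1L,
             strand = rep_len(strand, length(start)),
             La = rep_len(La, length(start)),
             Lq = 0.9, Lpv = 0.001, stringsAsFactors = FALSE)
}

ident_aln <- function(len) {
  s <- strrep("A", len)
  pairwise_alignment(s, s)
}

test_that("hit matching pairs same-factor overlapping sites and counts divergence", {
  aln <- ident_aln(500)
  ## identical hit sets: all shared
  h <- mk_hits("CRX", c(10, 100, 300))
  m <- match_hits(h, h, aln)
  expect_equal(m$S, 3L)
  expect_equal(m$D, 0L)

  ## 8 hits in A, 1 in B overlapping one of them: S = 1, D = 7
  hA <- mk_hits("CRX", seq(10, 430, by = 60))
  hB <- mk_hits("CRX", 130)
  m <- match_hits(hA, hB, aln)
  expect_equal(m$S, 1L)
  expect_equal(m$D, 7L)

  ## same position, different factors: no match
  m <- match_hits(mk_hits("CRX", 50), mk_hits("AP-1", 50), aln)
  expect_equal(m$S, 0L)
  expect_equal(m$D, 2L)

  ## strand-agnostic matching
  m <- match_hits(mk_hits("CRX", 50, "+"), mk_hits("CRX", 52, "-"), aln)
  expect_equal(m$S, 1L)

  ## hits beyond the aligned interval are dropped with a warning
  expect_warning(m <- match_hits(mk_hits("CRX", c(50, 495)),
                                 mk_hits("CRX", 50), aln),
                 "outside")
  expect_equal(m$S, 1L)
  expect_equal(m$D, 0L)
})

test_that("divergence counts are symmetric in the species order", {
  set.seed(31)
  aln <- ident_aln(1000)
  for (rep in 1:10) {
    hA <- mk_hits(sample(c("CRX", "AP-1"), 6, TRUE),
                  sample(seq(1, 980, by = 14), 6))
    hB <- mk_hits(sample(c("CRX", "AP-1"), 4, TRUE),
                  sample(seq(1, 980, by = 14), 4))
    m1 <- match_hits(hA, hB, aln)
    m2 <- match_hits(hB, hA, aln)
    expect_equal(m1$S, m2$S)
    expect_equal(m1$D, m2$D)
  }
})

test_that("P_div is the exact percentage and is scale-free", {
  expect_equal(pdiv(7, 1), 87.5)
  expect_equal(pdiv(0, 2), 0)
  expect_equal(pdiv(4, 4), 50)
  expect_equal(pdiv(2, 0), 100)
  expect_error(pdiv(0, 0), "untestable")
  for (k in 2:5) expect_equal(pdiv(3 * k, 7 * k), pdiv(3, 7))
})

test_that("the exact binomial test reproduces published values and binom.test", {
  expect_equal(binom_divergence_test(0, 5), 1)
  expect_equal(round(binom_divergence_test(4, 4), 3), 0.002)
  expect_equal(round(binom_divergence_test(1, 8), 3), 0.528)
  expect_equal(round(binom_divergence_test(3, 6), 3), 0.030)
  ## independent cross-check against stats::binom.test
  set.seed(32)
  for (rep in 1:20) {
    D <- sample(0:10, 1); S <- sample(0:15, 1)
    if (D + S == 0) S <- 1
    p0 <- runif(1, 0.02, 0.4)
    expect_equal(binom_divergence_test(D, S, p0),
                 binom.test(D, D + S, p0, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("binomial p is monotone in the null and in the divergent count", {
  n <- 12
  p0s <- seq(0.02, 0.5, by = 0.02)
  for (D in c(1, 4, 8)) {
    pv <- vapply(p0s, function(q) binom_divergence_test(D, n - D, q),
                 numeric(1))
    expect_true(all(diff(pv) >= -1e-12))  # non-decreasing in p0
  }
  pv <- vapply(0:n, function(D) binom_divergence_test(D, n - D, 0.08),
               numeric(1))
  expect_true(all(diff(pv) <= 1e-12))     # non-increasing in D
})

test_that("Bonferroni correction gives the family threshold and caps at one", {
  adj <- bonferroni_adjust(c(0.001, 1), m = 31)
  expect_equal(adj$threshold, 0.05 / 31)
  expect_equal(round(adj$threshold, 4), 0.0016)
  expect_equal(adj$adjusted, c(0.031, 1))
  expect_equal(bonferroni_adjust(0.001, m = 10)$adjusted, 0.01)
  expect_error(bonferroni_adjust(0.5, m = 0), "at least 1")
})

test_that("the paired Wilcoxon comparison sums positive ranks", {
  a <- 1:10 + 0.5
  b <- 1:10 - 0.5
  res <- enrichment_wilcoxon(a, b)
  expect_equal(res$V, 55)
  res <- enrichment_wilcoxon(b, a)
  expect_equal(res$V, 0)
  expect_error(enrichment_wilcoxon(a, a), "untestable")
  ## zero differences are dropped from n
  res <- enrichment_wilcoxon(c(a, 3), c(b, 3))
  expect_equal(res$n, 10)
})

test_that("the Mantel statistic matches vegan and honours affine invariance", {
  set.seed(33)
  m1 <- random_dist_matrix(8)
  expect_equal(mantel_test(m1, m1, n_perm = 19)$r, 1)
  expect_equal(mantel_test(m1, 3 * m1 + 2, n_perm = 19)$r, 1)
  m2 <- random_dist_matrix(8)
  got <- mantel_test(m1, m2, n_perm = 99, seed = 1)
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(m1, m2, permutations = 99)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
  expect_error(mantel_test(m1, matrix(0, 8, 8)), "constant")
  expect_error(mantel_test(m1, random_dist_matrix(5)), "dimensions")
})

test_that("the counts-based shadow table reproduces the published columns", {
  tab <- utils::read.delim(counts_fixture_path(), stringsAsFactors = FALSE)
  st <- shadow_table(data.frame(region = tab$region, D = tab$D, S = tab$S))
  expect_equal(attr(st, "m"), 31L)  # 31 testable regions in the family
  testable <- !is.na(st$p_value)
  expect_equal(sum(testable), 31L)

  ## P_div at one-decimal rounding; the RH2B promoter row is printed with
  ## inconsistent rounding (15/22 -> 68.18 prints as 68.1), so compare at
  ## one unit in the last printed digit
  pd_print <- suppressWarnings(as.numeric(tab$printed_pdiv))
  dev <- abs(round(st$P_div, 1) - pd_print)
  expect_true(all(dev[testable] <= 0.1 + 1e-9))
  expect_equal(sum(dev[testable] > 1e-9), 1L)
  expect_equal(tab$region[which(dev > 1e-9)], "RH2B_prom")

  ## untestable regions propagate as NA rows
  expect_true(all(is.na(st$P_div[tab$region %in%
                                   c("CNE_6", "CNE_19", "CNE_10")])))
  ## Bonferroni-adjusted values cap at 1 and scale by m
  expect_equal(st$p_adjusted[testable],
               pmin(1, st$p_value[testable] * 31))
})
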