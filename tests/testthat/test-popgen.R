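test_that("variant calling separates SNPs, indels and singletons", {
  ## identical rows: no variants
  p <- haplotype_panel(rep(strrep("ACGT", 10), 4))
  v <- call_variants(p)
  expect_equal(nrow(v), 0L)

  ## 4 T vs 14 C in an 18-taxon column: MAF 4/18 = 0.222
  base <- strrep("A", 30)
  rows <- rep(base, 18)
  substr(rows[1:4], 10, 10) <- "T"
  substr(rows[5:18], 10, 10) <- "C"
  v <- call_variants(haplotype_panel(rows))
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "SNP")
  expect_equal(round(v$maf, 3), 0.222)
  expect_false(v$singleton)

  ## an 8-bp deletion in 5 of 18 taxa: one indel variant
  rows <- rep(strrep("ACGT", 10), 18)
  substr(rows[1:5], 13, 20) <- "--------"
  v <- call_variants(haplotype_panel(rows))
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "indel")
  expect_equal(v$length, 8L)
  expect_equal(v$maf, 5 / 18)
  g <- attr(v, "genotypes")
  expect_equal(unname(g[, 1]), c(rep(1L, 5), rep(0L, 13)))

  ## singletons have MAF 1/n
  rows <- rep(base, 10)
  substr(rows[1], 5, 5) <- "G"
  v <- call_variants(haplotype_panel(rows))
  expect_true(v$singleton)
  expect_equal(v$maf, 0.1)
})

test_that("panel summaries match hand-derived small cases", {
  p <- haplotype_panel(rep(strrep("ACGT", 25), 5))
  s <- panel_summary(p)
  expect_equal(s$S, 0L)
  expect_equal(s$s, 0L)
  expect_equal(s$H, 1L)
  expect_equal(s$pi, 0)
  expect_equal(s$C, 1)
  expect_true(is.na(s$TD))

  ## n = 4, L = 100, one SNP split 2/2: khat = 4/6, pi = 0.006667
  rows <- rep(strrep("A", 100), 4)
  substr(rows[1:2], 50, 50) <- "G"
  s <- panel_summary(haplotype_panel(rows))
  expect_equal(s$khat, 4 / 6, tolerance = 1e-12)
  expect_equal(s$pi, 4 / 6 / 100, tolerance = 1e-12)
  expect_equal(s$S, 1L)
  expect_equal(s$s, 0L)
  expect_equal(s$H, 2L)

  ## two singleton SNPs in n = 10 push Tajima's D negative
  rows <- rep(strrep("A", 100), 10)
  substr(rows[1], 10, 10) <- "C"
  substr(rows[2], 60, 60) <- "T"
  s <- panel_summary(haplotype_panel(rows))
  expect_equal(s$S, 2L)
  expect_equal(s$s, 2L)
  expect_lt(s$TD, 0)
})

test_that("pi, S, s, H and Tajima's D match independent oracles on random panels", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    L <- sample(60:200, 1)
    mat <- random_panel(n, L)
    p <- panel_from_matrix(mat)
    got <- panel_summary(p)
    ora <- oracle_panel_stats(mat)
    expect_equal(got$S, ora$S)
    expect_equal(got$s, ora$s)
    expect_equal(got$H, ora$H)
    expect_equal(got$pi, ora$pi, tolerance = 1e-12)
    expect_equal(got$TD, oracle_tajima_d(ora$khat, ora$S, n),
                 tolerance = 1e-10)
  }
})

test_that("nucleotide diversity agrees with ape raw distances on gap-free panels", {
  skip_if_not_installed("ape")
  set.seed(52)
  for (rep in 1:5) {
    mat <- random_panel(8, 120)
    p <- panel_from_matrix(mat)
    bin <- ape::as.DNAbin(tolower(mat))
    ## mean pairwise raw distance = mean pairwise differences per site
    ref <- mean(ape::dist.dna(bin, model = "raw"))
    expect_equal(panel_summary(p)$pi, ref, tolerance = 1e-10)
  }
})

test_that("gap columns drop out of the diversity denominator", {
  rows <- rep(strrep("A", 60), 6)
  substr(rows[1], 30, 30) <- "-"
  substr(rows[1], 10, 10) <- "G"   # SNP at 10
  s <- panel_summary(haplotype_panel(rows))
  expect_equal(s$L_valid, 59L)
  expect_equal(s$S, 1L)
  expect_equal(s$C, 1 - 1 / 59)
})

test_that("sliding windows localise diversity and reduce denominators at gaps", {
  rows <- rep(strrep("A", 200), 6)
  substr(rows[1:3], 25, 25) <- "T"
  p <- haplotype_panel(rows)
  prof <- sliding_profile(p, window = 50, step = 10)
  hot <- prof$pi_window > 0
  expect_true(all(prof$start[hot] <= 25 & prof$end[hot] >= 25))
  expect_true(any(hot))
  expect_equal(max(prof$maf_window), 0.5)

  ## tiling windows (step = window) average back to the panel-wide pi
  prof <- sliding_profile(p, window = 50, step = 50)
  expect_equal(sum(prof$pi_window * prof$n_valid) / sum(prof$n_valid),
               panel_summary(p)$pi, tolerance = 1e-12)

  ## gap column reduces the window denominator by one
  substr(rows[2], 40, 40) <- "-"
  prof2 <- sliding_profile(haplotype_panel(rows), window = 50, step = 10)
  expect_equal(prof2$n_valid[1], 49L)

  ## region shorter than the window: single window
  short <- haplotype_panel(rep(strrep("ACGT", 10), 4))
  expect_equal(nrow(sliding_profile(short, window = 50, step = 10)), 1L)
})

test_that("windowed pi recomputes exactly per window", {
  set.seed(53)
  mat <- random_panel(8, 150, n_mut = 15)
  p <- panel_from_matrix(mat)
  prof <- sliding_profile(p, window = 50, step = 10)
  i <- which.max(prof$pi_window)
  sub <- mat[, prof$start[i]:prof$end[i], drop = FALSE]
  expect_equal(prof$pi_window[i], oracle_panel_stats(sub)$pi,
               tolerance = 1e-12)
})

test_that("MAF never exceeds one half", {
  set.seed(54)
  for (rep in 1:10) {
    v <- call_variants(panel_from_matrix(random_panel(sample(4:12, 1), 80)))
    if (nrow(v)) expect_true(all(v$maf <= 0.5 + 1e-12))
  }
})

test_that("additive association recovers clean effects and flags degeneracies", {
  g <- rep(c(0, 1), each = 9)
  ## exact linear phenotype: perfect fit
  res <- suppressWarnings(snp_association(g, 2 * g))
  expect_equal(res$r2, 1)
  expect_lt(res$p, 1e-12)
  expect_equal(res$beta, 2)

  res <- snp_association(rep(0, 18), rnorm(18))
  expect_equal(res$note, "monomorphic")
  expect_true(is.na(res$p))

  ## genotype identical to the covariate: collinear
  res <- snp_association(g, rnorm(18), covariate = g)
  expect_equal(res$note, "collinear")

  ## with a real covariate the genotype df drop is reported
  set.seed(55)
  cl <- rep(c(0, 1), 9)
  y <- 0.3 * g + 0.1 * cl + rnorm(18, 0, 0.1)
  res <- snp_association(g, y, covariate = cl)
  expect_equal(res$df, 15L)
  expect_lt(res$p, 0.01)
})

test_that("parameter recovery: beta estimated within two standard errors", {
  set.seed(56)
  ok <- 0
  for (rep in 1:20) {
    g <- sample(rep(c(0, 1), c(12, 6)))
    cl <- rep(c(0, 1), 9)
    y <- simulate_phenotype(g, beta = 0.3, clade = cl, clade_effect = 0.1,
                            sigma = 0.1)
    res <- snp_association(g, y, covariate = cl)
    if (abs(res$beta - 0.3) <= 2 * res$se) ok <- ok + 1
  }
  expect_gte(ok, 17)  # ~95% nominal coverage
})

test_that("a panel-wide scan orders variants by evidence", {
  set.seed(57)
  sim <- simulate_panel(random_sequence(800), n = 18, theta = 4)
  v <- call_variants(sim$panel)
  skip_if(nrow(v) < 2)
  g <- attr(v, "genotypes")
  causal <- which.max(v$maf)
  y <- simulate_phenotype(g[, causal], beta = 0.5, sigma = 0.05)
  res <- associate_panel(sim$panel, y)
  p_causal <- res$p[res$pos == v$pos[causal]]
  ## the causal variant attains the minimum p (ties only with variants in
  ## perfect linkage, i.e. identical genotype vectors)
  expect_equal(p_causal, min(res$p, na.rm = TRUE))
})

test_that("the VCF export is valid and round-trips genotypes", {
  skip_if_not_installed("vcfR")
  rows <- rep(strrep("ACGT", 20), 6)
  substr(rows[1:2], 10, 10) <- "T"
  substr(rows[3], 41, 44) <- "----"
  p <- haplotype_panel(rows, region_id = "reg1")
  v <- call_variants(p)
  tf <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, p, tf)
  vc <- suppressWarnings(vcfR::read.vcfR(tf, verbose = FALSE))
  expect_equal(nrow(vc@fix), nrow(v))
  gt <- vcfR::extract.gt(vc)
  expect_equal(unname(gt[1, ]), as.character(attr(v, "genotypes")[, 1]))
})
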