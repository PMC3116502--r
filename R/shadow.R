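## Phylogenetic shadowing: matching binding-site hits between orthologous
## sequences, the divergence proportion P_div, exact binomial tests against
## a neutral-divergence null, Bonferroni correction, and the panel-level
## enrichment (Wilcoxon) and expression-correlation (Mantel) comparisons.

#' Match binding-site hits between two orthologous sequences
#'
#' A hit in species A matches at most one hit in species B with the same
#' factor whose alignment-projected interval overlaps by at least one
#' column; matching is strand-agnostic (factors bind in an
#' orientation-independent manner) and greedy left to right, ties broken by
#' larger overlap, then higher `La` of the B hit. Hits falling outside the
#' aligned interval are excluded with a warning.
#'
#' @param hitsA,hitsB Hit tables from [scan_sequence()], on the ungapped A
#'   and B sequences respectively.
#' @param aln A [pairwise_alignment()] of the two sequences.
#' @return List of class `hit_match`: `S` (shared pairs), `D` (divergent
#'   hits), `pairs` (data frame of matched index pairs with overlap),
#'   `unmatchedA`, `unmatchedB` (row indices).
#' @export
match_hits <- function(hitsA, hitsB, aln) {
  projA <- .project_hits(hitsA, aln$invA, "A")
  projB <- .project_hits(hitsB, aln$invB, "B")
  hitsA <- hitsA[projA$keep, , drop = FALSE]
  hitsB <- hitsB[projB$keep, , drop = FALSE]
  cA <- projA$cols; cB <- projB$cols
  ordA <- order(cA[, 1])
  matchedB <- rep(FALSE, nrow(hitsB))
  pairs <- list()
  for (i in ordA) {
    cand <- which(!matchedB & hitsB$factor == hitsA$factor[i] &
                    cB[, 1] <= cA[i, 2] & cB[, 2] >= cA[i, 1])
    if (!length(cand)) next
    ov <- pmin(cB[cand, 2], cA[i, 2]) - pmax(cB[cand, 1], cA[i, 1]) + 1L
    pick <- order(-ov, -hitsB$La[cand])[1]
    j <- cand[pick]
    matchedB[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = i, b = j, factor = hitsA$factor[i],
      overlap = ov[pick], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(a = integer(), b = integer(),
                           factor = character(), overlap = integer())
  unmatchedA <- setdiff(seq_len(nrow(hitsA)), pairs$a)
  unmatchedB <- which(!matchedB)
  structure(
    list(S = nrow(pairs), D = length(unmatchedA) + length(unmatchedB),
         pairs = pairs, unmatchedA = unmatchedA, unmatchedB = unmatchedB),
    class = "hit_match"
  )
}

.project_hits <- function(hits, inv, label) {
  n <- length(inv)
  keep <- hits$start >= 1L & hits$end <= n
  if (any(!keep))
    warning(sum(!keep), " hit(s) in ", label,
            " outside the aligned interval; excluded")
  cols <- cbind(inv[hits$start[keep]], inv[hits$end[keep]])
  list(keep = keep, cols = cols)
}

#' @export
print.hit_match <- function(x, ...) {
  cat(sprintf("<hit_match> shared S = %d, divergent D = %d\n", x$S, x$D))
  invisible(x)
}

#' Divergence proportion of binding/target sites
#'
#' `P_div = 100 * D / (D + S)` percent, where `D` counts sites present in
#' exactly one species and `S` shared site pairs.
#'
#' @param D,S Non-negative counts with `D + S >= 1`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' pdiv(7, 1) # 87.5
#' @export
pdiv <- function(D, S) {
  stopifnot(D >= 0, S >= 0)
  if (D + S < 1) stop("untestable: D + S must be at least 1")
  100 * D / (D + S)
}

#' Exact binomial test of the divergence proportion
#'
#' Upper-tail exact binomial p-value for the hypothesis that the true
#' divergence proportion exceeds `p0`:
#' `p = sum_{k=D..n} C(n,k) p0^k (1-p0)^(n-k)` with `n = D + S`. The
#' default null `p0 = 0.08` reflects a genome-wide divergence of ~8%
#' (sequences ~92% identical); a region-specific null (e.g. the masked
#' intron divergence of the nearest gene) can be supplied instead.
#'
#' @param D,S Divergent and shared counts, `D + S >= 1`.
#' @param p0 Null divergence proportion in `(0, 1)`.
#' @return Upper-tail p-value.
#' @examples
#' binom_divergence_test(4, 4)  # ~0.002
#' @export
binom_divergence_test <- function(D, S, p0 = 0.08) {
  stopifnot(D >= 0, S >= 0, D + S >= 1, p0 > 0, p0 < 1)
  stats::pbinom(D - 1, D + S, p0, lower.tail = FALSE)
}

#' Bonferroni adjustment and family-wise threshold
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(pvals)`.
#' @param alpha Family-wise error rate.
#' @return List with `adjusted` (`min(1, p * m)`), `threshold`
#'   (`alpha / m`) and `m`.
#' @examples
#' bonferroni_adjust(0.001, m = 31)$threshold # 0.05/31 ~ 0.0016
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals), alpha = 0.05) {
  if (m < 1) stop("family size m must be at least 1")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  list(adjusted = pmin(1, pvals * m), threshold = alpha / m, m = m)
}

#' Paired Wilcoxon signed-rank comparison of per-factor site counts
#'
#' Zero differences are dropped; `V` is the sum of ranks of positive
#' differences (ranks of absolute differences, averaged on ties); the
#' two-sided p-value is exact when there are no ties or zeros, otherwise a
#' normal approximation is used.
#'
#' @param counts_groupA,counts_groupB Paired numeric vectors over the same
#'   factors.
#' @return List with `V`, `p` and `n` (non-zero pairs).
#' @export
enrichment_wilcoxon <- function(counts_groupA, counts_groupB) {
  stopifnot(length(counts_groupA) == length(counts_groupB))
  d <- counts_groupA - counts_groupB
  if (all(d == 0)) stop("untestable: all paired differences are zero")
  wt <- suppressWarnings(
    stats::wilcox.test(counts_groupA, counts_groupB, paired = TRUE,
                       exact = NULL, correct = TRUE)
  )
  list(V = unname(wt$statistic), p = wt$p.value, n = sum(d != 0))
}

#' Mantel test of two distance matrices
#'
#' `r` is the Pearson correlation of the strictly-lower-triangle entries;
#' the permutation p-value applies simultaneous row/column permutations to
#' the second matrix and uses the add-one correction
#' `p = (1 + #[r_perm >= r]) / (1 + n_perm)`.
#'
#' @param matrix1,matrix2 Square symmetric distance matrices with zero
#'   diagonal and identical dimensions.
#' @param n_perm Number of permutations (default 500).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(matrix1, matrix2, n_perm = 500L, seed = NULL) {
  matrix1 <- as.matrix(matrix1); matrix2 <- as.matrix(matrix2)
  n <- nrow(matrix1)
  if (!all(dim(matrix1) == n) || !all(dim(matrix2) == n))
    stop("matrices must be square with identical dimensions")
  if (max(abs(matrix1 - t(matrix1))) > 1e-8 ||
      max(abs(matrix2 - t(matrix2))) > 1e-8)
    stop("matrices must be symmetric")
  lt <- lower.tri(matrix1)
  v1 <- matrix1[lt]
  if (stats::sd(v1) == 0 || stats::sd(matrix2[lt]) == 0)
    stop("constant off-diagonal entries: correlation undefined")
  r <- stats::cor(v1, matrix2[lt])
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- stats::cor(v1, matrix2[p, p][lt])
    if (rp >= r) hits <- hits + 1L
  }
  list(r = r, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Region-level shadowing table from shared/divergent counts
#'
#' Builds the per-region summary from counts alone: divergence proportion
#' `P_div`, the upper-tail exact binomial p-value against `p0`, and
#' Bonferroni-adjusted p-values with family size `m` defaulting to the
#' number of testable regions (`D + S >= 1`). Untestable regions (missing
#' counts or `D + S = 0`) are carried through with `NA`s.
#'
#' @param counts Data frame with columns `region` (label), `D`, `S`
#'   (integers, `NA` for regions with no identifiable ortholog); further
#'   columns (identity, lengths, ...) are passed through.
#' @param p0 Null divergence proportion.
#' @param alpha Family-wise error rate for the significance flag.
#' @param m Family size override; default = number of testable regions.
#' @return Data frame of class `shadow_table` with added columns `P_div`,
#'   `p_value`, `p_adjusted`, `significant`, plus attributes `m`,
#'   `threshold`, `p0`.
#' @examples
#' shadow_table(data.frame(region = c("r1", "r2"), D = c(7, 0), S = c(1, 2)))
#' @export
shadow_table <- function(counts, p0 = 0.08, alpha = 0.05, m = NULL) {
  stopifnot(all(c("region", "D", "S") %in% names(counts)))
  testable <- !is.na(counts$D) & !is.na(counts$S) & (counts$D + counts$S) >= 1
  if (is.null(m)) m <- sum(testable)
  if (m < 1) stop("no testable regions")
  out <- counts
  out$P_div <- ifelse(testable, 100 * counts$D / (counts$D + counts$S),
                      NA_real_)
  out$p_value <- NA_real_
  out$p_value[testable] <- mapply(binom_divergence_test,
                                  counts$D[testable], counts$S[testable],
                                  MoreArgs = list(p0 = p0))
  adj <- bonferroni_adjust(out$p_value[testable], m = m, alpha = alpha)
  out$p_adjusted <- NA_real_
  out$p_adjusted[testable] <- adj$adjusted
  out$significant <- !is.na(out$p_value) & out$p_value < adj$threshold
  attr(out, "m") <- m
  attr(out, "threshold") <- adj$threshold
  attr(out, "p0") <- p0
  class(out) <- c("shadow_table", "data.frame")
  out
}

#' @export
print.shadow_table <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<shadow_table> %d region(s), %d testable; null p0 = %s, m = %d, threshold = %.3g\n",
    nrow(x), sum(!is.na(x$p_value)), format(attr(x, "p0")),
    attr(x, "m"), attr(x, "threshold")))
  df <- as.data.frame(x)
  df$P_div <- round(df$P_div, 1)
  df$p_value <- signif(df$p_value, digits)
  df$p_adjusted <- signif(df$p_adjusted, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
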