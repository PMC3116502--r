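## Independent oracles, deliberately coded from first principles rather
## than through the package's own code paths.

## exhaustive tail probability of a PWM score by enumerating all 4^L kmers
enum_pwm_tail <- function(pwm, La) {
  L <- pwm$width
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(pwm$scores[cbind(as.vector(grid),
                                        rep(seq_len(L), each = nrow(grid)))],
                       nrow(grid), L))
  pr <- exp(rowSums(matrix(log(pwm$background)[as.vector(grid)],
                           nrow(grid), L)))
  sum(pr[sc >= La])
}

## random PWM with Dirichlet-ish column counts
random_pwm <- function(width, depth = 20) {
  counts <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(width)) {
    w <- stats::rgamma(4, shape = 0.7)
    counts[, j] <- round(depth * w / sum(w))
  }
  pwm_model(counts, factor = "rand", accession = "RND")
}

## brute-force mean pairwise difference statistics for a character matrix
## (rows = taxa); complete deletion of columns with gap or N
oracle_panel_stats <- function(mat) {
  ok <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  vm <- mat[, ok, drop = FALSE]
  n <- nrow(vm)
  dsum <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    dsum <- dsum + sum(vm[i, ] != vm[j, ])
  khat <- dsum / (n * (n - 1) / 2)
  seg <- which(apply(vm, 2, function(col) length(unique(col)) > 1))
  sing <- 0
  for (j in seg) {
    tab <- table(vm[, j])
    if (length(tab) == 2 && min(tab) == 1) sing <- sing + 1
  }
  haps <- unique(apply(vm, 1, paste, collapse = ""))
  list(S = length(seg), s = sing, H = length(haps),
       khat = khat, pi = khat / ncol(vm), L_valid = ncol(vm))
}

## Tajima's D coded independently (different algebraic arrangement)
oracle_tajima_d <- function(khat, S, n) {
  if (S == 0) return(NA_real_)
  h <- sum(1 / seq_len(n - 1))
  g <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / h
  c2 <- b2 - (n + 2) / (h * n) + g / (h * h)
  v <- (c1 / h) * S + (c2 / (h * h + g)) * S * (S - 1)
  (khat - S / h) / sqrt(v)
}

## textbook pooled-variance two-sample t-test
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## naive substring scan for seed motifs
oracle_seed_count <- function(utr, motif) {
  L <- nchar(utr); w <- nchar(motif)
  if (L < w) return(0L)
  sum(vapply(seq_len(L - w + 1L),
             function(i) substr(utr, i, i + w - 1L) == motif, logical(1)))
}

## does any substring of length >= min_len have identity > min_id?
## (per-position match vector over focal coordinates, gap in comparison
## counted as mismatch)
oracle_has_conserved_substring <- function(match, min_len, min_id) {
  n <- length(match)
  if (n < min_len) return(FALSE)
  cs <- c(0, cumsum(match))
  for (len in min_len:n) {
    for (s in 1:(n - len + 1)) {
      if ((cs[s + len] - cs[s]) / len > min_id) return(TRUE)
    }
  }
  FALSE
}

## random symmetric distance matrix with zero diagonal
random_dist_matrix <- function(n) {
  pts <- matrix(stats::rnorm(n * 3), n)
  as.matrix(stats::dist(pts))
}

## a quick random panel: random ancestor + random per-column mutations
random_panel <- function(n, L, n_mut = rpois(1, 8)) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), n, L)
  for (m in seq_len(n_mut)) {
    j <- sample.int(L, 1)
    carriers <- sample.int(n, sample.int(n - 1, 1))
    alt <- sample(setdiff(c("A", "C", "G", "T"), mat[1, j]), 1)
    mat[carriers, j] <- alt
  }
  rownames(mat) <- paste0("t", seq_len(n))
  mat
}

panel_from_matrix <- function(mat, id = "test") {
  haplotype_panel(apply(mat, 1, paste, collapse = ""), region_id = id)
}

.read_report_for_test <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

counts_fixture_path <- function() {
  system.file("extdata", "onil_mzeb_site_counts.tsv", package = "regshadow")
}
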