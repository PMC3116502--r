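## Position-weight-matrix models: log-likelihood scoring in bits, maximum
## score ratio, exact tail p-values by dynamic programming over discretised
## per-position score distributions, and two-strand sequence scanning.

#' Construct a PWM model
#'
#' Per-position counts are converted to pseudocounted frequencies
#' `f = (count + pseudocount) / (N + 4 * pseudocount)` and to bit scores
#' `log2(f / background)`.
#'
#' @param counts Numeric matrix of non-negative base counts, 4 rows named
#'   `A`, `C`, `G`, `T`, one column per motif position.
#' @param factor Transcription-factor name (e.g. `"CRX"`).
#' @param accession Matrix identifier (e.g. `"T03461"`).
#' @param pseudocount Additive constant per base (default 0.5).
#' @param background Named base frequencies, strictly positive, summing
#'   to 1; default uniform.
#' @return Object of class `pwm_model`: list with `factor`, `accession`,
#'   `counts`, `freqs`, `scores` (4 x L bit-score matrix), `background`,
#'   `pseudocount`, `width`.
#' @examples
#' m <- pwm_model(matrix(c(8, 0, 0, 0), 4, dimnames = list(c("A","C","G","T"))),
#'                factor = "toy")
#' score_site(m, "A")
#' @export
pwm_model <- function(counts, factor = "", accession = "",
                      pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  if (ncol(counts) < 1L) stop("PWM must have at least one position")
  if (any(counts < 0)) stop("counts must be non-negative")
  background <- background[DNA_BASES]
  if (any(is.na(background)) || any(background <= 0))
    stop("background frequencies must be strictly positive")
  background <- background / sum(background)
  tot <- colSums(counts) + 4 * pseudocount
  freqs <- sweep(counts + pseudocount, 2, tot, "/")
  scores <- log2(freqs / background)
  structure(
    list(factor = as.character(factor), accession = as.character(accession),
         counts = counts, freqs = freqs, scores = scores,
         background = background, pseudocount = pseudocount,
         width = ncol(counts)),
    class = "pwm_model"
  )
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> %s (%s): %d positions, max score %.3f bits\n",
              x$factor, x$accession, x$width, max_score(x)))
  invisible(x)
}

#' Background frequencies from sequence composition
#'
#' @param seq Nucleotide string; `N` ignored.
#' @param pseudocount Added to each base count.
#' @return Named base-frequency vector usable as a PWM background.
#' @export
composition_background <- function(seq, pseudocount = 1) {
  ch <- seq_chars(toupper(seq))
  cnt <- table(factor(ch[ch %in% DNA_BASES], levels = DNA_BASES))
  f <- as.numeric(cnt) + pseudocount
  stats::setNames(f / sum(f), DNA_BASES)
}

#' Score a k-mer against a PWM
#'
#' `La = sum_i log2(f_i(b_i) / q(b_i))` in bits. Windows containing `N` are
#' not scored.
#'
#' @param pwm A [pwm_model()].
#' @param kmer Nucleotide string of the motif length.
#' @return Log-likelihood score in bits.
#' @export
score_site <- function(pwm, kmer) {
  ch <- seq_chars(toupper(kmer))
  if (length(ch) != pwm$width) stop("kmer length does not match motif length")
  idx <- match(ch, DNA_BASES)
  if (anyNA(idx)) stop("kmer contains non-ACGT characters (N windows are skipped)")
  sum(pwm$scores[cbind(idx, seq_len(pwm$width))])
}

#' Maximum possible PWM score
#'
#' @param pwm A [pwm_model()].
#' @return Sum over positions of the per-position maximum bit score.
#' @export
max_score <- function(pwm) sum(apply(pwm$scores, 2, max))

## Discretised exact score distribution under the background model.
## Per-position scores are floored to integer bins of width `bin`; the
## distribution of the binned sum is computed by convolution. Flooring
## under-counts each position's score by < bin, so a threshold lowered by
## `width` bins bounds the true tail from above: the reported p-value never
## understates P(score >= La).
pwm_score_distribution <- function(pwm, bin = 0.001) {
  k <- floor(pwm$scores / bin + 1e-9)
  ## iterative convolution; dist[i] = P(binned partial sum = dist_lo + i - 1)
  dist <- 1; dist_lo <- 0L
  for (j in seq_len(pwm$width)) {
    kj <- k[, j]
    newlo <- dist_lo + min(kj)
    newhi <- dist_lo + length(dist) - 1L + max(kj)
    new <- numeric(newhi - newlo + 1L)
    for (b in 1:4) {
      sh <- dist_lo + kj[b] - newlo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * pwm$background[b]
    }
    dist <- new; dist_lo <- newlo
  }
  list(prob = dist, lo = dist_lo, bin = bin)
}

#' Exact tail p-value of a PWM score
#'
#' `P(score(K) >= La)` for a k-mer `K` drawn i.i.d. from the background
#' model, computed by dynamic programming over per-position score
#' distributions discretised to `bin` bits. Rounding is conservative
#' (per-position scores floored, threshold lowered by one bin per
#' position), so the reported value never understates the true tail.
#'
#' @param pwm A [pwm_model()].
#' @param La Score threshold in bits.
#' @param bin Discretisation width in bits.
#' @param dist Optional precomputed result of the internal score
#'   distribution (reused during scanning).
#' @return Tail probability in `(0, 1]` (0 only above the maximal
#'   achievable score).
#' @examples
#' m <- pwm_model(matrix(c(8, 0, 0, 0), 4, dimnames = list(c("A","C","G","T"))))
#' score_pvalue(m, score_site(m, "A")) # 0.25: only "A" scores this high
#' @export
score_pvalue <- function(pwm, La, bin = 0.001, dist = NULL) {
  stopifnot(is.finite(La) || La == -Inf)
  if (La == -Inf) return(1)
  if (is.null(dist)) dist <- pwm_score_distribution(pwm, bin)
  thr <- ceiling(La / dist$bin - 1e-9) - pwm$width
  i0 <- thr - dist$lo + 1L
  if (i0 <= 1L) return(1)
  if (i0 > length(dist$prob)) return(0)
  sum(dist$prob[i0:length(dist$prob)])
}

## ---- TRANSFAC-style matrix parser ----------------------------------------

#' Parse a TRANSFAC-like count-matrix library
#'
#' Reads records separated by `//`. Recognised fields: `AC` (accession),
#' `ID`/`NA` (factor name; `NA` wins when both present), a `P0 A C G T`
#' header, and numbered count rows (`01 8 0 0 2 R`). Other lines are
#' ignored.
#'
#' @param path File path.
#' @param pseudocount,background Passed to [pwm_model()].
#' @return Named list of [pwm_model()]s keyed by accession.
#' @export
read_transfac <- function(path, pseudocount = 0.5,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (!length(rec)) next
    ac <- sub("^AC\\s+", "", grep("^AC\\s", rec, value = TRUE)[1])
    nm <- sub("^(ID|NA)\\s+", "", rev(grep("^(ID|NA)\\s", rec, value = TRUE))[1])
    if (is.na(ac) && is.na(nm)) next
    p0 <- grep("^P0\\s", rec)
    if (!length(p0)) next
    ord <- toupper(strsplit(trimws(sub("^P0\\s+", "", rec[p0[1]])), "\\s+")[[1]])
    rows <- grep("^[0-9]+\\s", rec, value = TRUE)
    cnt <- t(vapply(rows, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(f[2:5])
    }, numeric(4)))
    colnames(cnt) <- ord[1:4]
    counts <- t(cnt)[DNA_BASES, , drop = FALSE]
    key <- if (!is.na(ac)) ac else nm
    out[[key]] <- pwm_model(counts, factor = if (is.na(nm)) key else nm,
                            accession = if (is.na(ac)) "" else ac,
                            pseudocount = pseudocount,
                            background = background)
  }
  out
}

## ---- scanning -------------------------------------------------------------

.empty_hits <- function() {
  data.frame(factor = character(), accession = character(),
             start = integer(), end = integer(), strand = character(),
             La = numeric(), Lq = numeric(), Lpv = numeric(),
             stringsAsFactors = FALSE)
}

## score every window of x (integer-coded, NA for N) against pwm
.window_scores <- function(xi, pwm) {
  L <- pwm$width
  nw <- length(xi) - L + 1L
  if (nw < 1L) return(numeric())
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- pwm$scores[, j][xi[j:(j + nw - 1L)]]
    sc <- sc + v  # NA propagates for N-containing windows
  }
  sc
}

#' Scan a sequence for PWM hits on both strands
#'
#' Every window on the `+` and `-` strand is scored for every PWM; hits
#' must pass all three retention thresholds: score `La >= la_min` bits,
#' score ratio `Lq = La / La_max >= lq_min`, and exact background tail
#' probability `Lpv < lpv_max`. Windows containing `N` are skipped.
#' Duplicate hits (same factor, start and strand, e.g. from several
#' matrices for one factor) are collapsed keeping the highest `La`.
#'
#' @param seq An [annotated_seq()] or nucleotide string.
#' @param pwms A single [pwm_model()] or list of them.
#' @param la_min,lq_min,lpv_max Retention thresholds (defaults 9.0 bits,
#'   0.80, 0.05).
#' @param bin Discretisation width for the exact p-value.
#' @param collapse_rar Collapse retinoic-acid-receptor paralogs
#'   (factor names starting `RAR`) under the alias `"RAR"`.
#' @return Data frame of hits: `factor`, `accession`, `start`, `end`
#'   (1-based closed on the input sequence), `strand`, `La`, `Lq`, `Lpv`,
#'   sorted by `start`.
#' @export
scan_sequence <- function(seq, pwms, la_min = 9.0, lq_min = 0.80,
                          lpv_max = 0.05, bin = 0.001,
                          collapse_rar = FALSE) {
  residues <- if (inherits(seq, "annotated_seq")) seq$residues
              else toupper(seq)
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  n <- nchar(residues)
  fwd <- match(seq_chars(residues), DNA_BASES)
  rev_ <- match(seq_chars(revcomp(residues)), DNA_BASES)
  hits <- list()
  for (pwm in pwms) {
    L <- pwm$width
    if (L > n) next
    amax <- max_score(pwm)
    dist <- pwm_score_distribution(pwm, bin)
    for (strand in c("+", "-")) {
      xi <- if (strand == "+") fwd else rev_
      sc <- .window_scores(xi, pwm)
      cand <- which(!is.na(sc) & sc >= la_min &
                      (if (amax > 0) sc / amax >= lq_min else FALSE))
      if (!length(cand)) next
      lpv <- vapply(sc[cand], function(s) score_pvalue(pwm, s, dist = dist),
                    numeric(1))
      ok <- lpv < lpv_max
      cand <- cand[ok]; lpv <- lpv[ok]
      if (!length(cand)) next
      start <- if (strand == "+") cand else n - (cand + L - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        factor = pwm$factor, accession = pwm$accession,
        start = start, end = start + L - 1L, strand = strand,
        La = sc[cand], Lq = sc[cand] / amax, Lpv = lpv,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) return(.empty_hits())
  out <- do.call(rbind, hits)
  if (collapse_rar) out$factor <- sub("^RAR.*$", "RAR", out$factor)
  ## collapse duplicates at identical (factor, start, strand), keep best La
  out <- out[order(out$factor, out$start, out$strand, -out$La), ]
  dup <- duplicated(out[, c("factor", "start", "strand")])
  out <- out[!dup, ]
  out <- out[order(out$start, out$factor), ]
  rownames(out) <- NULL
  out
}
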