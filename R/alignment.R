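## Pairwise alignments and region-wise evolutionary divergence.

#' Construct a pairwise alignment
#'
#' Two gapped rows over a shared column axis, with bidirectional
#' column/sequence coordinate maps. Column indices, like all coordinates in
#' this package, are 1-based.
#'
#' @param rowA,rowB Gapped nucleotide strings of equal length (`-` for gaps).
#' @param idA,idB Row labels (e.g. species names).
#' @return An object of class `pairwise_alignment`: list with the gapped
#'   rows split into character vectors (`colsA`, `colsB`), maps from column
#'   to ungapped sequence position (`mapA`, `mapB`; `NA` at gap columns) and
#'   inverse maps from sequence position to column (`invA`, `invB`).
#' @examples
#' aln <- pairwise_alignment("AC-GT", "ACTGT")
#' aln$mapA
#' @export
pairwise_alignment <- function(rowA, rowB, idA = "A", idB = "B") {
  rowA <- toupper(rowA); rowB <- toupper(rowB)
  if (nchar(rowA) != nchar(rowB))
    stop("alignment rows must have equal column counts")
  if (nchar(rowA) == 0L) stop("empty alignment")
  colsA <- seq_chars(rowA)
  colsB <- seq_chars(rowB)
  if (any(!colsA %in% c(DNA_BASES, "N", "-")) ||
      any(!colsB %in% c(DNA_BASES, "N", "-")))
    stop("alignment rows contain characters outside A/C/G/T/N/-")
  mapA <- ifelse(colsA == "-", NA_integer_, cumsum(colsA != "-"))
  mapB <- ifelse(colsB == "-", NA_integer_, cumsum(colsB != "-"))
  structure(
    list(idA = idA, idB = idB, colsA = colsA, colsB = colsB,
         mapA = mapA, mapB = mapB,
         invA = which(colsA != "-"), invB = which(colsB != "-")),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s/%s: %d columns (%d/%d residues)\n",
              x$idA, x$idB, length(x$colsA), length(x$invA), length(x$invB)))
  invisible(x)
}

#' Ungapped sequence of one alignment row
#'
#' @param aln A [pairwise_alignment()].
#' @param row `"A"` or `"B"`.
#' @return Character scalar.
#' @export
ungap <- function(aln, row = c("A", "B")) {
  row <- match.arg(row)
  cols <- if (row == "A") aln$colsA else aln$colsB
  paste(cols[cols != "-"], collapse = "")
}

#' Read a two-record aligned FASTA file as a pairwise alignment
#'
#' @param path Aligned FASTA with exactly two records of equal gapped length.
#' @return A [pairwise_alignment()]; record names become the row ids.
#' @export
read_pairwise_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) != 2L) stop("expected exactly two records in ", path)
  pairwise_alignment(as.character(x[[1]]), as.character(x[[2]]),
                     idA = sub("\\s.*$", "", names(x)[1]),
                     idB = sub("\\s.*$", "", names(x)[2]))
}

#' Globally align two ungapped sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2 by
#' default) via [Biostrings::pairwiseAlignment()]. Provided so that
#' synthetic-data tests need no external aligner; real analyses normally
#' consume precomputed alignments.
#'
#' @param seqA,seqB Nucleotide strings.
#' @param idA,idB Row labels.
#' @param match,mismatch,gap Scoring parameters.
#' @return A [pairwise_alignment()].
#' @export
align_pair <- function(seqA, seqB, idA = "A", idB = "B",
                       match = 1, mismatch = -1, gap = -2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  al <- Biostrings::pairwiseAlignment(toupper(seqA), toupper(seqB),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = -gap)
  pairwise_alignment(as.character(Biostrings::alignedPattern(al)),
                     as.character(Biostrings::alignedSubject(al)),
                     idA = idA, idB = idB)
}

## ---- divergence -----------------------------------------------------------

#' Proportion of differing comparable columns
#'
#' Comparable columns carry an unambiguous base (`A/C/G/T`) in both rows and
#' are not masked. Columns with `N` in either row do not count as
#' differences: assembly ambiguity is not evidence of divergence.
#'
#' @param aln A [pairwise_alignment()].
#' @param mask Optional integer vector of column indices to exclude.
#' @return A list of class `divergence_estimate` with `p`, `Dxy` (`NA`, see
#'   [jc69_distance()]), `n_comparable` and `mismatches`.
#' @examples
#' p_distance(pairwise_alignment("AAAA", "AAAT"))$p # 0.25
#' @export
p_distance <- function(aln, mask = NULL) {
  ok <- aln$colsA %in% DNA_BASES & aln$colsB %in% DNA_BASES
  if (!is.null(mask)) ok[mask[mask >= 1L & mask <= length(ok)]] <- FALSE
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites")
  mm <- sum(aln$colsA[ok] != aln$colsB[ok])
  structure(list(p = mm / n, Dxy = NA_real_, n_comparable = n,
                 mismatches = mm),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> p = %.4g, Dxy = %.4g, n = %d\n",
              x$p, x$Dxy, x$n_comparable))
  invisible(x)
}

#' Jukes-Cantor corrected divergence
#'
#' `Dxy = -(3/4) * log(1 - (4/3) * p)` substitutions per site; undefined at
#' saturation (`p >= 3/4`).
#'
#' @param p Proportion of differing sites, in `[0, 0.75)`.
#' @return Corrected divergence (substitutions/site).
#' @examples
#' jc69_distance(0.25) # ~0.3041
#' @export
jc69_distance <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) stop("JC69 undefined (saturation)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Positions excluded from intron divergence
#'
#' First introns are dropped entirely; for every other intron the first and
#' last six bases are dropped (splice sites and possible regulatory sequence
#' are more conserved than intron interiors). Edge positions are counted on
#' the intron's own strand. Introns of 12 bp or less with rank >= 2 retain
#' no interior and are excluded whole.
#'
#' @param feats Feature table ([features()]); only `intron` rows are used
#'   and they must carry `rank`.
#' @param edge Number of bases masked at each retained intron's ends.
#' @return Sorted integer vector of masked sequence positions (1-based).
#' @export
intron_interior_mask <- function(feats, edge = 6L) {
  ints <- feats[feats$kind == "intron", , drop = FALSE]
  if (nrow(ints) == 0L) return(integer())
  if (any(is.na(ints$rank))) stop("intron features must carry rank")
  out <- integer()
  for (i in seq_len(nrow(ints))) {
    s <- ints$start[i]; e <- ints$end[i]
    len <- e - s + 1L
    if (ints$rank[i] == 1L || len <= 2L * edge) {
      out <- c(out, s:e)
    } else {
      ## strand only changes which end is "first"; masking both ends is
      ## strand-symmetric, so the masked set is the same either way
      out <- c(out, s:(s + edge - 1L), (e - edge + 1L):e)
    }
  }
  sort(unique(out))
}

#' Per-region divergence estimates
#'
#' Computes `p` and Jukes-Cantor `Dxy` for each feature of the requested
#' kinds, with feature coordinates taken on the ungapped A row and mapped to
#' alignment columns. For introns the edge/first-intron mask of
#' [intron_interior_mask()] is applied. Features with no comparable columns
#' are reported with `NA` (missing), not zero.
#'
#' @param aln A [pairwise_alignment()].
#' @param feats Feature table on the A sequence.
#' @param kinds Character vector of feature kinds to process.
#' @return Data frame: `kind`, `start`, `end`, `gene`, `rank`, `p`, `Dxy`,
#'   `n_comparable`.
#' @export
region_divergence <- function(aln, feats,
                              kinds = c("CDS", "intron", "UTR3", "UTR5",
                                        "promoter", "CNE")) {
  sel <- feats[feats$kind %in% kinds, , drop = FALSE]
  mask_pos <- intron_interior_mask(feats)
  n <- nrow(sel)
  p <- Dxy <- rep(NA_real_, n)
  ncomp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pos <- sel$start[i]:sel$end[i]
    if (sel$kind[i] == "intron") pos <- setdiff(pos, mask_pos)
    cols <- aln$invA[pos[pos <= length(aln$invA)]]
    est <- tryCatch(p_distance(aln, mask = setdiff(seq_along(aln$colsA), cols)),
                    error = function(e) NULL)
    if (!is.null(est) && length(cols)) {
      p[i] <- est$p
      ncomp[i] <- est$n_comparable
      Dxy[i] <- if (est$p < 0.75) jc69_distance(est$p) else NA_real_
    }
  }
  data.frame(kind = sel$kind, start = sel$start, end = sel$end,
             gene = sel$gene, rank = sel$rank,
             p = p, Dxy = Dxy, n_comparable = ncomp,
             stringsAsFactors = FALSE)
}

#' Two-sample t-test on log10-transformed divergences
#'
#' Pooled-variance (Student) two-sample t-test on `log10` values, two-sided;
#' `df = nA + nB - 2`. Divergences must be strictly positive.
#'
#' @param groupA,groupB Numeric vectors of divergence values, each of
#'   length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
log_ttest <- function(groupA, groupB) {
  if (any(groupA <= 0) || any(groupB <= 0))
    stop("log10 transform requires strictly positive divergences")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group must contain at least two values")
  la <- log10(groupA); lb <- log10(groupB)
  if (stats::var(la) == 0 && stats::var(lb) == 0 && mean(la) != mean(lb))
    stop("degenerate: zero within-group variance")
  tt <- stats::t.test(la, lb, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
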