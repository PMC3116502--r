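## Sequence + feature data model. All coordinates in this package are 1-based
## and closed, the native R/Bioconductor convention; GFF3 shares it, BED
## (0-based half-open) is converted at the boundary.

FEATURE_KINDS <- c("CDS", "intron", "UTR3", "UTR5", "promoter", "repeat", "CNE")

#' Construct a feature table
#'
#' A plain data frame of typed sequence features. `start`/`end` are 1-based
#' closed positions on the parent sequence; `rank` is the ordinal of the
#' feature within its gene (used for introns, where rank 1 is the first
#' intron); `gene` is a free-text label.
#'
#' @param kind Character vector, each element one of
#'   `"CDS"`, `"intron"`, `"UTR3"`, `"UTR5"`, `"promoter"`, `"repeat"`, `"CNE"`.
#' @param start,end Integer vectors, 1-based closed interval bounds.
#' @param strand `"+"` or `"-"` (recycled).
#' @param rank Integer ordinal within the parent gene, `NA` where meaningless.
#' @param gene Character label, `""` where unknown.
#' @return A `data.frame` with columns `kind`, `start`, `end`, `strand`,
#'   `rank`, `gene`.
#' @examples
#' features(c("CDS", "intron"), c(1, 101), c(100, 180), rank = c(NA, 1))
#' @export
features <- function(kind = character(), start = integer(), end = integer(),
                     strand = "+", rank = NA_integer_, gene = "") {
  kind <- as.character(kind)
  bad <- setdiff(kind, FEATURE_KINDS)
  if (length(bad)) stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  n <- length(kind)
  out <- data.frame(
    kind = kind,
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    rank = rep_len(as.integer(rank), n),
    gene = rep_len(as.character(gene), n),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 1L) || any(out$end < out$start))
    stop("feature intervals must satisfy 1 <= start <= end")
  out
}

#' Construct an annotated nucleotide sequence
#'
#' @param id Sequence label.
#' @param residues Nucleotide string over `A/C/G/T/N` (case-insensitive;
#'   stored upper case).
#' @param species Species label.
#' @param feats Feature table from [features()]; intervals must lie within
#'   the sequence.
#' @return An object of class `annotated_seq`: a list with elements `id`,
#'   `species`, `residues` and `features`.
#' @examples
#' s <- annotated_seq("cne1", "ACGTACGT", species = "O. niloticus")
#' nchar(s$residues)
#' @export
annotated_seq <- function(id, residues, species = "", feats = features()) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("residues must be non-empty")
  if (grepl("[^ACGTN]", residues))
    stop("residues contain characters outside A/C/G/T/N")
  if (nrow(feats) && any(feats$end > nchar(residues)))
    stop("feature interval extends beyond sequence length")
  structure(
    list(id = as.character(id), species = as.character(species),
         residues = residues, features = feats),
    class = "annotated_seq"
  )
}

#' @export
print.annotated_seq <- function(x, ...) {
  cat(sprintf("<annotated_seq> %s (%s): %d bp, %d feature(s)\n",
              x$id, if (nzchar(x$species)) x$species else "unknown species",
              nchar(x$residues), nrow(x$features)))
  invisible(x)
}

#' @export
length.annotated_seq <- function(x) nchar(x$residues)

## ---- FASTA ----------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector of upper-case sequences.
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' Sequences are written upper case, wrapped at 60 columns.
#'
#' @param seqs Named character vector (gaps `-` allowed, e.g. for aligned
#'   FASTA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

## ---- feature input --------------------------------------------------------

## map GFF3/BED type strings onto the internal feature vocabulary
.kind_from_type <- function(type) {
  type_l <- tolower(type)
  map <- c(cds = "CDS", intron = "intron",
           three_prime_utr = "UTR3", utr3 = "UTR3",
           five_prime_utr = "UTR5", utr5 = "UTR5",
           promoter = "promoter", repeat_region = "repeat",
           "repeat" = "repeat", cne = "CNE",
           conserved_noncoding_element = "CNE")
  out <- unname(map[type_l])
  ifelse(is.na(out), type, out)
}

#' Read features from a GFF3 or BED file
#'
#' Uses [rtracklayer::import()]; GFF3 `type` (or the BED name column) is
#' mapped onto the internal feature vocabulary where recognised. Intron rank
#' is taken from a `rank` attribute when present, otherwise introns are
#' numbered within each `gene` (GFF3 `gene` or `Parent` attribute) in
#' positional order.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file path.
#' @param seqname Optional: restrict to records on this sequence.
#' @return A feature table as from [features()].
#' @export
read_features <- function(path, seqname = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!is.null(seqname)) df <- df[df$seqnames == seqname, , drop = FALSE]
  type <- if ("type" %in% names(df)) as.character(df$type)
          else as.character(df$name %||% "CNE")
  gene <- rep("", nrow(df))
  for (col in c("gene", "Parent", "ID")) {
    if (col %in% names(df)) {
      v <- vapply(df[[col]], function(e) paste(as.character(e), collapse = ","),
                  character(1))
      gene <- ifelse(gene == "" & !is.na(v) & nzchar(v), v, gene)
    }
  }
  rank <- if ("rank" %in% names(df)) suppressWarnings(as.integer(df$rank))
          else rep(NA_integer_, nrow(df))
  out <- features(.kind_from_type(type), df$start, df$end,
                  strand = ifelse(as.character(df$strand) == "-", "-", "+"),
                  rank = rank, gene = gene)
  ## number introns within genes when no explicit rank is given
  ix <- which(out$kind == "intron" & is.na(out$rank))
  if (length(ix)) {
    for (g in unique(out$gene[ix])) {
      sel <- ix[out$gene[ix] == g]
      sel <- sel[order(out$start[sel])]
      fwd <- !any(out$strand[sel] == "-")
      out$rank[sel] <- if (fwd) seq_along(sel) else rev(seq_along(sel))
    }
  }
  out
}

#' Write intervals as a BED file
#'
#' Converts from the internal 1-based closed convention to BED's 0-based
#' half-open at the boundary.
#'
#' @param df Data frame with columns `start`, `end` and a name column
#'   (`id` or `name`).
#' @param path Output path.
#' @param seqname Chromosome/sequence label for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, seqname = "seq") {
  nm <- if ("id" %in% names(df)) df$id else df$name %||% seq_len(nrow(df))
  lines <- sprintf("%s\t%d\t%d\t%s", seqname, df$start - 1L, df$end, nm)
  writeLines(lines, path)
  invisible(path)
}
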