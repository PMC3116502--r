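## microRNA seed-target profiling: 3'-UTR extraction bounded by the
## polyadenylation signal, exact 8-mer seed matching on the sense strand,
## and cross-species conservation filtering on alignment columns.

#' Construct a miRNA seed-target library
#'
#' @param mirna Character vector of miRNA names (e.g. `"miR-725"`).
#' @param target_motif 8-mer DNA motifs to match in the UTR (the reverse
#'   complement of the miRNA seed).
#' @param source `"library"` or `"derived-from-mature"`.
#' @return Data frame `mirna`, `target_motif`, `source`.
#' @export
seed_library <- function(mirna, target_motif, source = "library") {
  target_motif <- toupper(target_motif)
  if (any(nchar(target_motif) != 8L))
    stop("target motifs must be 8-mers")
  if (any(grepl("[^ACGT]", target_motif)))
    stop("target motifs must be over A/C/G/T")
  data.frame(mirna = as.character(mirna), target_motif = target_motif,
             source = rep_len(source, length(mirna)),
             stringsAsFactors = FALSE)
}

#' Read a seed-target library from TSV
#'
#' @param path Tab-separated file with columns `mirna`, `target_motif`.
#' @return Data frame as from [seed_library()].
#' @export
read_seed_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  seed_library(df$mirna, df$target_motif)
}

#' Extract the 3'-UTR interval downstream of a coding sequence
#'
#' The UTR runs from the base after `cds_end` to the end of the first
#' polyadenylation signal (`AATAAA`), provided the signal ends within
#' `max_len` bp; with no such signal the UTR is truncated at `max_len`.
#' In `fallback` mode (for comparison species whose polyadenylation site
#' is not trusted) a fixed `fallback_len` is taken instead.
#'
#' @param seq An [annotated_seq()] or nucleotide string.
#' @param cds_end 1-based position of the last coding base.
#' @param max_len Maximum UTR length scanned for the signal.
#' @param polya_signal Polyadenylation signal motif.
#' @param fallback Use the fixed-length mode.
#' @param fallback_len Fixed length for the fallback mode.
#' @return List with `start`, `end` (1-based closed; `end < start` for an
#'   empty UTR), `length`, `seq` (the UTR sequence) and `polya_found`.
#' @export
extract_utr <- function(seq, cds_end, max_len = 500L,
                        polya_signal = "AATAAA",
                        fallback = FALSE, fallback_len = 1000L) {
  residues <- if (inherits(seq, "annotated_seq")) seq$residues
              else toupper(seq)
  n <- nchar(residues)
  if (cds_end > n) stop("cds_end beyond sequence end")
  start <- cds_end + 1L
  avail <- n - cds_end
  if (avail == 0L) {
    warning("coding sequence ends at the sequence end; empty UTR")
    return(list(start = start, end = cds_end, length = 0L, seq = "",
                polya_found = FALSE))
  }
  if (fallback) {
    len <- min(fallback_len, avail)
    return(list(start = start, end = cds_end + len, length = len,
                seq = substr(residues, start, cds_end + len),
                polya_found = NA))
  }
  down <- substr(residues, start, min(n, cds_end + max_len))
  hit <- regexpr(polya_signal, down, fixed = TRUE)
  w <- nchar(polya_signal)
  if (hit > 0 && (hit - 1L + w) <= max_len) {
    len <- as.integer(hit) - 1L + w
    found <- TRUE
  } else {
    len <- min(max_len, avail)
    found <- FALSE
  }
  list(start = start, end = cds_end + len, length = len,
       seq = substr(residues, start, cds_end + len), polya_found = found)
}

#' Find miRNA seed-target sites in a UTR
#'
#' All exact occurrences of each target motif on the sense strand
#' (miRNA repression acts on the mRNA), including overlapping ones; the
#' same motif shared by several miRNAs is reported once per miRNA.
#'
#' @param utr UTR nucleotide string (or `extract_utr()` result).
#' @param library Seed library ([seed_library()]).
#' @param utr_id Label for the output.
#' @return Data frame `utr_id`, `mirna`, `start`, `end` (1-based on the
#'   UTR), `target_motif`.
#' @export
find_seed_sites <- function(utr, library, utr_id = "utr") {
  if (is.list(utr)) utr <- utr$seq
  utr <- toupper(utr)
  if (nchar(utr) == 0L) stop("empty UTR")
  subject <- Biostrings::DNAString(utr)
  out <- list()
  for (i in seq_len(nrow(library))) {
    m <- Biostrings::matchPattern(library$target_motif[i], subject)
    if (length(m) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      utr_id = utr_id, mirna = library$mirna[i],
      start = Biostrings::start(m), end = Biostrings::end(m),
      target_motif = library$target_motif[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(utr_id = character(), mirna = character(),
                      start = integer(), end = integer(),
                      target_motif = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out[order(out$start, out$mirna), , drop = FALSE]
}

#' Cross-species conservation filter for seed-target sites
#'
#' A site is conserved when at least one other species has a site for the
#' same miRNA whose start, projected to the shared alignment, lies within
#' `tol` columns. Distances are measured in alignment columns (not
#' ungapped offsets) because the tolerance exists to absorb alignment
#' error.
#'
#' @param sites_by_species Named list of site tables from
#'   [find_seed_sites()], one per species, with `start` on each species'
#'   ungapped UTR.
#' @param utr_alignment Named character vector (or `DNAStringSet`) of
#'   gapped rows of the multi-species UTR alignment; must contain a row
#'   for every species with sites.
#' @param tol Column tolerance (default 50).
#' @return One data frame with columns of the inputs plus `species`,
#'   `column` (alignment column of the site start), `conserved` and
#'   `conserved_in` (comma-separated species list).
#' @export
conservation_filter <- function(sites_by_species, utr_alignment, tol = 50L) {
  rows <- toupper(vapply(utr_alignment, as.character, character(1)))
  missing <- setdiff(names(sites_by_species), names(rows))
  if (length(missing))
    stop("species with sites absent from alignment: ",
         paste(missing, collapse = ", "))
  inv <- lapply(rows, function(r) which(seq_chars(r) != "-"))
  all <- list()
  for (sp in names(sites_by_species)) {
    s <- sites_by_species[[sp]]
    if (!nrow(s)) next
    if (any(s$start > length(inv[[sp]])))
      stop("site beyond the ungapped UTR length for ", sp)
    s$species <- sp
    s$column <- inv[[sp]][s$start]
    all[[sp]] <- s
  }
  if (!length(all))
    return(data.frame(utr_id = character(), mirna = character(),
                      start = integer(), end = integer(),
                      target_motif = character(), species = character(),
                      column = integer(), conserved = logical(),
                      conserved_in = character(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, all)
  rownames(tab) <- NULL
  tab$conserved <- FALSE
  tab$conserved_in <- ""
  for (i in seq_len(nrow(tab))) {
    near <- tab$species != tab$species[i] &
      tab$mirna == tab$mirna[i] &
      abs(tab$column - tab$column[i]) <= tol
    if (any(near)) {
      tab$conserved[i] <- TRUE
      tab$conserved_in[i] <- paste(sort(unique(tab$species[near])),
                                   collapse = ",")
    }
  }
  tab
}

#' Derive a seed-target motif from a mature miRNA sequence
#'
#' Rule `m1-m8`: the DNA reverse complement of mature positions 1-8.
#' Rule `m2-m8+A`: the reverse complement of positions 2-8 followed by an
#' `A` at the target's 3' end (the canonical t1A).
#'
#' @param mature_mirna Mature miRNA as an RNA string (`A/C/G/U`).
#' @param rule `"m1-m8"` or `"m2-m8+A"`.
#' @param mirna Name carried into the output.
#' @return One-row data frame as from [seed_library()], `source =
#'   "derived-from-mature"`.
#' @examples
#' derive_target_from_mature("UCUCAGUCAUUU")$target_motif # "TGACTGAG"
#' @export
derive_target_from_mature <- function(mature_mirna,
                                      rule = c("m1-m8", "m2-m8+A"),
                                      mirna = "miRNA") {
  rule <- match.arg(rule)
  mature_mirna <- toupper(mature_mirna)
  if (grepl("[^ACGU]", mature_mirna))
    stop("mature miRNA must be an RNA string over A/C/G/U")
  if (nchar(mature_mirna) < 8L) stop("mature miRNA shorter than 8 nt")
  dna <- chartr("U", "T", mature_mirna)
  motif <- switch(rule,
    "m1-m8" = revcomp(substr(dna, 1L, 8L)),
    "m2-m8+A" = paste0(revcomp(substr(dna, 2L, 8L)), "A")
  )
  seed_library(mirna, motif, source = "derived-from-mature")
}
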