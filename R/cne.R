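## Conserved non-coding element (CNE) detection by sliding-window identity
## over pairwise alignments of a focal sequence against comparison species.

#' Sliding-window identity track on focal coordinates
#'
#' Windows are anchored on ungapped positions of the focal (A) row. The
#' identity denominator counts focal non-gap columns, so a gap in the
#' comparison row counts as mismatch: conservation is penalised by
#' lineage-specific loss.
#'
#' @param aln A [pairwise_alignment()], focal sequence as row A.
#' @param window Window length in focal bp.
#' @param step Step in focal bp.
#' @return Data frame `start`, `end` (focal coordinates, 1-based closed),
#'   `identity` in `[0, 1]`, and `truncated` (logical, only the final
#'   partial window when the sequence is shorter than `window`).
#' @examples
#' aln <- pairwise_alignment(strrep("ACGT", 25), strrep("ACGT", 25))
#' head(window_identity(aln, 50, 10))
#' @export
window_identity <- function(aln, window = 50L, step = 10L) {
  stopifnot(window >= 1L, step >= 1L)
  n <- length(aln$invA)
  ## per-focal-position match indicator
  m <- aln$colsA[aln$invA] == aln$colsB[aln$invA]
  if (window >= n) {
    return(data.frame(start = 1L, end = n, identity = mean(m),
                      truncated = window > n))
  }
  starts <- seq.int(1L, n - window + 1L, by = step)
  cs <- c(0L, cumsum(m))
  ident <- (cs[starts + window] - cs[starts]) / window
  data.frame(start = starts, end = starts + window - 1L,
             identity = ident, truncated = FALSE)
}

## max-scoring segment (Kadane scan) over per-position scores; returns the
## 1-based segment bounds plus its score, ties broken leftmost
max_scoring_segment <- function(sc) {
  best <- 0; best_s <- best_e <- 0L
  cur <- 0; cur_s <- 1L
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_s <- i }
    cur <- cur + sc[i]
    if (cur > best + 1e-12) { best <- cur; best_s <- cur_s; best_e <- i }
  }
  if (best_e == 0L) NULL else list(seg = c(best_s, best_e), score = best)
}

## log-likelihood-ratio boundary refinement of one candidate run: estimate
## the element match rate from the run interior and the background rate
## from its flanking context, then take the max-scoring segment of the
## per-position LLR (the two-changepoint maximum-likelihood boundaries)
refine_run <- function(match, run, span, p0, iterations = 2L) {
  idx <- span[1]:span[2]
  res <- NULL
  for (it in seq_len(iterations)) {
    ## element rate from the central half of the current run: the edges
    ## of window-grid runs are contaminated with background
    qs <- floor(run[1] + (run[2] - run[1]) * c(0.25, 0.75))
    p1 <- mean(match[qs[1]:qs[2]])
    p1 <- min(max(p1, 1e-3), 1 - 1e-3)
    p0c <- min(max(p0, 1e-3), p1 - 1e-3)
    if (p0c <= 0) return(NULL)
    up <- log(p1 / p0c); dn <- log((1 - p1) / (1 - p0c))
    res <- max_scoring_segment(ifelse(match[idx], up, dn))
    if (is.null(res)) return(NULL)
    new_run <- res$seg + span[1] - 1L
    if (identical(new_run, run)) break
    run <- new_run
  }
  res
}

#' Detect conserved non-coding elements
#'
#' A CNE is a maximal run of focal positions covered by sliding windows
#' whose identity exceeds `min_identity` for at least one comparison
#' species, trimmed to exclude CDS and repeat annotation, and at least
#' `min_length` bp long. Runs separated by less than `step` bp are merged.
#' By default each run's boundaries are then refined at single-base
#' resolution to the maximal-scoring segment (match scores
#' `1 - min_identity`, mismatch `-min_identity`) against the
#' best-supporting species, which removes the window-grid quantisation of
#' the raw runs.
#'
#' @param focal An [annotated_seq()] (its features supply the CDS/repeat
#'   exclusion) or a plain nucleotide string.
#' @param alignments Named list of [pairwise_alignment()]s, one per
#'   comparison species, each with the focal sequence as row A (the A row
#'   must ungap to the focal residues).
#' @param min_length Minimum element length (bp).
#' @param min_identity Identity threshold (fraction, exceeded strictly).
#' @param window,step Sliding-window parameters ([window_identity()]).
#' @param refine Refine boundaries by max-scoring segment (default `TRUE`).
#' @return A data frame of class `cne_set`: `id`, `start`, `end`, `length`,
#'   `best_identity`, `supporting_species` (comma-separated), sorted and
#'   disjoint on focal coordinates, numbered left to right.
#' @export
detect_cnes <- function(focal, alignments, min_length = 50L,
                        min_identity = 0.60, window = 50L, step = 10L,
                        refine = TRUE) {
  if (length(alignments) == 0L) stop("no alignments supplied")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list (one name per species)")
  feats <- if (inherits(focal, "annotated_seq")) focal$features else features()
  residues <- if (inherits(focal, "annotated_seq")) focal$residues
              else toupper(focal)
  n <- nchar(residues)
  for (sp in names(alignments)) {
    if (ungap(alignments[[sp]], "A") != residues)
      stop("alignment for ", sp, " does not ungap to the focal sequence")
  }

  ## union over species of positions covered by qualifying windows
  covered <- rep(FALSE, n)
  for (sp in names(alignments)) {
    wi <- window_identity(alignments[[sp]], window, step)
    for (i in which(wi$identity > min_identity))
      covered[wi$start[i]:wi$end[i]] <- TRUE
  }
  if (!any(covered)) return(empty_cne_set())

  runs <- logical_runs(covered)
  ## merge runs separated by < step
  if (nrow(runs) > 1L) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[i, 1] - last[2] - 1L < step)
        keep[[length(keep)]] <- c(last[1], runs[i, 2])
      else keep[[length(keep) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }

  ## per-species match indicator on focal coordinates
  match_by_sp <- lapply(alignments, function(a) {
    a$colsA[a$invA] == a$colsB[a$invA]
  })

  if (refine) {
    ## per-species background match rate, estimated outside all runs
    bg_rate <- vapply(match_by_sp, function(m) {
      out <- m[!covered]
      if (length(out) >= 50) mean(out) else min_identity / 2
    }, numeric(1))
    for (i in seq_len(nrow(runs))) {
      ## refinement context: halfway to the neighbouring runs, at most
      ## two windows out
      lo <- if (i > 1) ceiling((runs[i - 1, 2] + runs[i, 1]) / 2) else 1L
      hi <- if (i < nrow(runs)) floor((runs[i, 2] + runs[i + 1, 1]) / 2)
            else n
      s <- max(1L, lo, runs[i, 1] - 2L * window)
      e <- min(n, hi, runs[i, 2] + 2L * window)
      best <- NULL; best_score <- -Inf
      for (sp in names(alignments)) {
        res <- refine_run(match_by_sp[[sp]], runs[i, ], c(s, e),
                          bg_rate[[sp]])
        if (!is.null(res) && res$score > best_score) {
          best_score <- res$score
          best <- res$seg + s - 1L
        }
      }
      if (!is.null(best)) runs[i, ] <- best
    }
    ## refined boundaries are base-resolution: only overlapping or
    ## directly adjacent segments merge (re-gluing across a rejected gap
    ## would undo the refinement)
    o <- order(runs[, 1])
    runs <- runs[o, , drop = FALSE]
    merged <- list(runs[1, ])
    for (i in seq_len(nrow(runs))[-1]) {
      last <- merged[[length(merged)]]
      if (runs[i, 1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], runs[i, 2]))
      else merged[[length(merged) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, merged)
  }

  ## trim out CDS/repeat positions, splitting runs where needed
  excl <- rep(FALSE, n)
  bad <- feats[feats$kind %in% c("CDS", "repeat"), , drop = FALSE]
  for (i in seq_len(nrow(bad))) excl[bad$start[i]:bad$end[i]] <- TRUE
  keep <- rep(FALSE, n)
  for (i in seq_len(nrow(runs))) keep[runs[i, 1]:runs[i, 2]] <- TRUE
  keep <- keep & !excl
  if (!any(keep)) return(empty_cne_set())
  runs <- logical_runs(keep)
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= min_length, , drop = FALSE]
  if (nrow(runs) == 0L) return(empty_cne_set())

  ## per-element identity and supporting species
  best_id <- numeric(nrow(runs))
  support <- character(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    ids <- vapply(match_by_sp, function(m) mean(m[runs[i, 1]:runs[i, 2]]),
                  numeric(1))
    best_id[i] <- max(ids)
    support[i] <- paste(names(ids)[ids > min_identity], collapse = ",")
  }
  out <- data.frame(
    id = seq_len(nrow(runs)),
    start = runs[, 1], end = runs[, 2],
    length = runs[, 2] - runs[, 1] + 1L,
    best_identity = best_id,
    supporting_species = support,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cne_set", "data.frame")
  out
}

empty_cne_set <- function() {
  out <- data.frame(id = integer(), start = integer(), end = integer(),
                    length = integer(), best_identity = numeric(),
                    supporting_species = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("cne_set", "data.frame")
  out
}

#' @export
print.cne_set <- function(x, ...) {
  cat(sprintf("<cne_set> %d conserved non-coding element(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
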