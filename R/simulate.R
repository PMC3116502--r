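## Seeded generators giving every pipeline stage inputs with known ground
## truth: Jukes-Cantor-diverged orthologs, planted PWM motifs and seed
## targets, coalescent haplotype panels, and additive expression phenotypes.

#' Random nucleotide sequence
#'
#' @param length Length in bp.
#' @param seed Optional RNG seed.
#' @param freqs Base frequencies (default uniform).
#' @return Nucleotide string.
#' @export
random_sequence <- function(length, seed = NULL,
                            freqs = c(A = 0.25, C = 0.25,
                                      G = 0.25, T = 0.25)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = freqs[DNA_BASES]),
        collapse = "")
}

#' Evolve a sequence under the Jukes-Cantor model
#'
#' Each site is substituted independently with probability
#' `p = (3/4) * (1 - exp(-4 d / 3))`, the JC69 probability of observing a
#' difference after divergence `d` substitutions/site; the substitute base
#' is drawn uniformly from the three alternatives. No indels are
#' introduced, so the evolved copy aligns to the original column for
#' column.
#'
#' @param seq Nucleotide string.
#' @param d Target divergence (substitutions/site, `>= 0`).
#' @param seed Optional RNG seed.
#' @return Nucleotide string of the same length.
#' @export
evolve_sequence <- function(seq, d, seed = NULL) {
  stopifnot(d >= 0)
  if (!is.null(seed)) set.seed(seed)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  if (d == 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  ch <- seq_chars(seq)
  hit <- which(stats::runif(n) < p & ch %in% DNA_BASES)
  if (length(hit)) {
    cur <- match(ch[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

#' Plant motifs into a sequence
#'
#' Overwrites the sequence with the given motifs at the given offsets;
#' minus-strand plants are written as the reverse complement. Overlapping
#' plants are an error.
#'
#' @param seq Nucleotide string.
#' @param plants Data frame with columns `motif`, `start` (1-based) and
#'   optionally `strand` (`"+"`/`"-"`) and `name`.
#' @return List with `seq` (modified sequence) and `manifest` (data frame
#'   of ground-truth coordinates: `name`, `motif`, `start`, `end`,
#'   `strand`).
#' @export
plant_motifs <- function(seq, plants) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (!nrow(plants)) return(list(seq = seq, manifest = plants))
  if (is.null(plants$strand)) plants$strand <- "+"
  if (is.null(plants$name)) plants$name <- paste0("plant", seq_len(nrow(plants)))
  plants$end <- plants$start + nchar(plants$motif) - 1L
  if (any(plants$start < 1L) || any(plants$end > n))
    stop("plant outside the sequence")
  o <- order(plants$start)
  if (any(plants$start[o][-1] <= plants$end[o][-nrow(plants)]))
    stop("overlapping plants")
  ch <- seq_chars(seq)
  for (i in seq_len(nrow(plants))) {
    m <- toupper(plants$motif[i])
    if (plants$strand[i] == "-") m <- revcomp(m)
    ch[plants$start[i]:plants$end[i]] <- seq_chars(m)
  }
  list(seq = paste(ch, collapse = ""),
       manifest = plants[, c("name", "motif", "start", "end", "strand")])
}

#' Simulate an orthologous pair with a planted conserved block
#'
#' An ancestor is drawn at random; both descendant copies evolve
#' independently under JC69, with flank sites at divergence `d_flank` per
#' lineage half (total pairwise `d_flank`) and block sites at `d_block`.
#' Substitutions only, so the true alignment is the identity.
#'
#' @param length Total length (bp).
#' @param block 1-based closed interval `c(start, end)` of the conserved
#'   block, or `NULL` for a uniform divergence pair.
#' @param d_flank,d_block Target pairwise divergences (substitutions/site).
#' @param seed Optional RNG seed.
#' @return List with `seqA`, `seqB`, `aln` (a [pairwise_alignment()]) and
#'   `block`.
#' @export
simulate_ortholog_pair <- function(length, block = NULL, d_flank = 0.08,
                                   d_block = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- random_sequence(length)
  d <- rep(d_flank, length)
  if (!is.null(block)) d[block[1]:block[2]] <- d_block
  ## split the pairwise divergence across the two lineages
  mutate <- function(s) {
    p <- 0.75 * (1 - exp(-4 * (d / 2) / 3))
    ch <- seq_chars(s)
    hit <- which(stats::runif(length) < p)
    if (length(hit)) {
      cur <- match(ch[hit], DNA_BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      ch[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
  }
  seqA <- mutate(anc)
  seqB <- mutate(anc)
  list(seqA = seqA, seqB = seqB,
       aln = pairwise_alignment(seqA, seqB), block = block)
}

#' Simulate a haplotype panel on a random coalescent
#'
#' Builds a random coalescent tree (successive uniform pair merges with
#' exponential waiting times of rate `k(k-1)/2` while `k` lineages
#' remain), drops `Poisson(theta/2 * total branch length)` mutations on
#' branches proportionally to length, and assigns each mutation a distinct
#' site (infinite-sites on a finite sequence: sites are drawn without
#' replacement). Expected segregating sites are `theta * a1(n)`.
#'
#' @param ancestor Ancestral nucleotide string (defines the length).
#' @param n Number of taxa.
#' @param theta Population mutation parameter (per region).
#' @param seed Optional RNG seed.
#' @return List with `panel` (a [haplotype_panel()]) and `truth` (data
#'   frame `pos`, `carriers` of each planted mutation).
#' @export
simulate_panel <- function(ancestor, n, theta, seed = NULL) {
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ancestor <- toupper(ancestor)
  L <- nchar(ancestor)
  ## coalescent: track, per surviving lineage, its current leaf set
  branches <- list()   # each: list(leaves, length)
  k <- n
  ## per-lineage accumulated branch length since its creation
  open <- lapply(seq_len(n), function(i) i)
  open_len <- numeric(n)
  while (k > 1L) {
    t <- stats::rexp(1, rate = k * (k - 1) / 2)
    open_len <- open_len + t
    pick <- sample.int(k, 2L)
    for (i in pick) {
      branches[[length(branches) + 1L]] <-
        list(leaves = open[[i]], len = open_len[i])
    }
    merged <- c(open[[pick[1]]], open[[pick[2]]])
    open <- c(open[-pick], list(merged))
    open_len <- c(open_len[-pick], 0)
    k <- k - 1L
  }
  tot <- sum(vapply(branches, `[[`, numeric(1), "len"))
  n_mut <- stats::rpois(1, theta / 2 * tot)
  n_mut <- min(n_mut, L)  # infinite-sites on a finite sequence
  mat <- do.call(rbind, rep(list(seq_chars(ancestor)), n))
  rownames(mat) <- paste0("taxon", seq_len(n))
  truth <- data.frame(pos = integer(), carriers = character(),
                      stringsAsFactors = FALSE)
  if (n_mut > 0L) {
    sites <- sample.int(L, n_mut)
    wts <- vapply(branches, `[[`, numeric(1), "len")
    which_branch <- sample.int(length(branches), n_mut, replace = TRUE,
                               prob = wts)
    for (m in seq_len(n_mut)) {
      leaves <- branches[[which_branch[m]]]$leaves
      j <- sites[m]
      old <- mat[leaves[1], j]
      alt <- sample(setdiff(DNA_BASES, old), 1L)
      mat[leaves, j] <- alt
      truth <- rbind(truth, data.frame(
        pos = j, carriers = paste(sort(leaves), collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  list(panel = haplotype_panel(seqs, region_id = "simulated"),
       truth = truth[order(truth$pos), , drop = FALSE])
}

#' Simulate an expression phenotype with an additive SNP effect
#'
#' `phenotype_i = beta * genotype_i + clade_effect * clade_i +
#' Normal(0, sigma)`, optionally truncated to `[0, 1]` to emulate
#' expression fractions.
#'
#' @param genotypes Numeric 0/1 genotype vector at the causal variant.
#' @param beta Additive effect size.
#' @param clade 0/1 clade indicator vector (default all 0).
#' @param clade_effect Offset added to clade-1 taxa.
#' @param sigma Residual standard deviation.
#' @param seed Optional RNG seed.
#' @param truncate Clamp the phenotype to `[0, 1]`.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(genotypes, beta, clade = 0, clade_effect = 0,
                               sigma = 0.1, seed = NULL, truncate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genotypes)
  clade <- rep_len(clade, n)
  y <- beta * genotypes + clade_effect * clade + stats::rnorm(n, 0, sigma)
  if (truncate) y <- pmin(1, pmax(0, y))
  y
}
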