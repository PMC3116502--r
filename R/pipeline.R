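## Orchestration: run configuration, the footprint/shadow/popgen stage
## runners, and flat key:value config round-tripping. These functions tie
## the module surfaces into the study workflow; each writes TSV/BED
## reports plus a provenance block sufficient to reproduce its outputs.

#' Default run configuration
#'
#' All thresholds default to the study values: CNE rule >= 50 bp at > 60%
#' identity; motif-hit retention La >= 9.0 bits, Lq >= 80%, Lpv < 0.05;
#' shadowing null p0 = 0.08; 50 bp / 10 bp sliding windows; 50-column
#' miRNA conservation tolerance; 500 Mantel permutations.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_cne_len = 50L, min_cne_identity = 0.60,
    la_min = 9.0, lq_min = 0.80, lpv_max = 0.05,
    p0 = 0.08, alpha = 0.05,
    window = 50L, step = 10L,
    conservation_tol = 50L, mantel_perms = 500L,
    seed = 1L, out_dir = "."
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, stopifnot(
    min_cne_len >= 1, min_cne_identity > 0, min_cne_identity < 1,
    lq_min > 0, lq_min <= 1, lpv_max > 0, lpv_max <= 1,
    p0 > 0, p0 < 1, window >= 1, step >= 1,
    conservation_tol >= 0, mantel_perms >= 1
  ))
  structure(cfg, class = "run_config")
}

#' Write/read a flat key:value config file
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   [run_config()].
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s: %s", names(cfg),
                     vapply(cfg, function(v) format(v, digits = 15),
                            character(1))),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep(":", readLines(path), value = TRUE, fixed = TRUE)
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  defaults <- run_config()
  out <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    out[[k]] <- if (is.character(defaults[[k]] %||% "")) vals[i]
                else if (is.integer(defaults[[k]]))
                  as.integer(round(as.numeric(vals[i])))
                else as.numeric(vals[i])
  }
  do.call(run_config, out)
}

.provenance <- function(cfg, stage) {
  c(sprintf("# stage: %s", stage),
    sprintf("# regshadow %s | R %s",
            as.character(utils::packageVersion("regshadow")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("# seed: %s", cfg$seed),
    sprintf("# config: %s", paste(sprintf("%s=%s", names(cfg),
                                          vapply(cfg, format, character(1))),
                                  collapse = " ")))
}

.write_report <- function(df, path, cfg, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(cfg, stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the phylogenetic-footprinting stage
#'
#' Detects CNEs in a focal sequence from pairwise alignments against one
#' or more comparison species and writes a TSV report plus a BED file of
#' the element intervals.
#'
#' @param focal An [annotated_seq()] (or path to a FASTA + optional GFF3
#'   via `focal_path`/`features_path`).
#' @param alignments Named list of [pairwise_alignment()]s (or a named
#'   character vector of aligned-FASTA paths).
#' @param cfg A [run_config()].
#' @return The [detect_cnes()] result, invisibly; writes `cnes.tsv` and
#'   `cnes.bed` under `cfg$out_dir`.
#' @export
run_footprint <- function(focal, alignments, cfg = run_config()) {
  if (is.character(focal)) {
    if (!file.exists(focal)) stop("missing input: ", focal)
    seqs <- read_fasta(focal)
    focal <- annotated_seq(names(seqs)[1], seqs[[1]])
  }
  if (is.character(alignments)) {
    for (p in alignments) if (!file.exists(p)) stop("missing input: ", p)
    alignments <- lapply(alignments, read_pairwise_alignment)
  }
  cnes <- detect_cnes(focal, alignments,
                      min_length = cfg$min_cne_len,
                      min_identity = cfg$min_cne_identity,
                      window = cfg$window, step = cfg$step)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_report(as.data.frame(cnes), file.path(cfg$out_dir, "cnes.tsv"),
                cfg, "footprint")
  write_bed(cnes, file.path(cfg$out_dir, "cnes.bed"),
            seqname = if (inherits(focal, "annotated_seq")) focal$id else "focal")
  message(sprintf("footprint: %d CNE(s) at >%.0f%% identity, >=%d bp",
                  nrow(cnes), 100 * cfg$min_cne_identity, cfg$min_cne_len))
  invisible(cnes)
}

#' Run the phylogenetic-shadowing stage
#'
#' Either from a counts table (`region`, `D`, `S`; e.g. a transcription
#' of a published shared/divergent table) or from per-region hit tables
#' plus alignments. Produces the region-level [shadow_table()] and writes
#' it as TSV, with untestable regions carried as `NA` rows.
#'
#' @param counts Data frame (or TSV path) with columns `region`, `D`, `S`.
#' @param cfg A [run_config()].
#' @param m Optional family-size override (default: testable regions).
#' @return The [shadow_table()], invisibly; writes `shadow.tsv` under
#'   `cfg$out_dir`.
#' @export
run_shadow <- function(counts, cfg = run_config(), m = NULL) {
  if (is.character(counts)) {
    if (!file.exists(counts)) stop("missing input: ", counts)
    counts <- utils::read.delim(counts, comment.char = "#",
                                stringsAsFactors = FALSE)
  }
  if (nrow(counts) == 0L) {
    out <- counts
  } else {
    out <- shadow_table(counts, p0 = cfg$p0, alpha = cfg$alpha, m = m)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_report(as.data.frame(out), file.path(cfg$out_dir, "shadow.tsv"),
                cfg, "shadow")
  invisible(out)
}

#' Run the population-genetics stage
#'
#' Panel summary (S, s, H, pi, C, Tajima's D), 50/10 sliding diversity
#' and MAF profile, and, when a phenotype is supplied, the additive-model
#' association scan with an optional clade covariate. With fewer than 4
#' taxa Tajima's D is reported as `NA`; a monomorphic panel yields no
#' association rows.
#'
#' @param panel A [haplotype_panel()] or aligned-FASTA path.
#' @param phenotype Optional numeric phenotype vector (or TSV path with
#'   columns `taxon`, `value`), matched to the panel's taxa.
#' @param covariate Optional covariate vector.
#' @param cfg A [run_config()].
#' @return List with `summary`, `windows`, `association`, invisibly;
#'   writes `panel_summary.tsv`, `windows.tsv`, `association.tsv` and
#'   `variants.vcf` under `cfg$out_dir`.
#' @export
run_popgen <- function(panel, phenotype = NULL, covariate = NULL,
                       cfg = run_config()) {
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("missing input: ", panel)
    panel <- read_panel(panel)
  }
  if (is.character(phenotype)) {
    if (!file.exists(phenotype)) stop("missing input: ", phenotype)
    tab <- utils::read.delim(phenotype, stringsAsFactors = FALSE)
    phenotype <- tab$value[match(panel$taxa, tab$taxon)]
  }
  summ <- panel_summary(panel)
  wins <- sliding_profile(panel, window = cfg$window, step = cfg$step)
  variants <- call_variants(panel)
  assoc <- if (!is.null(phenotype))
    associate_panel(panel, phenotype, covariate, variants = variants)
  else NULL
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_report(data.frame(region = summ$region_id, n = summ$n,
                           L = summ$L, L_valid = summ$L_valid,
                           S = summ$S, s = summ$s, H = summ$H,
                           pi = summ$pi, C = summ$C, TD = summ$TD),
                file.path(cfg$out_dir, "panel_summary.tsv"), cfg, "popgen")
  .write_report(wins, file.path(cfg$out_dir, "windows.tsv"), cfg, "popgen")
  if (!is.null(assoc))
    .write_report(assoc, file.path(cfg$out_dir, "association.tsv"),
                  cfg, "popgen")
  write_variants_vcf(variants, panel,
                     file.path(cfg$out_dir, "variants.vcf"))
  invisible(list(summary = summ, windows = wins, association = assoc,
                 variants = variants))
}

## evolve with a per-site divergence profile (substitutions only)
evolve_profile <- function(seq, d) {
  ch <- seq_chars(seq)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(stats::runif(length(ch)) < p & ch %in% DNA_BASES)
  if (length(hit)) {
    cur <- match(ch[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

#' Simulate a full synthetic study region
#'
#' Generates, under one seed, every input of the pipeline with known
#' ground truth, mirroring the study design: a focal sequence; a deeply
#' diverged comparison species in which only the planted block remains
#' alignable (the phylogenetic-footprinting contrast, detectable at the
#' default >60% identity rule); a close ortholog at ~8% flank divergence
#' (the shadowing contrast) carrying the shared motif plants but not the
#' focal-only ones; a planted conserved miRNA seed site in both close
#' species; a coalescent haplotype panel derived from the focal sequence;
#' and an expression phenotype with one causal variant (the
#' highest-frequency panel variant) plus a two-level clade covariate.
#'
#' @param seed RNG seed (one seed determines every output).
#' @param length Region length (bp).
#' @param block Conserved-block interval `c(start, end)`.
#' @param d_close,d_close_block Pairwise divergence of the close ortholog
#'   outside/inside the block (defaults 0.08 / 0.04, the study's
#'   genome-wide and conserved-element levels).
#' @param d_deep,d_deep_block Same for the deep comparison species
#'   (defaults 1.2 / 0.05: flanks effectively unalignable, block
#'   conserved).
#' @param pwm A [pwm_model()] whose consensus is planted.
#' @param n_shared,n_div_a Numbers of shared and focal-only motif plants
#'   (placed inside the block).
#' @param seed_motif 8-mer planted in both close species (block tail).
#' @param panel_n,theta Haplotype-panel size and mutation parameter.
#' @param beta,sigma,clade_effect Phenotype model parameters.
#' @return List of class `synthetic_study` with elements `focal`,
#'   `close` (sequence, and `aln` vs focal), `deep` (idem), `pwm`,
#'   `manifest` (all planted truth), `panel`, `phenotype`, `clade`,
#'   `causal`.
#' @export
run_simulate <- function(seed = 1L, length = 3000L,
                         block = c(1201L, 1700L),
                         d_close = 0.08, d_close_block = 0.04,
                         d_deep = 1.2, d_deep_block = 0.05,
                         pwm = NULL, n_shared = 4L, n_div_a = 3L,
                         seed_motif = "TGACTGAG",
                         panel_n = 18L, theta = 6,
                         beta = 0.3, sigma = 0.1, clade_effect = 0.1) {
  set.seed(seed)
  if (is.null(pwm)) pwm <- strong_synthetic_pwm()
  cons <- pwm_consensus(pwm)
  w <- nchar(cons)
  focal <- random_sequence(length)
  prof <- function(d_flank, d_block) {
    d <- rep(d_flank, length); d[block[1]:block[2]] <- d_block; d
  }
  ## motif plants: evenly spaced, non-overlapping slots in the block body;
  ## the block tail is reserved for the seed-site plant
  n_plants <- n_shared + n_div_a
  slots <- floor(seq(block[1], block[2] - w - 30L,
                     length.out = n_plants + 1L))
  starts <- slots[seq_len(n_plants)]
  utr_at <- block[2] - 10L
  pf <- plant_motifs(focal, data.frame(motif = cons, start = starts,
                                       strand = "+"))
  pf <- plant_motifs(pf$seq, data.frame(motif = seed_motif, start = utr_at))
  focal <- pf$seq
  close_seq <- evolve_profile(focal, prof(d_close, d_close_block))
  deep_seq <- evolve_profile(focal, prof(d_deep, d_deep_block))
  ## re-plant in the close species: shared motifs + the conserved seed
  ## site survive intact; the focal-only plants are overwritten by the
  ## evolved background so they exist in the focal sequence alone
  pc <- plant_motifs(close_seq,
                     data.frame(motif = cons, start = starts[seq_len(n_shared)],
                                strand = "+"))
  pc <- plant_motifs(pc$seq, data.frame(motif = seed_motif, start = utr_at))
  close_seq <- pc$seq
  div_slots <- starts[n_shared + seq_len(n_div_a)]
  for (s in div_slots) {
    ## erase any residual high similarity at focal-only plant positions
    sub <- random_sequence(w)
    close_seq <- paste0(substr(close_seq, 1, s - 1), sub,
                        substr(close_seq, s + w, nchar(close_seq)))
  }
  aln_close <- pairwise_alignment(focal, close_seq,
                                  idA = "focal", idB = "close")
  aln_deep <- pairwise_alignment(focal, deep_seq,
                                 idA = "focal", idB = "deep")
  ## panel derived from the focal sequence; causal variant = the panel
  ## variant with the highest minor-allele frequency
  sim <- simulate_panel(focal, panel_n, theta)
  variants <- call_variants(sim$panel)
  g <- attr(variants, "genotypes")
  clade <- rep(c(0L, 1L), length.out = panel_n)
  causal <- if (ncol(g)) which.max(variants$maf) else NA_integer_
  phen <- if (!is.na(causal))
    simulate_phenotype(g[, causal], beta, clade, clade_effect, sigma)
  else simulate_phenotype(rep(0, panel_n), 0, clade, clade_effect, sigma)
  structure(
    list(focal = focal,
         close = list(seq = close_seq, aln = aln_close),
         deep = list(seq = deep_seq, aln = aln_deep),
         pwm = pwm,
         manifest = list(block = block,
                         motif_focal = data.frame(start = starts,
                                                  shared = c(rep(TRUE, n_shared),
                                                             rep(FALSE, n_div_a))),
                         seed_site = c(start = utr_at,
                                       end = utr_at + nchar(seed_motif) - 1L),
                         seed_motif = seed_motif,
                         D_true = n_div_a, S_true = n_shared,
                         panel_truth = sim$truth, causal = causal),
         panel = sim$panel, phenotype = phen, clade = clade,
         causal = causal),
    class = "synthetic_study"
  )
}

#' Consensus sequence of a PWM
#'
#' @param pwm A [pwm_model()].
#' @return The per-position argmax base string.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$scores, 2, which.max)], collapse = "")
}

#' A strongly informative synthetic PWM
#'
#' A 12-position matrix with 18 counts on the consensus base and 0
#' elsewhere at every position; with the default 0.5 pseudocount its
#' consensus scores ~21 bits, so planted consensus occurrences pass the
#' default retention thresholds while random background does not.
#'
#' @param consensus Consensus string (default `"TGACGTCATGCA"`).
#' @param depth Count depth per position.
#' @param factor,accession Labels.
#' @return A [pwm_model()].
#' @export
strong_synthetic_pwm <- function(consensus = "TGACGTCATGCA", depth = 18,
                                 factor = "SYN1", accession = "SYN0001") {
  ch <- seq_chars(toupper(consensus))
  counts <- matrix(0, 4, length(ch), dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(ch, DNA_BASES), seq_along(ch))] <- depth
  pwm_model(counts, factor = factor, accession = accession)
}
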