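## Haplotype-panel polymorphism summaries, sliding-window diversity/MAF
## profiles, and additive-model SNP-expression association. Species are
## haploid allele carriers (one sequence per species); gap columns are
## excluded from nucleotide statistics but contiguous gap runs are retained
## once each as indel variants for MAF and association.

#' Construct a haplotype panel
#'
#' @param seqs Named character vector (or `DNAStringSet`) of aligned
#'   sequences over `A/C/G/T/N/-`, one per taxon, equal lengths, `n >= 2`.
#' @param region_id Label.
#' @return Object of class `haplotype_panel`: list with `region_id`,
#'   `taxa`, `mat` (n x L character matrix), `L`.
#' @export
haplotype_panel <- function(seqs, region_id = "region") {
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  n <- length(seqs)
  if (n < 2L) stop("panel needs at least two taxa")
  if (length(unique(nchar(seqs))) != 1L)
    stop("all panel rows must have equal aligned length")
  if (is.null(names(seqs))) names(seqs) <- paste0("taxon", seq_len(n))
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  if (any(!mat %in% c(DNA_BASES, "N", "-")))
    stop("panel rows contain characters outside A/C/G/T/N/-")
  structure(list(region_id = region_id, taxa = names(seqs),
                 mat = mat, L = ncol(mat)),
            class = "haplotype_panel")
}

#' Read a haplotype panel from aligned FASTA
#'
#' @param path Aligned FASTA, one record per taxon.
#' @param region_id Label (default: file name).
#' @return A [haplotype_panel()].
#' @export
read_panel <- function(path, region_id = NULL) {
  x <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  haplotype_panel(seqs, region_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d taxa x %d columns\n",
              x$region_id, length(x$taxa), x$L))
  invisible(x)
}

## columns usable for nucleotide statistics: no gap, no N in any row
.valid_columns <- function(panel) {
  apply(panel$mat, 2, function(col) all(col %in% DNA_BASES))
}

#' Call variants from a haplotype panel
#'
#' SNPs are polymorphic gap-free columns (columns with any gap are
#' excluded from nucleotide statistics); maximal runs of consecutive
#' columns gapped in the same set of taxa are recorded once each as indel
#' variants, coded absence/presence. Singletons are variants whose minor
#' allele occurs in exactly one taxon.
#'
#' @param panel A [haplotype_panel()].
#' @return Data frame of class `variant_table`: `pos` (alignment column of
#'   the variant start), `type` (`"SNP"`/`"indel"`), `length`, `alleles`
#'   (`ref/alt`), `mac` (minor-allele count), `maf`, `singleton`, plus a
#'   `genotypes` attribute: 0/1 matrix (taxa x variants) coding the minor
#'   allele (SNPs) or indel presence.
#' @export
call_variants <- function(panel) {
  mat <- panel$mat
  n <- nrow(mat)
  valid <- .valid_columns(panel)
  vars <- list(); genos <- list()
  for (j in which(valid)) {
    col <- mat[, j]
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2L) next
    minor <- names(tab)[length(tab)]
    ## multi-allelic columns: minor allele = all non-major alleles pooled
    carriers <- col != names(tab)[1]
    mac <- sum(carriers)
    vars[[length(vars) + 1L]] <- data.frame(
      pos = j, type = "SNP", length = 1L,
      alleles = paste0(names(tab)[1], "/", paste(names(tab)[-1], collapse = ",")),
      mac = mac, maf = mac / n, singleton = mac == 1L,
      stringsAsFactors = FALSE)
    genos[[length(genos) + 1L]] <- as.integer(carriers)
  }
  ## indels: runs of columns with identical gapped-taxa sets
  gapped <- mat == "-"
  has_gap <- colSums(gapped) > 0L
  j <- 1L
  while (j <= panel$L) {
    if (has_gap[j]) {
      set <- gapped[, j]
      e <- j
      while (e + 1L <= panel$L && has_gap[e + 1L] &&
             identical(gapped[, e + 1L], set)) e <- e + 1L
      k <- sum(set)
      mac <- min(k, n - k)
      vars[[length(vars) + 1L]] <- data.frame(
        pos = j, type = "indel", length = e - j + 1L,
        alleles = "-", mac = mac, maf = mac / n, singleton = mac == 1L,
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <- as.integer(set)
      j <- e + 1L
    } else j <- j + 1L
  }
  if (!length(vars)) {
    out <- data.frame(pos = integer(), type = character(),
                      length = integer(), alleles = character(),
                      mac = integer(), maf = numeric(),
                      singleton = logical(), stringsAsFactors = FALSE)
    g <- matrix(integer(), nrow = n, ncol = 0,
                dimnames = list(panel$taxa, NULL))
  } else {
    out <- do.call(rbind, vars)
    o <- order(out$pos)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    g <- do.call(cbind, genos)[, o, drop = FALSE]
    rownames(g) <- panel$taxa
    colnames(g) <- paste0(out$type, "_", out$pos)
  }
  attr(out, "genotypes") <- g
  class(out) <- c("variant_table", "data.frame")
  out
}

## Tajima's D normalising constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Panel polymorphism summary
#'
#' Over gap-free, N-free columns: `S` segregating sites, `s` singletons,
#' `H` haplotype count, mean pairwise differences `khat`, nucleotide
#' diversity `pi = khat / L_valid`, conservation `C = 1 - S/L_valid`, and
#' Tajima's D `(khat - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants. `S = 0` (or `n < 4`) leaves D undefined (`NA`), not zero.
#' Indels are not counted in any of these statistics.
#'
#' @param panel A [haplotype_panel()].
#' @return List of class `panel_summary`: `region_id`, `n`, `L`,
#'   `L_valid`, `S`, `s`, `H`, `khat`, `pi`, `C`, `TD`.
#' @export
panel_summary <- function(panel) {
  mat <- panel$mat
  n <- nrow(mat)
  valid <- .valid_columns(panel)
  vm <- mat[, valid, drop = FALSE]
  Lv <- ncol(vm)
  if (Lv == 0L) stop("no gap-free columns")
  seg <- apply(vm, 2, function(col) length(unique(col)) > 1L)
  S <- sum(seg)
  s <- sum(apply(vm[, seg, drop = FALSE], 2, function(col) {
    tab <- table(col)
    sum(tab == 1L) >= 1L && length(tab) == 2L && min(tab) == 1L
  }))
  H <- length(unique(apply(vm, 1, paste, collapse = "")))
  ## mean pairwise differences via per-column allele counts:
  ## sum_j [C(n,2) - sum_b C(n_bj, 2)] / C(n,2)
  pairs <- n * (n - 1) / 2
  diffs <- sum(apply(vm[, seg, drop = FALSE], 2, function(col) {
    tab <- table(col)
    pairs - sum(tab * (tab - 1) / 2)
  }))
  khat <- diffs / pairs
  pi <- khat / Lv
  TD <- NA_real_
  if (S > 0L && n >= 4L) {
    k <- tajima_constants(n)
    TD <- (khat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  structure(list(region_id = panel$region_id, n = n, L = panel$L,
                 L_valid = Lv, S = S, s = s, H = H, khat = khat,
                 pi = pi, C = 1 - S / Lv, TD = TD),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> %s (n = %d, %d/%d valid sites)\n",
              x$region_id, x$n, x$L_valid, x$L))
  cat(sprintf("  S = %d  s = %d  H = %d  pi = %.4g  C = %.4g  Tajima's D = %s\n",
              x$S, x$s, x$H, x$pi, x$C,
              if (is.na(x$TD)) "undefined" else sprintf("%.4f", x$TD)))
  invisible(x)
}

#' Sliding-window diversity and MAF profile
#'
#' Windows advance on the alignment coordinate; within each window the
#' denominator counts only gap-free columns and `pi` is recomputed over
#' them; `maf_window` is the mean minor-allele frequency of SNPs in the
#' window, 0 when the window holds none.
#'
#' @param panel A [haplotype_panel()].
#' @param window,step Window length and step (bp; defaults 50 and 10).
#' @return Data frame `start`, `end`, `midpoint`, `n_valid`, `pi_window`,
#'   `maf_window`.
#' @export
sliding_profile <- function(panel, window = 50L, step = 10L) {
  stopifnot(window >= step, step >= 1L)
  mat <- panel$mat
  n <- nrow(mat)
  L <- panel$L
  valid <- .valid_columns(panel)
  pairs <- n * (n - 1) / 2
  coldiff <- numeric(L)
  colmaf <- rep(NA_real_, L)
  for (j in which(valid)) {
    tab <- table(mat[, j])
    coldiff[j] <- pairs - sum(tab * (tab - 1) / 2)
    if (length(tab) > 1L) {
      mac <- n - max(tab)
      colmaf[j] <- mac / n
    }
  }
  starts <- if (L <= window) 1L else seq.int(1L, L - window + 1L, by = step)
  out <- lapply(starts, function(s) {
    e <- min(L, s + window - 1L)
    idx <- s:e
    nv <- sum(valid[idx])
    segmaf <- colmaf[idx][valid[idx]]
    segmaf <- segmaf[!is.na(segmaf)]
    data.frame(start = s, end = e, midpoint = (s + e) / 2, n_valid = nv,
               pi_window = if (nv > 0) sum(coldiff[idx]) / pairs / nv
                           else NA_real_,
               maf_window = if (length(segmaf)) mean(segmaf) else 0)
  })
  do.call(rbind, out)
}

#' Additive-model SNP-expression association
#'
#' Ordinary least squares `phenotype ~ genotype (+ covariate)` with
#' haploid additive genotype coding (0/1; indels absence/presence). The
#' genotype coefficient's two-sided t-test and the model R^2 are
#' reported.
#'
#' @param genotypes Numeric vector of additive genotype codes, one per
#'   taxon.
#' @param phenotype Numeric vector (e.g. proportion of total opsin
#'   expression).
#' @param covariate Optional covariate (e.g. 0/1 clade indicator).
#' @param snp_id Label.
#' @return One-row data frame: `snp_id`, `maf`, `beta`, `se`, `t`, `p`,
#'   `r2`, `df`, `note` (`""`, `"monomorphic"` or `"collinear"`).
#' @export
snp_association <- function(genotypes, phenotype, covariate = NULL,
                            snp_id = "snp") {
  stopifnot(length(genotypes) == length(phenotype))
  n <- length(genotypes)
  maf <- min(mean(genotypes > 0), mean(genotypes == 0))
  blank <- data.frame(snp_id = snp_id, maf = maf, beta = NA_real_,
                      se = NA_real_, t = NA_real_, p = NA_real_,
                      r2 = NA_real_, df = NA_integer_, note = "",
                      stringsAsFactors = FALSE)
  if (length(unique(genotypes)) < 2L) {
    blank$note <- "monomorphic"
    return(blank)
  }
  dat <- data.frame(y = phenotype, g = genotypes)
  form <- y ~ g
  if (!is.null(covariate)) {
    dat$cl <- covariate
    if (stats::sd(covariate) > 0 &&
        abs(stats::cor(genotypes, covariate)) > 1 - 1e-10) {
      blank$note <- "collinear"
      return(blank)
    }
    form <- y ~ g + cl
  }
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  if (!"g" %in% rownames(co)) {
    blank$note <- "collinear"
    return(blank)
  }
  data.frame(snp_id = snp_id, maf = maf,
             beta = co["g", 1], se = co["g", 2], t = co["g", 3],
             p = co["g", 4], r2 = sm$r.squared,
             df = fit$df.residual, note = "", stringsAsFactors = FALSE)
}

#' Panel-wide association scan
#'
#' Runs [snp_association()] for every variant of the panel against one
#' phenotype.
#'
#' @param panel A [haplotype_panel()].
#' @param phenotype Numeric vector aligned with the panel's taxa.
#' @param covariate Optional covariate vector.
#' @param variants Optional precomputed [call_variants()] result.
#' @return Data frame, one row per variant, ordered by `p`.
#' @export
associate_panel <- function(panel, phenotype, covariate = NULL,
                            variants = NULL) {
  if (is.null(variants)) variants <- call_variants(panel)
  g <- attr(variants, "genotypes")
  if (ncol(g) == 0L)
    return(data.frame(snp_id = character(), maf = numeric(),
                      beta = numeric(), se = numeric(), t = numeric(),
                      p = numeric(), r2 = numeric(), df = integer(),
                      note = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(ncol(g)), function(i) {
    res <- snp_association(g[, i], phenotype, covariate,
                           snp_id = colnames(g)[i])
    res$pos <- variants$pos[i]
    res$type <- variants$type[i]
    res
  }))
  out[order(out$p), , drop = FALSE]
}

#' Export a variant table as a haploid VCF
#'
#' Writes a minimal VCFv4.2 text file with haploid genotypes (0 = major
#' allele / indel absent, 1 = minor allele / indel present). Indels are
#' encoded with symbolic alleles (`<DEL>`).
#'
#' @param variants A [call_variants()] result.
#' @param panel The originating [haplotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, panel, path) {
  g <- attr(variants, "genotypes")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", panel$region_id, panel$L),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$taxa), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    al <- strsplit(variants$alleles[i], "/", fixed = TRUE)[[1]]
    ref <- if (variants$type[i] == "SNP") al[1] else "N"
    alt <- if (variants$type[i] == "SNP") gsub(",", ",", al[2]) else "<DEL>"
    paste(c(panel$region_id, variants$pos[i],
            paste0(tolower(variants$type[i]), "_", variants$pos[i]),
            ref, alt, ".", "PASS",
            sprintf("TYPE=%s;MAF=%.4f", variants$type[i], variants$maf[i]),
            "GT", g[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
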