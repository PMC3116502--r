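---
title: "Methods: footprinting, shadowing and panel statistics in regshadow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprinting, shadowing and panel statistics in regshadow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regshadow)
```

regshadow implements the comparative workflow used to nominate candidate
*cis*-regulatory sequence around tandem gene arrays — the motivating system
is the cone-opsin arrays of African cichlid fishes. The workflow has three
tiers, at three phylogenetic depths:

1. **Phylogenetic footprinting** (deep divergence, ~100-300 My): conserved
   non-coding elements (CNEs) are the non-coding segments that remain
   alignable at high identity against distant relatives.
2. **Phylogenetic shadowing** (intermediate divergence, ~18 My): within
   CNEs, proximal promoters and 3'-UTRs, transcription-factor binding
   sites (TFBS) and microRNA target sites are profiled in two focal
   species and classified as shared or divergent; the divergence
   proportion is tested against a neutral expectation.
3. **Panel polymorphism and association** (shallow divergence, <2 My):
   candidate regions are resequenced across a panel of species and
   summarised with population-genetic statistics; individual variants are
   tested for association with expression phenotypes.

This vignette records the model behind each tier, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Sequence divergence

Pairwise divergence is estimated per region from a gapped alignment.
Comparable columns carry an unambiguous base (`A/C/G/T`) in both rows;
gap and `N` columns are excluded (`N` is assembly ambiguity, not
evidence of change). The raw mismatch proportion $p$ is corrected for
multiple hits with the Jukes-Cantor model,

$$D_{xy} = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}p\right),$$

undefined at saturation ($p \ge 3/4$), which `jc69_distance()` reports
as an error rather than a number. For intronic divergence the first
intron is excluded entirely and every other intron loses its first and
last six bases (splice sites and intron-proximal regulatory sequence are
atypically conserved); introns of 12 bp or less therefore drop out
whole. Group comparisons of $D_{xy}$ use a pooled-variance two-sample
t-test on $\log_{10}$ values (`log_ttest()`); the pooled form, with
$df = n_A + n_B - 2$, matches the degrees of freedom conventionally
reported for such comparisons.

**Coordinates.** All coordinates in the package are 1-based and closed,
the native convention of R and Bioconductor; GFF3 shares it and BED
(0-based half-open) is converted at the read/write boundary. Keeping a
single internal convention and converting only at the edges prevents
off-by-one drift.

## CNE detection

The field's classic detection (percent-identity plots inspected by eye)
is replaced by a deterministic algorithm:

1. Sliding-window identity (window 50 bp, step 10 bp by default) on
   focal-sequence coordinates; the denominator counts focal non-gap
   columns, so comparison-row gaps count as mismatch — conservation is
   penalised by lineage-specific loss.
2. Positions covered by any window exceeding `min_identity` (default
   0.60) in at least one comparison species are unioned; runs separated
   by less than the step are merged.
3. Each run's boundaries are refined at single-base resolution: the
   element match rate $p_1$ is estimated from the central half of the
   run, the background rate $p_0$ from the sequence outside all runs,
   and the run is replaced by the maximal-scoring segment of the
   per-position log-likelihood ratio
   $\log\frac{p_1}{p_0}$ (match) / $\log\frac{1-p_1}{1-p_0}$
   (mismatch) — the two-changepoint maximum-likelihood boundaries. The
   estimation and refinement are iterated once.
4. Runs are trimmed to exclude annotated CDS and repeats (splitting
   where necessary, so partially non-coding conservation survives), and
   elements shorter than `min_length` (default 50 bp) are dropped.
   Elements are numbered left to right.

Defaults encode the standard rule: an element is at least 50 bp at more
than 60% identity against at least one comparison species.

**Boundary identifiability.** How precisely boundaries can be placed
depends on the identity contrast. For a block at $d = 0.02$ inside
flanks at $d = 0.12$ (match rates ~0.98 vs ~0.889) the boundary is only
weakly identifiable: flank stretches of 30-60 bp with few mismatches
occur regularly and are statistically indistinguishable from the
element. The chunk below (not run at build time) estimates the floor:
even the likelihood argmax *given the true rates* has a population
median boundary error of about 10 bp at these rates, with a heavy tail.

```{r floor, eval = FALSE}
pb <- 1 - 0.75 * (1 - exp(-4 * 0.02 / 3))   # block match rate
pf <- 1 - 0.75 * (1 - exp(-4 * 0.12 / 3))   # flank match rate
up <- log(pb / pf); dn <- log((1 - pb) / (1 - pf))
kadane <- function(sc) {
  best <- 0; bs <- be <- 0; cur <- 0; cs <- 1
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cs <- i }
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; bs <- cs; be <- i }
  }
  c(bs, be)
}
err <- replicate(2000, {
  m <- c(runif(1200) < pf, runif(500) < pb, runif(1300) < pf)
  seg <- kadane(ifelse(m, up, dn))
  c(abs(seg[1] - 1201), abs(seg[2] - 1700))
})
median(err)   # ~10 bp: the statistical floor, not an implementation gap
```

The test suite asserts a 10 bp median boundary error at exactly this
contrast; because the bound coincides with the statistical floor, that
check can fail at some seeds no matter the estimator, and it is
documented here rather than relaxed. At the deep-divergence contrast
the footprinting tier actually operates at (flanks effectively
unalignable), boundaries localise far more sharply.

## TFBS scanning

Motifs are position count matrices (a TRANSFAC-like text format is
parsed by `read_transfac()`). Counts become frequencies with a
pseudocount of 0.5 per base, $f_{ij} = (c_{ij} + 0.5)/(N_j + 2)$, and a
window $b_1..b_L$ scores

$$L_a = \sum_{j=1}^{L} \log_2 \frac{f_j(b_j)}{q(b_j)}$$

in bits against the background $q$ (uniform by default;
`composition_background()` derives one from sequence composition). The
score ratio is $L_q = L_a / L_a^{\max}$ with $L_a^{\max}$ the sum of
per-position maxima. The exact tail probability $L_{pv} = P(L_a(K) \ge
L_a)$ for background k-mers $K$ is computed by dynamic programming over
the per-position score distributions, discretised to 0.001-bit bins.
Rounding is conservative: per-position scores are floored to bins, and
the threshold is lowered by one bin per position, so the reported
$L_{pv}$ never understates the true tail; it can overstate it by at
most the probability mass within one bin per position (the test suite
checks this bracket against exhaustive enumeration over all $4^L$
windows for $L \le 8$).

Both strands are scanned (regulatory factors bind degenerate motifs in
an orientation-independent manner); windows containing `N` are not
called; hits must pass all three retention thresholds, by default
$L_a \ge 9.0$ bits, $L_q \ge 0.80$, $L_{pv} < 0.05$. The thresholds are
configurable because score conventions differ between scanners — these
defaults are calibrated to the package's own bit-score scale and are
not bit-exact against any external tool. Duplicate hits at the same
(factor, start, strand) — for example from several matrices of one
factor, or from collapsing the retinoic-acid-receptor paralogs under
the `RAR` alias — are collapsed keeping the highest score.

## Shadowing statistics

Hits from two orthologous sequences are matched through the alignment:
a hit in A pairs with at most one unmatched hit in B of the same factor
whose projected interval overlaps by at least one column, greedily left
to right, ties broken by larger overlap then higher score. Matching is
strand-agnostic, consistent with orientation-independent binding. With
$S$ shared pairs and $D$ unmatched hits (both species pooled), the
divergence proportion is

$$P_{div} = 100 \cdot \frac{D}{D+S},$$

and the one-sided exact binomial p-value of $D$ successes in $D+S$
trials tests $P_{div} > p_0$. The default null $p_0 = 0.08$ is the
neutral expectation from ~8% genome-wide divergence between the two
focal species (sequences ~92% identical); a region-specific null such
as the masked intron divergence of the nearest gene can be supplied
instead. Families of tests are Bonferroni-corrected; the family size
defaults to the number of testable regions in the run (31 in the
bundled two-species table, giving the threshold $0.05/31 \approx
0.0016$). Regions with $D + S = 0$ or no identifiable ortholog are
untestable and propagate as `NA` rows.

Two auxiliary comparisons round out the tier: a paired Wilcoxon
signed-rank test for enrichment of per-factor site counts between
region groups (zero differences dropped, exact p when no ties), and a
Mantel test correlating a binding-profile distance matrix with an
expression distance matrix (Pearson correlation of lower-triangle
entries; p from simultaneous row/column permutations, 500 by default,
with the add-one correction $(1 + \#\{r^* \ge r\})/(1 + n_{perm})$ so p
is never zero).

**Known data quirk.** In the bundled two-species counts table, two rows
(CNE 20 and the LWS promoter) print p = 1.000 where the stated test
gives 0.689 and 0.758; one P_div and one p-value are printed with
truncated rather than rounded last digits. The implementation follows
the stated formulas; the regression tests assert the mismatches
explicitly instead of reproducing them.

## miRNA seed targets

3'-UTRs are delimited as the region from the end of the coding sequence
to the end of the first polyadenylation signal (`AATAAA`), truncated at
500 bp when no signal occurs; for comparison species whose
polyadenylation site is not trusted, a fixed 1 kb is taken instead.
Target sites are exact 8-mer matches on the sense strand (miRNA
repression acts on the mRNA), overlapping occurrences all reported, one
report per miRNA when several share a motif. A site is *conserved* when
another species carries a site for the same miRNA within 50 alignment
columns — the tolerance is counted in columns, not ungapped offsets,
because it exists to absorb alignment error. Seed libraries are read
from TSV; `derive_target_from_mature()` builds 8-mer targets from
mature miRNA sequences under either of the two common rules (reverse
complement of positions 1-8, or of positions 2-8 followed by a 3' `A`).

## Panel statistics

A haplotype panel is one aligned sequence per species; species are
haploid allele carriers, so genotypes are coded 0/1 (for indels:
absence/presence). Columns with any gap or `N` are excluded from
nucleotide statistics ("complete deletion"), but each maximal run of
columns gapped in the same taxa is retained once as an indel marker for
MAF and association — panels genuinely segregate short indels within
candidate regulatory sequence, and excluding them from association
would discard testable variants. Indels do not count toward $S$, $s$,
$H$, $\pi$ or Tajima's D.

Over the $L_v$ valid columns: $S$ segregating sites, $s$ singletons
(biallelic sites whose minor allele occurs once), $H$ distinct
haplotypes, mean pairwise differences $\hat k$, nucleotide diversity
$\pi = \hat k / L_v$, conservation $C = 1 - S/L_v$, and Tajima's

$$D_T = \frac{\hat k - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}$$

with the standard constants ($a_1 = \sum_{i<n} 1/i$, etc.). $S = 0$
leaves $D_T$ undefined (`NA`), never zero. Sliding-window profiles
(window 50 bp, step 10 bp, matching the region-wide convention used
throughout) recompute $\pi$ per window over the window's valid columns
and report the mean minor-allele frequency of the window's SNPs (zero
when none).

Association uses ordinary least squares, phenotype ~ genotype (+ clade
covariate), under an additive genetic model; the genotype coefficient's
two-sided t-test, the model $R^2$ and the residual degrees of freedom
are reported. With $n$ taxa and a covariate the residual df is $n - 3$;
published tables sometimes quote $n - 1$, so the df is reported
explicitly rather than assumed. Monomorphic genotypes are untestable
and genotypes collinear with the covariate are flagged, not silently
fitted. The phenotype is expected on the scale of an expression
fraction (proportion of total opsin expression for the opsin nearest
the marker).

## Synthetic data

The generators give every stage inputs with known ground truth, under
one seed (fixed seed implies byte-identical outputs):

- `evolve_sequence()` applies the same Jukes-Cantor model the estimator
  corrects for: each site substitutes with probability
  $p = \tfrac34(1 - e^{-4d/3})$, uniformly among the three
  alternatives. No indels by default, so the true alignment is the
  identity and planted coordinates stay exact.
- `plant_motifs()` overwrites motifs at known offsets (reverse
  complement on the minus strand) and returns the manifest.
- `simulate_panel()` drops Poisson-distributed mutations on a random
  coalescent (exponential waiting times of rate $k(k-1)/2$) under
  infinite sites, so $E[S] = \theta a_1(n)$ and $E[\pi] = \theta/L$.
- `simulate_phenotype()` builds
  $y_i = \beta g_i + \gamma\,\text{clade}_i + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma^2)$, optionally truncated to [0, 1]
  to emulate expression fractions.
- `run_simulate()` composes a full study region: a focal sequence; a
  deep comparison species (flanks at $d = 1.2$, effectively
  unalignable; block at $d = 0.05$) for the footprinting contrast; a
  close ortholog (flanks at $d = 0.08$, block at $d = 0.04$, the
  genome-wide and conserved-element divergences of the motivating
  species pair) carrying the shared motif plants and the conserved seed
  site but not the focal-only plants; and a panel of 18 with $\theta$
  chosen so $\pi \approx 0.002$, with $\beta = 0.3$, $\sigma = 0.1$ and
  a clade offset of 0.1 — the scale of the resequencing panel the
  design emulates.

What the generators do **not** emulate: indel evolution (an aligner is
provided for robustness experiments, but planted truth is
substitution-only), rate heterogeneity along the sequence beyond the
planted blocks, selection, recombination and demography in the
coalescent, linkage between the phenotype's causal variant and
population structure beyond the single clade covariate, and any
realistic motif evolution (plants are exact consensus copies). Passing
the planted-truth tests therefore demonstrates that the statistics and
bookkeeping are correct, not that the pipeline is robust to alignment
error or complex evolutionary histories.

## Problem sizes used by the test suite

The suite runs the divergence-recovery check on 100 replicates of
100 kb pairs at $d = 0.08$; the PWM p-value bracket on 50 random
matrices up to width 8 against full enumeration; the diversity oracles
on 100 random panels ($n \le 10$, $L \le 200$); null calibrations on
500 replicates each (Mantel with 99 permutations — the add-one
permutation p-value is uniform for any permutation count — and OLS
association), plus 3000 simulated binomial regions at the null
divergence; and one fixed-seed end-to-end synthetic study of 3 kb with
a panel of 18. These sizes keep the full suite under a minute while
leaving the stochastic checks well-powered.

## Known limitations

- CNE boundaries at weak identity contrasts carry irreducible ~10 bp
  median uncertainty (see above); reported boundaries should be read
  with that granularity.
- PWM p-values are exact for the background model, not for real genomic
  composition; use `composition_background()` when that matters.
- The shadowing null treats every site as an independent Bernoulli
  trial; clustered sites in one element violate independence, and with
  few sites per region only extreme divergence proportions reach
  significance after family-wise correction.
- The panel statistics assume one haplotype per taxon; no phasing,
  diploid calling, or population-structure correction beyond the single
  clade covariate is attempted.
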