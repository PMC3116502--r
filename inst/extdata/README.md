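# Bundled plain-text fixtures

- `onil_mzeb_site_counts.tsv` — published per-region shared/divergent
  TFBS and miRNA target-site counts (with identity, divergence and
  lengths) for the *O. niloticus* / *M. zebra* comparison, transcribed
  for use as input to the counts-based shadowing workflow; `printed_*`
  columns carry the values as printed in the source table (including
  its rounding idiosyncrasies) for regression checks.
- `mirna_seed_targets.tsv` — the conserved 8-mer miRNA seed-target
  library for the opsin 3'-UTRs (miRNA name, target motif, opsin,
  species sharing the site).
- `synthetic_pwms.transfac` — SYNTHETIC position count matrices in a
  TRANSFAC-like format. The accessions name the candidate
  opsin-regulating factors (CRX, AP-1, NF-kB, RAR/RXR/THR paralogs,
  PNR) but the counts are invented: the licensed TRANSFAC matrices are
  not redistributable. Use for format/scanning tests only, not for
  biological inference.
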