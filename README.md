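# venomics

Proteogenomic identification of parasitoid venom proteins from a
venom-gland transcriptome and a mass-spectrometry peptide list.

Parasitoid wasps regulate their hosts with injected venom proteins,
but for most species neither a genome nor a venom catalogue exists.
The standard strategy is an integrated transcriptomic + proteomic
analysis: translate every assembled contig in all six reading frames
into a protein database, map the peptides observed in the venom back
onto those translations, keep the candidates bearing an N-terminal
signal peptide (the secretome), and corroborate them by alignment
against the venom proteins of a related species plus an annotation
keyword search. `venomics` implements that pipeline as composable R
functions:

- **translation** — six-frame translation (`translate_contigs`), ORF
  extraction and 5'-completeness classing
- **peptide_mapping** — in-silico tryptic digestion (K/R, proline
  rule, missed cleavages) and exact peptide-to-translation matching
  with I/L equivalence
- **secretome** — a transparent signal-peptide heuristic
  (−3/−1 small residues, hydrophobic h-window, non-negative n-region
  charge) plus an import path for external predictor output
- **homology** — exact Smith–Waterman / Needleman–Wunsch affine-gap
  alignment (Rcpp), reference venom search with identity/coverage/score
  thresholds, catalytic-triad detection
- **keyword_mining** — "venom"/"toxin" annotation selection and its
  signal-peptide breakdown
- **quantification** — RPKM (`10^9·C/(N·L)`), expression ranking,
  dilution-series efficiency `E = 10^(−1/S) − 1`, efficiency-corrected
  ΔΔCt ratios, unpaired t-tests
- **enrichment** — OBO (is_a) parsing, true-path propagation, one-sided
  Fisher exact tests, BH-FDR, reduction to most-specific terms
- **venom_ledger** — stage-count ledger enforcing the arithmetic
  identities (`total venom = proteomic + keyword-only`, etc.) and a
  pattern-based functional categorisation
- **synthetic_data** — a fully ground-truthed miniature venom-gland
  study generator (`simulate_venom_study`) driving all tests

## Worked example

```r
library(venomics)

sim <- simulate_venom_study(generator_config(seed = 7))
res <- run_venom_pipeline(sim$contigs, sim$annotations, sim$peptides,
                          sim$reference, counts = sim$counts,
                          ontology = sim$ontology)
res$ledger
#> Venom count ledger
#>   n_contigs                    300
#>   n_db_entries                 1800
#>   n_peptides_observed          1543
#>   n_identified_contigs         261
#>   n_secretory                  60
#>   n_ref_matched                30
#>   n_ref_unmatched              30
#>   ...
#>   n_venom_proteomic            30
#>   n_venom_total                30

evaluate_recovery(res, sim$truth)[c("sensitivity", "fdp")]
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0

subset(res$enrichment, enriched)[, c("term", "name", "fdr")]
#>         term                               name          fdr
#> 4 GO:0004252 serine-type endopeptidase activity 1.278017e-11
```

The simulated study plants 300 contigs of which 60 encode secreted
proteins and 30 are venom proteins with reference homologs at 60–90%
identity. The pipeline identifies 261 contigs from the peptide list,
filters them to the 60 signal-peptide-bearing candidates, matches 30
to the reference venom set, and recovers the planted venom set with
sensitivity 1 and no false discoveries; the GO enrichment flags the
serine-type endopeptidase activity planted on the venom contigs.

With real data, replace the simulated inputs: contigs from a FASTA
(`Biostrings::readDNAStringSet`), peptides and annotations from
TSV, the reference venom set from a FASTA, and optionally real
signal-peptide predictions via `import_external_sp_calls()`.

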