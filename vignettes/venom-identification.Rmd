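---
title: "Identifying parasitoid venom proteins from transcriptome and peptide evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying parasitoid venom proteins from transcriptome and peptide evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomics)
```

## The problem

Parasitoid wasps inject a protein-rich venom that manipulates host
physiology. For most species the venom composition is unknown, and
there is rarely a sequenced genome to lean on. The standard remedy is
proteogenomic: assemble a venom-gland transcriptome de novo, translate
every contig in all six reading frames into a protein database, and
identify venom proteins by matching mass-spectrometry peptides from the
venom itself against that database. Because the database is built from
translations rather than gene models, two filters carry the biological
burden afterwards: only proteins bearing an N-terminal signal peptide
can be secreted into venom, and similarity to the venom proteins of a
related, well-characterised species corroborates venomous function.

`venomics` implements that pipeline end to end: six-frame translation,
in-silico tryptic digestion and exact peptide-to-translation mapping,
secretome filtering, local-alignment homology search, annotation
keyword mining, RPKM and efficiency-corrected qPCR quantification,
GO-term enrichment, and a count ledger that enforces the arithmetic
identities linking all the stage counts. A synthetic study generator
plants ground truth for every stage, so the whole pipeline is testable
without any external download.

## The pipeline stages and their assumptions

### Six-frame translation

Every contig is translated at all three offsets of both strands with
the standard genetic code; the database entry is the whole frame
translation, stops (`*`) included, because peptide evidence is matched
against translations, not curated gene models. Codons containing an
ambiguous base become `X`, and `X` never matches an observed peptide
residue. The database size is exactly `6 * n_contigs` by construction.
Open reading frames — maximal stop-free segments — are a separate view
used for two purposes: the secretome filter needs a credible
N-terminus, and the bookkeeping of keyword-selected transcripts splits
those lacking a signal peptide into 5'-incomplete, complete and
too-small ORFs (default threshold 30 residues: anything shorter cannot
display a signal peptide at all). An ORF abutting the contig edge
without an initial methionine is 5'-incomplete: the true start lies
upstream of the assembly, and no signal-peptide call can be made for
it, so such candidates are recorded as no-calls rather than negatives.

### Peptide mapping

Observed peptides are matched as exact substrings of the frame
translations. Isoleucine and leucine are collapsed by default: they are
isobaric and indistinguishable to standard MS/MS. Mass tolerances play
no role here because the package's input boundary is the peptide list,
not spectra. Tryptic termini (preceded/followed by K or R, proline
rule honoured) are annotated but not required by default, since the
upstream search engine has already enforced its own criteria. A
(contig, frame) pair with at least one distinct supporting peptide
(`min_peptides = 1`) becomes a protein candidate, linked to the longest
ORF containing one of its peptides.

### Secretome filter

A trained signal-peptide predictor cannot be reimplemented from
published material, so the package ships a transparent von-Heijne-style
heuristic with the classical three-region architecture: a cleavage
site `p` in 15–35 with small residues (A, G, S, C, T, V) at the −3 and
−1 positions, an 8-residue window within positions `1..p` of mean
Kyte–Doolittle hydropathy at least 2.0 (the hydrophobic h-region), and
a non-negative net charge over the n-region preceding that window.
Among valid sites the one with the most hydrophobic window wins, ties
to the smaller position. Sequences shorter than 18 residues and
5'-incomplete ORFs give no-calls. Users with genuine predictor output
can substitute it via `import_external_sp_calls()`; the filter
semantics (keep exactly the positive calls) are unchanged. The
heuristic and the generator's planted signal peptides are documented
together and evolve together — which also means the measured
sensitivity/specificity of 1.0 on synthetic data shows internal
consistency, not real-world predictor accuracy.

### Homology search

Candidate secretome proteins are validated against a reference venom
set by exact Smith–Waterman local alignment (affine gaps, BLOSUM62,
gap open 11, extend 1, a length-`k` gap costing `open + (k-1)·extend`;
`X` scores 0 against everything). Exact alignment replaces heuristic
seeded search deliberately: at desk scale it is affordable, fully
deterministic, and easy to verify against enumeration. Matches require
≥ 35% identity over aligned columns, ≥ 0.5 query coverage and score
≥ 50 — conventional defaults, configurable. No E-values are computed;
they depend on database size and add nothing at this scale. A
serine-protease catalytic-triad detector aligns queries to an annotated
canonical protease (a synthetic stand-in constructed in code, with the
conventional triad columns His 70, Asp 125/130, Ser 240/245) and
reports each member as canonical, substituted or undetermined.

### Keyword mining and the ledger

Transcripts whose annotation description contains "venom" or "toxin"
(case-insensitive substring — venom nomenclature includes compounds
like *plancitoxin* that word-boundary matching would miss) form the
transcriptomic venom set; those not already identified proteomically
are the keyword-only transcripts. Secretory proteins unmatched by the
reference set split by annotation into other-venom-similar,
unannotated, and venom trace elements (secreted, detected, but without
venom similarity — plausibly duct proteins or dissection
contaminants). The ledger derives all downstream counts from the
primitive stage counts and hard-errors on any violated identity:

* `n_db_entries = 6 · n_contigs`
* `n_secretory = n_ref_matched + n_ref_unmatched`
* `n_ref_unmatched = n_other_venom_similar + n_unannotated + n_trace_elements`
* `n_venom_proteomic = n_ref_matched + n_other_venom_similar`
* `n_venom_total = n_venom_proteomic + n_keyword_only`
* `n_keyword_total = n_keyword_sp + n_keyword_missing_sp`, the missing
  split into 5'-incomplete + complete + too-small

The proteomic venom set deliberately excludes unannotated secretory
proteins: they have peptide evidence and a signal peptide but no
similarity evidence of venomous function, which is the only reading
under which the identities above close simultaneously.

### Quantification

RPKM is `10^9 · C / (N · L)` for `C` uniquely aligned reads on a
contig of `L` bases in a library of `N` uniquely aligned reads; the
identity `Σ rpkm·L = 10^9` holds for any count vector and is tested.
Ranked expression tables report `log2(RPKM)` alongside. qPCR
efficiency comes from the dilution-series slope, `E = 10^(−1/S) − 1`,
and relative expression uses the efficiency-corrected (Pfaffl-form)
ratio

`ratio = (1+E_t)^(ΔCt_t) / geomean_r (1+E_r)^(ΔCt_r)`, ΔCt = calibrator − test,

which reduces to the classical `2^(−ΔΔCt)` at `E = 1`. Two reference
genes are combined by the geometric mean of their normalisation
factors — the standard multi-reference convention. Group comparison is
a classical pooled-variance unpaired t-test (Welch behind a flag),
with SEM reported per group.

### Enrichment

GO annotations are propagated to all is_a ancestors (true-path rule)
before counting; each term's over-representation in the venom set
against the whole-transcriptome background is a one-sided Fisher exact
test, BH-FDR-corrected at α = 0.05, and the enriched report is reduced
to most-specific terms (every enriched ancestor of another enriched
term is dropped, leaving an antichain). Enrichment counts contigs, not
proteins — one vote per contig per term. The OBO reader handles the
is_a fragment of the format only; `part_of` and other relations are
out of scope.

## The synthetic study generator

The generator's defaults define the study conditions used throughout
the tests: 300 contigs; 20% secreted, half of those venom proteins;
reference homologs planted at 60–90% global identity (by exact-count
point substitution of the mature protein) plus 5 decoys; peptide
sampling depth 10 with 5% contaminants; negative-binomial counts with
dispersion 0.3; qPCR efficiencies 0.9–1.0, technical noise 0.15
cycles, fold changes 4–64 on ten venom genes against GAPDH and
beta-tubulin stand-ins. One seed determines every output byte.

Constructions worth knowing before interpreting test results:

* Signal peptides are planted from the same three-region template the
  heuristic tests (randomised within each region), avoiding a circular
  dependence on an external predictor but making heuristic accuracy on
  synthetic data an internal-consistency check, not a benchmark.
  Non-secreted proteins interleave hydrophilic residues through their
  first 40 positions so that no h-window can reach the threshold —
  negative by construction.
* Mature regions are built as K/R-terminated blocks of 8–18 residues,
  so every planted protein has fully-cleaved tryptic fragments inside
  the observable 7–35 residue range. With fully uniform sequences an
  occasional protein has an empty observable digest and can never be
  detected — a real phenomenon, but one that would make exact-recovery
  invariants meaningless.
* Reference entries are the planted *mature* proteins. Full-length
  references would share the signal-peptide architecture across all
  secreted proteins and generate spurious SP-to-SP local alignments
  that pass conventional thresholds.
* Secreted proteins are more highly expressed (log-normal around 300
  reads versus 30), as expected of a secretory tissue; peptide counts
  per protein are Poisson in depth × relative expression.
* Contaminant peptides are random 7–25-mers verified (under I/L
  collapse) to match no frame translation of any contig.
* Noise magnitudes (count dispersion, Ct noise) are the package's own
  stated choices of plausible scale; no published values exist for
  them.

What passing tests therefore show: the pipeline's logic is exact and
its stages compose correctly under controlled truth. What they do not
show: robustness to fragmented assemblies, chimeric contigs, spectral
misidentification, shared peptides across paralogs, or real
signal-peptide biology.

## Worked example

```{r example, eval = FALSE}
library(venomics)

sim <- simulate_venom_study(generator_config(seed = 7))
res <- run_venom_pipeline(sim$contigs, sim$annotations, sim$peptides,
                          sim$reference, counts = sim$counts,
                          ontology = sim$ontology)
res$ledger
evaluate_recovery(res, sim$truth)
head(res$top_venom)
subset(res$enrichment, enriched)
```

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere; frame `-k` is the
  reverse complement at offset `k − 1`.
* Alignment traceback ties resolve toward the diagonal, then up, so
  reported alignments are deterministic; equal-scoring reference hits
  resolve by reference id.
* Expression ties rank lexicographically by contig id.
* `rpkm` errors on `N = 0` or `L = 0`; `log2(RPKM)` is NA at zero
  counts; the count simulator flags an all-zero library.
* An efficiency slope ≥ 0 warns rather than errors: the series is
  uninterpretable but downstream code may still want the fit.
* With zero replicate variance in both qPCR groups the t-test is
  undefined; the analysis reports NA statistics rather than failing.
* Problem sizes in the oracle tests are chosen for exactness at desk
  scale: alignment is verified by exhaustive enumeration over all
  2-letter pairs up to length 3 and randomized 4-letter pairs up to
  length 5 (enumeration grows explosively beyond that), and against an
  independent alignment library for longer sequences; Fisher p-values
  are verified against exhaustive table enumeration for margins ≤ 12;
  recovery runs use 300-contig studies over 10 seeds.

## Known limitations

* The secretome heuristic is a transparent approximation; for
  publication-grade secretome calls import real predictor output.
* Protein inference is per (contig, frame) with no parsimony across
  shared peptides; paralog families may multi-count.
* The OBO reader covers the is_a fragment only; GO-slim mapping and
  level-based bar charts are reduced to a depth column.
* No E-values, no profile search, no phylogenetics: the homology stage
  answers "is this similar to a known venom protein", nothing more.
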