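# edclocus

Annotation and comparative analysis of the **Epidermal Differentiation
Complex (EDC)** — the amniote gene cluster, flanked by *S100A12* and
*S100A11*, that encodes the proteins of skin cornification. The package
re-implements, as a tested and fully reproducible pipeline, the
comparative-genomics procedure used to discover and characterize the EDC in
crocodilian genome assemblies and to relate it to the EDC of birds and
turtles:

1. **Locus delimitation** — a six-frame translated homology search (exact
   Smith–Waterman/Gotoh dynamic programming over every reading frame,
   BLOSUM62, affine gaps `open = 11`, `extend = 1`, no low-complexity
   masking) locates the S100A marker genes and returns the region between
   them; fragmented scaffolds are ordered against a reference gene order.
2. **Gene prediction** — "simple EDC" (SEDC) genes, whose entire coding
   region lies on a single exon downstream of a TATA box, a short
   noncoding exon and a canonical GT..AG intron, are predicted de novo from
   ORF structure, a composition changepoint score over the
   EDC-characteristic residues {G,S,P,K,C,Q}, and promoter/splice evidence.
   Two-coding-exon S100-fused-type (SFTP) genes are assembled from paired
   translated-search hits joined across a canonical intron. Predictions are
   triaged into complete / partial / pseudogene and validated against
   RNA-seq reads (including intron-spanning reads).
3. **Protein profiling** — exact amino-acid composition percentages,
   enrichment classes under the strict "exceeds 20%" rule, and terminal
   lysine/glutamine motifs (candidate transglutamination cross-linking
   sites).
4. **Repeat profiling** — degenerate tandem-repeat detection with the motif
   grammar `CCDPCQ(K|-)(T|P)(V|-)` (the avian EDCRP feather-protein repeat),
   de novo periodicity discovery, and ortholog architecture comparison
   (conserved termini, signed copy-number expansion).
5. **Expression counting** — semiquantitative tissue expression by counting
   reads whose translation contains a 100%-identical match to a protein
   query, normalized against a ubiquitous housekeeping control (ALAS1).
6. **Comparative analysis** — reciprocal-best-hit orthology constrained by
   locus position (shared synteny), per-species gene-family censuses split
   by completeness, and Dollo-parsimony gain/loss histories (single gain,
   unlimited losses; ancestral copy numbers by linear-cost Sankoff, with
   expansion events at a 4-fold change).

Because the real analysis rests on external genome assemblies, the package
ships a **seeded synthetic-locus generator** (`generate_edc_locus()`,
`generate_ortholog_pair()`, `generate_tissue_reads()`) that emulates the
assumed genomic architecture with full ground truth — marker-flanked locus,
SEDC/SFTP gene anatomy, tandem CBP (beta-keratin) cluster, frameshift and
premature-stop pseudogenes, scaffold fragmentation, internal repeat
expansion, and skin-biased reads — so that every stage is testable with no
downloads.

## Worked example

```r
library(edclocus)

cfg  <- synthetic_config(seed = 1)          # 20 SEDC + 2 SFTP + 6 CBP + 4 pseudo
loc  <- generate_edc_locus(cfg)
tr   <- loc$truth

markers <- list(protein_record("S100A12", tr$proteins[["S100A12"]]),
                protein_record("S100A11", tr$proteins[["S100A11"]]))
region  <- find_flanked_region(loc$scaffolds, markers)
preds   <- predict_sedc_genes(region, loc$scaffolds)
evaluate_sedc_predictions(preds, tr)[c("recall", "precision", "exactness")]
#> $recall    [1] 1
#> $precision [1] 1
#> $exactness [1] 0.8846154
```

The printed numbers are gene-level recall and precision of the de novo
predictions against the generator's ground truth, and the fraction of
recovered genes whose coding-span coordinates are base-exact. A full
narrative run of all six stages lives in `analysis/01_simulate.R` …
`analysis/06_compare.R`, writing tables under `results/`; for example the
expression stage prints

```
specificity labels: broad=1, tissue-specific:skin=20, undetected=10
off-skin read count over all predicted EDC genes: 0 (control ALAS1 is 'broad')
```

— the skin-restricted expression of EDC genes with a uniformly expressed
control, reproduced from simulated reads.

## Layout

```
R/                 package implementation (one file per pipeline stage)
src/               C++ alignment core (Gotoh DP + enumeration oracles)
analysis/          numbered narrative drivers for the six stages
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (model, parameters, design choices)
```
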