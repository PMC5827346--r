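---
title: "Methods: annotating and comparing epidermal differentiation complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and comparing epidermal differentiation complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Epidermal Differentiation Complex (EDC) is a gene cluster, conserved
across amniotes and flanked by the *S100A12* and *S100A11* genes, that
encodes the structural proteins of cornifying skin. Its genes are difficult
for generic annotation pipelines: most are "simple EDC" (SEDC) genes whose
entire coding region sits on one short exon of strongly biased amino-acid
composition (glycine-, serine-, proline-, lysine-, cysteine- or
glutamine-rich), preceded by a noncoding first exon, a TATA box and a
single canonical GT..AG intron. Two S100-fused-type (SFTP) genes split
their coding sequence over two exons, a tandem cluster of corneous
beta-proteins (CBPs, beta-keratins) provides a multi-copy family, and
pseudogenized copies with frameshifts or premature stops are interspersed.
`edclocus` implements the specialised procedure such loci require: delimit
the cluster between its S100A markers, search it with exact six-frame
translated alignment, predict SEDC and SFTP models with promoter and splice
evidence, triage gene status, validate expression against tissue RNA-seq by
100%-identity read counting, and compare loci across species (orthology,
family census, Dollo gain/loss).

## The synthetic study system

Real analyses of this kind run on genome assemblies; the package instead
ships a generator whose output *is* the study condition for every test.
`synthetic_config()` defaults describe one locus with 20 SEDC genes, 2 SFTP
genes, a 6-member CBP cluster and 4 pseudogenes between two S100A
stand-ins, plus an ALAS1-like housekeeping gene outside the cluster. Key
geometry (all lengths in nucleotides, sampled uniformly per gene):

| parameter | default | rationale |
|---|---|---|
| coding length | 50–150 codons | EDC proteins are short |
| composition bias | G .14, S .14, P .11, K .09, C .09, Q .08 | biased toward the six EDC-characteristic residues (total 0.65) |
| TATA offset | 25–35 nt upstream of the transcription start | canonical core promoter |
| noncoding exon | 30–80 nt | short 5' exon |
| intron | 80–200 nt, GT..AG | canonical splice dialect only |
| 5'/3' UTR in the coding exon | 3–20 / 30–100 nt | short UTRs |
| intergenic | 300–800 nt | compact cluster |
| reads | 75 nt, error-free; skin 300 / heart 200 / liver 200 | matches the 100%-identity counting rule |

Genes are placed on random strands. Pseudogenes are built from valid genes
by premature stops planted every ~22 codons or by a single-nucleotide
deletion, followed by a deterministic post-check that no ATG-initiated
stop-free run of 40+ codons survives in any sense frame — so a pseudogene
can never be recalled as an intact gene by construction. Ortholog pairs
derive a second locus by per-site substitution with a 2:1 transition bias;
proposals creating a premature stop, or hitting a start/stop codon, splice
dinucleotide or the TATA box, are reverted (purifying selection on
essential signals), so the diverged locus stays annotatable the way real
orthologous loci are. The repeat gene ("EDCRP") carries tandem copies of
the motif `CCDPCQ(K|-)(T|P)(V|-)`; the second species can carry a planted
number of extra units inserted at a codon boundary mid-array.

What the generator does **not** emulate: sequencing error (optional, off by
default), indel divergence between orthologs, non-canonical splice sites,
alternative transcripts, paralogous interleaving of families, and
per-protein concentration of the composition bias in a single residue (real
EDC proteins often exceed 20% in one residue; the generator spreads the
bias over all six, so single-residue enrichment calls are rarer on
synthetic proteins than in real data). Passing tests therefore demonstrate
correctness of the algorithms under the stated architecture, not
performance on real assemblies.

## Alignment core

Protein alignment is exact affine-gap dynamic programming (Gotoh) in C++:
local (Smith–Waterman) and global (Needleman–Wunsch, end gaps penalized).
The default scheme is BLOSUM62 with gap open 11 and extend 1 — a length-k
gap costs `11 + k` — matching the defaults of routine translated searches.
Two local conventions: `X` (unknown/gap-translated codons) scores 0 against
everything, and the translated stop `*` scores −16 so local alignments
never cross a stop. Tie-breaking is deterministic: among equal-scoring
local endpoints, earliest target start, then earliest query start, then
shortest alignment; traceback prefers diagonal continuations. The
translated search aligns the query against all six frame translations with
no low-complexity masking and reports hits in forward-strand nucleotide
coordinates; overlapping copies of tandem families are found by iterated
masking of each best hit (stop-symbol masking, up to `max_hits_per_frame`
rounds). There is no E-value model: hits are thresholded on raw score
(default 40), a deliberate simplification documented here — the procedure
this package reproduces reported hits, not statistics. The test suite
checks both aligners against exhaustive path-enumeration oracles (no
dynamic programming) on all pairs up to length 8, and against an
independent implementation (`Biostrings::pairwiseAlignment`).

## SEDC gene prediction and the start-choice model

Candidates are ATG-initiated, stop-free ORFs of at least `min_codons = 50`
residues in any of the six frames of the delimited region. A candidate is
kept when it overlaps a supplied homology hit or when its fraction of
{G,S,P,K,C,Q} reaches `bias_threshold = 0.5`. Homology hits over runs
without a qualifying ATG yield stop-to-stop candidates, so partial genes at
scaffold edges and pseudogene relics are still reported (and triaged
downstream). Overlapping candidates in different frames are both kept and
flagged, never merged, because real EDC loci contain nested and antisense
gene arrangements.

When several in-frame ATGs could start the same ORF, the chosen start
maximizes a composition changepoint score: each residue contributes
`log(p1/p0)` if it is one of the six EDC residues and `log((1-p1)/(1-p0))`
otherwise, with `p1 = coding_bias = 0.6` (the expected biased fraction of
EDC coding sequence) and `p0 = 20/61` (the chance rate over the sense
codons); methionine is scored 0 because every candidate start is an M and
internal M content carries no signal. The score of a start is the summed
weight of its suffix, plus a bonus of 3 (log-likelihood units) when the
start has full promoter evidence — an acceptor AG within `utr_window = 25`
nt, a GT donor giving an intron of 70–250 nt, and a TATAWA motif 45–135 nt
upstream of the donor (a core promoter plus one short noncoding exon; the
motif and the 250-nt promoter scan window follow the canonical TATA-box
description, the distance band is this package's choice). Ties go to the
most upstream ATG. The 5' noncoding exon is attached to the model only when
both TATA and splice evidence exist; its 5' boundary is an estimate (the
transcription start is not recoverable from sequence alone), so only the
coding span is held to base precision. Residual start errors of one to a
few codons remain when a neighbouring in-frame ATG is separated from the
true start by residues whose composition happens to mimic the other class;
on default synthetic loci this leaves roughly 8% of recovered genes with a
shifted start, which is the exactness level the acceptance suite measures
(recall and precision stay near 1).

SFTP models are assembled from translated-search hits of an SFTP query: the
hit reaching the query N-terminus anchors the ATG, the hit reaching the
C-terminus anchors the stop, and all codon-boundary GT donors with an AG
acceptor at an allowed intron distance are enumerated; the stop-free
in-frame join that best matches the query wins, and joins whose only
canonical solutions contain internal stops are demoted to pseudogene
candidates. The generator plants SFTP introns at codon boundaries (phase
0), and the assembler searches codon-boundary donors accordingly — a
documented simplification of real phase-mixed splicing.

`classify_gene_status()` is total over predictions: internal stop or
missing ATG means pseudogene, a coding span abutting a scaffold end (within
2 nt) or overlapping a 5+ nt N run means partial, gross truncation relative
to supplied intact family members (under half the median length) also means
pseudogene; everything else is complete. Pseudogenes are retained but
flagged for exclusion from protein-level analyses. Each prediction carries
a tiered confidence label (homology / composition-only, with read support
recorded separately) rather than a hard accept/reject rule, since the
original procedure's final acceptance rule is not recoverable.

`validate_with_reads()` counts reads matching the prediction exactly. The
predicted transcript ends are approximate, so matching runs against the
genomic window extended by `validation_flank = 250` nt; reads that fail the
unspliced window are retried across candidate GT..AG junctions consistent
with the model's coding start (this is what "validated by intron-spanning
reads" means operationally), and those spanning a junction with at least
`min_overhang = 5` nt on each side are counted as intron-spanning.

## Expression counting

A read counts for a protein query when one of its six frame translations
contains a stop- and X-free run of at least `min_match` residues occurring
verbatim in the query. The default is `floor((read_length - 2)/3)` — the
full translatable length guaranteed in every frame — i.e. effectively
full-read identity at the protein level; a read is counted at most once per
query. Counts are normalized per tissue by the ALAS1-like control (not by
library size, following the control-based design of the semiquantitative
procedure): a gene is `tissue-specific:<t>` when ≥ 90% of its normalized
signal falls in one tissue, `undetected` below 5 raw reads, else `broad`.
A control with zero counts in any tissue is an error, because the
normalization is then undefined.

## Repeat profiling

The motif grammar transcribes the field's notation: fixed residues,
alternation sets `( | )`, and `-` inside a set for an optional position; a
pattern needs at least 3 non-optional positions. Copies may deviate at up
to `max_mismatch = 1` non-optional positions (matching the described
C-terminal variability of the avian repeat) and consecutive copies may be
separated by up to `max_spacer = 2` residues — the package's explicit proxy
for how interrupted arrays count toward a copy total. The maximal tandem
array is found by dynamic programming over single-copy matches; ties on
copy count prefer fewer deviations, then longer copies, then the leftmost
start. De novo discovery self-compares the protein at each unit length,
segments positions whose residue matches the residue one unit downstream at
periodic identity ≥ 0.7, trims edge copies that deviate from the
majority-rule consensus by more than the allowed fraction (the periodicity
run can leak into flanking sequence by chance), and resolves overlapping
unit lengths by maximal copy count then smallest unit. `min_unit` may be as
small as 2 so that simple dipeptide repeats (e.g. GS-rich) are reportable.
Ortholog architecture comparison counts pattern copies in both proteins and
globally aligns the regions outside the detected spans (halves, when a
protein has no array), reporting the mean terminal identity and the signed
expansion.

## Comparative analyses

Orthology requires reciprocal best global-alignment scores *and* locus
ranks within `max_rank_delta = 3`, because a tandem array of similar
paralogs confounds sequence-only assignment — synteny is part of the call.
Family censuses split complete/partial/pseudogene counts per species;
unassignable genes go to an explicit `unclassified` family, and assignment
scores are reported so borderline calls can be audited. Dollo histories
place one gain on the stem of the smallest clade containing every species
with an intact or partial copy and one loss on the stem of each maximal
copy-free subclade inside it; ancestral copy numbers minimize the total
absolute count change along the tree (linear-cost Sankoff over the observed
count range — no duplication/loss rate model is fitted, matching the purely
schematic treatment of family-size evolution this package reproduces), and
a ≥ 4-fold parent-to-child change emits an expansion or contraction event
(the 4-fold default mirrors the crocodilian-vs-bird EDCH contrast). The
test suite checks the Dollo reconstruction against exhaustive
minimal-change enumeration over every presence pattern on 4–6 tip trees.

## Problem sizes and numerical choices

The default test and acceptance runs use 20-seed sweeps of the default
locus (~45 kb, 33 genes), 20 ortholog pairs at 0.1 substitutions/site for
orthology recovery, planted expansions up to 50 extra units, 200-pair
alignment oracles at length ≤ 8, and 200 repeat-decomposition oracles at
length ≤ 60 — sizes chosen so the entire suite completes in a few minutes
while keeping binomial sampling error on the recovery rates near one
percentage point. All randomness flows from a single integer seed;
identical seeds give byte-identical loci, reads and results. Degenerate
inputs are rejected early with informative errors (empty sequences,
non-DNA characters, min_score < 1, divergence outside [0, 0.5], malformed
FASTA/FASTQ/GFF3 with the offending line number). Internal coordinates are
0-based half-open everywhere; emitted GFF3 is 1-based inclusive per the
standard.

## Known limitations

* The start-choice changepoint cannot resolve in-frame ATGs separated by
  compositionally ambiguous spans of a few codons (~8% of synthetic genes);
  homology to a known family member resolves these in practice.
* The 3' end of the transcript is not modelled (no polyadenylation
  signal); only coding spans are held to base precision.
* No E-value calibration: raw-score thresholds must be chosen relative to
  target size (the chance-hit score grows with search space).
* The expression counter is protein-level and strand-aware; it does not
  align reads to the genome and cannot separate identical paralogs.
* Dollo parsimony assumes the family was gained once; horizontal reuse or
  convergent emergence would be misassigned by construction.
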