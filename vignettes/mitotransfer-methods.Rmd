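---
title: "Inferring the fate of plant mitochondrial genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the fate of plant mitochondrial genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotransfer)
```

## The inference problem

Plant mitochondrial genomes lose protein-coding genes over evolutionary
time, and many of the "missing" genes are not gone: they have been
functionally transferred to the nuclear genome.  Because plant
mitogenomes are multipartite and hard to assemble, the practical evidence
for a transfer is indirect.  This package implements the full inference
chain on draft assemblies and paired DNA/cDNA sequence sets:

1. **Copy-number evidence.**  Organellar DNA is present at many copies
   per cell, single-copy nuclear DNA at two.  A gene still encoded in the
   mitogenome therefore shows shotgun read depth near an organellar
   control gene (a *nad2*/*nad5* analog), while a transferred gene shows
   depth near a single-copy nuclear control (a *LEAFY* analog).
2. **Retroprocessing signatures.**  Plant mitochondrial transcripts are
   C-to-U edited and many genes carry group-II introns, some spliced in
   *trans* across separate molecules.  A gene that reached the nucleus
   through a processed mRNA intermediate (retroprocessing followed by
   DNA-mediated integration) carries neither signature: its editing
   positions are hardened to genomic T and its mitochondrial introns are
   absent, often with a novel N-terminal presequence extension.
3. **Ancestral event reconstruction.**  Given per-species states, the
   history of transfer and loss events is reconstructed on a fixed
   species tree.
4. **Retention correlates.**  Across genes, the number of species that
   retain the mitochondrial copy is regressed on gene length, GC content,
   GRAVY hydropathy and substitution rates.

Each gene in each species is assigned one of four states: `M`
(mitochondrion-encoded), `T` (transferred to the nucleus), `L` (lost from
both compartments), or `U` (unknown).  `U` is a deliberate output state:
ambiguous evidence — for example a fast-evolving gene whose depth falls
between the two control bands — is reported as unknown rather than forced
into a call.

## State classification from k-mer depth

`find_homologs()` locates each panel gene on the scaffolds by a
nucleotide seed–chain–extend search: exact 15-mer seeds are grouped by
alignment diagonal, extended without gaps, and chained colinearly per
scaffold and strand.  Chain identity is computed over aligned columns;
stretches of isolated substitutions on the same diagonal count as aligned
mismatches, whereas diagonal jumps (intron insertions) contribute no
columns.  Hits on multiple scaffolds are all retained, which is what
makes trans-spliced genes detectable.  Tabular hit sets from an external
search engine can be substituted for the internal search on real data.

`kmer_depth()` estimates coverage as the mean multiplicity, in the read
multiset, of the region's positional k-mers (default `k = 31`).  This is
deterministic and invariant to read order and naming.

`classify_state()` applies explicit depth-ratio bands:

* `M` when `depth / control_mito` lies in `[0.5, 2]`;
* `T` when `depth / control_nuc` lies in `[0.5, 2]` **and**
  `depth / control_mito < 0.25`;
* `L` when the gene is absent from both the DNA and the cDNA sets;
* `U` otherwise.

Real studies state only qualitative depth equality with the nuclear
control, so the numeric bands are package choices, exposed in
`depth_thresholds()`.  The defaults separate the tiers comfortably for
organelle-to-nuclear copy-number ratios of 8 or more, which is the
contrast the classifier is designed for; with ratios near 2 the bands
overlap and genes fall into `U`.

## Editing sites and gene structure

`call_editing()` compares the intron-excised genomic CDS with its cDNA:
DNA `C` / cDNA `T` is a C-to-U site, DNA `T` / cDNA `C` the rare reverse
direction, and *any other mismatch is a discordance, never an edit* — a
guard against substitution noise.  `compare_to_reference()` reproduces
the three-class site comparison for transferred genes (`edited`,
`converted_C_to_T`, `unedited_C`, with `other` for gaps), using global
alignment with match 1, mismatch −1, gap open 5, gap extend 1.

`map_exons()` chains the cDNA onto the scaffolds left-to-right.  Each
exon is seeded with a 20-nt probe tolerating up to 2 mismatches and
extended by an X-drop scheme (match +1, mismatch −8, drop 40); the exon
ends at the earliest maximum of the cumulative score.  The asymmetric
penalty makes isolated mismatches — RNA-edited positions seen against the
cDNA — cheap to cross, while the ~75% mismatch density beyond an intron
boundary terminates the exon at the boundary itself.  `infer_introns()`
then labels each inter-exon junction: *cis* when the flanking exons are
colinear on one scaffold and strand (gap = intron length), *trans*
otherwise, with trans intron lengths reported as unknown rather than
estimated.  Insertion points are 1-based nucleotide offsets in the CDS,
so intron names follow the `geneID + "i" + offset` convention (e.g.
`nad2i542`, phase `542 mod 3 = 2`), and phases are insertion points mod
3 by construction.  Genes with less than 90% of their cDNA placeable get
a structural-failure flag and are excluded from intron statistics —
real-data ambiguity maps to the flag, not to a forced call.

`detect_presequence()` measures the 5' extension of a transferred gene
upstream of the aligned homolog start.  Alignment identity is counted
over all alignment columns including gaps, and alignments under 0.4 are
refused; this metric is deliberately conservative, since identity over
matched columns only can be gamed by gap placement between unrelated
sequences.

## Sequence statistics and substitution rates

GC content is reported overall and per codon position, with `N` bases
excluded from numerator and denominator.  GRAVY is the mean
Kyte–Doolittle hydropathy of the translation (the scale is embedded as
the exported constant `KYTE_DOOLITTLE`).

Pairwise dN/dS uses the Nei–Gojobori (1986) mutation-fate method with
equal pathway weighting rather than maximum-likelihood codon models.
This is a deliberate design decision: the estimator is deterministic,
verifiable by hand enumeration (the package's test suite checks it
against an independent brute-force pathway enumerator), dependency-free,
and adequate for the rank comparisons the analysis makes.  Site counts
treat mutations to stop codons as nonsynonymous (sites per codon sum
to 3); pathways through stop codons are excluded from difference
averaging when an alternative pathway exists.  Proportions are
Jukes–Cantor corrected, `d = −3/4 ln(1 − 4p/3)`; `p ≥ 3/4` lies outside
the correction's domain and is reported as saturated (`NA`) rather than
clamped.  Absolute per-branch rates divide dN and dS by user-supplied
divergence times (Myr); no times are hard-coded because published
analyses source them from prior studies and public time trees.

## Ancestral reconstruction

`sankoff_reconstruct()` minimises total transition cost per gene by
dynamic programming with backtrace.  The default cost model prices
transfer (M→T) and loss (M→L, T→L) at 1 and blocks reversals with
infinity: a lineage never regains a lost or transferred mitochondrial
copy.  Irreversibility is a modelling choice grounded in the biology of
the system (reacquisition of an organellar copy after functional
transfer has no documented mechanism at these time scales); the cost
matrix is user-configurable for sensitivity analysis.  Cost ties are
broken by the fixed priority M > T > L, which biases toward ancestral
retention and is therefore conservative with respect to inferring
transfer; the priority is an argument and can be overridden.  Tips
observed as `U` are uninformative for that gene (flat zero cost) and
never generate events.

`gymnosperm_fixture()` packages a 19-genus tree covering all 13
gymnosperm families under the Gnepine topology, the 41-gene ancestral
seed-plant panel, and the curated transfer/loss event table of the
gymnosperm radiation.  Replaying the table with `apply_events()` gives
the published gene-content accounting (41 genes in cycads, *Ginkgo* and
Pinaceae; 32 universally retained across Conifer II; 29 in *Gnetum* and
*Welwitschia*; 22 in *Ephedra*), and reconstruction from the replayed
tips recovers exactly the curated branch events — the fixture is
parsimony-identifiable.  The six *Ephedra* absences are annotated
`putative` (fast-evolving undetected nuclear copies cannot be excluded);
the annotation travels with the events and does not alter states.

## The synthetic-evolution generator

`simulate_dataset()` provides ground truth for every downstream stage.
Its defaults define the study conditions used throughout the tests:

* a balanced 8-species tree and a 40-gene panel drawn from the ancestral
  41-gene set;
* per-branch per-gene event probabilities `p_transfer = 0.04`,
  `p_loss_M = 0.02`, `p_loss_T = 0.02` — chosen so that a typical run
  contains a few dozen transfers and losses while most genes stay `M`,
  mirroring the dominance of retention over turnover in real panels;
* 3 editing sites per 100 codons and 0.7 introns per gene (20% trans),
  within the ranges seen in seed-plant mitochondrial genes;
* mitochondrial depth 100×, nuclear depth 10× — a 10-fold copy-number
  contrast, comfortably above the ≥8-fold regime the classifier
  targets — with 100-bp error-free reads;
* substitution and read-error rates of 0 (the noiseless baseline; both
  are knobs for robustness experiments).

Transferred genes are written to the nuclear scaffold retroprocessed:
editing sites hardened to `T`, mitochondrial introns absent, and a
random presequence extension of 60–150 nt prepended with probability
0.5 (deliberately not always a multiple of 3, so both in-frame and
out-of-frame extensions occur downstream).  Trans introns are realised
by splitting a gene across two mitochondrial scaffolds; about a quarter
of gene fragments are placed reverse-complemented.

All randomness flows from one integer seed; the stages draw from fixed
derived streams (`seed`, `seed+1`, `seed+2`, `seed+3`), so each
operation is independently reproducible and a full run is
bit-reproducible.  One uniform draw is consumed per branch × gene pair
regardless of state, which makes the event stream replayable by
inspection.

Three generator details exist purely to make exact recovery a
well-posed test, and are worth knowing about when interpreting results:
the first base of every planted intron differs from the cDNA base
following the insertion point; editing sites sit at least 12 nt from CDS
ends and intron boundaries and at least 18 nt apart; and trans-split
fragments carry a one-base guard against chance extension into flanking
spacer.  Without these margins, a boundary placed by any left-greedy
chaining algorithm is ambiguous at a rate of roughly one in four introns
— the ambiguity is intrinsic to the data, not to the algorithm.  Real
data carry exactly this ambiguity, so on real assemblies intron
positions should be read as exact only up to such boundary ties.

What the generator does **not** emulate: structural recombination and
repeat content of real plant mitogenomes, indels, sequencing-quality
models, partial editing (sites edited in a fraction of transcripts),
nuclear paralogs, and contamination.  Passing the recovery suite
therefore demonstrates correctness of the inference logic under clean
copy-number and signature contrasts, not robustness to every real-data
artefact; the explicit `U` state and the structural-failure flag are the
designed escape hatches for that messiness.

## Pipeline orchestration

`run_pipeline()` chains simulate → classify → structure → editing →
stats → ancestral → retention.  Structure runs before editing because
editing calls need the intron-excised genomic CDS that exon mapping
produces.  Every output is TSV plus a JSON report carrying md5 content
hashes of all artefacts; identical configs and seeds give bit-identical
reports, and a rerun against an unchanged config is skipped unless
forced.  Retention fits are simple per-predictor OLS (no
multiple-testing adjustment, matching how such correlates are usually
presented); a caveat is emitted when predictors are mutually correlated,
and predictors that are degenerate in a run — e.g. dN/dS on noiseless
data, where every pairwise distance is 0 — are skipped with a note.

## Problem sizes and runtime

The shipped tests run the full recovery experiment at the default study
conditions (8 species × 40 genes, ≈230,000 reads, ≈260 kb of scaffold)
in about a minute on one core, plus a smaller 4 × 10 configuration for
the per-module tests; the Sankoff oracle suite checks 1,000 random
instances on trees of 3–6 tips against exhaustive enumeration.  These
sizes were chosen so the whole suite completes in a few minutes while
still exercising every code path (trans introns on reverse strands,
presequences, multi-fragment genes, saturated distances).

## Known limitations

* The homolog search is ungapped within chains; genuine indel-rich
  divergence between query and target will fragment hits.  At the
  identity levels the search targets (≥0.9 by default) this is
  immaterial, but real cross-genus searches should lower `min_identity`
  or supply external hit tables.
* Depth classification assumes controls behave: a mitochondrial control
  that was itself transferred, or a nuclear control inside a recent
  segmental duplication, shifts both bands.
* The Nei–Gojobori estimator is biased at high divergence relative to
  ML codon models; it is used for rank comparisons, not for absolute
  rate estimation.
* Reconstruction assumes the species tree; it does not average over
  topological uncertainty, and the irreversibility assumption makes
  `T` and `L` absorbing.
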