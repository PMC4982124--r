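---
title: "Methods: identifying and annotating LRR-RLK gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and annotating LRR-RLK gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(familyscope)
```

## The problem

Plant genomes encode hundreds of receptor-like kinases (RLKs):
single-pass transmembrane proteins with an extracellular domain, a
transmembrane (TM) helix and a cytoplasmic Ser/Thr kinase domain (KD).
The leucine-rich-repeat subfamily (LRR-RLK) is the largest and contains
many immunity receptors; its subfamily XII in particular holds
pattern-recognition receptors of the FLS2/EFR/XA21 type. A recurring
comparative-genomics task is: given predicted proteomes and genomes of
two related species plus a well-annotated reference (the *Arabidopsis*
role), identify all LRR-RLKs, classify them into the canonical subfamily
groups I–XVI, characterise their catalytic loops (RD vs non-RD), and
describe their genomic arrangement — tandem clusters, orthologs and
syntenic blocks.

`familyscope` implements that workflow as a reusable, fully tested
pipeline, together with a synthetic two-species genome simulator that
plants every structure the pipeline is supposed to find, so that every
stage can be validated against a machine-readable truth table.

## Domain-based classification

Classification is annotation-driven: the pipeline consumes one
tab-separated table of domain hits per proteome (protein id, accession,
1-based start/end in protein coordinates), the dialect produced by
InterProScan-style annotators. Kinase domains are recognised by the Pfam
accessions PF00069 (Pkinase) and PF07714 (Pkinase_Tyr), LRRs by eleven
Pfam accessions (PF00560, PF01462, PF01816, PF08263, PF12799, PF13306,
PF13855, PF14580, PF01463, PF07723, PF07725), and TM helices by the
reserved accession `TMHELIX`, which stands in for a TM predictor's
output in the same table. The tiers nest: a protein is a *kinase* if it
has a KD, a *TM kinase* if it also has a TM helix (receptor-like
cytoplasmic kinases fail here), and an *LRR-RLK* if it additionally
carries at least one LRR. Alternative splice variants are excluded
first: one primary transcript is kept per gene (the longest, with a
warning, if no primary flag is present). We do no topology reasoning: a
protein whose only TM call overlaps the KD still counts as a TM kinase,
because the annotation table carries no orientation information.

Some proteins carry more than one raw KD hit — either one domain
annotated as two truncated fragments, or a genuine tandem-kinase
architecture. Where the original analyses resolved these by hand, we fix
an automatic rule: consecutive hits are merged into one unit iff the gap
between them is ≤ 100 aa *and* the merged span is ≤ 450 aa. A typical
protein kinase domain is ~250–300 aa; 450 aa bounds a merged unit below
about 1.5× that, so truncated fragments merge while tandem domains stay
separate. Both thresholds are exposed as parameters.

## Alignment and filtering

Kinase-domain sequences are aligned with an in-package progressive
aligner: a guide tree from fractional common 3-mer distances
(average-linkage clustering) and profile–profile merges by global
dynamic programming with affine gaps (BLOSUM62; a gap run of length
*L* costs `gap_open + L * gap_extend`, defaults −10/−1). The aligner is
deliberately simple and deterministic; a pre-computed alignment from an
external aligner can be supplied instead through `read_alignment()`.

Three filters reproduce the usual pre-phylogeny cleanup:

* sequences shorter than 100 aa (strict) are dropped;
* alignment columns whose gap fraction exceeds 0.9 are trimmed (a fixed
  threshold in place of slope-based heuristics; the contract is "remove
  gap-rich columns" and the threshold is configurable);
* redundancy is reduced with the classic two-sided rule — pairs above
  99 % identity keep the longer member (ties keep the lexicographically
  smaller id), then sequences below 30 % identity to everything kept are
  discarded as unrelated. Identity is computed over global pairwise
  alignment columns excluding terminal gaps, since the historical tool
  does not document its exact metric.

## Phylogeny and subfamily assignment

Distances are Poisson-corrected p-distances over shared non-gap columns
(`d = −ln(1 − p)`, saturated pairs capped at a configurable maximum with
a warning). Trees are built with neighbor joining, with two defined
tie-breaks: equal Q-criterion entries resolve to the lexicographically
smallest id pair, and negative branch lengths are clamped to zero with
the deficit moved to the sister edge. Edge support is nonparametric
bootstrap over alignment columns: the fraction of replicate NJ trees
containing the same bipartition, deterministic given a seed. This
distance-based stand-in replaces full maximum-likelihood inference with
model selection; it is dependency-free, fast at desk scale, and
sufficient to exercise the clade-based classification logic, which is
the scientific point. An externally estimated tree (Newick with support
node labels) can be substituted anywhere a tree is consumed.

Subfamily groups are assigned by co-clustering with labelled reference
sequences: a query tip receives the label of the *smallest* clade
containing it whose defining edge has support strictly above 0.70 and
whose reference tips all carry one label. Tips in no such clade —
including tips falling between two differently labelled reference
clades — are reported `unassigned` rather than guessed. Reference tips
never change label. Rooting uses a divergent outgroup kinase family; if
the outgroup tips are not monophyletic on the unrooted topology the
first outgroup tip serves as the root. Group XII is split into XIIa and
XIIb by the same homogeneity rule restricted to the XIIa/XIIb exemplars
(the reference ships two XIIb exemplars, mirroring the classic
two-sequence XIIb clade); if no XIIb exemplar is present, XII tips fall
back to XIIa with a warning.

## Catalytic-loop classes

The kinase catalytic loop carries the conserved His-Arg-Asp (HRD)
tripeptide; kinases lacking the arginine ("non-RD") are enriched among
pattern-recognition receptors, and usually carry C or G (rarely S or
other residues) in its place. Because the target motif is known a
priori, de-novo motif discovery is unnecessary: the loop is located on a
reference row containing a literal HRD run and its three columns are
projected onto every row. Classification is then: catalytic D present
and R present → RD; D present, R replaced → non-RD (the substituting
residue is recorded; a gap at the R position counts as absence of R and
is flagged separately); catalytic D absent → ACF (alternative catalytic
function, a degenerate loop). The three classes partition the input by
construction. Note the residue letter is reported as-is: the historical
literature is ambiguous between tyrosine (Y) and tryptophan (W) for one
rare substitution, so neither reading is privileged.

## Genomic arrangement

Family genes are mapped onto chromosomes from the GFF3. Clusters chain
genes per chromosome by single linkage where the gap to the next gene
(next start − previous end) is at most 200 kb; the window and the
measure (gap vs start-to-start) are parameters, with the gap chosen as
default because it is robust to gene length. Tandem duplicated paralogs
are operationalised as genes that co-occur in one cluster *and* share a
well-supported clade — the only distance the source analyses quantify is
the 200 kb rule, so proximity is cluster co-membership. A gene joins at
most one tandem set; larger clades win, ties go to higher support. A
deterministic text chromosome map (machine-parseable, with a parser
provided) stands in for graphical chromosome drawings.

## Orthologs and synteny

Cross-species ortholog candidates are bidirectional best hits (BBH):
all-vs-all Smith–Waterman local alignment (BLOSUM62, affine gaps, an
optional shared-k-mer prefilter for speed), subjects ranked per query by
score with ties broken by identity then id, and a pair emitted iff each
member is the other's rank-1 hit. Exact local DP replaces heuristic
search because desk-scale corpora (hundreds of proteins) do not need
heuristics. Pairs are then confirmed on a joint two-species tree: a pair
is clade-confirmed iff both members co-occur in a well-supported clade.
No redundancy reduction is applied to the joint tree, because at low
divergence true orthologs can exceed the identity cap and both members
must stay on the tree to be confirmable.

Syntenic blocks are found by exact-anchor chaining: maximal exact shared
k-mer runs (k = 21, both strands, only k-mers unique within each
sequence — repetitive seeds carry no collinearity information) are
chained greedily when collinear and within 5 kb on both sequences, and
chains spanning less than 1,000 bp are discarded — the floor is the one
parameter the workflow tradition fixes. This replaces de Bruijn-graph
block decomposition with a transparent, testable primitive; anchor k and
the chain gap are exposed.

## The synthetic-data generator

`simulate_rlk_dataset()` builds two related species (genome FASTA, GFF3,
proteome FASTA, domain TSV) plus a labelled reference proteome and a
truth table. Its design choices:

* **Shared KD scaffold.** All kinase domains descend from one random
  280-aa scaffold with the HRD loop planted at a fixed site; each family
  diverges from it at 30 % per residue (outgroup: 45 %), each member
  ancestor from its family at the `paralog_divergence` nucleotide rate
  (default 0.08), and each species copy from its member ancestor at
  `mutation_rate`. This mirrors the real situation — kinase domains are
  homologous and alignable across families, families are well separated,
  orthologs are closer than paralogs.
* **Single-exon genes.** Proteins are exact translations of single-exon
  CDS planted in random chromosome backgrounds (one representative codon
  per amino acid; mutations creating internal stop codons revert to the
  ancestor codon; motif and domain-boundary codons are shielded).
  Splicing is irrelevant to every stage under test, so intron structure
  is deliberately absent.
* **Planted structures.** Tandem families are placed as adjacent genes
  with 20–80 kb neighbour gaps (inside the 200 kb window); all other
  placement units are separated by >200 kb so the planted arrays are
  exactly the detectable clusters. A configurable fraction of genes
  emits a truncated alternative transcript flagged `primary=false`, so
  the splice-variant filter has work to do. A fraction of families has
  the KD annotated as two truncated hits 10 aa apart, exercising the
  merge rule. Intergenic segments copied between the genomes plant
  syntenic blocks. Decoy kinase-only and TM-kinase-only genes populate
  the lower funnel tiers.
* **Determinism.** One seed drives everything; the same configuration
  and seed reproduce byte-identical files.

What the generator does *not* emulate: realistic codon usage, indels,
rate heterogeneity across sites, gene conversion, or annotation noise
(missing/spurious domain calls). Passing tests therefore demonstrate the
correctness of the pipeline's logic and its behaviour under substitution
noise — not robustness to annotation error on real proteomes, which is a
property of the upstream annotator.

## Numerical and engineering choices

* Probabilities in generator configurations must sum to 1 within 1e-9;
  mutation rates are limited to [0, 0.5].
* Distance saturation (p ≥ 1) caps at `d_max` (default 10) with a
  warning; a pair sharing zero non-gap columns is an error naming the
  pair.
* Bootstrap replicates whose distance matrix degenerates are dropped
  from the support denominator (they essentially never occur on KD-dense
  alignments).
* All orderings (hit ranking, NJ tie-breaks, cluster and tandem-set
  construction, table rendering) are deterministic, so a full pipeline
  rerun with the same seed is byte-identical, including the JSON run
  report.
* Problem sizes used in the test-suite and in `scripts/acceptance.R`
  are desk-scale by choice: 16–25 families, two species, chromosomes of
  ~2 Mb, 25–50 bootstrap replicates. These are large enough to exercise
  every code path and small enough to iterate on quickly.

## Known limitations

* NJ with Poisson correction is a stand-in for model-based inference;
  support values are bootstrap proportions, not likelihood-ratio
  supports. Both are swappable via the external-tree entry point.
* The borderline-TM problem (a known family member whose TM helix the
  predictor misses) is left to the annotation producer: classification
  is strictly annotation-driven.
* Queries between two differently labelled reference clades are
  `unassigned` by design; no nearest-neighbour guessing is performed.
* The synteny scan reports per-chromosome-pair blocks; it does not
  attempt whole-genome collinearity chains across chromosomes or
  rearrangement inference.
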