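---
title: "Methods: detecting and classifying A-to-I mRNA editing landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and classifying A-to-I mRNA editing landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscape)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded mRNA.
Sequencers and ribosomes read inosine as guanosine, so editing appears as
an A→G mismatch between a transcriptome and the genome of the same
individual. Coleoid cephalopods (squid, cuttlefish, octopus) recode their
neural proteomes this way at a scale seen nowhere else, which makes the
genome-wide *editing landscape* — where sites are, how strongly each tissue
edits them, which ones recode proteins, and how recently they arose — a
primary object of study.

`editscape` implements the landscape analysis downstream of read alignment
and variant calling. Its inputs are per-site, per-sample allele-depth
tables (how many reads support the unedited A state and the edited G
state), the same individual's genomic genotypes, gene models, and optional
repeat/domain tracks and outgroup genotypes. Everything upstream — mapping,
duplicate marking, pileup — is deliberately out of scope; any caller that
produces allele depths can feed the pipeline.

## Edit frequencies and candidate sites

The edit frequency of a site in a sample is the fraction of reads
supporting the edited state,

$$ f = \frac{\#G}{\#A + \#G}, $$

computed on the *transcribed strand*: for genes on the minus strand the
genomic signature is T→C, and the readers re-orient it before anything
else happens. When a site has no coverage in a sample, $f$ is missing, not
zero — absence of data must never masquerade as absence of editing.

A site is a **candidate edit site** when three things hold:

1. the same-individual genomic genotype is homozygous A on the transcribed
   strand — heterozygous A/G polymorphisms produce a spurious 50% "editing"
   signal in RNA and are excluded, with the reason recorded;
2. some sample has $f$ strictly above 0.1% (`min_site_freq = 0.001`);
3. some sample carries at least one edited read.

The 0.1% filter is applied per sample ("any sample exceeds") rather than to
pooled counts; this is the weakest reading of the rule and it is a plain
argument, so a stricter pooled variant costs one line. Sites outside
annotated genes are retained with strand taken from the record orientation
and flagged low-confidence.

## Pooling, robustness and the (WN, WNN) plane

Tissues are partitioned by a panel file into `neural`, `non_neural`,
`mixed` and `excluded` groups. The **weighted neural** and **weighted
non-neural** frequencies of a site pool the raw reads,

$$ WN = \frac{\sum_{s \in \text{neural}} g_s}
             {\sum_{s \in \text{neural}} (a_s + g_s)}, $$

and likewise $WNN$ over non-neural samples. Pooling reads — not averaging
ratios — weights each sample by its depth, so a deeply covered sample
dominates a shallow one. Mixed tissues (in the squid study, retina and the
axial nerve cord, whose composition straddles the neural/non-neural
boundary) are excluded from both pools; they still count toward the robust
flag below, which quantifies over *all* reference-individual samples.

A site is **robust** when some sample has $f > 0.25$, strictly: a site at
exactly 25% is not robust. A site is classified only when its cumulative
pooled depth (neural + non-neural reads) reaches 10; below that it is
`unclassified` and reported separately.

Classification assigns one of five classes from the position of
$(WN, WNN)$ in the unit square:

| class       | region                                        |
|-------------|-----------------------------------------------|
| `neural`    | $WN / WNN > 2.75$                             |
| `ubiq_high` | $WN > 0.60$ and $WNN > 0.40$                  |
| `ubiq_low`  | $WN < 0.05$ and $WNN < 0.05$                  |
| `ubiq_med`  | $0.05 \le WN \le 0.40$ and $0.05 \le WNN \le 0.60$ |
| `other`     | none of the above                             |

$WNN = 0$ with $WN > 0$ counts as an infinite ratio (neural);
$WN = WNN = 0$ does not — such sites belong to the low-frequency band.
The `neural` and `ubiq_high` regions are provably disjoint: both firing
would force $WN > 2.75 \times 0.40 = 1.1 > 1$. The test suite verifies
this analytically-motivated fact on a dense grid, and checks the whole
classifier against an independent brute-force enumeration of the region
predicates.

### Precedence at low frequencies

The regions overlap near the origin: a site with $WN = 0.03$,
$WNN = 0.008$ is inside the `ubiq_low` box *and* has a ratio above 2.75.
Published descriptions of this scheme do not resolve the overlap, so the
order in which predicates are tested is a design choice, exposed as the
`precedence` argument of `edit_thresholds()`.

The package defaults to testing `ubiq_low` before the neural ratio, for a
statistical reason: the ratio of two near-zero pooled frequencies is
dominated by sampling noise. Under the package's own generative model
(Beta-distributed true frequencies with concentration 30, negative-binomial
depth with mean 50, ten samples per group), a Monte Carlo of 20,000
low-frequency ubiquitous sites showed that testing the ratio first
mislabels about 13% of them as neural — the two pooled frequencies sit
near 0.02 with standard errors near 0.01, so their ratio crosses 2.75
freely — while testing the low box first recovers over 97% of every class
and costs genuinely neural sites nothing (their $WN \approx 0.4$ never
falls below 5%). The figure-level description, which colours the sub-5%
region as Ubiquitous Low, is consistent with this order. Users who want
ratio-first behaviour pass
`precedence = c("neural", "ubiq_high", "ubiq_low", "ubiq_med")`; the
classifier-versus-oracle test runs under both orders.

## Annotation

Gene models are read from GFF3; one **primary transcript** per gene — the
longest isoform by summed exon length, ties broken lexicographically by
transcript identifier — is used throughout, so every site has a single,
deterministic consequence. Features are assigned by position: splice
junction (the two intronic bases at each intron end plus one terminal
exonic base, both window sizes configurable), then CDS, then 5′/3′ UTR by
transcript coordinate, then intron, else intergenic. A site inside a gene
is only annotated against transcripts on its own strand.

CDS sites are translated: the codon is read on the coding strand, the A→G
substitution applied at the edited position, and both codons translated
with the standard genetic code. `recoding` means the amino acid changes
(this includes stop-codon loss, TGA→TGG); `synonymous` means it does not,
and a property test re-translates every synonymous site to prove it. Each
coding change carries its BLOSUM62 score, from the standard matrix
embedded as a constant, as a measure of how conservative the substitution
is.

Repeat intervals are intersected in genomic coordinates with half-open BED
semantics; protein-domain and transmembrane intervals are given in protein
coordinates (half-open `[start_aa, end_aa)`) and mapped through the codon
index of each coding site. The **editable-adenosine background** counts,
per feature, transcribed-strand adenosines with pooled depth strictly
above 10 and no edited read at all; per-feature enrichment is the ratio of
the edited fraction to this background fraction, undefined (missing) where
a feature has no editable adenosine.

## Conservation against outgroups

To ask whether an edited adenosine is old or new, each site is compared
with the genomic genotype of outgroup species at the orthologous position
(an explicit coordinate map, identity by default, which represents the
congeneric case where outgroup reads are mapped directly to the focal
genome). A call is trusted only when mapping quality is at least 20, depth
lies within the species' expected CDS coverage window (mean ± 2 SD,
floored at one read) and reaches a configurable minimum (default 5), and
the genotype is homozygous. A trusted homozygous A is `conserved_A`; a
trusted homozygous non-A is `derived_in_focal`. A site counts as a **new
edit** only when *every* outgroup yields `derived_in_focal`; a `no_call`
anywhere withholds the flag — the conservative reading of an ambiguous
case. Tallies are reported by class and for the recoding subset.

## Reporting

`tabulate_sites()` cross-tabulates classified genic sites by robustness
block, class and feature, and computes every marginal by summation;
the marginal identities (row totals sum to block totals, blocks to the
grand total) are asserted on every run. Unclassified sites are excluded
from the blocks and counted separately; classified sites without a genic
feature go to a logged `unassigned` bucket rather than vanishing. The
`ubiq_high` row of the non-robust block is structurally zero: $WN > 0.60$
and the fact that a pooled frequency cannot exceed the per-sample maximum
force some sample above 25%.

`frequency_histogram()` bins pooled group frequencies and reports the
below-1% mass explicitly. `tissue_clustering()` correlates samples over
**constitutive sites** — covered by more than 3 reads in every sample with
at least 5% editing somewhere — and clusters them with average linkage on
$1 - r$ (product-moment by default, rank-based by argument; the linkage
and coefficient are choices, not published facts, and are configurable).
`gene_profile()` returns one gene's sites-by-tissues frequency matrix,
ordered by position, with missing cells left missing.

## The synthetic-data generator

Real squid data needs a genome and two dozen deep transcriptomes; the
package instead verifies every stage against a generator that plants the
classes the analysis is supposed to find. Under a fixed seed the bundle is
byte-identical across runs.

* **Genome and genes** — by default two 500-kb chromosomes carrying 200
  single-transcript genes (2–5 exons, realistic UTR and intron sizes, CDS
  length a multiple of 3, both strands), written as FASTA + GFF3.
* **Classes** — by default 500 sites each of `neural`, `ubiq_low`,
  `ubiq_med`, `ubiq_high`, `het_artifact`, `unedited`, planted across
  features with configurable weights, always on a transcribed-strand
  adenosine.
* **Frequencies** — per site and tissue, true frequencies are drawn from
  Beta distributions with class means (neural 0.40/0.01, low 0.02/0.02,
  medium 0.20/0.20, high 0.70/0.55 for neural/non-neural tissues) and
  concentration 30. Mixed tissues draw 50/50 mixtures of a neural and a
  non-neural value. Heterozygous artifacts sit near 0.5 everywhere
  (concentration 50) and are genotyped AG; unedited sites emit no G read.
  No published per-class frequency distribution exists; these are the
  package's stand-ins, chosen to land each class inside its nominal region
  with realistic spread, and all are configurable.
* **Depths** — negative-binomial per cell, mean 50, size 5 (variance
  ≈ 550): markedly overdispersed, as RNA-seq coverage is. Edited reads are
  binomial given depth and true frequency.
* **Context tracks** — repeat intervals (a quarter of sites are anchored
  inside one by default), protein domains on ~30% of genes, transmembrane
  segments on ~10%, and two outgroup genotype tracks in which a configurable
  fraction (default 5%) of edited-class sites are lineage-specific
  (homozygous non-A in both outgroups).

What the generator does **not** emulate: read-level artifacts (mapping
bias, sequencing error, hyper-edited read loss), correlated editing along
transcripts, expression differences between tissues, isoform complexity,
or genuine orthology breaks. Passing the recovery tests therefore shows
the pipeline's logic is correct under its stated statistical assumptions,
not that those assumptions exhaust real data.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally (the GFF3/VCF convention, and
  the native convention of the R/Bioconductor containers used); BED input
  is converted at the boundary by the importer.
* All published thresholds are applied with the stated strictness:
  frequency filter $f > 0.001$, robustness $f > 0.25$, constitutive depth
  $> 3$ per sample with maximum $f \ge 0.05$, classification depth
  $\ge 10$, background depth $> 10$.
* Zero depth gives a missing frequency everywhere; a group with zero
  pooled depth gives a missing WN/WNN and the site is `unclassified`.
* Ties in primary-transcript selection break lexicographically;
  re-running any reporting step on the same inputs is byte-identical.
* Degenerate configurations (empty tissue groups, negative counts, empty
  sample panels, unknown genes) raise immediate errors rather than
  propagating.

## Problem sizes used by the tests

The shipped test suite runs the full pipeline on the default 3000-site,
22-sample simulation (seed 1), plus a reduced 360-site bundle for
per-module tests; the annotation oracle compares every base of a 10-gene
genome against an independently built per-base feature map. These sizes
give stable stochastic margins (the weakest per-class recall sits near
0.97 against the 0.90 requirement) at a few tens of seconds for the whole
suite.

## Known limitations

* The classifier is threshold-based by design, matching the scheme it
  implements; it attaches no uncertainty to WN/WNN and performs no
  hypothesis test for differential editing.
* Sites with $WN \in (0.40, 0.60]$ and moderate $WNN$ fall outside every
  named region and are reported as `other`; the published scheme leaves
  this part of the plane undescribed.
* Annotation consults only the primary isoform; a site may have different
  consequences on minor isoforms.
* The conservation caller takes orthology as given (identity map or user
  table) and does no alignment or ancestral-state reconstruction.
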