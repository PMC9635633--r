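---
title: "Methods: dissecting repeat-dense MHC-like haplotypes with haplokit"
author: "haplokit developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting repeat-dense MHC-like haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplokit)
```

# Scope and scientific setting

Some MHC-like regions — the chicken MHCY region is the motivating case — are
organized unlike classical MHCs: dozens of near-identical class I-like and
lectin-like loci spaced roughly every 10 kb, about 40% of the sequence
occupied by LTR and CR1 retroelements, and multi-gene segmental duplication
blocks present in direct and inverted orientation, in full and partial
copies. haplokit packages the computational workflow used to characterize
such a haplotype:

* a locus **census** by contig and gene family with pseudogene accounting,
  gene-density arithmetic and predicted-protein type clustering;
* **repeat-content summaries** from RepeatMasker-style annotations;
* **Wu–Kabat variability profiling** of class I domain alignments;
* a **virtual Southern blot**: restriction digest, probe hybridization,
  gel co-migration and band matching;
* **k-mer dot plots** with chaining and segmental duplication block calling;
* **dN/dS** by the Nei–Gojobori (1986) counting method over structural
  segments, with neighbor-joining grouping of putative alleles;
* a **synthetic haplotype generator** that emits ground truth for all of
  the above.

Everything is driven either by real FASTA/GFF3/RepeatMasker inputs or by the
generator, and is exposed through `haplokit_run()` (subcommands `simulate`,
`census`, `vi`, `southern`, `dotplot`, `dnds`, `nj`, `demo`).

# Census and table conventions

Coordinates are 1-based inclusive throughout (GFF3 convention). The gap
between two adjacent features is defined as `start2 − end1`, not minus one;
under this convention an rRNA spacer ending at 103,436 followed by an LTR
element at 106,161 lies 2,725 bp away, matching how such boundaries are
conventionally quoted.

`gene_density()` rounds half away from zero: 107 loci over 0.639 Mb gives
167 loci/Mb; 46/0.242 gives 190; 253/3.78 gives 67.

`summarize_repeats()` computes per-class percentages from unrounded bp sums
and rounds half-up to two decimals. Published repeat tables usually print a
group total (e.g. "total transposable elements") equal to the **sum of the
rounded member rows**, which can differ from the recomputed ratio in the
last digit (40.14 vs 40.15 over 638,645 bp). The summary therefore carries
both: `percent` (recomputed) and `percent_table` (sum of rounded rows). The
same effect makes a small denominator produce visibly inconsistent totals
(a 241,833 bp comparison region prints 1.13% where the recomputed ratio is
0.98%); we report both rather than silently picking one.

A related caveat for anyone encoding a published census as a fixture: the
reference table this package's test fixture mirrors has per-cell pseudogene
counts summing to one more than its own printed column and grand totals
(38P vs 37P); the fixture follows the printed totals.

`cluster_types()` groups **only full-length loci by exact predicted-protein
identity** — near-identity does not merge types, since types in this setting
are defined by variable amino acids. Labels restart per family ("a", "b", …
in order of first genomic occurrence), so the clustering is invariant to
input order up to the first-occurrence rule.

# Wu–Kabat variability

For an alignment column the variability index is

$$VI = \frac{k}{n_{\max} / N}$$

with $k$ the number of distinct residues, $n_{\max}$ the count of the most
common residue and $N$ the residues observed. Gaps are excluded from all
three tallies (the classical treatment for immunoglobulin alignments; the
choice matters only for ragged domain boundaries). A column is called
polymorphic at $VI \ge 6$, with the threshold **inclusive**. Closed forms
anchor the tests: an invariant column gives $VI = 1$; a column of $N$
distinct residues gives $VI = N^2$. `compute_vi()` tallies characters
without enforcing a 20-letter alphabet, so degenerate or synthetic symbols
simply count as residues.

Cross-group comparison (`compare_polymorphic_sets()`) computes VI within
each group of a joint alignment separately, intersects the polymorphic
column sets, and reports positions in each group's declared reference-row
numbering (columns gapped in that reference carry no number). This mirrors
how "position 9 in one family aligns with position 9 in the other" style
statements are made.

# Virtual Southern

`digest()` cuts at every exact occurrence of the recognition site
(overlapping occurrences included; windows containing `N` never match).
TaqI is `T^CGA`, cut offset 1. Only the top strand is scanned for
palindromic sites — TaqI's site is its own reverse complement, so this is
lossless; non-palindromic sites trigger a both-strand scan. Fragment
lengths always sum to the sequence length and the fragment count equals the
cut count plus one; these conservation laws are property-tested on random
sequences and enzymes.

**Hybridization rule.** "A fragment hybridizes if a local alignment reaches
80% identity over at least 60 bp" does not pin down *which* alignment. We
make it operational: a fragment is probe-positive when the optimal
Smith–Waterman local alignment between fragment (either strand) and probe,
under BLASTN-like scoring (match +1, mismatch −2, gap open 5 / extend 2),
reaches the score an ungapped 80%-identity, 60 bp duplex would earn
(`60 × (3 × 0.8 − 2) = 24`). The strong mismatch and gap penalties matter:
under unit match/mismatch with cheap linear gaps, *random* 400 × 2000 bp
pairs reach scores above 60, so no threshold can separate homology from
noise. Both thresholds are exposed (`min_identity`, `min_overlap_bp`) and
the implementation is checked against an independent quadratic-time Gotoh
oracle.

Gel behavior is modeled minimally: `to_band_pattern()` merges sizes by
single linkage at 5% relative difference (an agarose-resolution proxy; the
method source states no tolerance) and `match_bands()` matches predicted to
observed bands greedily, best relative error first, one-to-one, ties toward
the larger band. On synthetic data with no dropout the match is exact on
both sides; a dropout region covering a probe-positive fragment produces
exactly the "observed but unpredictable" bands that real blots show when
part of a haplotype is missing from the clones.

# Dot plots and duplication blocks

`find_anchors()` reports exact shared k-mers (k = 21 by default) in both
orientations, replacing inexact megablast seeds; tolerance to divergence
comes from chaining across anchor gaps rather than fuzzy matching, which
keeps the stage deterministic and dependency-free. Two filters are applied
at the k-mer level: windows containing `N`, and low-complexity windows with
fewer than three distinct bases — a DUST-like filter mirroring what
megablast's default masking removes from seeding. Without it, `(TA)n`,
pentamer-satellite and A-rich arrays seed anchor clouds at every diagonal
offset and bridge unrelated chains.

`chain_anchors()` single-links same-orientation anchors along their
diagonal (forward: `pos_b − pos_a`; inverted: `pos_b + pos_a`) with at most
2 kb of diagonal drift, then splits where consecutive positions jump by
more than 2 kb; chains under 300 bp are noise and discarded.

`call_blocks()` keeps chains whose **both** intervals reach `min_block_bp`
(20 kb by default — above single-gene repeats spaced every ~10 kb, below
the ~25–45 kb scale of multi-gene blocks) **and** whose anchor density is
at least 0.02 anchors/bp. The density floor is a detector design choice
grounded in the k-mer arithmetic: copies at pairwise divergence 4% still
share $(0.96^2)^{21} \approx 0.18$ of their 21-mers, while chains glued
together out of scattered repeat-family matches stay well below 0.01
anchors/bp (and typically have grossly asymmetric sides). Copy intervals
are merged by single linkage at ≥50% reciprocal overlap; the archetype is
the longest copy, orientations are propagated from it through the chain
graph, and completeness is span over archetype span (full at ≥0.90).

One structural caveat: with a lone full + partial copy pair, the only
*observable* duplication is their shared segment, so both copies are
complete relative to it. Distinguishing full from partial copies requires
at least two full copies to fix the archetype span. The block census on a
real haplotype depends on these thresholds and is an exploration, not a
validated output.

# dN/dS and allele grouping

The maximum-likelihood analysis a codon-model package would perform is
deliberately replaced by the NG86 counting method, which is fully
specifiable and oracle-testable; published medians obtained with ML are
therefore **not** reproduction targets. Per codon, each position
contributes the fraction of its three possible changes that are synonymous;
changes to stop codons count as nonsynonymous, so potential sites always
sum to three per codon — a conservation law asserted on every pair.
Observed differences average over all minimal substitution pathways,
excluding pathways through stop codons (if every pathway is blocked, the
average falls back to all pathways). Proportions are Jukes–Cantor
corrected, $d = -\tfrac34 \ln(1 - \tfrac43 p)$.

Ratio conventions: $d_N = 0$ gives ratio 0 **with precedence** — a pair
with no nonsynonymous change is evidence of constraint even when its tiny
synonymous comparison saturates (single-codon comparisons saturate at one
difference); then saturation ($4p/3 \ge 1$) and $d_S = 0$ with $d_N > 0$
exclude the pair from medians. Under these rules a fully conserved helix
yields a segment median of exactly 0.00, and a simulated neutral alignment
(uniform substitution) yields a median near 1 — both are part of the
acceptance suite. Note that "synonymous-only evolution" gives an exactly
zero median only when pairwise codon differences are single-site: with two
synonymous hits in one codon, pathway averaging legitimately assigns
fractional nonsynonymous counts. The test simulator therefore restricts
synonymous evolution to third-codon positions.

Neighbor joining (`nj_tree()`) is the Saitou–Nei algorithm with the
Studier–Keppler Q criterion, deterministic lexicographic tie-breaking and
negative branch estimates clamped to zero (flagged). Additive matrices are
recovered exactly — topology and branch lengths — which the suite checks on
random 5–8 taxon trees, alongside topological agreement with `ape::nj()` on
noisy p-distance matrices. Which sequences constitute an "allele group" on
a real tree is a user decision; the package only builds the tree.

# The synthetic world

`generate_haplotype()` states the emulated conditions as defaults: gene
loci at ~10 kb spacing with a family mix proportional to the 45:41:8:8:4:1
census of the motivating haplotype (about one locus per 6 kb), 35% of loci
pseudogenized by an injected premature stop, 40% of bp inside repeat
elements, duplication blocks implanted per spec with 0.5% per-copy
divergence (the real blocks are described only as "identical and
near-identical"; 0.005 is this package's choice), and an observed Southern
band ladder derived from the full sequences.

Design choices a user should know:

* **Gene templates are fixed literals** shipped in
  `inst/extdata/gene_templates.fa` (ten class I protein types as point
  variants of one CDS, plus lectin-like, class IIβ, LENG9-like and zinc
  finger templates), so type clustering of generated haplotypes is
  deterministic. Templates are intron-less CDS; typing and pseudogene
  detection operate on the CDS, so exon structure would be inert
  complexity.
* **Blocks are gene-free**: archetypes contain repeat content but no gene
  loci, so `family_mix` equals the truth census exactly. Real duplication
  blocks carry genes; block *detection* operates on sequence identity and
  is unaffected, but gene-in-block dosage effects are out of scope.
* **Repeat instances diverge 15% from their family consensus** (i.i.d.
  substitutions, no indels). Aged interspersed repeats are at least that
  diverged; at materially lower divergence every repeat family would share
  enough exact 21-mers to masquerade as segmental duplication, which real
  repeats do not.
* **Dropout is modeled at band-generation time**: the truth sequences stay
  canonical, observed bands always come from the full sequences, and
  `apply_dropout()` derives the released (truncated) contigs on which
  predictions are made.
* If the configured family mix cannot fit the inter-block background at
  the configured spacing, the placement step tightens (density, not
  spacing, is the contract for exact counts); genuinely infeasible packing
  raises a capacity error before any output.

What a green test on this world does **not** establish: realistic
retroelement sequence models, indel processes, recombination, intron/exon
structure, or population-level haplotype variation — all out of scope. The
generator's value is exact, seeded ground truth for every downstream stage.

# Numerical and degenerate-input conventions

* Percent and density rounding is half-up/half-away-from-zero (documented
  per function); all other arithmetic is double precision.
* Empty inputs return empty, well-formed objects (empty FASTA, header-only
  GFF3/.out, empty band and anchor sets); all-gap alignments and
  zero-length regions raise errors instead.
* Every stochastic stage consumes one user seed; the generator restores
  the caller's RNG state, and identical config plus seed gives
  byte-identical files (hash-compared in the suite).
* `N` bases are allowed in sequences; digest sites and k-mer windows
  containing `N` simply never match, and `N` scores as a mismatch in
  hybridization.

# Known limitations

* The virtual Southern has no physical mobility model (log-size migration,
  partial digestion, methylation sensitivity); co-migration is a flat 5%
  relative window.
* Block completeness is relative to the longest *detected* copy (see the
  full+partial caveat above); breakpoints are k-mer-resolution, not
  base-pair refined.
* NG86 is a counting method: no transition/transversion or codon-frequency
  weighting, no ML branch estimation. It is the right tool for an
  oracle-testable reimplementation, not a replacement for codon models in
  inference about real selection pressure.
* The dot-plot census on real contigs depends on `min_block_bp`,
  `min_anchor_density` and the chaining gap; these defaults reproduce
  implanted truth on synthetic data but real-data block counts should be
  read as threshold-dependent.
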