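---
title: "Methods: characterizing alpha satellite families from digest-targeted reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing alpha satellite families from digest-targeted reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(alphasat)
```

# The problem

Alpha satellite DNA is the tandemly repeated, AT-rich, ~171-172 bp monomer
family that builds primate centromeres and pericentromeres. Because arrays
of nearly identical repeats defeat shotgun assembly, a practical way to
survey their diversity in a non-model primate is targeted sequencing:
digest genomic DNA with a restriction enzyme whose site sits in most
monomers (here XmnI, `GAANNNNTTC`, blunt cut `GAANN^NNTTC`), gel-purify the
monomer (~170 bp) and dimer (~340 bp) bands, and sequence them. The
monomers carry the signal of *families* — groups of related sequences with
their own consensus — and the dimers carry the signal of *organization* —
which monomer follows which in the genome, including dimeric higher-order
repeats (HORs).

`alphasat` implements the complete downstream computation: read filtering,
dimer splitting, alignment-free family discovery, per-family
characterization, artifact detection, FISH probe design and family
phylogenetics — together with a fully labeled synthetic genome and read
simulator, so every stage is testable without the original sequencing data.

# Read filtering

Four filters are applied in sequence; the survivor count after each stage
is reported so dataset accounting is always reconcilable.

1. **Quality**: mean Phred score >= 25. We read the threshold as a mean
   over the read (the operational definition used when reads are actually
   discarded); FASTA input without qualities passes with a notice.
2. **Extremity**: the read must carry the digested half-sites at both ends,
   `5'-NNTTC ... GAANN-3'`, checked exactly on the 3-base cores with the two
   flanking N positions unconstrained. The pattern is its own reverse
   complement in shape, so the check is orientation-symmetric.
3. **Length**: inclusive windows, 162-182 bp for monomers and 324-364 bp
   for dimers (the gel bands).
4. **Similarity and reorientation**: local (Smith-Waterman) alignment of
   the read and its reverse complement against a reference monomer
   (against two concatenated copies for the dimer band) with BLASTN-like
   scoring (match +2, mismatch -3, gap open -5, gap extend -2). The read
   passes when the best alignment spans at least 80 read bases (monomers)
   or 160 (dimers), and is returned in the reference orientation with its
   original orientation recorded — that orientation is the raw material of
   the later artifact test.

Digestion itself is deterministic: every site match is cut at the pattern
midpoint; coordinates are 0-based half-open throughout, and fragment
lengths always sum to the input length.

# Dimer splitting

A dimer with an intact XmnI site whose cut point lies within +-30 bp of
the sequence center is split at that site (the `X` dataset). The +-30
window quantifies "approximately central": monomer lengths vary by at most
~20 bp, so 30 leaves slack without picking up terminal sites. Equally
central sites are resolved leftmost, with a notice.

Dimers without such a site (the `noX` dataset) are aligned globally
(Needleman-Wunsch, match +1, mismatch -1, linear gap -2 — robust scoring
for ~95%-identical sequences) against two concatenated reference copies
and split at the read position aligned to the reference junction. When the
junction falls inside a read gap the split is placed at the first read
base at or after the junction, so deletions accrue deterministically to
the left monomer. Pairs with a monomer outside 162-182 bp are discarded;
pairing metadata (partner ids) is preserved for the association analysis.

# Family discovery and assignment

Sequences are compared without alignment through their 5-mer composition:
counts of all overlapping 5-mers on the oriented strand, divided by the
number of counted windows, giving 1024-dimensional profiles that sum
to 1. Profiles are centered (no per-column standardization — frequencies
share a scale) and decomposed by PCA; the first 100 components are
retained. A random training subset (2,500 by default) is clustered by
Ward's criterion (`ward.D2`) on Euclidean distances in the 100-PC space,
the dendrogram is cut at `k` clusters, and a linear discriminant model
trained on the training PC scores extends the labels to every sequence.

`k` is a user parameter. In `"auto"` mode the package cuts at the `k` in
2..6 with the highest mean silhouette width, with one refinement: the
silhouette distances are evaluated in the subspace of the first
`min(10, n_components)` PCs rather than all 100. Between-family structure
for up to six families is concentrated in a handful of leading components,
while the remaining ~90 retained components carry within-family noise that
dilutes relative separations; evaluated in the full space the index can
tie between nested cluster levels (e.g. a close family pair versus its
merge) and flip with the sampling seed, whereas in the leading subspace
the choice is stable. The clustering itself still uses the full 100-PC
distances. Cuts producing a near-singleton cluster are not eligible —
a one-member "family" is not a usable structure and cannot train a
discriminant.

Family labels `F1, F2, ...` are ordered by decreasing training-cluster
size, so the most abundant family is always `F1`.

# Per-family characterization

**Consensus.** A seeded subset (500 by default; all members when fewer)
is projected onto the family's majority template by global alignment in
two passes: first onto the most frequent member sequence, then onto the
first-pass per-column plurality string. Columns that are gaps in more
than half the members are dropped. A column is called when strictly more
than 60% of its non-gap members agree; otherwise it is `N` — a 6/10 column
is ambiguous, a 7/11 column is not.

**Identity.** Mean pairwise identity over a seeded subset:
matches / alignment columns per pair (global alignment; dual-gap columns
cannot occur pairwise), as a percentage. A position-wise variant (no
alignment, equal lengths required) is available and agrees closely on
these near-length-identical monomers.

**Motifs.** The CENP-B box (`TTCGTTGGAARCGGGA`) and pJalpha box
(`TTCCTTTTYCACCRTAG`) are searched IUPAC-aware on both strands with up to
2 mismatches; minus-strand hits are reported in plus-strand coordinates.

**Duplicate census and the orientation-bias artifact test.** Byte-identical
oriented sequences are grouped and counted, along with how many of each
group's reads were originally read in the reference orientation. True
genomic duplicates should be sequenced from both strands about equally;
semiconductor-sequencing homopolymer deletions, by contrast, are strongly
strand-asymmetric. Each group with >= 2 copies gets a two-sided exact
binomial test of its forward count against p = 0.5, Bonferroni-corrected
over the tested groups. A group is flagged as an artifact when the
adjusted p-value is below 0.05 **and** its forward fraction deviates from
1/2 by at least 0.25 (a 3:1 imbalance). The magnitude condition is part of
the definition of a *strong* bias: in a group with thousands of copies a
46%/54% imbalance is statistically detectable but is not the signature of
a strand-specific sequencing artifact, and flagging it would discard the
most abundant genuine genomic variants. On the published 20-group
duplicate table shipped in `inst/extdata/` this definition flags exactly
the five homopolymer-deletion-bearing groups.

**Left-right association.** The split dimers give a left-family x
right-family contingency table, tested for independence with Pearson's
chi-square; cells with standardized residuals above 2 are reported as
preferential associations (e.g. a planted C3->C4 HOR). When any expected
count is below 5 the p-value is replaced by a seeded Monte-Carlo estimate
(10,000 replicates); the residuals are still those of the Pearson fit.

# Probe design

FISH probes that distinguish families differing at a few positions must be
short; the package scores every N-free 18-mer window of the target
family's consensus. The probe is the window's reverse complement, so the
window itself is the hybridization target. Binding frequency against a
family is the fraction of members containing the target within a Hamming
budget (0 or 1; no indels) on either strand — FISH targets denatured DNA.
Windows forming fewer than 7 G/C pairs are extended to 19-mers, preferring
the extension direction that adds a G/C (3' on ties); a 19-mer still below
7 G/C is reported but can never be specific. A probe is **specific** when
its target-family binding frequency is strictly above 20% and every other
family's strictly below 3%, at 0 mismatches and (by default) again at 1
mismatch. Thresholds are strict: exactly 20% fails.

LNA (locked nucleic acid) positions raise affinity and are annotated in
lowercase at every second position from the 5' end — a convention for
synthesis; annotation never affects the binding computation. The four
published probe strings are shipped as a fixture for parsing tests; their
hand-tuned LNA placements are data, not outputs of the default rule.

# Phylogenetics

All retained monomers share the XmnI phase (they start at the cut point),
so a multiple alignment can be replaced by a deterministic
reference-projection: each member is globally aligned to the reference;
reference columns are shared, and member insertions open shared gap
columns sized to the longest insertion at that reference position. Members
under 50% identity to the reference are excluded with a notice.

Distances are Kimura 2-parameter: with transition proportion P and
transversion proportion Q over sites without gaps or ambiguities in either
row (pairwise deletion; global deletion available as an option),
`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`; a non-positive log argument is
a saturated distance, flagged as `NA` and refused by tree construction.
Trees are neighbor-joining (Saitou-Nei); negative branch lengths are
clamped to zero with the deficit moved to the sibling edge. Support values
come from 100 column-resampling bootstrap replicates: the percentage of
replicate trees containing each original internal bipartition, with
saturated replicates dropped from the denominator.

# The synthetic data generator

The generator is a first-class, tested module. It emulates, with full
ground-truth labels:

* **Families**: four built-in 172-bp synthetic consensuses (`C1`-`C4`)
  with exactly one XmnI site (placed at positions 1-10, so tandem arrays
  digest into phase-rotated monomers with a 5-bp carry-over) and a pJalpha
  box present in all but `C3`. `C2` differs from `C1` at exactly 9
  positions; `C3`/`C4` differ from `C1` at 25.
* **Within-family divergence**: each copy is independently substituted at
  a per-base rate outside the protected site. Two copies match at an
  unprotected position with probability `(1-d)^2 + d^2/3`, so the expected
  identity is `(162((1-d)^2 + d^2/3) + 10)/172`; the default rates
  (0.0270, 0.0844, 0.0784, 0.0964) solve this for the target identities
  95%, 85%, 86% and 83%.
* **Organization**: monomeric `C1` and `C2` arrays in an 82:18 unit ratio
  (2,050 and 450 units) plus a 300-unit `C3`-`C4` HOR array. `C4` copies
  always carry an inactivated site, so the HOR is released as 344-bp
  dimers; `C2` copies lose their site at rate 0.05 and `C1` at 0.002
  (homogeneous families mutate their site away more rarely). Array sizes
  are deliberately large relative to the simulated read depths so that
  duplicate reads overwhelmingly reflect identical genomic copies, not
  resequencing of the same copy — the regime of a real experiment.
* **Partial digestion**: each internal cut can be skipped (default
  probability 0.10 in the pipeline), producing dimers that retain an
  intact internal site — the `X` dataset.
* **Errors**: uniform substitutions (0.005/base), homopolymer-tract
  deletions (runs >= 2; 0.01 per run per read) and, crucially, an
  orientation bias: each artifact class (a specific run in a specific
  fragment) is strand-restricted with probability `orientation_bias`
  (default 0.5), the mechanism the artifact test is designed to catch.
  Qualities are position-independent truncated normals (mean 30, sd 4);
  only the per-read mean feeds the filter, so positional structure would
  add nothing the pipeline can see.

It does **not** simulate flowgrams or ionograms, PCR/emulsion
amplification, fragment-abundance bias in gel extraction (band sampling is
uniform — the simplest null), read-length effects beyond fragment length,
or trimers and longer multimers. Passing tests therefore demonstrate the
pipeline's correctness and calibration under a faithful but idealized
error structure; they do not certify behavior under instrument drift or
library-preparation biases absent from the model. The homopolymer
deletion rate itself is a calibration choice, not an empirical value.

# Numerical choices and degenerate inputs

* Length windows are inclusive at both ends.
* Equally central dimer sites: leftmost, logged. Junction-in-gap splits:
  after the gap.
* PCA centering uses the full dataset mean so that later projections are
  consistent; profiles are never column-standardized.
* Identity and consensus subset draws, training subsets, Monte-Carlo
  p-values and bootstrap resampling are all seeded; the pipeline derives
  stage seeds from one master seed by fixed offsets, making full runs
  byte-reproducible.
* Degenerate inputs fail loudly: all-identical profiles (no variance),
  sequences shorter than the k-mer, empty member sets, saturated
  distances, fewer than 3 taxa, a missing master seed.
* Problem sizes in the test-suite and acceptance script (4,000 monomer
  and 1,500 dimer reads; identity subsets of 150-200; 500 noX dimers;
  100 bootstrap replicates) are the package's chosen working sizes: large
  enough that every calibrated property is measured with comfortable
  margin, small enough to run interactively.

# Known limitations

* The similarity filter's internal Smith-Waterman uses one fixed scoring
  scheme; it honors the "hit longer than 80/160 bp" contract but is not a
  drop-in reimplementation of any particular BLAST version.
* Auto-`k` answers "how many flat clusters", and nested family structure
  is genuinely hierarchical; for fine work `k` should be set from
  inspection of the dendrogram and PCA scatter, which the pipeline
  exports.
* The LDA operates on PC scores of 5-mer profiles; families separated
  only by features invisible to 5-mer composition (e.g. pure
  rearrangements) would not be distinguished.
* Probe specificity is combinatorial (mismatch counts), not
  thermodynamic: no melting temperature, ΔG or LNA affinity model.
* The tree machinery accepts any user FASTA of phase-aligned monomers,
  but no external reference families are bundled.
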