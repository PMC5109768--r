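# alphasat

Characterization of alpha satellite DNA diversity and organization from
restriction-digest targeted sequencing.

Alpha satellite is the tandemly repeated ~171-172 bp monomer that builds
primate centromeres. Because near-identical repeats defeat assembly, a
practical survey of their diversity in a non-model primate digests genomic
DNA with XmnI (`GAANNNNTTC`, cutting `GAANN^NNTTC` inside most monomers),
gel-purifies the monomer (~170 bp) and dimer (~340 bp) bands, and
sequences them. `alphasat` implements the complete computation downstream
of the sequencer, for centromere and satellite-DNA researchers analyzing
such band-targeted read sets:

* **Filtering** — in-silico digestion plus a four-stage cascade (mean
  Phred >= 25; digested half-sites `5'-NNTTC ... GAANN-3'` at both ends;
  band length windows 162-182 / 324-364 bp; Smith-Waterman similarity to
  a reference with a >= 80 / 160 bp hit), with reorientation to the
  reference strand.
* **Dimer splitting** — at a central intact XmnI site (X dataset) or by
  Needleman-Wunsch against a doubled reference (noX dataset), preserving
  left-right pairing.
* **Family discovery** — normalized 5-mer frequency vectors, PCA (100
  components), Ward clustering of a 2,500-sequence training subset,
  silhouette-guided choice of the family count k, and linear discriminant
  assignment of every sequence.
* **Characterization** — per-family consensus (a column is called when
  > 60% of members agree, else `N`), mean pairwise identity, CENP-B /
  pJalpha box content (<= 2 mismatches, both strands), a duplicate-sequence
  census with an exact-binomial orientation-bias test that flags
  homopolymer-deletion sequencing artifacts, and a chi-square left-right
  association analysis of the split dimers.
* **Probe design** — 18/19-mer oligonucleotides with >= 7 G/C pairs,
  predicted to bind > 20% of the target family and < 3% of the others at
  0 and 1 mismatches, with lowercase LNA annotation.
* **Phylogenetics** — XmnI-phase projection alignment, Kimura 2-parameter
  distances (`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`), neighbor-joining, and
  100-replicate column bootstrap.
* **Synthetic data** — a seeded satellite-genome and read simulator
  (families with calibrated within-identity, a planted dimeric
  higher-order repeat, partial digestion, orientation-biased homopolymer
  deletions) with full ground-truth labels, so the whole pipeline runs
  and is tested without any external data.

## Worked example

The orientation-bias artifact test on the published 20-group duplicate
table shipped with the package:

```r
library(alphasat)
tab <- read.delim(system.file("extdata", "monomer_duplicate_counts.tsv",
                              package = "alphasat"))
tab$forward_count <- round(tab$forward_pct / 100 * tab$copy_number)
res <- orientation_bias_test(tab)
res[res$artifact_flag, c("variant", "copy_number", "forward_pct",
                         "bias_p_adjusted")]
#>       variant copy_number forward_pct bias_p_adjusted
#>       C114Del         486           1   4.477519e-134
#>       T101Del         357          99    9.170882e-98
#>        T80Del          78         100    1.323489e-22
#>  T39G-C114Del          57           0    2.775558e-16
#>  T39G-T101Del          41          98    7.639755e-10
```

Exactly the five groups read almost exclusively from one strand — the
signature of homopolymer-deletion artifacts — are flagged; abundant
variants read from both strands (46-63% forward) are not.

A complete run on a small synthetic genome:

```r
report <- run_pipeline(run_config(seed = 42,
  arrays = default_arrays(n_c1 = 600, n_c2 = 130, n_hor = 80),
  n_reads = c(monomer = 1200, dimer = 500),
  identity_subset = 100, tree_subset = 8, n_bootstrap = 50))
report
#> alpha satellite pipeline run (seed 42)
#>   monomer band cascade: input=1200 > quality=1200 > extremity=1148 > length=1148 > similarity=1148
#>   dimer band cascade: input=500 > quality=500 > extremity=472 > length=472 > similarity=472
#>   monomer dataset: 1148 sequences in 2 families (F1:986, F2:162)
#>     F1: n=986 identity=93.7% pJalpha=0.96 CENP-B=0.0000
#>     F2: n=162 identity=84.1% pJalpha=0.76 CENP-B=0.0000
#>   duplicate groups (>=2 copies): 87; artifact-flagged: 0
#>   dimer pairs: 472 (noX:266, X:206), k=3
#>   left-right association: X2=472.0 p=1.18e-104 (pearson)
```

The monomer dataset resolves into the two planted monomeric families
(86:14 here; the generator plants 82:18 array units) with their calibrated
identities (~94% and ~84% at the read level, where sequencing errors sit
on top of the genomic divergence). The dimer-derived monomers cluster into
the X-dataset family plus the two HOR partners, and the association test
rejects left-right independence — the planted C3-C4 higher-order repeat.
At these read depths no duplicate group is orientation-flagged; artifact
flags appear when a biased homopolymer-deletion class is sampled enough
times, as in the published table above.

## The analysis workflow

`analysis/01_simulate.R` through `analysis/07_trees.R` run the whole study
on the default synthetic genome, each step reading the previous step's
plain-text artifacts and writing its own under `results/`
(FASTA/FASTQ/TSV/newick):

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

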