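#!/usr/bin/env Rscript
# Step 1 -- simulate the satellite genome and the two gel-band read sets.
#
# The synthetic genome carries the four built-in families: monomeric C1 and
# C2 arrays in an 82:18 unit ratio and a C3-C4 higher-order repeat array
# whose C4 site is always inactivated, so the HOR is released as dimers.
# Reads emulate semiconductor sequencing of the two gel bands: random
# orientation, truncated-normal qualities, substitutions and
# orientation-biased homopolymer deletions. Partial digestion (10% skipped
# cuts) supplies dimers that retain an internal XmnI site.

suppressMessages(library(alphasat))
seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fams <- solatus_families()
genome <- simulate_genome(fams, default_arrays(), seed = seed + 1)
write_fasta(c(genome = genome$genome), file.path(out, "genome.fasta"))
write_tsv(genome$copies, file.path(out, "genome_truth.tsv"))
cat(sprintf("genome: %d bp, %d monomer copies (%d site-killed)\n",
            nchar(genome$genome), nrow(genome$copies),
            sum(genome$copies$site_killed)))

em <- error_model()
for (band in c("monomer", "dimer")) {
  n <- if (band == "monomer") 4000 else 1500
  rd <- simulate_reads(genome, em, band, n,
                       seed = seed + if (band == "monomer") 2 else 3,
                       cut_skip_prob = 0.10)
  write_reads_fastq(rd, file.path(out, paste0("reads_", band, ".fastq")))
  write_tsv(rd, file.path(out, paste0("truth_", band, ".tsv")))
  cat(sprintf("%s band: %d reads, lengths %d-%d, %.1f%% with homopolymer deletions\n",
              band, n, min(nchar(rd$bases)), max(nchar(rd$bases)),
              100 * mean(rd$n_hp_del > 0)))
}
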