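#!/usr/bin/env Rscript
# Step 6 -- family-discriminating oligonucleotide probes.
#
# Candidate probes are reverse complements of the N-free 18-mer windows of
# each family consensus (extended to 19 when fewer than 7 G/C pairs form).
# A probe is specific when it is predicted to bind > 20% of its target
# family and < 3% of every other family, at both 0 and 1 mismatches. The
# default LNA annotation (every second position) is included for synthesis.

suppressMessages(library(alphasat))
out <- "results/probes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mono <- read.delim("results/filtered/monomer_records.tsv")
assign <- read.delim("results/classification/assignments_monomer.tsv")
cons <- read_fasta("results/characterization/consensus.fasta")
members <- split(mono$bases, assign$family)

for (f in names(members)) {
  cands <- enumerate_candidates(cons[[f]], members, f)
  write_tsv(cands, file.path(out, paste0("probes_", f, ".tsv")))
  spec <- cands[cands$specific, ]
  cat(sprintf("%s: %d candidate windows, %d specific\n",
              f, nrow(cands), nrow(spec)))
  if (nrow(spec) > 0) {
    best <- spec[which.max(spec[[paste0("freq_exact_", f)]]), ]
    cat(sprintf("  best: %s (%.0f%% on-target exact, LNA %s)\n",
                best$probe, 100 * best[[paste0("freq_exact_", f)]],
                best$lna))
  }
}
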