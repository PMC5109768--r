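#!/usr/bin/env Rscript
# Step 5 -- per-family characterization.
#
# For each monomer family: the >60%-rule consensus from 500 random members,
# mean pairwise identity (200-member subset), and pJalpha / CENP-B box
# content (<= 2 mismatches, both strands). Then the duplicate census with
# the orientation-bias artifact test, and the left-right association test
# on the split dimers.

suppressMessages(library(alphasat))
seed <- 1
out <- "results/characterization"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mono <- read.delim("results/filtered/monomer_records.tsv")
assign <- read.delim("results/classification/assignments_monomer.tsv")
stopifnot(identical(mono$id, assign$id))

members <- split(mono$bases, assign$family)
rows <- list(); cons <- character(0)
for (f in names(members)) {
  mem <- members[[f]]
  cp <- build_consensus(mem, subset_size = 500, seed = seed + 7)
  cons[f] <- cp$consensus
  rows[[f]] <- data.frame(
    family = f, n = length(mem),
    identity_pct = mean_pairwise_identity(mem, subset_size = 200,
                                          seed = seed + 8),
    pjalpha_pct = 100 * motif_frequency(mem, PJALPHA_BOX),
    cenpb_pct = 100 * motif_frequency(mem, CENPB_BOX))
}
summary <- do.call(rbind, rows)
write_tsv(summary, file.path(out, "family_summary.tsv"))
write_fasta(cons, file.path(out, "consensus.fasta"))
print(summary, row.names = FALSE)

census <- orientation_bias_test(duplicate_census(mono))
write_tsv(census[census$copy_number >= 2, ], file.path(out, "census.tsv"))
cat(sprintf("%d duplicate groups (>= 2 copies), %d flagged as orientation artifacts\n",
            sum(census$copy_number >= 2),
            sum(census$artifact_flag, na.rm = TRUE)))

dassign <- read.delim("results/classification/assignments_dimer.tsv")
dmono <- read.delim("results/dimers/monomers.tsv")
lab <- stats::setNames(dassign$family, dassign$id)
lefts <- dmono[dmono$source == "dimer_left", ]
assoc <- association_test(lab[lefts$id], lab[lefts$partner_id],
                          seed = seed + 9)
write_tsv(as.data.frame.matrix(assoc$table), file.path(out,
                                                       "association.tsv"))
write_tsv(as.data.frame.matrix(assoc$stdres),
          file.path(out, "association_residuals.tsv"))
cat(sprintf("left-right association: X2 = %.1f, p = %.3g (%s)\n",
            assoc$statistic, assoc$p.value, assoc$method))
pref <- which(assoc$preferential, arr.ind = TRUE)
for (i in seq_len(nrow(pref))) {
  cat(sprintf("  preferential: left %s -> right %s (residual %.1f)\n",
              rownames(assoc$stdres)[pref[i, 1]],
              colnames(assoc$stdres)[pref[i, 2]],
              assoc$stdres[pref[i, 1], pref[i, 2]]))
}
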