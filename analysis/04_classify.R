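#!/usr/bin/env Rscript
# Step 4 -- alignment-free family discovery and assignment.
#
# 5-mer frequency profiles -> PCA -> Ward clustering of a random training
# subset in 100-PC space (cluster count chosen by silhouette) -> linear
# discriminant assignment of every sequence. The monomer dataset and the
# dimer-derived monomers are fitted separately; the dimer fit should
# rediscover the monomer families plus the HOR-only C3/C4 pair.

suppressMessages(library(alphasat))
seed <- 1
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mono <- read.delim("results/filtered/monomer_records.tsv")
prof <- kmer_profile(stats::setNames(mono$bases, mono$id))
model <- fit_family_model(prof, k = "auto", seed = seed + 4)
assign <- assign_families(model, prof)
write_tsv(assign, file.path(out, "assignments_monomer.tsv"))
scores <- project_profiles(model, prof)
write_tsv(data.frame(id = assign$id, PC1 = scores[, 1], PC2 = scores[, 2],
                     family = assign$family),
          file.path(out, "pca_scatter_monomer.tsv"))
cat("monomer dataset: k =", model$k, "families;",
    paste(names(table(assign$family)), table(assign$family),
          sep = ":", collapse = ", "), "\n")
saveRDS(model, file.path(out, "model_monomer.rds"))

dmono <- read.delim("results/dimers/monomers.tsv")
dprof <- kmer_profile(stats::setNames(dmono$bases, dmono$id))
dmodel <- fit_family_model(dprof, k = "auto", seed = seed + 5)
dassign <- assign_families(dmodel, dprof)
write_tsv(dassign, file.path(out, "assignments_dimer.tsv"))
cat("dimer-derived monomers: k =", dmodel$k, "families;",
    paste(names(table(dassign$family)), table(dassign$family),
          sep = ":", collapse = ", "), "\n")
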