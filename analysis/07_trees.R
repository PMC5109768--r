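#!/usr/bin/env Rscript
# Step 7 -- family phylogenetics.
#
# A per-family random subset of monomers (plus the dimer-derived C3/C4
# monomers) is projection-aligned onto the reference in the shared XmnI
# phase, pairwise K2P distances are computed with pairwise gap deletion,
# and a neighbor-joining tree with 100 column-resampling bootstrap
# replicates is written in newick format.

suppressMessages(library(alphasat))
seed <- 1
out <- "results/trees"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mono <- read.delim("results/filtered/monomer_records.tsv")
assign <- read.delim("results/classification/assignments_monomer.tsv")
dmono <- read.delim("results/dimers/monomers.tsv")
dassign <- read.delim("results/classification/assignments_dimer.tsv")

pool <- rbind(data.frame(bases = mono$bases,
                         family = paste0("M", assign$family)),
              data.frame(bases = dmono$bases,
                         family = paste0("D", dassign$family)))
set.seed(seed + 10)
groups <- split(pool$bases, pool$family)
sel <- do.call(c, lapply(names(groups), function(f) {
  mem <- groups[[f]]
  take <- sample.int(length(mem), min(10L, length(mem)))
  stats::setNames(mem[take], paste0(f, "_", seq_along(take)))
}))

aln <- project_align(sel, default_reference())
D <- k2p_matrix(aln)
write_tsv(cbind(id = rownames(D), as.data.frame(D)),
          file.path(out, "k2p_distances.tsv"))
tree <- bootstrap_support(aln, n_reps = 100, seed = seed + 11)
ape::write.tree(tree, file.path(out, "family_tree.nwk"))
cat(sprintf("tree over %d monomers from %d groups; bootstrap supports %d-%d\n",
            length(sel), length(groups),
            min(tree$node.label), max(tree$node.label)))
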