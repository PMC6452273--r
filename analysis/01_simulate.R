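#!/usr/bin/env Rscript
# Stage 1: simulate the benchmark inputs.
#
# Builds a 200-tip Yule tree (birth rate 1.2, root-to-tip height ~4), ten
# branch-length-jittered copies standing in for bootstrap trees, and a binary
# trait table containing three (system, cas) pairs -- one evolving with a
# positive dependency (partner gained 5x faster / lost 5x slower when the
# other is present), one with the mirrored negative dependency, one
# independently -- plus 32 background control genes at frequencies spanning
# 0.15-0.85. Everything is written as Newick/TSV under results/data/.

suppressPackageStartupMessages(library(cooccurphylo))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 1L

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

tree <- simulate_tree(200L, birth_rate = 1.2, seed = derive_seed(seed, "tree"))
cat(sprintf("simulated tree: %d tips, mean root-to-tip depth %.2f\n",
            ape::Ntip(tree),
            mean(ape::node.depth.edgelength(tree)[1:200])))

dep_pos <- dependent_model(q12 = 1, q13 = 1, q21 = 1, q24 = 5,
                           q31 = 1, q34 = 1, q42 = 1, q43 = 0.2)
dep_neg <- dependent_model(q12 = 1, q13 = 1, q21 = 1, q24 = 1,
                           q31 = 1, q34 = 0.2, q42 = 1, q43 = 5)
models <- list(dep_pos, dep_neg, independent_model(1, 1, 1, 1))

pairs <- lapply(seq_along(models), function(i) {
  simulate_pair_traits(tree, models[[i]],
                       seed = derive_seed(seed, paste0("pair_", i)),
                       trait_ids = c(paste0("sys", i), paste0("cas", i)))
})
controls <- simulate_controls(tree$tip.label,
                              rep(seq(0.15, 0.85, by = 0.1), 4L),
                              seed = derive_seed(seed, "controls"))
traits <- do.call(cbind_traits, c(pairs, list(controls)))
print(traits)

boots <- jitter_trees(tree, n = 10L, length_cv = 0.15,
                      seed = derive_seed(seed, "boot"))

write_newick(tree, file.path(outdir, "tree.nwk"))
write_newick(boots, file.path(outdir, "boot_trees.nwk"))
write_trait_table(traits, file.path(outdir, "traits.tsv"))
cat("wrote", outdir, "/{tree.nwk, boot_trees.nwk, traits.tsv}\n")
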