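#!/usr/bin/env Rscript
# Stage 2: phylogeny-naive association screen.
#
# Frequency-filters the traits (strictly between 1% and 99% presence),
# builds all (system, cas) contingency tables, computes phi for each pair
# and for 10 frequency-matched control genes per system trait, tests whether
# the mean delta-phi (|phi| of the focal pair minus mean |phi| of its
# controls) is positive, and applies Fisher exact tests with a Bonferroni
# correction at alpha = 0.05. Inputs come from stage 1.

suppressPackageStartupMessages(library(cooccurphylo))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 1L

traits <- read_trait_table("results/data/traits.tsv")
scr <- screen_associations(traits, k_controls = 10L, margin = 0.01,
                           alpha = 0.05, seed = derive_seed(seed, "screen"))
print(scr)

dir.create("results/screen", recursive = TRUE, showWarnings = FALSE)
write.table(scr$records, "results/screen/screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
dp <- scr$delta_phi
write.table(data.frame(mean_delta_phi = dp$mean, t = dp$t,
                       one_sided_p = dp$p, n_pairs = dp$n),
            "results/screen/delta_phi.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/screen/{screen.tsv, delta_phi.tsv}\n")
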