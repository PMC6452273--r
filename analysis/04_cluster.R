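#!/usr/bin/env Rscript
# Stage 4: signed association matrix and clustering.
#
# Combines the screen (stage 2) and the phylogenetic tests (stage 3) into a
# cas x system matrix of {-1, 0, +1} calls (nonzero only where both the
# Bonferroni and the median-LRT rules pass), drops empty rows/columns, and
# orders rows and columns by single-linkage hierarchical clustering.

suppressPackageStartupMessages(library(cooccurphylo))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 1L

traits <- read_trait_table("results/data/traits.tsv")
screen <- read.delim("results/screen/screen.tsv")
phylo <- read.delim("results/phylo/phylo_test.tsv")

# rebuild a screen_result shell around the stored records
scr <- structure(list(records = screen,
                      delta_phi = list(), m_tests = unique(screen$m_tests),
                      alpha = 0.05, controls = list()),
                 class = "screen_result")
signed <- signed_matrix(scr, phylo)
cat("signed matrix:", nrow(signed), "x", ncol(signed), "\n")
print(signed)

dir.create("results/cluster", recursive = TRUE, showWarnings = FALSE)
signed_df <- cbind(cas = rownames(signed), as.data.frame(signed))
write.table(signed_df, "results/cluster/signed_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

if (nrow(signed) >= 1L && ncol(signed) >= 1L) {
  cl <- cluster_signed(signed)
  cat("row order:", paste(cl$row_order, collapse = " "), "\n")
  cat("col order:", paste(cl$col_order, collapse = " "), "\n")
  write.table(cl$row_merge, "results/cluster/row_merge.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cl$col_merge, "results/cluster/col_merge.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(paste(c("rows:", cl$row_order), collapse = "\t"),
               paste(c("cols:", cl$col_order), collapse = "\t")),
             "results/cluster/leaf_orders.tsv")
}
cat("wrote results/cluster/\n")
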