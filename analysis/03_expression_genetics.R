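#!/usr/bin/env Rscript
# Step 3 — expression genetics of the hybrid.
#
# Builds the in-silico mid-parent hybrid (1:1 normalized parental mix),
# classifies genes as additive or non-additive (|log2FC| >= 1.5, FDR < 0.05
# versus the mid-parent), partitions non-additive genes into
# expression-level dominance and transgressive classes (DEG rule
# |log2FC| >= 2), calls single-parental expression (FPKM > 1 vs < 0.1), and
# scores subgenome dosage dependence (r^2 > 0.64, FDR < 0.05 against the
# A = (1/2, 2/3, 1) and C = (1/2, 1/3, 0) dosage vectors).

library(triadomics)

sim <- read_simulation("results/simdata")
res <- run_pipeline(sim)
gc <- res$gene_classes

dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)
write.table(gc, "results/expression/gene_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$homolog_pairs, "results/expression/homolog_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("additivity: ",
        paste(names(table(gc$additivity)), table(gc$additivity),
              collapse = ", ", sep = "="))
message("patterns:   ",
        paste(names(table(gc$pattern)), table(gc$pattern),
              collapse = ", ", sep = "="))
message("SPE:        ",
        paste(names(table(gc$spe)), table(gc$spe), collapse = ", ", sep = "="))
message("dosage:     ",
        paste(names(table(gc$dosage)), table(gc$dosage),
              collapse = ", ", sep = "="))
message("homolog-pair categories: ",
        paste(names(table(res$homolog_pairs$category)),
              table(res$homolog_pairs$category), collapse = ", ", sep = "="))
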