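#!/usr/bin/env Rscript
# Step 4 — DNA methylation and small RNA.
#
# Builds the in-silico mid-parent methylome (1:1 coverage-balanced mix on
# the A subgenome, maternal pass-through on C), calls context-specific DMRs
# in 200-bp bins (Fisher exact + BH; level difference > 0.3/0.2/0.1 for
# CG/CHG/CHH) and per-cytosine DMLs, assigns DMRs to genes, scores ACR
# methylation status, clusters 18-30 nt sRNA reads, and tests sRNA
# accumulation shifts inside hyper- and hypo-DMRs.

library(triadomics)

sim <- read_simulation("results/simdata")
res <- run_pipeline(sim)

dir.create("results/methylation", recursive = TRUE, showWarnings = FALSE)
write.table(res$dmr_hits, "results/methylation/dmrs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$dmls[res$dmls$dml, ], "results/methylation/dmls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$srna_enrichment, "results/methylation/srna_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("DMRs by context/direction:")
print(table(res$dmr_hits$context, res$dmr_hits$direction))
message("DMLs: ", sum(res$dmls$dml), " of ", nrow(res$dmls), " tested sites")
message("DMG positional classes: ",
        paste(names(table(res$dmr_hits$positional)),
              table(res$dmr_hits$positional), collapse = ", ", sep = "="))
message("sRNA clusters: hybrid ", nrow(res$srna_clusters$hybrid),
        ", in-silico ", nrow(res$srna_clusters$insilico))
message("sRNA shift at DMRs:")
print(res$srna_enrichment)
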