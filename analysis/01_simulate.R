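#!/usr/bin/env Rscript
# Step 1 — generate the synthetic allotriploid study.
#
# Two allotetraploid (AACC) maternal lines collapsed into one maternal
# sample, a diploid (AA) paternal line with no C subgenome, and their AAC F1
# hybrid, simulated across four assays (ATAC peaks, RNA counts, WGBS calls,
# sRNA reads) with planted ground-truth labels. Everything downstream reads
# the plain-text study written here.

library(triadomics)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg)
write_simulation(sim, "results/simdata")

message("genes:        ", nrow(sim$genome$genes),
        " (", sum(sim$genome$genes$subgenome == "A"), " A / ",
        sum(sim$genome$genes$subgenome == "C"), " C; ",
        nrow(sim$genome$homologs), " homolog pairs)")
message("TEs:          ", nrow(sim$genome$tes))
message("planted gene classes:")
print(table(sim$expression$truth$class))
message("planted ACR categories:")
print(table(sim$acr$truth$category))
message("planted DMR bins: ", nrow(sim$meth$truth),
        " | cytosines: ", nrow(sim$meth$calls$maternal))
message("written to results/simdata (truth in truth.json)")
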