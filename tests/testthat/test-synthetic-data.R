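test_that("the generator is deterministic for a fixed seed", {
  cfg <- small_config(seed = 9)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$expression$counts, s2$expression$counts)
  expect_identical(s1$acr$peaks, s2$acr$peaks)
  expect_identical(s1$meth$calls, s2$meth$calls)
  expect_identical(s1$srna$reads, s2$srna$reads)
  s3 <- simulate_all(small_config(seed = 10))
  expect_false(identical(s1$expression$counts, s3$expression$counts))
})

test_that("the genome has symmetric homolog pairs and subgenome structure", {
  g <- make_genome(small_config())
  a <- g$genes$subgenome[match(g$homologs$a_gene, g$genes$gene_id)]
  c_ <- g$genes$subgenome[match(g$homologs$c_gene, g$genes$gene_id)]
  expect_true(all(a == "A"))
  expect_true(all(c_ == "C"))
  # symmetry of the partner relation
  pa <- g$genes$homolog_partner[match(g$homologs$a_gene, g$genes$gene_id)]
  expect_equal(pa, g$homologs$c_gene)
  # genes are valid non-overlapping intervals per chromosome
  validate_intervals(g$genes)
  by_chr <- split(g$genes, g$genes$chrom)
  for (d in by_chr) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= head(d$end, -1)))
  }
})

test_that("the generator refuses TE-driven ACRs without TEs", {
  cfg <- small_config()
  cfg$n_tes <- 0L
  genome <- make_genome(cfg)
  expect_equal(nrow(genome$tes), 0)
  expect_error(simulate_acrs(cfg, genome), "TE")
})

test_that("planted expression classes obey their construction", {
  sim <- default_sim()
  tr <- sim$expression$truth
  counts <- sim$expression$counts
  man <- sim$expression$manifest
  pcols <- man$sample[man$role == "paternal"]
  # SPE silent parents and the C subgenome are structural zeros
  spe_m <- tr$gene_id[tr$class == "SPE-M"]
  expect_true(all(counts[spe_m, pcols] == 0))
  expect_true(all(counts[tr$gene_id[tr$subgenome == "C"], pcols] == 0))
  spe_p <- tr$gene_id[tr$class == "SPE-P"]
  mcols <- man$sample[man$role == "maternal"]
  expect_true(all(counts[spe_p, mcols] == 0))
  # planted dosage-dependent A genes scale roughly as (1/2, 2/3, 1)
  dep_a <- tr$gene_id[!is.na(tr$dosage) & tr$dosage == "dependent" &
                      tr$subgenome == "A"]
  hcols <- man$sample[man$role == "hybrid"]
  ratio_mp <- rowMeans(counts[dep_a, mcols]) / rowMeans(counts[dep_a, pcols])
  ratio_hp <- rowMeans(counts[dep_a, hcols]) / rowMeans(counts[dep_a, pcols])
  expect_equal(median(ratio_mp), 0.5, tolerance = 0.1)
  expect_equal(median(ratio_hp), 2 / 3, tolerance = 0.1)
})

test_that("planted ACR categories round-trip through their defining calls", {
  sim <- default_sim()
  truth <- sim$acr$truth
  # merged hybrid replicates reproduce one consensus ACR per planted locus
  merged <- merge_replicate_peaks(sim$acr$peaks$hybrid)
  hybrid_loci <- truth[truth$category != "silent", ]
  idx <- match_truth_acrs(hybrid_loci, merged)
  expect_true(all(!is.na(idx)))
  # TE-driven loci exceed half TE coverage; novel loci have zero parent reads
  te <- truth[truth$category == "TE-driven", ]
  expect_true(all(overlap_fraction(te, sim$genome$tes) > 0.5))
  reads_m <- quantify_acr_reads(truth, sim$acr$peaks$maternal)
  reads_p <- quantify_acr_reads(truth, sim$acr$peaks$paternal)
  reads_h <- quantify_acr_reads(truth, sim$acr$peaks$hybrid)
  nov <- truth$category == "novel"
  expect_true(all(reads_m[nov, ] == 0) && all(reads_p[nov, ] == 0))
  expect_true(all(reads_h[nov, ] >= 5))
  sil <- truth$category == "silent"
  expect_true(all(reads_h[sil, ] == 0))
  expect_true(all(reads_m[sil, ] >= 5) && all(reads_p[sil, ] >= 5))
})

test_that("the methylome plants its TE/proximal ordering and DMR bins", {
  cfg <- small_config(seed = 3)
  genome <- make_genome(cfg)
  meth <- simulate_methylome(cfg, genome)
  m <- meth$calls$maternal
  lev <- function(rows) sum(m$meth[rows]) / sum(m$meth[rows] + m$unmeth[rows])
  pos <- data.frame(chrom = m$chrom, start = m$pos, end = m$pos + 1)
  in_te <- overlap_fraction(pos, genome$tes) > 0
  prox <- classify_position(pos, genome$genes) == "proximal"
  for (ctx in c("CG", "CHG", "CHH")) {
    i <- m$context == ctx
    expect_gt(lev(which(i & in_te)), lev(which(i & prox & !in_te)))
  }
  # paternal calls carry no C-subgenome positions
  expect_true(all(subgenome_of(meth$calls$paternal$chrom) == "A"))
  # read lengths of simulated sRNA stay within 18-30 nt
  srna <- simulate_srna(cfg, meth$truth)
  for (rd in srna$reads)
    expect_true(all(rd$length >= 18 & rd$length <= 30))
})

test_that("simulation output round-trips through the plain-text writers", {
  cfg <- small_config(seed = 13)
  sim <- simulate_all(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_simulation(dir)
  expect_equal(back$genome$genes[, c("chrom", "start", "end", "gene_id")],
               sim$genome$genes[, c("chrom", "start", "end", "gene_id")])
  expect_equal(back$genome$tes[, c("chrom", "start", "end")],
               sim$genome$tes[, c("chrom", "start", "end")])
  expect_identical(unname(back$expression$counts),
                   unname(sim$expression$counts))
  expect_equal(back$acr$peaks$hybrid$rep1[, c("chrom", "start", "end", "count")],
               sim$acr$peaks$hybrid$rep1[, c("chrom", "start", "end", "count")])
  expect_equal(back$meth$calls$maternal, sim$meth$calls$maternal)
  expect_equal(back$srna$reads$hybrid[, c("chrom", "start", "end", "length")],
               sim$srna$reads$hybrid[, c("chrom", "start", "end", "length")])
})
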