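mk_calls <- function(pos, meth, unmeth, context = "CG", chrom = "A01",
                     strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             meth = meth, unmeth = unmeth, stringsAsFactors = FALSE)
}

test_that("weighted methylation pools counts and filters by coverage", {
  expect_equal(weighted_methylation(mk_calls(10, 17, 3), "A01", 0, 100, "CG"),
               0.85)
  calls <- mk_calls(c(10, 20), c(3, 7), c(7, 3))
  expect_equal(weighted_methylation(calls, "A01", 0, 100, "CG"), 0.5)
  # count-weighted, not site-averaged: 1/10 and 9/10 pool to 0.5 but
  # 1/2 and 9/18 pool to 10/20
  a <- mk_calls(c(10, 20), c(1, 9), c(9, 1))
  b <- mk_calls(c(10, 20), c(1, 9), c(1, 9))
  expect_equal(weighted_methylation(a, "A01", 0, 100, "CG"), 0.5)
  expect_equal(weighted_methylation(b, "A01", 0, 100, "CG"), 0.5)
  c2 <- mk_calls(c(10, 20), c(1, 9), c(4, 12))
  expect_equal(weighted_methylation(c2, "A01", 0, 100, "CG"), 10 / 26)
  # sub-coverage site alone: undefined
  expect_true(is.na(weighted_methylation(mk_calls(10, 2, 2), "A01", 0, 100,
                                         "CG")))
})

test_that("in-silico methylome mixes parents 1:1 on A and passes C through", {
  m <- mk_calls(c(100, 200), c(8, 5), c(2, 5),
                chrom = c("A01", "C01"))
  p <- mk_calls(100, 2, 8, chrom = "A01")
  ins <- build_insilico_methylome(m, p)
  a <- ins[ins$chrom == "A01", ]
  expect_equal(a$meth / (a$meth + a$unmeth), 0.5)
  expect_equal(a$meth + a$unmeth, 20)
  cc <- ins[ins$chrom == "C01", ]
  expect_equal(cc$meth, 5)
  expect_equal(cc$unmeth, 5)
  # identical parents: levels unchanged everywhere
  m2 <- mk_calls(c(100, 300), c(6, 9), c(4, 1))
  ins2 <- build_insilico_methylome(m2, m2)
  expect_equal(ins2$meth / (ins2$meth + ins2$unmeth),
               m2$meth / (m2$meth + m2$unmeth))
})

test_that("bins tile chromosomes without overlap and pool per context", {
  calls <- mk_calls(c(10, 150, 210, 399, 450), rep(6, 5), rep(4, 5))
  b <- bin_methylation(calls, "CG", 200)
  expect_equal(b$start, c(0, 200, 400))
  expect_equal(b$n_sites, c(2, 2, 1))
  expect_true(all(b$end - b$start == 200))
  expect_true(!is.unsorted(b$start))
  expect_equal(b$level, rep(0.6, 3))
})

test_that("DMR calls combine the Fisher test with context deltas", {
  # CG: 17/20 vs 10/20 has delta 0.35 > 0.3; DMR iff the BH Fisher p clears
  b1 <- data.frame(chrom = "A01", start = 0, end = 200, n_sites = 3,
                   meth = 170, unmeth = 30, level = 0.85)
  b2 <- data.frame(chrom = "A01", start = 0, end = 200, n_sites = 3,
                   meth = 100, unmeth = 100, level = 0.50)
  res <- call_dmrs(b1, b2, "CG")
  expect_equal(res$p_value, bf_fisher_p(170, 30, 100, 100), tolerance = 1e-12)
  expect_true(res$dmr)
  expect_equal(res$direction, "hyper")
  # CHH delta below 0.1 is never a DMR no matter the p-value
  c1 <- b1; c1$meth <- 180; c1$unmeth <- 820; c1$level <- 0.18
  c2 <- b2; c2$meth <- 100; c2$unmeth <- 900; c2$level <- 0.10
  chh <- call_dmrs(c1, c2, "CHH")
  expect_false(chh$dmr)
  # identical bins: p = 1, no DMR
  same <- call_dmrs(b1, b1, "CG")
  expect_equal(same$p_value, 1)
  expect_false(same$dmr)
  expect_error(call_dmrs(b1, b2, "CpG"), "context")
})

test_that("DMR calling is antisymmetric under sample swap", {
  withr::local_seed(7)
  n <- 60
  b1 <- data.frame(chrom = "A01", start = seq(0, by = 200, length.out = n),
                   n_sites = 5,
                   meth = rbinom(n, 200, runif(n, 0.2, 0.9)))
  b1$end <- b1$start + 200; b1$unmeth <- 200 - b1$meth
  b1$level <- b1$meth / 200
  b2 <- b1
  b2$meth <- rbinom(n, 200, runif(n, 0.2, 0.9))
  b2$unmeth <- 200 - b2$meth; b2$level <- b2$meth / 200
  ab <- call_dmrs(b1, b2, "CG")
  ba <- call_dmrs(b2, b1, "CG")
  expect_equal(ab$dmr, ba$dmr)
  expect_equal(ab$p_value, ba$p_value)
  flip <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(unname(flip[ab$direction[ab$dmr]]), ba$direction[ba$dmr])
})

test_that("DML calls test covered sites per context with direction labels", {
  c1 <- mk_calls(c(10, 20, 30), c(20, 10, 5), c(0, 10, 0))
  c2 <- mk_calls(c(10, 20, 30), c(0, 10, 0), c(20, 10, 4))
  res <- call_dmls(c1, c2)
  # site 30 has coverage 4 in sample 2: excluded
  expect_equal(res$pos, c(10, 20))
  expect_equal(res$p_value[1], bf_fisher_p(20, 0, 0, 20), tolerance = 1e-12)
  expect_true(res$dml[1])
  expect_equal(res$direction[1], "hyper")
  expect_false(res$dml[2])
})

test_that("ACR methylation status uses per-context thresholds", {
  lowm <- rbind(mk_calls(10, 1, 49),
                mk_calls(20, 1, 39, context = "CHG"),
                mk_calls(30, 0, 40, context = "CHH"))
  expect_equal(acr_methylation_status(lowm, "A01", 0, 100), "unmethylated")
  him <- lowm; him$meth[1] <- 20; him$unmeth[1] <- 30
  expect_equal(acr_methylation_status(him, "A01", 0, 100), "methylated")
  expect_equal(acr_methylation_status(lowm, "A01", 5000, 5100), "undefined")
})

test_that("sRNA clustering filters lengths, merges by gap, normalizes to RPM", {
  reads <- data.frame(chrom = "A01", start = c(100, 150, 190),
                      end = c(121, 171, 211), length = 21L)
  cl <- cluster_srna(reads, total_reads = 1e6, min_reads = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$rpm, 3)
  expect_equal(cl$dominant_length, 21L)
  # out-of-range lengths are removed
  bad <- rbind(reads, data.frame(chrom = "A01", start = 300, end = 335,
                                 length = 35L))
  expect_equal(sum(cluster_srna(bad, 1e6, min_reads = 1)$read_count), 3)
  # two reads 500 bp apart stay separate and die to min_reads = 5
  far <- data.frame(chrom = "A01", start = c(0, 500), end = c(21, 521),
                    length = 21L)
  expect_equal(nrow(cluster_srna(far, 1e6)), 0)
  expect_equal(nrow(cluster_srna(far, 1e6, min_reads = 1)), 2)
})

test_that("sRNA enrichment at DMRs detects planted shifts and flags thin data", {
  withr::local_seed(47)
  n <- 30
  dmrs <- data.frame(chrom = "A01", start = seq(0, by = 1000, length.out = n))
  dmrs$end <- dmrs$start + 200
  dmrs$direction <- "hyper"
  mk_clusters <- function(rpm) data.frame(chrom = "A01", start = dmrs$start + 10,
                                          end = dmrs$start + 100,
                                          read_count = 10, rpm = rpm)
  res <- dmr_srna_enrichment(dmrs, mk_clusters(rexp(n, 1)),
                             mk_clusters(2 + rexp(n, 1)))
  hyper <- res[res$direction == "hyper", ]
  expect_lt(hyper$p_value, 0.05)
  expect_equal(hyper$higher_in, "insilico")
  # no hypo DMRs: underpowered flag rather than a p-value
  hypo <- res[res$direction == "hypo", ]
  expect_true(hypo$underpowered)
  expect_true(is.na(hypo$p_value))
})

test_that("CX report IO round-trips", {
  calls <- mk_calls(c(5, 9), c(3, 0), c(2, 8), context = c("CG", "CHH"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cx_report(calls, f)
  back <- read_cx_report(f)
  expect_equal(back, calls)
})
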