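test_that("size factors implement median-of-ratios with sensible identities", {
  m <- matrix(rpois(40, 50) + 1, ncol = 4)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))
  doubled <- cbind(A = m[, 1], B = 2L * m[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # all-zero reference rows fall back to total-count scaling
  z <- matrix(c(0, 5, 10, 0), ncol = 2)
  expect_warning(sfz <- size_factors(z), "total-count")
  expect_equal(unname(sfz[2] / sfz[1]), 2)
})

test_that("size factors match the reference implementation on random tables", {
  skip_if_not_installed("DESeq2")
  withr::local_seed(61)
  counts <- matrix(rnbinom(500 * 6, mu = 80, size = 5), ncol = 6)
  counts[] <- as.integer(round(sweep(counts, 2, c(1, 1.5, 0.7, 1.2, 0.9, 1.1),
                                     "*")))
  expect_equal(unname(size_factors(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-8)
})

test_that("FPKM follows its closed form with a strict expressed bound", {
  expect_equal(compute_fpkm(matrix(10), 1000, 1e6)[1, 1], 10)
  expect_equal(compute_fpkm(matrix(0), 1000, 1e6)[1, 1], 0)
  expect_false(is_expressed(1.0))
  expect_true(is_expressed(1.0 + 1e-9))
  expect_error(compute_fpkm(matrix(1), 1000, 0), "library size")
})

test_that("in-silico hybrids are the 1:1 normalized parental mix", {
  m <- matrix(10, 1, 3); p <- matrix(20, 1, 3)
  expect_equal(as.vector(build_insilico_hybrid(m, p)), rep(15L, 3))
  # identical parents reproduce themselves
  expect_equal(as.vector(build_insilico_hybrid(m, m)), rep(10L, 3))
  # linearity in the inputs
  expect_equal(build_insilico_hybrid(2L * m, 2L * p)[1, ],
               2L * build_insilico_hybrid(m, p)[1, ])
  # signal conservation across genes
  withr::local_seed(71)
  M <- matrix(rpois(60, 100), ncol = 3)
  P <- matrix(rpois(60, 150), ncol = 3)
  ins <- build_insilico_hybrid(M, P)
  expect_equal(sum(ins), 0.5 * (sum(M) + sum(P)), tolerance = 0.005)
  expect_warning(build_insilico_hybrid(M, P[, 1:2]), "rank order")
})

test_that("additivity calls require both significance and the 1.5 fold bound", {
  withr::local_seed(83)
  n <- 400
  ins <- matrix(rnbinom(n * 3, mu = 100, size = 200), ncol = 3)
  hyb <- matrix(rnbinom(n * 3, mu = 100, size = 200), ncol = 3)
  hyb[1:30, ] <- matrix(rnbinom(90, mu = 800, size = 200), ncol = 3)  # 8x up
  hyb[31:60, ] <- matrix(rnbinom(90, mu = 50, size = 200), ncol = 3)  # 2x down
  res <- classify_additivity(hyb, ins)
  expect_true(all(res$additivity[1:30] == "nonadditive-up"))
  # a 2-fold shift misses the 1.5 log2 bound regardless of significance
  expect_true(all(res$additivity[31:60] == "additive"))
  expect_gt(mean(res$additivity[61:n] == "additive"), 0.95)
})

test_that("pattern classification separates transgressive, ELD and additive", {
  withr::local_seed(97)
  draw <- function(mu) matrix(rnbinom(length(mu) * 3, mu = rep(mu, 3),
                                      size = 50), ncol = 3)
  mu_m <- c(800, 100, 100, 800, 100)
  mu_p <- c(100, 800, 100, 100, 100)
  mu_h <- c(6400, 6400, 12, 100, 100)   # trans-up x2, trans-down, ELD-P low, null
  m <- draw(mu_m); p <- draw(mu_p); h <- draw(mu_h)
  mpv <- build_insilico_hybrid(m, p)
  add <- classify_additivity(h, mpv)
  pat <- classify_pattern(h, m, p, add$additivity)
  expect_equal(pat$pattern[1:3],
               c("transgressive-up", "transgressive-up", "transgressive-down"))
  # hybrid = low parent while parents differ: dominance of that parent
  expect_equal(pat$pattern[4], "ELD-P")
  # null gene: additive, never transgressive
  expect_equal(pat$pattern[5], "additive")
})

test_that("SPE calls need expression on one side and silence on the other", {
  m <- matrix(c(1.5, 2.0, 1.8), 1); p <- matrix(c(0, 0, 0.05), 1)
  h <- matrix(c(1.2, 1.4, 1.1), 1)
  expect_equal(call_spe(m, p, h, "A")$spe, "SPE-M")
  expect_equal(call_spe(p, m, h, "A")$spe, "SPE-P")
  # both parents expressed
  expect_equal(call_spe(m, m, h, "A")$spe, "none")
  # 0.5 is not silent under the 0.1 bound
  p2 <- matrix(c(0, 0.5, 0), 1)
  expect_equal(call_spe(m, p2, h, "A")$spe, "none")
  # C-subgenome genes are excluded with a reason
  res <- call_spe(m, p, h, "C")
  expect_equal(res$spe, "none")
  expect_equal(res$reason, "C-subgenome")
})

test_that("dosage vectors encode the AACC/AAC/AA copy fractions", {
  expect_equal(unname(dosage_vector("A")), c(1/2, 2/3, 1))
  expect_equal(unname(dosage_vector("C")), c(1/2, 1/3, 0))
})

test_that("dosage dependence recovers linear dosage response at 5% noise", {
  withr::local_seed(103)
  n <- 200
  dv <- dosage_vector("A")
  scale <- runif(n, 50, 500)
  mk <- function(mu, sd) matrix(rnorm(n * 3, rep(mu, 3), rep(sd, 3)), ncol = 3)
  dep_m <- mk(scale * dv[1], 0.05 * scale)
  dep_h <- mk(scale * dv[2], 0.05 * scale)
  dep_p <- mk(scale * dv[3], 0.05 * scale)
  flat_m <- mk(scale, 0.05 * scale); flat_h <- mk(scale, 0.05 * scale)
  flat_p <- mk(scale, 0.05 * scale)
  res <- dosage_dependence(rbind(dep_m, flat_m), rbind(dep_h, flat_h),
                           rbind(dep_p, flat_p), rep("A", 2 * n))
  expect_gt(mean(res$dosage[1:n] == "dependent"), 0.95)
  expect_lt(mean(res$dosage[(n + 1):(2 * n)] == "dependent"), 0.05)
  # constant expression is independent, not an error
  con <- dosage_dependence(matrix(5, 1, 3), matrix(5, 1, 3), matrix(5, 1, 3),
                           "A")
  expect_equal(con$dosage, "independent")
})

test_that("the worked dosage example is labeled dependent", {
  res <- dosage_dependence(matrix(1.72, 1, 1), matrix(1.96, 1, 1),
                           matrix(2.54, 1, 1), "A", mode = "genotype-mean")
  expect_equal(res$r, 0.99, tolerance = 0.011)
  expect_true(res$r_squared > 0.64)
  expect_equal(res$dosage, "dependent")
})

test_that("homolog categories cross the A and C dosage labels", {
  labs <- c(a1 = "dependent", a2 = "independent", c1 = "dependent",
            c2 = "independent")
  pairs <- data.frame(a_gene = c("a1", "a1", "a2", "a2", "a1"),
                      c_gene = c("c1", "c2", "c1", "c2", "zz"))
  expect_message(res <- homolog_categories(labs, pairs), "skipped")
  expect_equal(res$category, c("AdCd", "AdCi", "AiCd", "AiCi"))
  expect_equal(nrow(res), 4)
})
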