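test_that("BH adjustment matches the step-up definition and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.2, 1.4)), "0,1")
  withr::local_seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), bf_bh(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
  # adjusted sequence is non-decreasing in the sorted order
  p <- sort(runif(100))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("Pearson correlation reproduces the dosage worked example", {
  res <- pearson_cor(c(1/2, 2/3, 1), c(1.72, 1.96, 2.54))
  expect_equal(res$r, 0.99, tolerance = 0.011)
  expect_equal(res$r_squared, 0.99, tolerance = 0.011)
  expect_true(res$r_squared > 0.64)
  # exact linear relation and degenerate input
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1)$r, 1)
  expect_true(pearson_cor(1:5, rep(3, 5))$undefined)
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("Pearson correlation is symmetric and scale/shift invariant", {
  withr::local_seed(19)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_cor(x, y)$r, pearson_cor(y, x)$r)
  expect_equal(pearson_cor(3 * x + 2, y)$r, pearson_cor(x, y)$r)
  expect_equal(pearson_cor(-3 * x + 2, y)$r, -pearson_cor(x, y)$r)
})

test_that("Fisher exact matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)$p_value, 2 / choose(20, 10))
  expect_equal(fisher_exact_2x2(17, 3, 10, 10)$p_value,
               bf_fisher_p(17, 3, 10, 10), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
  # empty margin: no information, p = 1
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p_value, 1)
  # symmetry under simultaneous row and column swap
  expect_equal(fisher_exact_2x2(7, 2, 3, 9)$p_value,
               fisher_exact_2x2(9, 3, 2, 7)$p_value)
  # Haldane-corrected odds ratio with a zero cell
  expect_equal(fisher_exact_2x2(5, 0, 2, 6)$odds_ratio,
               (5.5 * 6.5) / (0.5 * 2.5))
})

test_that("rank tests dispatch to Wilcoxon or Kruskal-Wallis", {
  expect_equal(rank_tests(list(c(1, 2, 3), c(1.5, 2.5, 3.5)))$test, "wilcoxon")
  # exact two-sided tail for fully separated n=3 vs 3 is 2/20
  r <- rank_tests(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, bf_wilcox_p(c(1, 2, 3), c(10, 11, 12)))
  k <- rank_tests(list(1:5, 2:6, 3:7))
  expect_equal(k$test, "kruskal")
  expect_equal(k$p_value,
               kruskal.test(list(1:5, 2:6, 3:7))$p.value)
  expect_error(rank_tests(list(1:3, numeric(0))), "empty")
  expect_error(rank_tests(list(1:3)), ">= 2 groups")
})

test_that("Kruskal-Wallis holds its nominal size on null data", {
  withr::local_seed(101)
  reject <- vapply(1:400, function(i) {
    g <- split(rnorm(90), rep(1:3, each = 30))
    rank_tests(unname(g))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.08)
})

test_that("NB test contracts: null case, degenerate zeros, antisymmetry", {
  r <- nb_two_group_test(c(10, 12, 11), c(10, 11, 12))
  expect_lt(abs(r$log2FC), 0.2)
  expect_gt(r$p_value, 0.5)
  z <- nb_two_group_test(c(0, 0, 0), c(0, 0, 0))
  expect_equal(z$log2FC, 0)
  expect_equal(z$p_value, 1)
  withr::local_seed(5)
  a <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 3)
  b <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 3)
  ab <- nb_two_group_test(a, b)
  ba <- nb_two_group_test(b, a)
  expect_equal(ab$log2FC, -ba$log2FC)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("NB test finds large planted effects after BH", {
  withr::local_seed(17)
  a <- matrix(rnbinom(3000, mu = 100, size = 10), ncol = 3)
  b <- matrix(rnbinom(3000, mu = 100, size = 10), ncol = 3)
  b[1:50, ] <- matrix(rnbinom(150, mu = 800, size = 10), ncol = 3)
  res <- nb_two_group_test(a, b)
  padj <- bh_adjust(res$p_value)
  expect_gt(mean(padj[1:50] < 0.05 & res$log2FC[1:50] > 1.5), 0.9)
  expect_lt(mean(padj[-(1:50)] < 0.05), 0.01)
})

test_that("fuzzy c-means satisfies its algebraic and convergence contracts", {
  withr::local_seed(31)
  blob1 <- matrix(rnorm(150, mean = rep(c(0, 0, 6), each = 50), sd = 0.5),
                  ncol = 3)
  blob2 <- matrix(rnorm(150, mean = rep(c(6, 0, 0), each = 50), sd = 0.5),
                  ncol = 3)
  x <- rbind(blob1, blob2)
  fit <- fuzzy_cmeans(x, k = 2, seed = 9)
  expect_equal(rowSums(fit$membership), rep(1, nrow(x)))
  expect_true(all(fit$membership >= 0))
  expect_true(all(diff(fit$objective) <= 1e-8))
  # well-separated blobs: confident membership in the generating blob
  top <- apply(fit$membership, 1, max)
  grp <- max.col(fit$membership)
  expect_gt(mean(top > 0.9), 0.95)
  expect_equal(length(unique(grp[1:50])), 1)
  expect_equal(length(unique(grp[51:100])), 1)
  expect_true(grp[1] != grp[51])
  # determinism for a fixed seed
  fit2 <- fuzzy_cmeans(x, k = 2, seed = 9)
  expect_identical(fit$membership, fit2$membership)
  # k = 9 labels clusters C1..C9
  y <- matrix(rnorm(100 * 5), 100)
  f9 <- fuzzy_cmeans(y, k = 9, seed = 2)
  expect_setequal(rownames(f9$centers), paste0("C", 1:9))
  # constant rows are dropped with a warning
  y[3, ] <- 1
  expect_warning(fd <- fuzzy_cmeans(y, k = 2, seed = 2), "constant")
  expect_equal(fd$dropped, 3L)
})

test_that("fuzzy c-means memberships agree with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::local_seed(41)
  x <- rbind(matrix(rnorm(90, 0), ncol = 3),
             matrix(rnorm(90, 4), ncol = 3))
  mine <- fuzzy_cmeans(x, k = 2, seed = 1, tol = 1e-8)
  z <- t(scale(t(x)))
  ref <- e1071::cmeans(z, centers = 2, m = 2)
  # same hard partition up to cluster relabeling
  a <- max.col(mine$membership)
  b <- as.integer(ref$cluster)
  agree <- max(mean(a == b), mean(a == 3 - b))
  expect_gt(agree, 0.97)
})
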