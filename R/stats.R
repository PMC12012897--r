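# ---- statistical kernel -----------------------------------------------------
# Thin, contract-checked wrappers around base R tests where base R already
# provides the textbook procedure (BH, Fisher exact, rank tests, Pearson),
# plus two procedures authored here: a simplified negative-binomial Wald test
# for replicated count data and Bezdek fuzzy c-means.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment, returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be in [0,1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation with a two-sided p-value from the t distribution
#' on `n - 2` degrees of freedom. Zero-variance input yields an undefined
#' correlation (`r = NA`) rather than an error; with `n = 3` the single degree
#' of freedom is used as-is, without small-sample correction.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, `r_squared`, `p_value`, `n`, `undefined`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                n = n, undefined = TRUE))
  r <- cor(x, y)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, r_squared = r^2, p_value = p, n = n, undefined = FALSE)
}

#' Spearman correlation
#'
#' Pearson correlation of midranks, with the same t-based p-value as
#' [pearson_cor()].
#'
#' @inheritParams pearson_cor
#' @return list as in [pearson_cor()] (`r` is rho).
#' @export
spearman_cor <- function(x, y) {
  pearson_cor(rank(x), rank(y))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p (sum of tables at fixed margins with
#' probability not exceeding the observed one). The odds-ratio statistic uses
#' the Haldane 0.5 correction when any cell is zero.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`a`,`b` = group 1; `c`,`d` = group 2).
#' @return list with `p_value`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell", call. = FALSE)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p_value = 1, odds_ratio = NA_real_))
  p <- fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  or <- if (any(cells == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  list(p_value = min(1, p), odds_ratio = or)
}

#' Rank-based group comparison
#'
#' For two groups, the Wilcoxon rank-sum test (exact when both groups have at
#' most 25 observations and no ties, otherwise the normal approximation with
#' tie and continuity correction); for three or more groups, the
#' Kruskal-Wallis H test with its chi-square p-value. Ties receive midranks.
#'
#' @param groups list of non-empty numeric vectors (length >= 2).
#' @return list with `statistic`, `p_value`, `test` (`"wilcoxon"` or
#'   `"kruskal"`).
#' @export
rank_tests <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0))
    stop("empty group", call. = FALSE)
  if (length(groups) == 2) {
    exact <- all(lengths(groups) <= 25) &&
      !any(duplicated(unlist(groups)))
    ht <- suppressWarnings(
      wilcox.test(groups[[1]], groups[[2]], exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "wilcoxon")
  } else {
    x <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ht <- kruskal.test(x, g)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "kruskal")
  }
}

# ---- negative-binomial two-group Wald test ----------------------------------

# Method-of-moments dispersion shrunk toward a fitted mean-dispersion trend
# a0 + a1/mu (weights: residual df versus NB_PRIOR_DF pseudo-observations).
# At 3 replicates the per-feature moment estimate is too noisy to use alone;
# the shrinkage both stabilizes it and buys the extra degrees of freedom the
# Wald t reference assumes.
NB_PRIOR_DF <- 10

.nb_dispersion <- function(norm_a, norm_b, sf_a, sf_b) {
  n_a <- ncol(norm_a); n_b <- ncol(norm_b)
  mu_a <- rowMeans(norm_a); mu_b <- rowMeans(norm_b)
  mu <- (n_a * mu_a + n_b * mu_b) / (n_a + n_b)
  v_a <- apply(norm_a, 1, var); v_b <- apply(norm_b, 1, var)
  v <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
  # moment estimate: Var(K/s) = mu/s + alpha mu^2 -> subtract mean Poisson part
  pois <- (mu_a * mean(1 / sf_a) * (n_a - 1) + mu_b * mean(1 / sf_b) * (n_b - 1)) /
    (n_a + n_b - 2)
  raw <- (v - pois) / mu^2
  raw[!is.finite(raw)] <- NA
  ok <- which(!is.na(raw) & mu > 0)
  a0 <- 0.01; a1 <- 1
  if (length(ok) >= 50) {
    # robust trend: medians of the moment estimates within log-mean bins,
    # so features with large true differences cannot drag the fit
    bins <- cut(log(mu[ok]), breaks = 12)
    med <- tapply(pmax(raw[ok], 0), bins, median)
    mid <- tapply(mu[ok], bins, median)
    use <- !is.na(med) & tabulate(bins)[seq_along(med)] >= 5
    if (sum(use) >= 3) {
      fit <- try(lm(med[use] ~ I(1 / mid[use])), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        a0 <- max(coef(fit)[1], 1e-3)
        a1 <- max(coef(fit)[2], 0)
      }
    }
  }
  trend <- a0 + a1 / pmax(mu, 1e-8)
  rawp <- pmax(raw, 0)
  rawp[is.na(rawp)] <- trend[is.na(rawp)]
  df_res <- n_a + n_b - 2
  pmax((df_res * rawp + NB_PRIOR_DF * trend) / (df_res + NB_PRIOR_DF), 1e-8)
}

#' Negative-binomial two-group Wald test
#'
#' A simplified replicated-count test: counts are normalized by the supplied
#' size factors; per-feature dispersion is estimated by method of moments and
#' shrunk toward a fitted mean-dispersion trend (10 pseudo-observations); the
#' Wald statistic is the log2 fold change of group means (pseudocount 0.5)
#' over its delta-method standard error, referred to the t distribution with
#' the residual-plus-prior degrees of freedom. The log2 fold change is `b`
#' over `a`. Features with zero counts in both groups return `p = 1`,
#' `log2FC = 0`.
#'
#' @param counts_a,counts_b matrices (features x replicates) of raw counts;
#'   vectors are treated as a single feature.
#' @param sf_a,sf_b positive size factors, one per replicate column.
#' @return data frame with `baseMean`, `log2FC`, `stat`, `p_value`.
#' @export
nb_two_group_test <- function(counts_a, counts_b,
                              sf_a = rep(1, ncol(counts_a)),
                              sf_b = rep(1, ncol(counts_b))) {
  if (is.vector(counts_a)) counts_a <- matrix(counts_a, nrow = 1)
  if (is.vector(counts_b)) counts_b <- matrix(counts_b, nrow = 1)
  stopifnot(nrow(counts_a) == nrow(counts_b), all(sf_a > 0), all(sf_b > 0))
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)
  norm_a <- sweep(counts_a, 2, sf_a, "/")
  norm_b <- sweep(counts_b, 2, sf_b, "/")
  mu_a <- rowMeans(norm_a); mu_b <- rowMeans(norm_b)
  disp <- .nb_dispersion(norm_a, norm_b, sf_a, sf_b)
  lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  # delta-method variance of log2(mean + 0.5) per group
  var_mean_a <- (mu_a * mean(1 / sf_a) + disp * mu_a^2) / n_a
  var_mean_b <- (mu_b * mean(1 / sf_b) + disp * mu_b^2) / n_b
  se <- sqrt(var_mean_a / (mu_a + 0.5)^2 + var_mean_b / (mu_b + 0.5)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  df <- n_a + n_b - 2 + NB_PRIOR_DF
  p <- 2 * pt(-abs(stat), df = df)
  zero <- (rowSums(counts_a) + rowSums(counts_b)) == 0
  lfc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
  data.frame(baseMean = (n_a * mu_a + n_b * mu_b) / (n_a + n_b),
             log2FC = lfc, stat = stat, p_value = pmin(1, p))
}

# ---- fuzzy c-means ----------------------------------------------------------

#' Bezdek fuzzy c-means clustering
#'
#' Standard fuzzy c-means on row-wise z-scored profiles: memberships and
#' centers are alternated until the maximum center shift falls below `tol`.
#' Constant rows (zero variance) cannot be z-scored and are dropped with a
#' warning. The objective function is recorded at every iteration and is
#' non-increasing; runs are deterministic for a fixed seed.
#'
#' @param profiles numeric matrix, items x features.
#' @param k number of clusters (>= 2); cluster labels are `C1 ... Ck`.
#' @param m fuzzifier (> 1, default 2).
#' @param seed integer seed for the membership initialization.
#' @param tol convergence tolerance on the center shift (default 1e-5).
#' @param max_iter iteration cap (default 300).
#' @return list with `membership` (items x k, rows sum to 1), `centers`,
#'   `cluster` (hard assignment `C1...Ck`), `objective` (per-iteration trace),
#'   `dropped` (row names/indices of constant rows).
#' @export
fuzzy_cmeans <- function(profiles, k, m = 2, seed = 1L, tol = 1e-5,
                         max_iter = 300L) {
  stopifnot(k >= 2, m > 1)
  profiles <- as.matrix(profiles)
  rs <- apply(profiles, 1, sd)
  dropped <- which(rs == 0 | is.na(rs))
  if (length(dropped)) {
    warning(length(dropped), " constant profile(s) dropped before z-scoring")
    profiles <- profiles[-dropped, , drop = FALSE]
  }
  if (nrow(profiles) < k) stop("fewer items than clusters", call. = FALSE)
  x <- t(scale(t(profiles)))
  n <- nrow(x)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  u <- matrix(runif(n * k), n, k)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv())
  u <- u / rowSums(u)
  centers <- matrix(0, k, ncol(x))
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers_new <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rowSums(centers_new^2), "+") -
      2 * x %*% t(centers_new)
    d2 <- pmax(d2, 1e-12)
    objective <- c(objective, sum(um * d2))
    u <- 1 / (d2^(1 / (m - 1)) * rowSums((1 / d2)^(1 / (m - 1))))
    shift <- max(abs(centers_new - centers))
    centers <- centers_new
    if (shift < tol) break
  }
  rownames(centers) <- paste0("C", seq_len(k))
  hard <- paste0("C", max.col(u, ties.method = "first"))
  list(membership = u, centers = centers, cluster = hard,
       objective = objective, dropped = dropped)
}
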