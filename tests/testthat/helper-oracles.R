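# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

# per-base covered fraction of one region
bf_overlap_fraction <- function(region, feats) {
  if (nrow(feats) == 0) return(0)
  bases <- seq(region$start, region$end - 1L)
  covered <- vapply(bases, function(b)
    any(feats$chrom == region$chrom & feats$start <= b & b < feats$end),
    logical(1))
  mean(covered)
}

# per-base positional class of one region
bf_classify_position <- function(region, genes, w) {
  bases <- seq(region$start, region$end - 1L)
  hit <- function(s, e) any(vapply(bases, function(b)
    any(genes$chrom == region$chrom & s <= b & b < e), logical(1)))
  if (nrow(genes) && hit(genes$start, genes$end)) return("genic")
  if (nrow(genes) && hit(genes$start - w, genes$end + w)) return("proximal")
  "distal"
}

# textbook BH step-up, loop form
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- prev
  }
  adj
}

# full enumeration of 2x2 tables at fixed margins
bf_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) dhyper(x, r1, r2, c1), numeric(1))
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided Wilcoxon rank-sum by full enumeration (no ties)
bf_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  w_obs <- sum(rank(pooled)[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  ws <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

random_intervals <- function(n, chrom = "A01", max_pos = 10000L,
                            max_len = 500L) {
  s <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = rep(chrom, n), start = s,
             end = s + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
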