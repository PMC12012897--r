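# ---- expression genetics of the allotriploid hybrid -------------------------
# Count matrices are genes x samples with a sample manifest giving each
# column's role (maternal / paternal / hybrid / insilico) and replicate id.

#' Median-of-ratios size factors
#'
#' Geometric-mean reference per gene; each sample's factor is the median of
#' its count ratios over genes with a nonzero reference. When no gene is
#' nonzero in every sample the function falls back to total-count scaling
#' (factors proportional to column sums, geometric mean 1) with a warning.
#'
#' @param counts genes x samples matrix of raw counts.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no gene with nonzero counts in all samples; using total-count scaling")
    cs <- colSums(counts)
    if (any(cs == 0)) stop("sample with zero total counts", call. = FALSE)
    return(cs / exp(mean(log(cs))))
  }
  logref <- rowMeans(log(counts[ok, , drop = FALSE]))
  apply(counts[ok, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logref)))
}

#' FPKM normalization
#'
#' `FPKM = count * 1e9 / (gene_length_bp * library_size)`. A gene is called
#' expressed when FPKM is strictly greater than 1.
#'
#' @param counts genes x samples matrix.
#' @param gene_lengths bp lengths, one per gene row.
#' @param library_sizes optional per-sample library sizes (default: column
#'   sums of `counts`); must be positive.
#' @return matrix of FPKM values with the dimensions of `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
  if (any(library_sizes <= 0)) stop("zero library size", call. = FALSE)
  sweep(counts * 1e9 / gene_lengths, 2, library_sizes, "/")
}

#' Expressed-gene mask
#'
#' @param fpkm FPKM matrix or vector.
#' @param threshold expression bound (default 1; strict `>`).
#' @return logical of the same shape.
#' @export
is_expressed <- function(fpkm, threshold = 1) fpkm > threshold

#' Build in-silico mid-parent hybrids
#'
#' Combines parental RNA-seq replicates 1:1: replicate `i` of the in-silico
#' hybrid is `round(0.5 * (maternal_i / sf_m + paternal_i / sf_p))` per gene,
#' i.e. the mid-parent value on the normalized scale, re-rounded to integer
#' counts so downstream count tests apply. The number of in-silico replicates
#' is the smaller parental replicate count; unequal replicate sets are paired
#' by rank order with a warning.
#'
#' @param maternal_counts,paternal_counts genes x replicates matrices.
#' @param sf_m,sf_p size factors for the parental columns (default 1).
#' @param weight maternal weight in the mix (default 0.5 = the 1:1 rule);
#'   exposed for sensitivity analysis.
#' @return genes x replicates integer matrix of in-silico counts.
#' @export
build_insilico_hybrid <- function(maternal_counts, paternal_counts,
                                  sf_m = rep(1, ncol(maternal_counts)),
                                  sf_p = rep(1, ncol(paternal_counts)),
                                  weight = 0.5) {
  maternal_counts <- as.matrix(maternal_counts)
  paternal_counts <- as.matrix(paternal_counts)
  stopifnot(nrow(maternal_counts) == nrow(paternal_counts))
  n <- min(ncol(maternal_counts), ncol(paternal_counts))
  if (ncol(maternal_counts) != ncol(paternal_counts))
    warning("unequal parental replicate counts; pairing by rank order")
  m <- sweep(maternal_counts[, seq_len(n), drop = FALSE], 2, sf_m[seq_len(n)], "/")
  p <- sweep(paternal_counts[, seq_len(n), drop = FALSE], 2, sf_p[seq_len(n)], "/")
  out <- round(weight * m + (1 - weight) * p)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(rownames(maternal_counts),
                        paste0("insilico_", seq_len(n)))
  out
}

# internal: per-gene DE call table from two count matrices
.de_table <- function(counts_a, counts_b, sf_a, sf_b, alpha, lfc_min) {
  res <- nb_two_group_test(counts_a, counts_b, sf_a, sf_b)
  res$adjusted_p <- bh_adjust(res$p_value)
  res$de <- res$adjusted_p < alpha & abs(res$log2FC) >= lfc_min
  res
}

#' Additive versus non-additive expression
#'
#' Tests each gene's F1 hybrid counts against the in-silico mid-parent hybrid
#' with the negative-binomial Wald test and BH adjustment. Genes with adjusted
#' p below `alpha` and `|log2FC| >= lfc_min` are non-additive (up when the
#' hybrid exceeds the mid-parent value); all others are additive.
#'
#' @param hybrid_counts,insilico_counts genes x replicates matrices.
#' @param sf_h,sf_i size factors per column.
#' @param alpha significance level (default 0.05).
#' @param lfc_min log2 fold-change bound (default 1.5).
#' @return data frame with `log2FC` (hybrid over mid-parent), `p_value`,
#'   `adjusted_p`, and `additivity` in
#'   `{additive, nonadditive-up, nonadditive-down}`.
#' @export
classify_additivity <- function(hybrid_counts, insilico_counts,
                                sf_h = rep(1, ncol(hybrid_counts)),
                                sf_i = rep(1, ncol(insilico_counts)),
                                alpha = 0.05, lfc_min = 1.5) {
  res <- .de_table(insilico_counts, hybrid_counts, sf_i, sf_h, alpha, lfc_min)
  res$additivity <- ifelse(!res$de, "additive",
                           ifelse(res$log2FC > 0, "nonadditive-up",
                                  "nonadditive-down"))
  rownames(res) <- rownames(hybrid_counts)
  res[c("log2FC", "p_value", "adjusted_p", "additivity")]
}

#' Expression-pattern classification (ELD / transgressive)
#'
#' Partitions genes by the hybrid's position relative to its parents, using
#' the differential-expression rule (adjusted p < `alpha`,
#' `|log2FC| >= lfc_deg`) for the hybrid-parent and parent-parent contrasts:
#' *transgressive-up* (hybrid significantly above both parents),
#' *transgressive-down* (below both), *ELD-M* (hybrid indistinguishable from
#' the maternal parent while parents differ), *ELD-P* (symmetric), *additive*
#' (non-differential versus the mid-parent hybrid, from `additivity`), and
#' *other*. Precedence: additive, then transgressive, then ELD.
#'
#' @param hybrid,maternal,paternal genes x replicates count matrices.
#' @param additivity character vector from [classify_additivity()].
#' @param sf_h,sf_m,sf_p size factors per column.
#' @param alpha significance level (default 0.05).
#' @param lfc_deg log2 fold-change bound of the DEG rule (default 2).
#' @return data frame with the three contrasts' log2FCs and `pattern`.
#' @export
classify_pattern <- function(hybrid, maternal, paternal, additivity,
                             sf_h = rep(1, ncol(hybrid)),
                             sf_m = rep(1, ncol(maternal)),
                             sf_p = rep(1, ncol(paternal)),
                             alpha = 0.05, lfc_deg = 2) {
  hm <- .de_table(maternal, hybrid, sf_m, sf_h, alpha, lfc_deg)  # lfc: H over M
  hp <- .de_table(paternal, hybrid, sf_p, sf_h, alpha, lfc_deg)  # lfc: H over P
  mp <- .de_table(paternal, maternal, sf_p, sf_m, alpha, lfc_deg) # lfc: M over P
  up_m <- hm$de & hm$log2FC > 0; down_m <- hm$de & hm$log2FC < 0
  up_p <- hp$de & hp$log2FC > 0; down_p <- hp$de & hp$log2FC < 0
  parents_differ <- mp$de
  pattern <- rep("other", nrow(hm))
  pattern[!hp$de & hm$de & parents_differ] <- "ELD-P"
  pattern[!hm$de & hp$de & parents_differ] <- "ELD-M"
  pattern[up_m & up_p] <- "transgressive-up"
  pattern[down_m & down_p] <- "transgressive-down"
  pattern[additivity == "additive"] <- "additive"
  data.frame(lfc_h_vs_m = hm$log2FC, lfc_h_vs_p = hp$log2FC,
             lfc_m_vs_p = mp$log2FC, pattern = pattern,
             row.names = rownames(hybrid))
}

#' Single-parental expression (SPE)
#'
#' A gene shows SPE when it is expressed (FPKM > `expressed_threshold` in
#' every replicate) in one parent and in the hybrid while the other parent is
#' silent (FPKM < `silent_threshold` in every replicate). Because the paternal
#' line carries no C subgenome, SPE is defined only for A-subgenome genes;
#' C-subgenome genes receive `none` with reason `C-subgenome`.
#'
#' @param fpkm_m,fpkm_p,fpkm_h genes x replicates FPKM matrices
#'   (maternal, paternal, hybrid).
#' @param subgenome per-gene `"A"`/`"C"` labels.
#' @param expressed_threshold FPKM bound for "expressed" (default 1, strict >).
#' @param silent_threshold FPKM bound for "silent" (default 0.1, strict <).
#' @return data frame with `spe` in `{SPE-M, SPE-P, none}` and `reason`.
#' @export
call_spe <- function(fpkm_m, fpkm_p, fpkm_h, subgenome,
                     expressed_threshold = 1, silent_threshold = 0.1) {
  expr_m <- rowSums(fpkm_m > expressed_threshold) == ncol(fpkm_m)
  expr_p <- rowSums(fpkm_p > expressed_threshold) == ncol(fpkm_p)
  expr_h <- rowSums(fpkm_h > expressed_threshold) == ncol(fpkm_h)
  sil_m <- rowSums(fpkm_m < silent_threshold) == ncol(fpkm_m)
  sil_p <- rowSums(fpkm_p < silent_threshold) == ncol(fpkm_p)
  spe <- rep("none", nrow(fpkm_m))
  reason <- rep("", nrow(fpkm_m))
  spe[expr_m & sil_p & expr_h] <- "SPE-M"
  spe[expr_p & sil_m & expr_h] <- "SPE-P"
  isC <- subgenome == "C"
  reason[isC & spe != "none"] <- "C-subgenome"
  spe[isC] <- "none"
  data.frame(spe = spe, reason = reason, row.names = rownames(fpkm_m))
}

#' Subgenome dosage vectors
#'
#' Relative subgenome copy fraction per genotype, ordered
#' (maternal AACC, hybrid AAC, paternal AA): A subgenome `(1/2, 2/3, 1)`,
#' C subgenome `(1/2, 1/3, 0)`.
#'
#' @param subgenome `"A"` or `"C"`.
#' @return numeric length-3 vector.
#' @export
dosage_vector <- function(subgenome) {
  switch(match.arg(subgenome, c("A", "C")),
         A = c(maternal = 1/2, hybrid = 2/3, paternal = 1),
         C = c(maternal = 1/2, hybrid = 1/3, paternal = 0))
}

#' Dosage dependence of gene expression
#'
#' Pearson-correlates each gene's expression with its subgenome dosage vector
#' and classifies the gene as dosage-*dependent* when `r^2 > r2_min` (strict)
#' and the BH-adjusted p-value is below `alpha`, otherwise *independent*.
#' Genes with zero expression variance are independent. By default the
#' correlation uses replicate-level expression (the dosage value of each
#' genotype repeated across its replicates); `mode = "genotype-mean"` uses the
#' three per-genotype means instead (a single degree of freedom).
#'
#' @param expr_m,expr_h,expr_p genes x replicates expression (FPKM) matrices
#'   for maternal, hybrid, paternal samples.
#' @param subgenome per-gene `"A"`/`"C"` labels.
#' @param r2_min squared-correlation bound (default 0.64).
#' @param alpha FDR level (default 0.05).
#' @param mode `"replicate"` (default) or `"genotype-mean"`.
#' @return data frame with `r`, `r_squared`, `p_value`, `adjusted_p`,
#'   `dosage` in `{dependent, independent}`.
#' @export
dosage_dependence <- function(expr_m, expr_h, expr_p, subgenome,
                              r2_min = 0.64, alpha = 0.05,
                              mode = c("replicate", "genotype-mean")) {
  mode <- match.arg(mode)
  stopifnot(nrow(expr_m) == nrow(expr_h), nrow(expr_m) == nrow(expr_p),
            length(subgenome) == nrow(expr_m))
  n <- nrow(expr_m)
  r <- rep(NA_real_, n); p <- rep(NA_real_, n)
  for (sg in c("A", "C")) {
    idx <- which(subgenome == sg)
    if (!length(idx)) next
    dv <- dosage_vector(sg)
    for (i in idx) {
      if (mode == "replicate") {
        x <- c(rep(dv[1], ncol(expr_m)), rep(dv[2], ncol(expr_h)),
               rep(dv[3], ncol(expr_p)))
        y <- c(expr_m[i, ], expr_h[i, ], expr_p[i, ])
      } else {
        x <- dv
        y <- c(mean(expr_m[i, ]), mean(expr_h[i, ]), mean(expr_p[i, ]))
      }
      res <- pearson_cor(x, y)
      r[i] <- res$r; p[i] <- res$p_value
    }
  }
  padj <- rep(NA_real_, n)
  ok <- !is.na(p)
  padj[ok] <- bh_adjust(p[ok])
  dep <- !is.na(r) & r^2 > r2_min & !is.na(padj) & padj < alpha
  data.frame(r = r, r_squared = r^2, p_value = p, adjusted_p = padj,
             dosage = ifelse(dep, "dependent", "independent"),
             row.names = rownames(expr_m))
}

#' Homolog-pair dosage categories
#'
#' Crosses the dosage labels of the A and C members of each homologous pair
#' into `AdCd`, `AdCi`, `AiCd`, `AiCi`. Pairs referencing unclassified genes
#' are skipped; genes without a partner can be summarized separately as
#' genome-unique.
#'
#' @param dosage_labels named character vector (`dependent`/`independent`),
#'   names are gene ids.
#' @param pairs data frame with columns `a_gene`, `c_gene`.
#' @return data frame `a_gene`, `c_gene`, `category`.
#' @export
homolog_categories <- function(dosage_labels, pairs) {
  a <- dosage_labels[pairs$a_gene]
  c_ <- dosage_labels[pairs$c_gene]
  keep <- !is.na(a) & !is.na(c_)
  if (!all(keep)) message(sum(!keep), " pair(s) skipped: unclassified gene")
  code <- function(z) ifelse(z == "dependent", "d", "i")
  data.frame(a_gene = pairs$a_gene[keep], c_gene = pairs$c_gene[keep],
             category = paste0("A", code(a[keep]), "C", code(c_[keep])),
             stringsAsFactors = FALSE)
}
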