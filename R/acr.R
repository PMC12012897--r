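# ---- accessible chromatin regions -------------------------------------------
# Per-replicate MACS-style peaks (BED intervals with a read-count score) are
# merged into replicate-consistent ACRs, quantified, and categorized.

#' Merge replicate peaks into consensus ACRs
#'
#' A genomic location becomes an ACR when peaks from at least `min_replicates`
#' distinct replicates are connected by pairwise overlaps strictly longer
#' than `min_overlap_bp`; the ACR interval is the union of the supporting
#' peaks. Per-replicate read counts of the supporting peaks are summed onto
#' the ACR (replicates without a supporting peak contribute 0).
#'
#' @param replicates named list of peak tables (`chrom`, `start`, `end`,
#'   `count`), one per replicate.
#' @param min_overlap_bp overlap bound in bp (default 50; strict `>`).
#' @param min_replicates replicate support needed (default 2).
#' @return ACR table: `chrom`, `start`, `end`, `n_replicates`, one
#'   `reads_<replicate>` column per replicate.
#' @export
merge_replicate_peaks <- function(replicates, min_overlap_bp = 50L,
                                  min_replicates = 2L) {
  if (length(replicates) < 2)
    stop("need >= 2 replicates; for single-replicate data pass peaks through unmerged",
         call. = FALSE)
  if (is.null(names(replicates)))
    names(replicates) <- paste0("rep", seq_along(replicates))
  peaks <- do.call(rbind, lapply(names(replicates), function(r) {
    df <- replicates[[r]]
    validate_intervals(df, paste0("peaks[", r, "]"))
    if (!"count" %in% names(df)) df$count <- NA_real_
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               count = df$count, replicate = r, stringsAsFactors = FALSE)
  }))
  if (nrow(peaks) == 0) return(.empty_acrs(names(replicates)))
  gr <- .df2gr(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE,
                                      minoverlap = as.integer(min_overlap_bp) + 1L)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s & peaks$replicate[q] != peaks$replicate[s]
  # union-find over qualifying cross-replicate overlap edges
  comp <- seq_len(nrow(peaks))
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (e in which(keep)) {
    a <- find(q[e]); b <- find(s[e])
    if (a != b) comp[min(a, b)] <- comp[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_along(comp), find, 1L)
  linked <- comp %in% comp[q[keep]] | comp %in% comp[s[keep]]
  out <- lapply(split(which(linked), comp[linked]), function(idx) {
    reps <- unique(peaks$replicate[idx])
    if (length(reps) < min_replicates) return(NULL)
    row <- data.frame(chrom = peaks$chrom[idx[1]],
                      start = min(peaks$start[idx]),
                      end = max(peaks$end[idx]),
                      n_replicates = length(reps),
                      stringsAsFactors = FALSE)
    for (r in names(replicates))
      row[[paste0("reads_", r)]] <-
        sum(peaks$count[idx][peaks$replicate[idx] == r], na.rm = TRUE)
    row
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(.empty_acrs(names(replicates)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_acrs <- function(rep_names) {
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    n_replicates = integer(0))
  for (r in rep_names) out[[paste0("reads_", r)]] <- numeric(0)
  out
}

#' Novel / silent ACR call
#'
#' *Novel*: supported in the F1 hybrid (every hybrid replicate has at least
#' `min_reads` raw reads) with exact zeros in every replicate of both
#' parents. *Silent*: the mirror image (every parental replicate of both
#' parents at or above `min_reads`, every hybrid replicate exactly 0).
#' The zero side is tested on raw counts: a normalized zero is only ever a
#' true zero.
#'
#' @param hybrid_reads numeric vector of per-replicate hybrid reads.
#' @param maternal_reads,paternal_reads per-replicate reads of the parents.
#' @param min_reads read-support bound (default 5).
#' @return one of `"novel"`, `"silent"`, `"neither"`.
#' @export
call_novel_silent <- function(hybrid_reads, maternal_reads, paternal_reads,
                              min_reads = 5) {
  if (is.null(maternal_reads) || is.null(paternal_reads))
    stop("both parental samples are required", call. = FALSE)
  parents <- c(maternal_reads, paternal_reads)
  if (all(hybrid_reads >= min_reads) && all(parents == 0)) return("novel")
  if (all(parents >= min_reads) && all(hybrid_reads == 0)) return("silent")
  "neither"
}

#' Single-parent-activation (SPA) call
#'
#' SPA-M: the region is present (every replicate at or above `min_reads`) in
#' the maternal parent and the hybrid but absent (all zeros) in the paternal
#' parent; SPA-P is symmetric; *shared* when both parents are present.
#' Because the paternal line carries no C subgenome, SPA is undefined there
#' and C-subgenome input is an error.
#'
#' @param maternal_reads,paternal_reads,hybrid_reads per-replicate reads.
#' @param subgenome `"A"` or `"C"` of the region.
#' @param min_reads presence bound (default 5).
#' @return one of `"SPA-M"`, `"SPA-P"`, `"shared"`, `"absent-informative"`.
#' @export
call_spa <- function(maternal_reads, paternal_reads, hybrid_reads, subgenome,
                     min_reads = 5) {
  if (identical(subgenome, "C"))
    stop("SPA is undefined on the C subgenome: the AA paternal line has no C chromosomes",
         call. = FALSE)
  pres <- function(x) all(x >= min_reads)
  abst <- function(x) all(x == 0)
  if (pres(maternal_reads) && pres(paternal_reads)) return("shared")
  if (pres(maternal_reads) && abst(paternal_reads) && pres(hybrid_reads))
    return("SPA-M")
  if (pres(paternal_reads) && abst(maternal_reads) && pres(hybrid_reads))
    return("SPA-P")
  "absent-informative"
}

#' Differential accessibility between two samples
#'
#' Negative-binomial Wald test per ACR on the replicate count matrices,
#' BH-adjusted across ACRs; an ACR is differential when the adjusted p-value
#' is below `alpha` and `|log2FC| >= lfc_min` (log2FC is sample b over
#' sample a). ACRs with zero counts in both samples are excluded.
#'
#' @param counts_a,counts_b ACR x replicate count matrices.
#' @param sf_a,sf_b size factors (default: median-of-ratios on the combined
#'   matrix).
#' @param alpha FDR level (default 0.05).
#' @param lfc_min log2 fold-change bound (default 1).
#' @return data frame with test columns and `de` in
#'   `{"DE-up", "DE-down", "ns"}`; excluded rows carry `NA`.
#' @export
differential_accessibility <- function(counts_a, counts_b, sf_a = NULL,
                                       sf_b = NULL, alpha = 0.05,
                                       lfc_min = 1) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (is.null(sf_a) || is.null(sf_b)) {
    sf <- size_factors(cbind(counts_a, counts_b))
    sf_a <- sf[seq_len(ncol(counts_a))]
    sf_b <- sf[-seq_len(ncol(counts_a))]
  }
  nonzero <- rowSums(counts_a) + rowSums(counts_b) > 0
  if (!all(nonzero))
    message(sum(!nonzero), " zero-count ACR(s) excluded from the differential test")
  n <- nrow(counts_a)
  out <- data.frame(baseMean = rep(NA_real_, n), log2FC = NA_real_,
                    stat = NA_real_, p_value = NA_real_, adjusted_p = NA_real_,
                    de = NA_character_, row.names = rownames(counts_a))
  if (any(nonzero)) {
    res <- nb_two_group_test(counts_a[nonzero, , drop = FALSE],
                             counts_b[nonzero, , drop = FALSE], sf_a, sf_b)
    res$adjusted_p <- bh_adjust(res$p_value)
    sig <- res$adjusted_p < alpha & abs(res$log2FC) >= lfc_min
    res$de <- ifelse(!sig, "ns", ifelse(res$log2FC > 0, "DE-up", "DE-down"))
    out[nonzero, ] <- res[c("baseMean", "log2FC", "stat", "p_value",
                            "adjusted_p", "de")]
  }
  out
}

#' TE-driven ACR flag
#'
#' An ACR is TE-driven when strictly more than `threshold` of its length is
#' covered by transposable-element annotation.
#'
#' @param acrs ACR interval table.
#' @param tes TE interval table.
#' @param threshold covered-fraction bound (default 0.5; strict `>`).
#' @return logical vector, one flag per ACR.
#' @export
label_te_driven <- function(acrs, tes, threshold = 0.5) {
  overlap_fraction(acrs, tes) > threshold
}

#' Link ACRs to genes
#'
#' Combines [classify_position()] with [nearest_gene()]: genic ACRs target
#' the overlapped gene, proximal ACRs the nearest gene within `window_bp`,
#' distal ACRs record their nearest gene but are flagged unlinked.
#'
#' @param acrs ACR interval table.
#' @param genes gene table.
#' @param window_bp proximal window (default 2000).
#' @return data frame with `positional`, `gene_id`, `distance`, `linked`.
#' @export
link_acr_to_genes <- function(acrs, genes, window_bp = 2000L) {
  pos <- classify_position(acrs, genes, window_bp)
  ng <- nearest_gene(acrs, genes)
  linked <- pos %in% c("genic", "proximal") & !is.na(ng$gene_id)
  data.frame(positional = pos, gene_id = ng$gene_id, distance = ng$distance,
             linked = linked)
}

#' Accessibility-expression correlation
#'
#' Spearman-correlates, across genes, (a) summed ACR read intensity in the
#' TSS window with log-scaled expression and (b) the distance from the TSS to
#' the nearest ACR with log-scaled expression.
#'
#' @param acr_intensity per-gene summed normalized reads of TSS-window ACRs.
#' @param tss_distance per-gene bp distance from TSS to the nearest ACR.
#' @param expression per-gene expression (FPKM); log1p-scaled internally.
#' @return list with `intensity` and `distance`, each as [spearman_cor()].
#' @export
accessibility_expression_correlation <- function(acr_intensity, tss_distance,
                                                 expression) {
  if (length(expression) < 10)
    stop("need >= 10 genes with both measurements", call. = FALSE)
  y <- log1p(expression)
  list(intensity = spearman_cor(acr_intensity, y),
       distance = spearman_cor(tss_distance, y))
}

#' Quantify ACR read support in a sample
#'
#' Sums, per ACR and replicate, the read counts of the sample's peaks
#' overlapping the ACR. ACRs without an overlapping peak in a replicate get
#' 0, which is how structural absence (a parent that never had the peak)
#' enters the novel/silent and SPA rules.
#'
#' @param acrs ACR interval table.
#' @param peaksets named list of peak tables (`chrom`, `start`, `end`,
#'   `count`), one per replicate of the sample.
#' @return numeric matrix, ACRs x replicates.
#' @export
quantify_acr_reads <- function(acrs, peaksets) {
  validate_intervals(acrs, "ACR")
  if (is.null(names(peaksets)))
    names(peaksets) <- paste0("rep", seq_along(peaksets))
  out <- matrix(0, nrow(acrs), length(peaksets),
                dimnames = list(NULL, names(peaksets)))
  if (!nrow(acrs)) return(out)
  ag <- .df2gr(acrs)
  for (j in seq_along(peaksets)) {
    pk <- peaksets[[j]]
    if (!nrow(pk)) next
    hits <- GenomicRanges::findOverlaps(ag, .df2gr(pk), ignore.strand = TRUE)
    v <- tapply(pk$count[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(acrs))),
                sum, default = 0)
    out[, j] <- as.numeric(v)
  }
  out
}
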