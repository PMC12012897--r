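# ---- WGBS methylation and small RNA -----------------------------------------
# Per-cytosine calls travel as CX-report-style tables: chrom, pos (0-based),
# strand, context (CG/CHG/CHH), meth, unmeth. Levels are always weighted
# (pooled methylated / pooled total), never site-averaged.

METH_CONTEXTS <- c("CG", "CHG", "CHH")

# DMR level-difference bounds per context (strict >)
DMR_DELTA <- c(CG = 0.3, CHG = 0.2, CHH = 0.1)

#' Read a CX-report-style methylation table
#'
#' Tab-separated columns: chrom, pos (0-based), strand, context
#' (CG/CHG/CHH), methylated count, unmethylated count.
#'
#' @param path TSV path.
#' @return methylation-call data frame.
#' @export
read_cx_report <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "pos", "strand", "context",
                                 "meth", "unmeth"))
  validate_meth_calls(df)
  df
}

#' Write a CX-report-style methylation table
#'
#' @param calls methylation-call data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(calls, path) {
  write.table(calls[, c("chrom", "pos", "strand", "context", "meth", "unmeth")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Validate methylation calls
#'
#' @param calls data frame with `chrom`, `pos`, `strand`, `context`, `meth`,
#'   `unmeth`.
#' @return `calls`, invisibly.
#' @export
validate_meth_calls <- function(calls) {
  stopifnot(all(c("chrom", "pos", "strand", "context", "meth", "unmeth")
                %in% names(calls)))
  if (nrow(calls)) {
    stopifnot(all(calls$context %in% METH_CONTEXTS),
              all(calls$meth >= 0), all(calls$unmeth >= 0))
  }
  invisible(calls)
}

#' Weighted methylation level of a region
#'
#' Pooled methylated reads over pooled total reads for the sites of the given
#' context inside `[start, end)` whose coverage reaches `min_coverage`.
#' Count-weighted by construction: sites 3/10 and 7/10 give 0.5.
#'
#' @param calls methylation-call data frame.
#' @param chrom,start,end region (0-based half-open).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage per-site total-read bound (default 5).
#' @return level in `[0, 1]`, or `NA` when no site qualifies.
#' @export
weighted_methylation <- function(calls, chrom, start, end, context,
                                 min_coverage = 5) {
  sel <- calls$chrom == chrom & calls$pos >= start & calls$pos < end &
    calls$context == context &
    (calls$meth + calls$unmeth) >= min_coverage
  if (!any(sel)) return(NA_real_)
  sum(calls$meth[sel]) / sum(calls$meth[sel] + calls$unmeth[sel])
}

#' Build an in-silico mid-parent methylome
#'
#' Mixes parental WGBS calls 1:1: at each shared A-subgenome position, each
#' parent's counts are scaled to the position's mean total coverage (so both
#' parents weigh equally) and summed. C-subgenome positions, absent from the
#' AA paternal line, carry the maternal counts through unchanged.
#'
#' @param maternal_calls,paternal_calls methylation-call data frames.
#' @return merged methylation-call data frame.
#' @export
build_insilico_methylome <- function(maternal_calls, paternal_calls) {
  validate_meth_calls(maternal_calls); validate_meth_calls(paternal_calls)
  key <- function(d) paste(d$chrom, d$pos, d$strand, d$context, sep = "\r")
  km <- key(maternal_calls); kp <- key(paternal_calls)
  sgm <- subgenome_of(maternal_calls$chrom)
  idx <- match(km, kp)
  shared <- !is.na(idx) & sgm == "A"
  out <- maternal_calls
  if (any(shared)) {
    mm <- maternal_calls$meth[shared]; mu <- maternal_calls$unmeth[shared]
    pm <- paternal_calls$meth[idx[shared]]
    pu <- paternal_calls$unmeth[idx[shared]]
    tm <- mm + mu; tp <- pm + pu
    target <- (tm + tp) / 2
    wm <- ifelse(tm > 0, target / tm, 0); wp <- ifelse(tp > 0, target / tp, 0)
    out$meth[shared] <- round(mm * wm + pm * wp)
    out$unmeth[shared] <- round(mu * wm + pu * wp)
  }
  # A-subgenome positions seen only in the paternal parent are appended as-is
  only_p <- is.na(match(kp, km)) & subgenome_of(paternal_calls$chrom) == "A"
  if (any(only_p)) out <- rbind(out, paternal_calls[only_p, ])
  out[order(out$chrom, out$pos, out$context), ]
}

#' Aggregate calls into fixed-width bins
#'
#' Tiles each chromosome with non-overlapping `bin_width` bins and pools the
#' qualifying sites (coverage at least `min_coverage`) of one context per
#' bin.
#'
#' @param calls methylation-call data frame.
#' @param context methylation context.
#' @param bin_width bin size in bp (default 200).
#' @param min_coverage per-site coverage bound (default 5).
#' @return bin table: `chrom`, `start`, `end`, `n_sites`, `meth`, `unmeth`,
#'   `level`.
#' @export
bin_methylation <- function(calls, context, bin_width = 200L,
                            min_coverage = 5) {
  sel <- calls$context == context &
    (calls$meth + calls$unmeth) >= min_coverage
  x <- calls[sel, , drop = FALSE]
  if (!nrow(x))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      meth = numeric(0), unmeth = numeric(0),
                      level = numeric(0)))
  bin <- (x$pos %/% bin_width) * bin_width
  keyf <- interaction(x$chrom, bin, drop = TRUE)
  agg <- data.frame(
    chrom = tapply(x$chrom, keyf, `[`, 1),
    start = as.integer(tapply(bin, keyf, `[`, 1)),
    n_sites = as.integer(tapply(x$pos, keyf, length)),
    meth = as.numeric(tapply(x$meth, keyf, sum)),
    unmeth = as.numeric(tapply(x$unmeth, keyf, sum)),
    stringsAsFactors = FALSE)
  agg$end <- agg$start + as.integer(bin_width)
  agg$level <- agg$meth / (agg$meth + agg$unmeth)
  agg <- agg[order(agg$chrom, agg$start),
             c("chrom", "start", "end", "n_sites", "meth", "unmeth", "level")]
  rownames(agg) <- NULL
  agg
}

#' Call differentially methylated regions (DMRs)
#'
#' Joins the 200-bp bins present in both samples with at least `min_sites`
#' qualifying cytosines each, applies a two-sided Fisher exact test to the
#' pooled methylated/unmethylated counts per bin, BH-adjusts within the
#' context, and keeps bins with adjusted p below `alpha` whose weighted-level
#' difference strictly exceeds the context bound (CG 0.3, CHG 0.2, CHH 0.1 by
#' default). Direction is *hyper* when sample 1 is more methylated than
#' sample 2.
#'
#' @param bins1,bins2 bin tables from [bin_methylation()] for the two samples.
#' @param context methylation context (selects the default delta).
#' @param delta level-difference bound (default `DMR_DELTA[context]`).
#' @param alpha FDR level (default 0.05).
#' @param min_sites minimum qualifying cytosines per bin in each sample
#'   (default 3).
#' @return data frame of tested bins with `level1`, `level2`, `delta`,
#'   `p_value`, `adjusted_p`, `dmr` (logical), `direction`.
#' @export
call_dmrs <- function(bins1, bins2, context, delta = NULL, alpha = 0.05,
                      min_sites = 3L) {
  if (is.null(delta)) {
    if (!context %in% names(DMR_DELTA))
      stop("no level-difference bound for context ", context, call. = FALSE)
    delta <- DMR_DELTA[[context]]
  }
  k1 <- paste(bins1$chrom, bins1$start); k2 <- paste(bins2$chrom, bins2$start)
  idx <- match(k1, k2)
  keep <- !is.na(idx) & bins1$n_sites >= min_sites &
    bins2$n_sites[idx] >= min_sites
  b1 <- bins1[keep, , drop = FALSE]
  b2 <- bins2[idx[keep], , drop = FALSE]
  n <- nrow(b1)
  p <- numeric(n)
  for (i in seq_len(n))
    p[i] <- fisher_exact_2x2(round(b1$meth[i]), round(b1$unmeth[i]),
                             round(b2$meth[i]), round(b2$unmeth[i]))$p_value
  padj <- if (n) bh_adjust(p) else numeric(0)
  out <- data.frame(chrom = b1$chrom, start = b1$start, end = b1$end,
                    context = rep(context, n),
                    level1 = b1$level, level2 = b2$level,
                    delta = b1$level - b2$level,
                    p_value = p, adjusted_p = padj,
                    stringsAsFactors = FALSE)
  out$dmr <- out$adjusted_p < alpha & abs(out$delta) > delta
  out$direction <- ifelse(out$delta > 0, "hyper", "hypo")
  out$direction[!out$dmr] <- NA_character_
  out
}

#' Call differentially methylated loci (DMLs)
#'
#' Per-cytosine Fisher exact test between two samples, BH-adjusted within
#' each context; only sites reaching `min_coverage` in both samples are
#' tested. Significant sites are labeled hyper (sample 1 higher) or hypo.
#'
#' @param calls1,calls2 methylation-call data frames.
#' @param alpha FDR level (default 0.05).
#' @param min_coverage per-site coverage bound (default 5).
#' @return data frame of tested sites with `p_value`, `adjusted_p`, `dml`,
#'   `direction`.
#' @export
call_dmls <- function(calls1, calls2, alpha = 0.05, min_coverage = 5) {
  key <- function(d) paste(d$chrom, d$pos, d$strand, d$context, sep = "\r")
  idx <- match(key(calls1), key(calls2))
  keep <- !is.na(idx) &
    (calls1$meth + calls1$unmeth) >= min_coverage &
    (calls2$meth + calls2$unmeth)[idx] >= min_coverage
  c1 <- calls1[keep, , drop = FALSE]
  c2 <- calls2[idx[keep], , drop = FALSE]
  n <- nrow(c1)
  p <- numeric(n)
  for (i in seq_len(n))
    p[i] <- fisher_exact_2x2(c1$meth[i], c1$unmeth[i],
                             c2$meth[i], c2$unmeth[i])$p_value
  out <- data.frame(chrom = c1$chrom, pos = c1$pos, context = c1$context,
                    level1 = c1$meth / (c1$meth + c1$unmeth),
                    level2 = c2$meth / (c2$meth + c2$unmeth),
                    p_value = p, adjusted_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (ctx in unique(out$context)) {
    i <- out$context == ctx
    out$adjusted_p[i] <- bh_adjust(out$p_value[i])
  }
  out$dml <- out$adjusted_p < alpha
  out$direction <- ifelse(out$level1 > out$level2, "hyper", "hypo")
  out$direction[!out$dml] <- NA_character_
  out
}

#' Positional class and target gene (DMG) for DMRs
#'
#' @param dmrs DMR table (interval columns).
#' @param genes gene table.
#' @param window_bp proximal window (default 2000).
#' @return `dmrs` with `positional`, `gene_id` (the DMG; `NA` for distal),
#'   `distance`.
#' @export
classify_dmr_targets <- function(dmrs, genes, window_bp = 2000L) {
  link <- link_acr_to_genes(dmrs, genes, window_bp)
  dmrs$positional <- link$positional
  dmrs$gene_id <- ifelse(link$linked, link$gene_id, NA_character_)
  dmrs$distance <- link$distance
  dmrs
}

#' Methylation status of an ACR
#'
#' *Unmethylated* when every context with qualifying sites lies strictly
#' below its bound (defaults mCG < 0.1, mCHG < 0.1, mCHH < 0.05);
#' *methylated* when any context reaches its bound; *undefined* when no
#' context has a qualifying site. The bounds are package choices, exposed for
#' configuration.
#'
#' @param calls methylation-call data frame.
#' @param chrom,start,end ACR interval.
#' @param thresholds named numeric vector of per-context bounds.
#' @param min_coverage per-site coverage bound (default 5).
#' @return `"methylated"`, `"unmethylated"` or `"undefined"`.
#' @export
acr_methylation_status <- function(calls, chrom, start, end,
                                   thresholds = c(CG = 0.1, CHG = 0.1,
                                                  CHH = 0.05),
                                   min_coverage = 5) {
  levels <- vapply(names(thresholds), function(ctx)
    weighted_methylation(calls, chrom, start, end, ctx, min_coverage),
    numeric(1))
  ok <- !is.na(levels)
  if (!any(ok)) return("undefined")
  if (any(levels[ok] >= thresholds[ok])) return("methylated")
  "unmethylated"
}

# ---- small RNA --------------------------------------------------------------

#' Cluster mapped small-RNA reads
#'
#' Filters reads to `[min_len, max_len]` nt, merges reads whose intervals are
#' within `max_gap` bp of each other into maximal clusters, and keeps
#' clusters with at least `min_reads` reads. RPM is reads per million of
#' `total_reads` (total clean reads).
#'
#' @param reads data frame `chrom`, `start`, `end`, `length`.
#' @param total_reads total clean-read count for RPM normalization
#'   (default: `nrow(reads)`).
#' @param min_len,max_len read-length bounds in nt (defaults 18, 30).
#' @param max_gap merge distance in bp (default 75).
#' @param min_reads cluster support bound (default 5).
#' @return cluster table: `chrom`, `start`, `end`, `read_count`, `rpm`,
#'   `dominant_length`.
#' @export
cluster_srna <- function(reads, total_reads = nrow(reads), min_len = 18L,
                         max_len = 30L, max_gap = 75L, min_reads = 5L) {
  keep <- reads$length >= min_len & reads$length <= max_len
  x <- reads[keep, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), read_count = integer(0),
                      rpm = numeric(0), dominant_length = integer(0))
  if (!nrow(x)) return(empty)
  gr <- .df2gr(x)
  cl <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(max_gap) + 1L,
                              ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, cl,
                                      maxgap = as.integer(max_gap),
                                      ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  counts <- tabulate(grp, nbins = length(cl))
  dom <- vapply(seq_along(cl), function(i) {
    lens <- x$length[grp == i]
    as.integer(names(which.max(table(lens))))
  }, 1L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(cl)),
                    start = GenomicRanges::start(cl) - 1L,
                    end = GenomicRanges::end(cl),
                    read_count = counts,
                    rpm = 1e6 * counts / total_reads,
                    dominant_length = dom,
                    stringsAsFactors = FALSE)
  out <- out[out$read_count >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' sRNA accumulation at DMRs
#'
#' Sums cluster RPM over each DMR and compares the per-DMR totals between the
#' F1 hybrid and the in-silico mid-parent with the Wilcoxon rank-sum test,
#' separately for hyper- and hypo-DMRs. Directions with fewer than 3 DMRs are
#' flagged underpowered (`p = NA`).
#'
#' @param dmrs DMR table with `direction` (`hyper`/`hypo`).
#' @param clusters_hybrid,clusters_insilico cluster tables from
#'   [cluster_srna()].
#' @return data frame, one row per direction: `n_dmrs`, `median_hybrid`,
#'   `median_insilico`, `p_value`, `higher_in`, `underpowered`.
#' @export
dmr_srna_enrichment <- function(dmrs, clusters_hybrid, clusters_insilico) {
  rpm_at <- function(clusters, regions) {
    if (!nrow(regions)) return(numeric(0))
    if (!nrow(clusters)) return(rep(0, nrow(regions)))
    hits <- GenomicRanges::findOverlaps(.df2gr(regions), .df2gr(clusters),
                                        ignore.strand = TRUE)
    v <- tapply(clusters$rpm[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))),
                sum, default = 0)
    as.numeric(v)
  }
  out <- lapply(c("hyper", "hypo"), function(dir) {
    d <- dmrs[!is.na(dmrs$direction) & dmrs$direction == dir, , drop = FALSE]
    h <- rpm_at(clusters_hybrid, d)
    i <- rpm_at(clusters_insilico, d)
    under <- nrow(d) < 3
    p <- if (under || (all(h == i))) NA_real_ else
      rank_tests(list(h, i))$p_value
    data.frame(direction = dir, n_dmrs = nrow(d),
               median_hybrid = if (length(h)) median(h) else NA_real_,
               median_insilico = if (length(i)) median(i) else NA_real_,
               p_value = p,
               higher_in = if (!length(h) || median(i) == median(h)) NA_character_
                           else if (median(i) > median(h)) "insilico" else "hybrid",
               underpowered = under, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
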