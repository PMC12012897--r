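#' @importFrom stats median p.adjust pnorm pt qnorm rbinom rnbinom rnorm rpois
#'   runif sd var cor complete.cases kruskal.test wilcox.test fisher.test
#'   setNames aggregate lm coef rlnorm quantile
#' @importFrom utils read.delim write.table head modifyList
NULL

# ---- interval containers ----------------------------------------------------
# All coordinates are 0-based half-open (BED convention). GFF3 input
# (1-based inclusive) is converted on read and back-converted on write.

#' Construct a genomic interval table
#'
#' The package represents genomic features as plain data frames with columns
#' `chrom`, `start`, `end` (0-based half-open) and optionally `strand`.
#' Chromosome names carry the subgenome as their first letter (`A01`, `C03`);
#' see [subgenome_of()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `end > start`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param ... further equal-length columns appended to the table.
#' @return a `data.frame` with one row per interval.
#' @export
gintervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = strand,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the 0-based half-open invariants (`end > start`, non-empty `chrom`).
#'
#' @param x interval data frame.
#' @param what label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x)))
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": chrom must be non-empty", call. = FALSE)
  bad <- which(!(x$end > x$start))
  if (length(bad))
    stop(what, ": end must be > start (rows ", paste(head(bad, 5), collapse = ","),
         ")", call. = FALSE)
  invisible(x)
}

#' Subgenome of a chromosome name
#'
#' The A/C subgenome is derived from the first letter of the chromosome name
#' unless an explicit mapping is supplied.
#'
#' @param chrom character vector.
#' @param map optional named character vector, `map[chrom] -> "A"|"C"`,
#'   overriding the prefix rule for nonstandard names.
#' @return character vector of `"A"`/`"C"` (or `NA` when underivable).
#' @export
subgenome_of <- function(chrom, map = NULL) {
  out <- toupper(substr(as.character(chrom), 1L, 1L))
  out[!out %in% c("A", "C")] <- NA_character_
  if (!is.null(map)) {
    hit <- !is.na(match(chrom, names(map)))
    out[hit] <- unname(map[chrom[hit]])
  }
  out
}

# internal: data.frame -> GRanges (shifts to 1-based closed for IRanges)
.df2gr <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "."
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = strand)
}

# ---- positional classification ----------------------------------------------

#' Classify regions as genic, proximal or distal
#'
#' A region is *genic* when it overlaps any gene body by at least 1 bp,
#' *proximal* when it lies within `window_bp` of a gene body (upstream or
#' downstream, strand-agnostic), and *distal* otherwise. The precedence is
#' genic > proximal > distal, so each region receives exactly one class.
#'
#' @param regions interval data frame.
#' @param genes gene table (interval columns plus `gene_id`).
#' @param window_bp flank width in bp defining "proximal" (default 2000).
#' @return factor with levels `genic`, `proximal`, `distal`, one per region.
#' @export
classify_position <- function(regions, genes, window_bp = 2000L) {
  validate_intervals(regions, "region")
  stopifnot(window_bp > 0)
  out <- factor(rep("distal", nrow(regions)),
                levels = c("genic", "proximal", "distal"))
  if (nrow(regions) == 0 || is.null(genes) || nrow(genes) == 0) return(out)
  validate_intervals(genes, "gene")
  rg <- .df2gr(regions)
  gg <- .df2gr(genes)
  genic <- GenomicRanges::countOverlaps(rg, gg, ignore.strand = TRUE) > 0
  flank <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::resize(
      gg, GenomicRanges::width(gg) + 2L * as.integer(window_bp), fix = "center")))
  prox <- GenomicRanges::countOverlaps(rg, flank, ignore.strand = TRUE) > 0
  out[prox] <- "proximal"
  out[genic] <- "genic"
  out
}

#' Fraction of a region covered by a feature set
#'
#' Computes, per region, the number of bases covered by the union of the
#' features divided by the region length. Overlapping features are unioned
#' first and never double-counted, so the result is invariant to splitting a
#' feature into adjacent pieces.
#'
#' @param regions interval data frame.
#' @param features interval data frame (e.g. transposable elements); may be
#'   empty.
#' @return numeric vector in `[0, 1]`, one value per region.
#' @export
overlap_fraction <- function(regions, features) {
  validate_intervals(regions, "region")
  if (nrow(regions) == 0) return(numeric(0))
  if (is.null(features) || nrow(features) == 0) return(rep(0, nrow(regions)))
  validate_intervals(features, "feature")
  rg <- .df2gr(regions)
  fg <- GenomicRanges::reduce(.df2gr(features), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(rg, fg, ignore.strand = TRUE)
  cov <- GenomicRanges::width(IRanges::pintersect(
    rg[S4Vectors::queryHits(hits)], fg[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  tot <- tapply(cov, factor(S4Vectors::queryHits(hits), levels = seq_along(rg)),
                sum, default = 0)
  as.numeric(tot) / GenomicRanges::width(rg)
}

#' Nearest gene and distance for each region
#'
#' Distance is 0 for any overlap, otherwise the bp gap to the closest gene
#' boundary on the same chromosome. Ties go to the gene with the smaller start
#' coordinate, then to the lexicographically smaller `gene_id`. Regions on a
#' chromosome without genes are unassignable (`NA` gene, `NA` distance), not
#' an error.
#'
#' @param regions interval data frame.
#' @param genes gene table with `gene_id`.
#' @return data frame with columns `gene_id`, `distance`.
#' @export
nearest_gene <- function(regions, genes) {
  validate_intervals(regions, "region")
  out <- data.frame(gene_id = rep(NA_character_, nrow(regions)),
                    distance = rep(NA_real_, nrow(regions)),
                    stringsAsFactors = FALSE)
  if (nrow(regions) == 0 || is.null(genes) || nrow(genes) == 0) return(out)
  validate_intervals(genes, "gene")
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    g <- genes[gi, , drop = FALSE]
    ord <- order(g$start, g$gene_id)   # tie-break order baked into which.min
    g <- g[ord, , drop = FALSE]
    for (i in ri) {
      gap <- ifelse(g$start >= regions$end[i], g$start - regions$end[i],
             ifelse(g$end <= regions$start[i], regions$start[i] - g$end, 0L))
      j <- which.min(gap)              # first minimum respects tie-break order
      out$gene_id[i] <- g$gene_id[j]
      out$distance[i] <- gap[j]
    }
  }
  out
}

# ---- readers / writers ------------------------------------------------------

#' Read a BED file
#'
#' Reads BED3+ (tab-separated, 0-based half-open). Columns beyond the third
#' are taken from `extra_cols`; the standard BED names `name`, `score`,
#' `strand` are used when `extra_cols` is `NULL`.
#'
#' @param path file path.
#' @param extra_cols optional character vector naming columns 4, 5, ...
#' @return interval data frame.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  ncol_extra <- ncol(df) - 3L
  nms <- c("chrom", "start", "end")
  if (ncol_extra > 0) {
    if (is.null(extra_cols))
      extra_cols <- c("name", "score", "strand")[seq_len(min(3L, ncol_extra))]
    nms <- c(nms, extra_cols, paste0("V", seq_len(ncol_extra))[-seq_along(extra_cols)])
    nms <- nms[seq_len(ncol(df))]
  }
  names(df) <- nms
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_intervals(df, basename(path))
  df
}

#' Write a BED file
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` plus any columns
#' named in `extra_cols`, tab-separated without header, preserving the
#' 0-based half-open convention bit-exactly.
#'
#' @param x interval data frame.
#' @param path output path.
#' @param extra_cols character vector of additional columns to write.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = intersect(c("name", "score", "strand"),
                                                      names(x))) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end", extra_cols)
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses `gene` features and their `ID` attribute; converts the 1-based
#' inclusive GFF3 coordinates to the package's 0-based half-open convention.
#' The subgenome is derived from the chromosome name.
#'
#' @param path GFF3 path.
#' @param subgenome_map optional chromosome-to-subgenome override
#'   (see [subgenome_of()]).
#' @return gene table: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `subgenome`.
#' @export
read_gff_genes <- function(path, subgenome_map = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  df <- data.frame(gene_id = as.character(gr$ID),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  df$subgenome <- subgenome_of(df$chrom, subgenome_map)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ", path, call. = FALSE)
  validate_intervals(df, "gene")
  df
}

#' Write gene models to GFF3
#'
#' @param genes gene table as returned by [read_gff_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  validate_intervals(genes, "gene")
  lines <- sprintf("%s\ttriadomics\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, genes$start + 1L, genes$end,
                   ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a homolog-pair table
#'
#' Two-column tab-separated file (`A_gene_id`, `C_gene_id`), one A/C
#' homologous pair per line.
#'
#' @param path TSV path.
#' @return data frame with columns `a_gene`, `c_gene`.
#' @export
read_homolog_pairs <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:2]
  names(df) <- c("a_gene", "c_gene")
  df
}
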