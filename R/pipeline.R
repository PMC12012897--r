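# ---- end-to-end orchestration -----------------------------------------------

#' Pipeline parameters
#'
#' All thresholds of the analysis in one place: 2-kb gene window, >50 bp
#' peak overlap, >=5 reads, FPKM > 1, |log2FC| 1.5 versus the mid-parent
#' and 2 for parent contrasts, R^2 > 0.64, methylation deltas 0.3/0.2/0.1
#' in 200-bp bins, TE fraction 0.5, k = 9 accessibility clusters. A bare
#' run applies these standard rules; every override is explicit.
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  par <- list(window_bp = 2000L, min_overlap_bp = 50L, min_replicates = 2L,
              min_reads = 5, te_threshold = 0.5, lfc_acr = 1,
              fpkm_expressed = 1, fpkm_silent = 0.1,
              lfc_additive = 1.5, lfc_deg = 2, alpha = 0.05,
              r2_min = 0.64, dosage_mode = "replicate",
              bin_width = 200L, min_coverage = 5, min_sites = 3L,
              dmr_delta = DMR_DELTA,
              acr_meth_thresholds = c(CG = 0.1, CHG = 0.1, CHH = 0.05),
              srna_min_len = 18L, srna_max_len = 30L, srna_max_gap = 75L,
              srna_min_reads = 5L,
              k_clusters = 9L, cmeans_m = 2, cmeans_seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(par))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  modifyList(par, over)
}

# consensus ACR universe: per-sample replicate merge, then union of the
# per-sample consensus intervals
.acr_universe <- function(peaks, params) {
  cons <- lapply(peaks, merge_replicate_peaks,
                 min_overlap_bp = params$min_overlap_bp,
                 min_replicates = params$min_replicates)
  all <- do.call(rbind, lapply(cons, function(d) d[c("chrom", "start", "end")]))
  if (!nrow(all))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  gr <- GenomicRanges::reduce(.df2gr(all), ignore.strand = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Run the full analysis on a simulated or on-disk study
#'
#' Executes the stages in dependency order: annotation, ACR construction and
#' classification, expression genetics, methylation, sRNA, and integration.
#' Input is either the in-memory bundle from [simulate_all()] or a directory
#' written by [write_simulation()]. Deterministic for fixed input and
#' parameters.
#'
#' @param input a [simulate_all()] bundle or a directory path.
#' @param params a [pipeline_params()] list.
#' @param out_dir optional output directory; when given, result tables are
#'   written as TSV/BED/JSON.
#' @return list with per-stage tables and a `summary` of class counts.
#' @export
run_pipeline <- function(input, params = pipeline_params(), out_dir = NULL) {
  if (is.character(input)) input <- read_simulation(input)
  genes <- input$genome$genes
  tes <- input$genome$tes
  homologs <- input$genome$homologs

  ## ---- input validation ----
  peaks <- input$acr$peaks
  if (!all(c("maternal", "paternal", "hybrid") %in% names(peaks)))
    stop("missing sample role: need maternal, paternal and hybrid peak sets",
         call. = FALSE)
  for (role in c("maternal", "paternal", "hybrid"))
    if (!any(input$expression$manifest$role == role))
      stop("missing sample role in expression manifest: ", role, call. = FALSE)

  ## ---- ACR stage ----
  acrs <- .acr_universe(peaks, params)
  reads <- lapply(peaks, function(ps) quantify_acr_reads(acrs, ps))
  acrs$mean_maternal <- rowMeans(reads$maternal)
  acrs$mean_hybrid <- rowMeans(reads$hybrid)
  acrs$mean_paternal <- rowMeans(reads$paternal)
  acrs$positional <- classify_position(acrs, genes, params$window_bp)
  acrs$te_fraction <- overlap_fraction(acrs, tes)
  acrs$te_driven <- acrs$te_fraction > params$te_threshold
  acrs$subgenome <- subgenome_of(acrs$chrom)
  nov <- vapply(seq_len(nrow(acrs)), function(i)
    call_novel_silent(reads$hybrid[i, ], reads$maternal[i, ],
                      reads$paternal[i, ], params$min_reads), "")
  acrs$novel_silent <- nov
  acrs$spa <- NA_character_
  onA <- acrs$subgenome == "A"
  acrs$spa[onA] <- vapply(which(onA), function(i)
    call_spa(reads$maternal[i, ], reads$paternal[i, ], reads$hybrid[i, ],
             "A", params$min_reads), "")
  link <- link_acr_to_genes(acrs, genes, params$window_bp)
  acrs$gene_id <- link$gene_id
  acrs$distance <- link$distance
  acrs$linked <- link$linked
  da <- differential_accessibility(reads$maternal, reads$hybrid,
                                   alpha = params$alpha,
                                   lfc_min = params$lfc_acr)
  acrs$de <- da$de
  acrs$lfc_accessibility <- da$log2FC

  ## ---- expression stage ----
  expr <- input$expression
  man <- expr$manifest
  counts <- expr$counts
  cols <- function(role) man$sample[man$role == role]
  for (role in c("maternal", "paternal", "hybrid"))
    if (!length(cols(role)))
      stop("missing sample role: ", role, call. = FALSE)
  sf <- size_factors(counts)
  insilico <- build_insilico_hybrid(counts[, cols("maternal"), drop = FALSE],
                                    counts[, cols("paternal"), drop = FALSE],
                                    sf[cols("maternal")], sf[cols("paternal")])
  fpkm <- compute_fpkm(counts, expr$lengths[rownames(counts)])
  gene_tab <- data.frame(gene_id = rownames(counts),
                         subgenome = genes$subgenome[match(rownames(counts),
                                                           genes$gene_id)],
                         stringsAsFactors = FALSE)
  add <- classify_additivity(counts[, cols("hybrid"), drop = FALSE], insilico,
                             sf[cols("hybrid")], rep(1, ncol(insilico)),
                             params$alpha, params$lfc_additive)
  gene_tab$additivity <- add$additivity
  pat <- classify_pattern(counts[, cols("hybrid"), drop = FALSE],
                          counts[, cols("maternal"), drop = FALSE],
                          counts[, cols("paternal"), drop = FALSE],
                          add$additivity,
                          sf[cols("hybrid")], sf[cols("maternal")],
                          sf[cols("paternal")], params$alpha, params$lfc_deg)
  gene_tab$pattern <- pat$pattern
  spe <- call_spe(fpkm[, cols("maternal"), drop = FALSE],
                  fpkm[, cols("paternal"), drop = FALSE],
                  fpkm[, cols("hybrid"), drop = FALSE],
                  gene_tab$subgenome,
                  params$fpkm_expressed, params$fpkm_silent)
  gene_tab$spe <- spe$spe
  # dosage uses median-of-ratios-normalized counts, not FPKM: the paternal
  # library has no C subgenome, so whole-library FPKM scaling inflates its
  # A-subgenome values and would fabricate dosage correlations
  norm <- sweep(counts, 2, sf, "/")
  dos <- dosage_dependence(norm[, cols("maternal"), drop = FALSE],
                           norm[, cols("hybrid"), drop = FALSE],
                           norm[, cols("paternal"), drop = FALSE],
                           gene_tab$subgenome, params$r2_min, params$alpha,
                           params$dosage_mode)
  gene_tab$dosage <- dos$dosage
  gene_tab$dosage_r2 <- dos$r_squared
  pair_cat <- homolog_categories(setNames(gene_tab$dosage, gene_tab$gene_id),
                                 homologs)

  ## ---- methylation stage ----
  meth <- input$meth$calls
  insilico_meth <- build_insilico_methylome(meth$maternal, meth$paternal)
  dmrs <- do.call(rbind, lapply(METH_CONTEXTS, function(ctx) {
    b1 <- bin_methylation(meth$hybrid, ctx, params$bin_width,
                          params$min_coverage)
    b2 <- bin_methylation(insilico_meth, ctx, params$bin_width,
                          params$min_coverage)
    call_dmrs(b1, b2, ctx, params$dmr_delta[[ctx]], params$alpha,
              params$min_sites)
  }))
  dmr_hits <- dmrs[dmrs$dmr, , drop = FALSE]
  if (nrow(dmr_hits))
    dmr_hits <- classify_dmr_targets(dmr_hits, genes, params$window_bp)
  dmls <- call_dmls(meth$hybrid, insilico_meth, params$alpha,
                    params$min_coverage)
  acrs$meth_status <- vapply(seq_len(nrow(acrs)), function(i)
    acr_methylation_status(meth$hybrid, acrs$chrom[i], acrs$start[i],
                           acrs$end[i], params$acr_meth_thresholds,
                           params$min_coverage), "")

  ## ---- sRNA stage ----
  srna <- input$srna$reads
  clusters <- lapply(srna, function(rd)
    cluster_srna(rd, nrow(rd), params$srna_min_len, params$srna_max_len,
                 params$srna_max_gap, params$srna_min_reads))
  srna_enrich <- dmr_srna_enrichment(dmr_hits, clusters$hybrid,
                                     clusters$insilico)

  ## ---- integration ----
  integration <- integrate_results(acrs, gene_tab, fpkm, cols, params)

  summary <- list(
    n_acrs = nrow(acrs),
    acr_positional = as.list(table(acrs$positional)),
    acr_categories = as.list(table(acrs$novel_silent)),
    acr_spa = as.list(table(acrs$spa[onA])),
    n_te_driven = sum(acrs$te_driven),
    gene_pattern = as.list(table(gene_tab$pattern)),
    gene_additivity = as.list(table(gene_tab$additivity)),
    gene_spe = as.list(table(gene_tab$spe)),
    gene_dosage = as.list(table(gene_tab$dosage)),
    homolog_categories = as.list(table(pair_cat$category)),
    n_dmrs = nrow(dmr_hits),
    dmr_direction = as.list(table(dmr_hits$direction)),
    n_dmls = sum(dmls$dml),
    n_srna_clusters = vapply(clusters, nrow, 1L))

  out <- list(acrs = acrs, acr_reads = reads, gene_classes = gene_tab,
              homolog_pairs = pair_cat, dmrs = dmrs, dmr_hits = dmr_hits,
              dmls = dmls, srna_clusters = clusters,
              srna_enrichment = srna_enrich, integration = integration,
              summary = summary, params = params)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

#' Integration tables across assays
#'
#' Builds the cross-assay views: the novel-ACR x transgressive-up gene
#' overlap, expression grouped by ACR positional class, expression grouped by
#' ACR methylation status, expression for TE-driven versus non-TE ACR genes,
#' the accessibility-expression correlations, and the fuzzy c-means
#' clustering of ACR accessibility profiles.
#'
#' @param acrs annotated ACR table from the pipeline.
#' @param gene_tab per-gene classification table.
#' @param fpkm FPKM matrix.
#' @param cols function mapping a role to its sample columns.
#' @param params a [pipeline_params()] list.
#' @return list of integration tables.
#' @export
integrate_results <- function(acrs, gene_tab, fpkm, cols, params) {
  hyb_expr <- rowMeans(fpkm[, cols("hybrid"), drop = FALSE])
  gexpr <- setNames(hyb_expr, rownames(fpkm))
  # (a) novel ACRs versus transgressive-up genes
  trans_up <- gene_tab$gene_id[gene_tab$pattern == "transgressive-up"]
  novel_genes <- unique(acrs$gene_id[acrs$novel_silent == "novel" & acrs$linked])
  novel_genes <- novel_genes[!is.na(novel_genes)]
  novel_overlap <- data.frame(
    n_novel_linked = length(novel_genes),
    n_transgressive_up = length(trans_up),
    n_overlap = length(intersect(novel_genes, trans_up)),
    fraction_novel_targeting = if (length(novel_genes))
      length(intersect(novel_genes, trans_up)) / length(novel_genes)
    else NA_real_)
  # (b) expression by ACR positional class
  by_pos <- split(gexpr[acrs$gene_id[!is.na(acrs$gene_id)]],
                  acrs$positional[!is.na(acrs$gene_id)])
  by_pos <- by_pos[vapply(by_pos, length, 1L) > 0]
  pos_test <- if (length(by_pos) >= 2) rank_tests(unname(by_pos)) else
    list(statistic = NA_real_, p_value = NA_real_, test = NA_character_)
  # (c) expression by ACR methylation status
  ok <- acrs$linked & !is.na(acrs$gene_id) &
    acrs$meth_status %in% c("methylated", "unmethylated")
  by_meth <- split(gexpr[acrs$gene_id[ok]], acrs$meth_status[ok])
  meth_test <- if (length(by_meth) == 2 && all(lengths(by_meth) > 0))
    rank_tests(unname(by_meth)) else
    list(statistic = NA_real_, p_value = NA_real_, test = NA_character_)
  # (d) TE-driven versus non-TE ACR genes
  okt <- acrs$linked & !is.na(acrs$gene_id)
  by_te <- split(gexpr[acrs$gene_id[okt]], acrs$te_driven[okt])
  te_test <- if (length(by_te) == 2) rank_tests(unname(by_te)) else
    list(statistic = NA_real_, p_value = NA_real_, test = NA_character_)
  # (e) accessibility-expression correlation over linked genes
  linked <- acrs[okt, , drop = FALSE]
  intensity <- tapply(linked$mean_hybrid, linked$gene_id, sum)
  corr <- NULL
  if (length(intensity) >= 10) {
    gids <- names(intensity)
    dist <- tapply(linked$distance, linked$gene_id, min)[gids]
    corr <- accessibility_expression_correlation(as.numeric(intensity),
                                                 as.numeric(dist),
                                                 as.numeric(gexpr[gids]))
  }
  # (f) fuzzy c-means on per-sample accessibility profiles of DE ACRs
  prof_cols <- c("mean_maternal", "mean_hybrid", "mean_paternal")
  clusters <- NULL
  de_idx <- which(!is.na(acrs$de) & acrs$de != "ns")
  if (length(de_idx) >= params$k_clusters && all(prof_cols %in% names(acrs))) {
    prof <- as.matrix(acrs[de_idx, prof_cols])
    clusters <- fuzzy_cmeans(prof, params$k_clusters, params$cmeans_m,
                             params$cmeans_seed)
  }
  list(novel_transgressive = novel_overlap,
       expression_by_position = lapply(by_pos, median),
       position_test = pos_test,
       expression_by_meth_status = lapply(by_meth, median),
       meth_status_test = meth_test,
       te_expression_test = te_test,
       accessibility_expression = corr,
       acr_clusters = clusters)
}

#' Read a study directory written by [write_simulation()]
#'
#' @param dir directory path.
#' @return a bundle shaped like [simulate_all()] output (without truth).
#' @export
read_simulation <- function(dir) {
  genes <- read_gff_genes(file.path(dir, "genes.gff3"))
  tes <- read_bed(file.path(dir, "tes.bed"), extra_cols = "te_class")
  homologs <- read_homolog_pairs(file.path(dir, "homologs.tsv"))
  cnt <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cnt[, -(1:2)])
  rownames(counts) <- cnt$gene_id
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  peak_files <- list.files(file.path(dir, "peaks"), full.names = TRUE)
  peaks <- list()
  for (f in peak_files) {
    nm <- sub("\\.bed$", "", basename(f))
    smp <- sub("_rep[0-9]+$", "", nm)
    rep <- sub("^.*_(rep[0-9]+)$", "\\1", nm)
    pk <- read_bed(f, extra_cols = c("name", "count"))
    peaks[[smp]][[rep]] <- pk
  }
  meth <- lapply(list.files(file.path(dir, "meth"), full.names = TRUE),
                 read_cx_report)
  names(meth) <- sub("\\.cx\\.tsv$", "",
                     list.files(file.path(dir, "meth")))
  srna <- lapply(list.files(file.path(dir, "srna"), full.names = TRUE),
                 function(f) {
                   rd <- read_bed(f, extra_cols = c("name", "length"))
                   rd$length <- as.integer(rd$length)
                   rd
                 })
  names(srna) <- sub("\\.bed$", "", list.files(file.path(dir, "srna")))
  list(genome = list(genes = genes, tes = tes, homologs = homologs),
       expression = list(counts = counts,
                         lengths = setNames(cnt$length, cnt$gene_id),
                         manifest = manifest),
       acr = list(peaks = peaks),
       meth = list(calls = meth),
       srna = list(reads = srna))
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(out$acrs, "acrs.tsv")
  wt(out$gene_classes, "gene_classes.tsv")
  wt(out$homolog_pairs, "homolog_pairs.tsv")
  wt(out$dmrs, "dmr_tests.tsv")
  wt(out$dmr_hits, "dmrs.tsv")
  wt(out$dmls[out$dmls$dml, , drop = FALSE], "dmls.tsv")
  for (s in names(out$srna_clusters))
    wt(out$srna_clusters[[s]], paste0("srna_clusters_", s, ".tsv"))
  wt(out$srna_enrichment, "srna_enrichment.tsv")
  jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
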