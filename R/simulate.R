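# ---- synthetic allotriploid multi-omics generator ---------------------------
# Emulates the study design: two allotetraploid (AACC) maternal lines are
# collapsed into one maternal sample, the diploid (AA) paternal line carries
# no C subgenome in any assay, and the F1 hybrid is allotriploid (AAC).
# Every feature carries a planted ground-truth label so each pipeline stage
# can be scored against exact truth. All draws are seeded; each assay uses
# its own derived seed so the assays are individually reproducible.

#' Simulation configuration
#'
#' Returns the default study-condition configuration, with any field
#' overridden by name. Defaults: 2 A + 2 C chromosomes of 1 Mb; 800 genes;
#' 3 replicates; NB expression with dispersion 0.1 and >= 8-fold planted
#' effects; 600 ACR loci with jittered replicate peaks; 50,000 cytosines with
#' 200 planted CG DMR bins of delta 0.4 at coverage 30; sRNA accumulation
#' shifted 2-fold at DMRs.
#'
#' @param ... named overrides of any default field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    chrom_lengths = c(A01 = 1e6, A02 = 1e6, C01 = 1e6, C02 = 1e6),
    n_genes = 800L,
    gene_length_range = c(1000L, 3000L),
    homolog_fraction = 0.75,     # fraction of A genes with a C homolog
    n_tes = 240L,
    te_length_range = c(400L, 3000L),
    replicates = 3L,
    # expression
    nb_meanlog = log(150), nb_sdlog = 0.7, dispersion = 0.1,
    parent_fold = 8, transgressive_fold = 8,
    class_props = c(additive = 0.40, `ELD-M` = 0.05, `ELD-P` = 0.05,
                    `transgressive-up` = 0.05, `transgressive-down` = 0.05,
                    `SPE-M` = 0.025, `SPE-P` = 0.025),
    dosage_props = c(dependent = 0.10, independent = 0.10),
    dosage_meanlog = log(800), dosage_sdlog = 0.3, dosage_dispersion = 0.01,
    depth_range = c(0.8, 1.2),   # per-library depth factors
    # ACRs
    n_acrs = 600L,
    acr_width_range = c(300L, 800L),
    acr_props = c(shared = 0.70, novel = 0.05, silent = 0.05,
                  `SPA-M` = 0.05, `SPA-P` = 0.05, `TE-driven` = 0.10),
    acr_read_mean = 30, acr_read_size = 10, acr_min_reads = 5L,
    peak_jitter = 30L, n_singleton_peaks = 30L,
    novel_trans_link = 0.6,  # fraction of novel ACRs planted in the bodies
                             # of transgressive-up genes
    # methylome
    n_cytosines = 50000L,
    meth_baseline = c(CG = 0.6, CHG = 0.3, CHH = 0.1),
    te_meth_boost = 0.25, proximal_meth_factor = 0.5,
    coverage_mean = 30,
    n_dmrs = 200L, dmr_delta = 0.4, dmr_sites = 8L, dmr_context = "CG",
    dmr_base_level = 0.3,
    # sRNA
    n_srna_loci = 300L, srna_reads_mean = 20, srna_shift = 2,
    srna_total = NULL)           # NULL: per-sample read count is the total
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  modifyList(cfg, over)
}

# run expr with a local, seeded RNG stream; restores the caller's stream
.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Simulate the genome annotation
#'
#' Places non-overlapping genes per chromosome, pairs a configured fraction
#' of A-subgenome genes with C-subgenome homologs, and scatters TEs with a
#' preference for intergenic space. Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()] list.
#' @return list with `genes` (gene table), `tes` (TE table), `homologs`
#'   (`a_gene`, `c_gene`).
#' @export
make_genome <- function(config = sim_config()) {
  .with_seed(config$seed + 11L, {
    chroms <- names(config$chrom_lengths)
    per <- table(factor(rep_len(chroms, config$n_genes), levels = chroms))
    # genes occupy a gene-rich arm (first 60% of each chromosome), leaving a
    # gene-poor arm where distal regulatory regions and TEs can be planted
    genes <- do.call(rbind, lapply(chroms, function(ch) {
      n <- per[[ch]]
      len <- floor(config$chrom_lengths[[ch]] * 0.6)
      slot <- floor(len / n)
      gl <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                   n, replace = TRUE)
      gl <- pmin(gl, slot - 200L)
      start <- (seq_len(n) - 1L) * slot +
        sample.int(max(1L, slot - max(gl) - 100L), n, replace = TRUE)
      data.frame(chrom = ch, start = as.integer(start),
                 end = as.integer(start + gl),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    genes$subgenome <- subgenome_of(genes$chrom)
    ord <- order(genes$subgenome, genes$chrom, genes$start)
    genes <- genes[ord, ]
    nA <- sum(genes$subgenome == "A"); nC <- sum(genes$subgenome == "C")
    genes$gene_id <- NA_character_
    genes$gene_id[genes$subgenome == "A"] <- sprintf("GA%04d", seq_len(nA))
    genes$gene_id[genes$subgenome == "C"] <- sprintf("GC%04d", seq_len(nC))
    n_pairs <- floor(config$homolog_fraction * min(nA, nC))
    a_ids <- genes$gene_id[genes$subgenome == "A"][seq_len(n_pairs)]
    c_ids <- genes$gene_id[genes$subgenome == "C"][seq_len(n_pairs)]
    homologs <- data.frame(a_gene = a_ids, c_gene = c_ids,
                           stringsAsFactors = FALSE)
    genes$homolog_partner <- NA_character_
    genes$homolog_partner[match(a_ids, genes$gene_id)] <- c_ids
    genes$homolog_partner[match(c_ids, genes$gene_id)] <- a_ids
    # TEs: drawn uniformly, then shifted off gene bodies where easy
    tes <- do.call(rbind, lapply(chroms, function(ch) {
      n <- ceiling(config$n_tes / length(chroms))
      if (n == 0)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), te_class = character(0)))
      w <- sample(seq(config$te_length_range[1], config$te_length_range[2]),
                  n, replace = TRUE)
      s <- sample.int(config$chrom_lengths[[ch]] - max(w), n)
      data.frame(chrom = ch, start = as.integer(s), end = as.integer(s + w),
                 te_class = sample(c("LTR/Gypsy", "LTR/Copia", "LINE", "DNA"),
                                   n, replace = TRUE, prob = c(.4, .3, .2, .1)),
                 stringsAsFactors = FALSE)
    }))
    gidx <- classify_position(tes, genes, 1L) == "genic"
    tes <- rbind(tes[!gidx, ], tes[gidx, ][
      overlap_fraction(tes[gidx, ], genes) < 0.5, ])
    tes <- tes[order(tes$chrom, tes$start), ]
    rownames(genes) <- rownames(tes) <- NULL
    genes <- genes[order(genes$chrom, genes$start), ]
    rownames(genes) <- NULL
    list(genes = genes, tes = tes, homologs = homologs)
  })
}

# draw NB counts: one row per gene, columns = replicates
.nb_draw <- function(mu, reps, dispersion, depth) {
  n <- length(mu)
  out <- matrix(0L, n, reps)
  for (j in seq_len(reps)) {
    m <- mu * depth[j]
    k <- integer(n)
    pos <- m > 0
    k[pos] <- rnbinom(sum(pos), mu = m[pos], size = 1 / dispersion)
    out[, j] <- k
  }
  out
}

#' Simulate the expression experiment
#'
#' Draws NB replicate counts for the maternal (AACC), paternal (AA) and F1
#' hybrid (AAC) samples with planted per-gene classes: additive genes sit at
#' the mid-parent value; ELD genes copy one parent while parents differ
#' `parent_fold`-fold; transgressive genes exceed (or fall below) both
#' parents `transgressive_fold`-fold; SPE genes are structural zeros in the
#' silent parent; dosage-dependent genes scale with the subgenome dosage
#' vector; and every C-subgenome gene is a structural zero in the paternal
#' sample. Planted expression classes live on the A subgenome (the only
#' parent-comparable one); dosage classes are planted on both subgenomes.
#'
#' @param config a [sim_config()] list.
#' @param genome output of [make_genome()].
#' @return list with `counts` (genes x 9 samples), `lengths`, `manifest`
#'   (sample, role, replicate), and `truth` (per-gene `class`, `dosage`).
#' @export
simulate_expression <- function(config = sim_config(), genome = make_genome(config)) {
  .with_seed(config$seed + 23L, {
    genes <- genome$genes
    n <- nrow(genes)
    reps <- config$replicates
    isA <- genes$subgenome == "A"
    truth <- data.frame(gene_id = genes$gene_id, subgenome = genes$subgenome,
                        class = "background", dosage = NA_character_,
                        stringsAsFactors = FALSE)
    # planted expression classes live on the parent-comparable A subgenome;
    # class proportions are fractions of the A-subgenome gene count
    a_pool <- sample(which(isA))
    k <- round(config$class_props * length(a_pool))
    take <- function(m) { out <- a_pool[seq_len(m)]; a_pool <<- a_pool[-seq_len(m)]; out }
    cls_idx <- lapply(k, take)
    for (cl in names(cls_idx)) truth$class[cls_idx[[cl]]] <- cl
    # dosage classes: half on the remaining A genes, half on C genes
    kd <- round(config$dosage_props * sum(isA))
    c_pool <- sample(which(!isA))
    dep_a <- a_pool[seq_len(ceiling(kd[["dependent"]] / 2))]
    a_pool <- setdiff(a_pool, dep_a)
    dep_c <- c_pool[seq_len(floor(kd[["dependent"]] / 2))]
    c_pool <- setdiff(c_pool, dep_c)
    ind_a <- a_pool[seq_len(ceiling(kd[["independent"]] / 2))]
    ind_c <- c_pool[seq_len(floor(kd[["independent"]] / 2))]
    truth$dosage[c(dep_a, dep_c)] <- "dependent"
    truth$dosage[c(ind_a, ind_c)] <- "independent"
    # per-gene genotype means
    base <- rlnorm(n, config$nb_meanlog, config$nb_sdlog)
    mu_m <- base; mu_p <- base; mu_h <- base
    f <- config$parent_fold
    flip <- runif(n) < 0.5        # which parent is the high one, where relevant
    differ <- runif(n) < 0.5      # additive/background genes: parents equal or not
    hi <- ifelse(flip, f, 1); lo <- ifelse(flip, 1, f)
    bg <- truth$class %in% c("background", "additive")
    mu_m[bg] <- base[bg] * ifelse(differ[bg], hi[bg], 1)
    mu_p[bg] <- base[bg] * ifelse(differ[bg], lo[bg], 1)
    mu_h[bg] <- (mu_m[bg] + mu_p[bg]) / 2
    el <- truth$class == "ELD-M"
    mu_m[el] <- base[el] * hi[el]; mu_p[el] <- base[el] * lo[el]
    mu_h[el] <- mu_m[el]
    el <- truth$class == "ELD-P"
    mu_m[el] <- base[el] * hi[el]; mu_p[el] <- base[el] * lo[el]
    mu_h[el] <- mu_p[el]
    tr <- truth$class == "transgressive-up"
    mu_h[tr] <- pmax(mu_m[tr], mu_p[tr]) * config$transgressive_fold
    tr <- truth$class == "transgressive-down"
    mu_h[tr] <- pmin(mu_m[tr], mu_p[tr]) / config$transgressive_fold
    sp <- truth$class == "SPE-M"
    mu_p[sp] <- 0; mu_h[sp] <- mu_m[sp] * 2 / 3
    sp <- truth$class == "SPE-P"
    mu_m[sp] <- 0; mu_h[sp] <- mu_p[sp] / 3
    # dosage classes: low-dispersion, abundant transcripts
    ds <- rlnorm(n, config$dosage_meanlog, config$dosage_sdlog)
    i <- dep_a; mu_m[i] <- ds[i] / 2; mu_h[i] <- ds[i] * 2 / 3; mu_p[i] <- ds[i]
    i <- dep_c; mu_m[i] <- ds[i] / 2; mu_h[i] <- ds[i] / 3; mu_p[i] <- 0
    i <- ind_a; mu_m[i] <- ds[i]; mu_h[i] <- ds[i]; mu_p[i] <- ds[i]
    # independent C genes: dosage-compensation overshoot (hybrid 2x maternal),
    # which decorrelates expression from the (1/2, 1/3, 0) dosage vector
    i <- ind_c; mu_m[i] <- ds[i]; mu_h[i] <- 2 * ds[i]; mu_p[i] <- 0
    # the paternal AA line has no C subgenome at all; the hybrid carries one
    # maternal C copy, so non-dosage C genes sit at half the maternal level,
    # which is exactly the mid-parent value of (maternal, 0)
    nondos_c <- !isA & is.na(truth$dosage)
    mu_p[!isA] <- 0
    mu_h[nondos_c] <- mu_m[nondos_c] / 2
    depth <- matrix(runif(3 * reps, config$depth_range[1], config$depth_range[2]),
                    nrow = 3)
    counts <- cbind(.nb_draw(mu_m, reps, config$dispersion, depth[1, ]),
                    .nb_draw(mu_h, reps, config$dispersion, depth[2, ]),
                    .nb_draw(mu_p, reps, config$dispersion, depth[3, ]))
    # redraw the dosage-class rows at their own dispersion
    di <- which(!is.na(truth$dosage))
    if (length(di)) {
      counts[di, ] <- cbind(
        .nb_draw(mu_m[di], reps, config$dosage_dispersion, depth[1, ]),
        .nb_draw(mu_h[di], reps, config$dosage_dispersion, depth[2, ]),
        .nb_draw(mu_p[di], reps, config$dosage_dispersion, depth[3, ]))
    }
    storage.mode(counts) <- "integer"
    samples <- c(paste0("maternal_", seq_len(reps)),
                 paste0("hybrid_", seq_len(reps)),
                 paste0("paternal_", seq_len(reps)))
    dimnames(counts) <- list(genes$gene_id, samples)
    manifest <- data.frame(sample = samples,
                           role = rep(c("maternal", "hybrid", "paternal"),
                                      each = reps),
                           replicate = rep(seq_len(reps), 3),
                           stringsAsFactors = FALSE)
    list(counts = counts, lengths = setNames(genes$end - genes$start,
                                             genes$gene_id),
         manifest = manifest, truth = truth)
  })
}

#' Simulate per-replicate ATAC peaks with planted ACR categories
#'
#' Plants `n_acrs` loci with categories shared / novel / silent / SPA-M /
#' SPA-P / TE-driven. Present samples receive a peak in every replicate,
#' jittered by up to `peak_jitter` bp per edge so the strict >50 bp merge
#' rule is exercised; absent samples have no peak at all (structural zeros).
#' Novel, silent and SPA loci live on the A subgenome; the paternal sample
#' never has C-subgenome peaks. Singleton peaks present in only one
#' replicate are sprinkled in as merge-rule distractors.
#'
#' A configured fraction of the novel ACRs is planted inside the bodies of
#' planted transgressive-up genes (when `expr_truth` is supplied), emulating
#' hybridization-born accessibility driving transgressive expression; the
#' rest land in unoccupied intergenic space.
#'
#' @param config a [sim_config()] list.
#' @param genome output of [make_genome()].
#' @param expr_truth optional per-gene truth table from
#'   [simulate_expression()], used to target novel ACRs at transgressive-up
#'   genes.
#' @return list with `peaks` (nested list: sample -> replicate -> peak
#'   table) and `truth` (locus table with `category`).
#' @export
simulate_acrs <- function(config = sim_config(), genome = make_genome(config),
                          expr_truth = NULL) {
  .with_seed(config$seed + 37L, {
    chroms <- names(config$chrom_lengths)
    a_chroms <- chroms[subgenome_of(chroms) == "A"]
    reps <- config$replicates
    n <- config$n_acrs
    cat_n <- round(config$acr_props * n)
    cat_n[["shared"]] <- n - sum(cat_n[names(cat_n) != "shared"])
    categories <- rep(names(cat_n), cat_n)
    widths <- sample(seq(config$acr_width_range[1], config$acr_width_range[2]),
                     n, replace = TRUE)
    # TE-driven loci are placed inside a TE; all others on a grid clear of
    # previously used space, A-subgenome-only where the category demands it
    tes <- genome$tes
    big_tes <- tes[tes$end - tes$start >= max(widths) + 20, ]
    chrom <- character(n); start <- integer(n)
    slot <- 1500L
    grid_pos <- lapply(chroms, function(ch)
      seq(0L, config$chrom_lengths[[ch]] - slot, by = slot))
    names(grid_pos) <- chroms
    used <- lapply(chroms, function(ch) integer(0)); names(used) <- chroms
    pick_slot <- function(ch_set) {
      ch <- sample(ch_set, 1)
      free <- setdiff(grid_pos[[ch]], used[[ch]])
      s <- sample(free, 1)
      used[[ch]] <<- c(used[[ch]], s)
      c(ch, s)
    }
    # TE-driven loci first: accept non-overlapping TEs, then retire every
    # grid slot their footprint touches so no other locus can collide
    te_idx <- which(categories == "TE-driven")
    accepted <- big_tes[0, ]
    for (j in sample.int(nrow(big_tes))) {
      if (nrow(accepted) >= length(te_idx)) break
      cand <- big_tes[j, ]
      clash <- nrow(accepted) && any(
        accepted$chrom == cand$chrom &
        accepted$start < cand$end & cand$start < accepted$end)
      if (!clash) accepted <- rbind(accepted, cand)
    }
    if (nrow(accepted) < length(te_idx))
      stop("TE density too low to plant the requested TE-driven ACRs",
           call. = FALSE)
    for (z in seq_along(te_idx)) {
      i <- te_idx[z]
      chrom[i] <- accepted$chrom[z]
      start[i] <- accepted$start[z] + 10L
      touched <- grid_pos[[chrom[i]]]
      touched <- touched[touched + slot > accepted$start[z] - 100L &
                         touched < accepted$end[z] + 100L]
      used[[chrom[i]]] <- c(used[[chrom[i]]], touched)
    }
    # a fraction of novel ACRs sits inside transgressive-up gene bodies
    linked <- integer(0)
    if (!is.null(expr_truth) && config$novel_trans_link > 0) {
      nov_idx <- which(categories == "novel")
      n_link <- round(config$novel_trans_link * length(nov_idx))
      cand <- genome$genes[genome$genes$gene_id %in%
                             expr_truth$gene_id[expr_truth$class ==
                                                  "transgressive-up"], ]
      cand <- cand[cand$end - cand$start >= 500, ]
      # keep clear of the TE-driven ACR footprints
      if (nrow(accepted) && nrow(cand)) {
        clash <- vapply(seq_len(nrow(cand)), function(z)
          any(accepted$chrom == cand$chrom[z] &
              accepted$start < cand$end[z] + 200 &
              cand$start[z] - 200 < accepted$end), TRUE)
        cand <- cand[!clash, ]
      }
      n_link <- min(n_link, nrow(cand))
      if (n_link > 0) {
        pick <- cand[sample.int(nrow(cand), n_link), ]
        linked <- nov_idx[seq_len(n_link)]
        chrom[linked] <- pick$chrom
        start[linked] <- pick$start + 100L
        widths[linked] <- pmin(300L, pick$end - pick$start - 200L)
        for (z in seq_len(n_link)) {
          touched <- grid_pos[[pick$chrom[z]]]
          touched <- touched[touched + slot > pick$start[z] - 100L &
                             touched < pick$end[z] + 100L]
          used[[pick$chrom[z]]] <- c(used[[pick$chrom[z]]], touched)
        }
      }
    }
    for (i in seq_len(n)) {
      if (categories[i] == "TE-driven" || i %in% linked) next
      ch_set <- if (categories[i] %in% c("novel", "silent", "SPA-M", "SPA-P"))
        a_chroms else chroms
      ps <- pick_slot(ch_set)
      chrom[i] <- ps[1]; start[i] <- as.integer(ps[2]) + 100L
    }
    truth <- data.frame(acr_id = sprintf("ACR%04d", seq_len(n)),
                        chrom = chrom, start = start,
                        end = start + widths, category = categories,
                        stringsAsFactors = FALSE)
    truth$subgenome <- subgenome_of(truth$chrom)
    presence <- list(
      shared = c(maternal = TRUE, hybrid = TRUE, paternal = TRUE),
      `TE-driven` = c(maternal = TRUE, hybrid = TRUE, paternal = TRUE),
      novel = c(maternal = FALSE, hybrid = TRUE, paternal = FALSE),
      silent = c(maternal = TRUE, hybrid = FALSE, paternal = TRUE),
      `SPA-M` = c(maternal = TRUE, hybrid = TRUE, paternal = FALSE),
      `SPA-P` = c(maternal = FALSE, hybrid = TRUE, paternal = TRUE))
    draw_reads <- function(m) pmax(config$acr_min_reads,
                                   rnbinom(m, mu = config$acr_read_mean,
                                           size = config$acr_read_size))
    peaks <- list()
    for (smp in c("maternal", "hybrid", "paternal")) {
      pres <- vapply(truth$category, function(cat) presence[[cat]][[smp]], TRUE)
      if (smp == "paternal") pres <- pres & truth$subgenome == "A"
      idx <- which(pres)
      peaks[[smp]] <- lapply(seq_len(reps), function(r) {
        j1 <- sample(seq(-config$peak_jitter, config$peak_jitter),
                     length(idx), replace = TRUE)
        j2 <- sample(seq(-config$peak_jitter, config$peak_jitter),
                     length(idx), replace = TRUE)
        df <- data.frame(chrom = truth$chrom[idx],
                         start = pmax(0L, truth$start[idx] + j1),
                         end = truth$end[idx] + j2,
                         count = draw_reads(length(idx)),
                         stringsAsFactors = FALSE)
        # singleton distractor peaks in replicate 1 only
        if (r == 1 && config$n_singleton_peaks > 0) {
          m <- config$n_singleton_peaks
          sl <- t(vapply(seq_len(m), function(z) pick_slot(chroms),
                         c("", "")))
          df <- rbind(df, data.frame(
            chrom = sl[, 1], start = as.integer(sl[, 2]) + 200L,
            end = as.integer(sl[, 2]) + 200L + 250L,
            count = draw_reads(m), stringsAsFactors = FALSE))
        }
        df <- df[order(df$chrom, df$start), ]
        rownames(df) <- NULL
        df
      })
      names(peaks[[smp]]) <- paste0("rep", seq_len(reps))
    }
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate per-cytosine WGBS calls with planted DMR bins
#'
#' Binomial counts at uniformly placed cytosines with context baselines
#' (CG 0.6, CHG 0.3, CHH 0.1 by default), elevated inside TEs and depressed
#' within 2 kb of genes. The parents share one methylation landscape; the
#' paternal sample has A-subgenome positions only. Planted DMR bins carry
#' `dmr_sites` extra cytosines of the DMR context whose hybrid rate is
#' shifted by `dmr_delta` (hyper: up; hypo: down) against the parental rate.
#'
#' @param config a [sim_config()] list.
#' @param genome output of [make_genome()].
#' @return list with `calls` (named list maternal/paternal/hybrid) and
#'   `truth` (bin table with `direction`).
#' @export
simulate_methylome <- function(config = sim_config(), genome = make_genome(config)) {
  .with_seed(config$seed + 53L, {
    chroms <- names(config$chrom_lengths)
    n <- config$n_cytosines
    chrom <- sample(chroms, n, replace = TRUE,
                    prob = config$chrom_lengths / sum(config$chrom_lengths))
    pos <- vapply(chrom, function(ch) sample.int(config$chrom_lengths[[ch]], 1L),
                  1L)
    context <- sample(METH_CONTEXTS, n, replace = TRUE, prob = c(.25, .25, .5))
    sites <- data.frame(chrom = chrom, pos = as.integer(pos - 1L),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        context = context, stringsAsFactors = FALSE)
    sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), ]
    rate <- unname(config$meth_baseline[sites$context])
    sites$end <- sites$pos + 1L
    sites$start <- sites$pos
    in_te <- overlap_fraction(sites[, c("chrom", "start", "end")],
                              genome$tes) > 0
    prox <- classify_position(sites[, c("chrom", "start", "end")],
                              genome$genes, 2000L) == "proximal"
    rate[in_te] <- pmin(0.95, rate[in_te] + config$te_meth_boost)
    rate[prox & !in_te] <- rate[prox & !in_te] * config$proximal_meth_factor
    sites$rate_parent <- rate
    sites$rate_hybrid <- rate
    # planted DMR bins: fresh sites appended on A chromosomes
    a_chroms <- chroms[subgenome_of(chroms) == "A"]
    nb <- config$n_dmrs
    bin_w <- 200L
    bch <- sample(a_chroms, nb, replace = TRUE)
    bstart <- vapply(bch, function(ch)
      as.integer(sample.int(config$chrom_lengths[[ch]] %/% bin_w - 1L, 1L) - 1L) * bin_w,
      1L)
    dup <- duplicated(paste(bch, bstart))
    bch <- bch[!dup]; bstart <- bstart[!dup]
    direction <- rep(c("hyper", "hypo"), length.out = length(bch))
    dmr_truth <- data.frame(chrom = bch, start = bstart, end = bstart + bin_w,
                            context = config$dmr_context,
                            direction = direction, stringsAsFactors = FALSE)
    extra <- do.call(rbind, lapply(seq_len(nrow(dmr_truth)), function(i) {
      k <- config$dmr_sites
      p0 <- config$dmr_base_level
      p1 <- if (dmr_truth$direction[i] == "hyper") p0 + config$dmr_delta
            else p0 + config$dmr_delta  # parents high, hybrid drops for hypo
      data.frame(chrom = dmr_truth$chrom[i],
                 pos = as.integer(dmr_truth$start[i] +
                                    sort(sample.int(bin_w, k))) - 1L,
                 strand = "+", context = config$dmr_context,
                 rate_parent = if (dmr_truth$direction[i] == "hyper") p0 else p1,
                 rate_hybrid = if (dmr_truth$direction[i] == "hyper") p1 else p0,
                 stringsAsFactors = FALSE)
    }))
    sites <- rbind(sites[, c("chrom", "pos", "strand", "context",
                             "rate_parent", "rate_hybrid")], extra)
    # on position clashes the planted (later) site wins
    sites <- sites[!duplicated(paste(sites$chrom, sites$pos), fromLast = TRUE), ]
    sites <- sites[order(sites$chrom, sites$pos, sites$context), ]
    draw <- function(rates) {
      cov <- rpois(nrow(sites), config$coverage_mean)
      meth <- rbinom(nrow(sites), cov, rates)
      data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
                 context = sites$context, meth = meth, unmeth = cov - meth,
                 stringsAsFactors = FALSE)
    }
    maternal <- draw(sites$rate_parent)
    paternal <- draw(sites$rate_parent)
    paternal <- paternal[subgenome_of(paternal$chrom) == "A", ]
    hybrid <- draw(sites$rate_hybrid)
    list(calls = list(maternal = maternal, paternal = paternal,
                      hybrid = hybrid),
         truth = dmr_truth)
  })
}

#' Simulate mapped small-RNA reads
#'
#' Background sRNA loci get equal expected read counts in the hybrid and
#' in-silico samples; loci inside hyper-DMR bins get `srna_shift`-fold more
#' reads in the in-silico sample, and loci inside hypo-DMR bins the reverse.
#' Read lengths are drawn from 18-30 nt with modes at 21 and 24.
#'
#' @param config a [sim_config()] list.
#' @param dmr_truth DMR truth table from [simulate_methylome()].
#' @return list with `reads` (named list hybrid/insilico of read tables) and
#'   `truth` (locus table).
#' @export
simulate_srna <- function(config = sim_config(), dmr_truth) {
  .with_seed(config$seed + 71L, {
    chroms <- names(config$chrom_lengths)
    nb <- config$n_srna_loci
    loc <- data.frame(
      chrom = sample(chroms, nb, replace = TRUE),
      stringsAsFactors = FALSE)
    loc$start <- vapply(loc$chrom, function(ch)
      sample.int(config$chrom_lengths[[ch]] - 400L, 1L), 1L)
    loc$kind <- "background"
    dm <- dmr_truth
    loc <- rbind(loc, data.frame(chrom = dm$chrom, start = dm$start + 10L,
                                 kind = paste0("dmr-", dm$direction),
                                 stringsAsFactors = FALSE))
    mu_h <- rep(config$srna_reads_mean, nrow(loc))
    mu_i <- mu_h
    mu_i[loc$kind == "dmr-hyper"] <- mu_h[loc$kind == "dmr-hyper"] * config$srna_shift
    mu_h[loc$kind == "dmr-hypo"] <- mu_i[loc$kind == "dmr-hypo"] * config$srna_shift
    draw_lengths <- function(m)
      sample(18:30, m, replace = TRUE,
             prob = c(rep(.03, 3), .25, .04, .04, .25, rep(.03, 6)) /
               sum(c(rep(.03, 3), .25, .04, .04, .25, rep(.03, 6))))
    draw_sample <- function(mu) {
      counts <- pmax(1L, rnbinom(length(mu), mu = mu, size = 10))
      idx <- rep(seq_along(mu), counts)
      len <- draw_lengths(length(idx))
      off <- sample.int(150L, length(idx), replace = TRUE)
      data.frame(chrom = loc$chrom[idx],
                 start = as.integer(loc$start[idx] + off),
                 end = as.integer(loc$start[idx] + off + len),
                 length = as.integer(len), stringsAsFactors = FALSE)
    }
    list(reads = list(hybrid = draw_sample(mu_h), insilico = draw_sample(mu_i)),
         truth = loc)
  })
}

#' Simulate the complete study
#'
#' Runs every assay generator off one seed and returns the bundle of inputs
#' and ground truth used by the pipeline tests and the acceptance run.
#'
#' @param config a [sim_config()] list.
#' @return list with `config`, `genome`, `expression`, `acr`, `meth`, `srna`.
#' @export
simulate_all <- function(config = sim_config()) {
  genome <- make_genome(config)
  expression <- simulate_expression(config, genome)
  meth <- simulate_methylome(config, genome)
  list(config = config,
       genome = genome,
       expression = expression,
       acr = simulate_acrs(config, genome, expression$truth),
       meth = meth,
       srna = simulate_srna(config, meth$truth))
}

#' Write a simulated study to disk
#'
#' Materializes a [simulate_all()] bundle as the plain-text formats the
#' pipeline readers consume: `genes.gff3`, `tes.bed`, `homologs.tsv`,
#' `counts.tsv`, `manifest.tsv`, `peaks/<sample>_<rep>.bed`,
#' `meth/<sample>.cx.tsv`, `srna/<sample>.bed` and `truth.json`.
#'
#' @param sim output of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "meth"), showWarnings = FALSE)
  dir.create(file.path(dir, "srna"), showWarnings = FALSE)
  write_gff_genes(sim$genome$genes, file.path(dir, "genes.gff3"))
  te <- sim$genome$tes; te$name <- te$te_class
  write_bed(te, file.path(dir, "tes.bed"), extra_cols = "name")
  write.table(sim$genome$homologs, file.path(dir, "homologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  counts <- data.frame(gene_id = rownames(sim$expression$counts),
                       length = sim$expression$lengths[rownames(sim$expression$counts)],
                       sim$expression$counts, check.names = FALSE)
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$expression$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (smp in names(sim$acr$peaks))
    for (r in names(sim$acr$peaks[[smp]])) {
      pk <- sim$acr$peaks[[smp]][[r]]
      pk$name <- "."; pk$score <- pk$count
      write_bed(pk, file.path(dir, "peaks", paste0(smp, "_", r, ".bed")),
                extra_cols = c("name", "score"))
    }
  for (smp in names(sim$meth$calls))
    write_cx_report(sim$meth$calls[[smp]],
                    file.path(dir, "meth", paste0(smp, ".cx.tsv")))
  for (smp in names(sim$srna$reads)) {
    rd <- sim$srna$reads[[smp]]; rd$name <- "."; rd$score <- rd$length
    write_bed(rd, file.path(dir, "srna", paste0(smp, ".bed")),
              extra_cols = c("name", "score"))
  }
  truth <- list(genes = sim$expression$truth, acrs = sim$acr$truth,
                dmrs = sim$meth$truth, srna = sim$srna$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "columns",
                       digits = NA)
  invisible(dir)
}
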