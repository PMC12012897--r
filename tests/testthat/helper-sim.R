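# One default simulated study plus its pipeline run, shared across test
# files (computed lazily, once per session).

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_all(sim_config(seed = 1))
  .sim_cache$sim
}

default_run <- function() {
  if (is.null(.sim_cache$run))
    .sim_cache$run <- run_pipeline(default_sim())
  .sim_cache$run
}

# small genome/config for fast structural tests
small_config <- function(seed = 5) {
  sim_config(seed = seed,
             chrom_lengths = c(A01 = 2e5, C01 = 2e5),
             n_genes = 40L, n_tes = 30L, n_acrs = 60L,
             n_cytosines = 4000L, n_dmrs = 20L,
             n_srna_loci = 40L, n_singleton_peaks = 5L)
}

# match planted truth loci to called ACR intervals by overlap
match_truth_acrs <- function(truth, acrs) {
  idx <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- which(acrs$chrom == truth$chrom[i] &
                 acrs$start < truth$end[i] & truth$start[i] < acrs$end)
    if (length(hit) == 1) idx[i] <- hit
  }
  idx
}
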