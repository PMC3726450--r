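# Shared small-scale simulation fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

small_cfg <- function(seed = 11L) {
  sim_config(n_mirna_genes = 10L, n_families = 6L, reads_per_sample = 3000L,
             n_samples = 6L, genome_length = 30000L, utr_count = 20L,
             seed = seed)
}

small_run <- function(seed = 11L) {
  key <- paste0("run", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- small_cfg(seed)
  sim <- simulate_genome(cfg)
  reads_dir <- file.path(tempdir(), paste0("smoltmir_reads_", seed))
  rd <- simulate_reads(sim, cfg, reads_dir)
  pp <- preprocess_run(rd$manifest)
  idx <- index_genome(sim$genome)
  disc <- discover_mirnas(pp$collapsed, idx, sim$annotation)
  out <- list(cfg = cfg, sim = sim, reads = rd, pp = pp, idx = idx,
              disc = disc)
  .fixture_env[[key]] <- out
  out
}

# match an accepted gene back to the planted truth table; returns the truth
# row index or NA
match_truth <- function(gene, truth_genes) {
  t5 <- ifelse(truth_genes$strand == "+", truth_genes$mature_start,
               truth_genes$mature_end)
  m5 <- if (gene$strand == "+") gene$mature[1] else gene$mature[2]
  hit <- which(truth_genes$strand == gene$strand & abs(t5 - m5) <= 1 &
                 truth_genes$pre_start <= gene$pre[2] &
                 truth_genes$pre_end >= gene$pre[1])
  if (length(hit) > 0) hit[1] else NA_integer_
}
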