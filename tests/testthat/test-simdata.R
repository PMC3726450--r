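test_that("configuration invariants are validated", {
  expect_error(sim_config(star_fraction = 1.2))
  expect_error(sim_config(mature_length_range = c(12, 22)))
  expect_error(sim_config(reads_per_sample = 0))
  cfg <- sim_config()
  expect_equal(cfg$n_samples, 18L)
  expect_equal(cfg$mature_length_range, c(18L, 26L))
})

test_that("perfect hairpin construction has the stated duplex geometry", {
  set.seed(1)
  hp <- make_hairpin(mature_len = 22L, loop_len = 4L, bulges = NULL,
                     wobbles = 0L)
  n <- nchar(hp$precursor)
  mat <- substr(hp$precursor, hp$mature[1], hp$mature[2])
  # star of a perfect inverted repeat: reverse complement region shifted 2 nt
  star_expected_iv <- c(n + 1 - hp$mature[2] + 2, n + 1 - hp$mature[1] + 2)
  expect_equal(hp$star, as.integer(star_expected_iv))
  expect_equal(substr(hp$precursor, hp$star[1], hp$star[2]),
               substr(paste0(revcomp(substr(hp$precursor, hp$mature[1] - 2,
                                            hp$mature[2] - 2))), 1, 22))
  expect_gte(nchar(hp$precursor), 65)
})

test_that("short matures still yield >= 65-nt precursors", {
  set.seed(2)
  hp <- make_hairpin(mature_len = 18L, loop_len = 3L, bulges = NULL)
  expect_gte(nchar(hp$precursor), 65)
  expect_gte(hp$pre[2] - hp$pre[1] + 1, 65)
  expect_error(make_hairpin(mature_len = 17L), "mature_len")
  expect_error(make_hairpin(loop_len = 2L), "loop_len")
  expect_error(make_hairpin(bulges = c(9L)), "unsatisfiable")
})

test_that("constructed hairpins refold with valid Dicer overhangs", {
  set.seed(5)
  for (i in 1:20) {
    hp <- make_hairpin(mature_len = sample(18:26, 1),
                       loop_len = sample(4:8, 1),
                       bulges = if (i %% 3 == 0) NULL else
                         sample(1:3, sample(1:2, 1), replace = TRUE))
    st <- mfe_fold(hp$precursor)
    expect_true(is_single_hairpin(st, mature = hp$mature,
                                  region = hp$pre))
    expect_true(check_overhang(st, hp$mature, hp$star))
    star <- predict_star(st, hp$mature)
    expect_equal(star, hp$star)
  }
})

test_that("genome simulation plants genes, duplicates and decoys", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  tg <- sim$truth$genes
  expect_equal(nrow(tg), cfg$n_mirna_genes)
  # floor(0.2 * 10 / 2) = 1 identical pri pair
  expect_equal(sim$truth$n_duplicate_pairs, 1L)
  expect_equal(sum(!is.na(tg$duplicate_of)), 1L)
  dup <- tg[!is.na(tg$duplicate_of), ]
  orig <- tg[tg$gene_id == dup$duplicate_of[1], ]
  expect_equal(dup$pri_seq, orig$pri_seq)
  # decoy classes recorded in the annotation
  expect_equal(sum(sim$truth$decoys$class == "tRNA"), cfg$n_decoy_trna)
  # planted precursor sequence is on the genome at its coordinates
  g <- tg[1, ]
  gseq <- as.character(Biostrings::subseq(sim$genome[[g$chrom]],
                                          g$pri_start, g$pri_end))
  if (g$strand == "-") gseq <- revcomp(gseq)
  expect_equal(gseq, g$pri_seq)
  # genes do not overlap each other
  ord <- order(tg$pri_start)
  expect_true(all(tg$pri_start[ord][-1] > tg$pri_end[ord][-nrow(tg)]))
})

test_that("simulation is deterministic in the seed", {
  cfg <- small_cfg(seed = 99L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- simulate_genome(cfg, out_dir = d1)
  s2 <- simulate_genome(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(s1$truth$genes, s2$truth$genes)
})

test_that("read simulation honours star fraction, jitter and conservation", {
  cfg <- sim_config(n_mirna_genes = 4L, n_families = 3L,
                    reads_per_sample = 800L, n_samples = 2L,
                    genome_length = 20000L, star_fraction = 0,
                    five_prime_jitter = 0, decoy_read_fraction = 0,
                    seed = 31L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg, file.path(tempdir(), "nostar"))
  pp <- preprocess_run(rd$manifest)
  # no star reads, no jitter: exactly one collapsed sequence per gene
  # (identical duplicates share their sequence)
  expected <- length(unique(sim$truth$genes$mature_seq))
  expect_equal(length(pp$collapsed$sequence), expected)
  expect_setequal(pp$collapsed$sequence, unique(sim$truth$genes$mature_seq))
  # conservation: collapsed totals equal the number of simulated pairs
  expect_equal(sum(pp$collapsed$total), 2L * 800L)
})

test_that("transcriptome simulation plants recoverable seed sites", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  tx <- simulate_transcriptome(sim, cfg)
  expect_equal(length(tx$utrs), cfg$utr_count)
  expect_equal(nrow(tx$sites), cfg$utr_count * cfg$planted_sites_per_utr)
  for (i in seq_len(min(10, nrow(tx$sites)))) {
    s <- tx$sites[i, ]
    found <- seed_sites(s$mirna_seq, tx$utrs[[s$utr_id]])
    expect_true(any(found$start <= s$end & found$end >= s$start),
                info = paste(s$utr_id, s$mirna_id))
  }
  # no planted sites -> background only
  cfg0 <- small_cfg()
  cfg0$planted_sites_per_utr <- 0L
  tx0 <- simulate_transcriptome(sim, cfg0)
  expect_equal(nrow(tx0$sites), 0L)
})
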