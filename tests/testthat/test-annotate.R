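test_that("mature calling picks the dominant read and scores 5' consistency", {
  col <- structure(list(
    sequence = c("ACGTACGTACGTACGTACGTAC", "CGTACGTACGTACGTACGTACG"),
    counts = matrix(c(90L, 10L), 2, 1), total = c(90L, 10L)),
    class = "collapsed_reads")
  locus <- structure(list(chrom = "c", start = 100L, end = 122L,
                          strand = "+",
                          reads = data.frame(seq_id = 1:2,
                                             start = c(100L, 101L),
                                             end = c(121L, 122L)),
                          counts = 100, total = 100L), class = "locus")
  m <- call_mature(locus, col)
  expect_equal(m$sequence, "ACGTACGTACGTACGTACGTAC")
  expect_equal(m$five_prime_consistency, 0.9)

  # single read: consistency 1
  l1 <- locus; l1$reads <- locus$reads[1, ]; l1$total <- 90L
  expect_equal(call_mature(l1, col)$five_prime_consistency, 1.0)

  # equal totals: lexicographically smaller sequence wins
  col2 <- col; col2$total <- c(50L, 50L); col2$counts[] <- c(50L, 50L)
  expect_equal(call_mature(locus, col2)$sequence,
               "ACGTACGTACGTACGTACGTAC")
})

test_that("star prediction applies Dicer geometry on a perfect stem", {
  half <- "GCAGTCCAGGTACGGATCCGAGCTAGG" # 27-nt arm
  hp <- paste0(half, "AAAA", revcomp(half))
  st <- mfe_fold(hp)
  n <- nchar(hp)
  mature <- c(3L, 24L)
  star <- predict_star(st, mature)
  expect_equal(star, c(n + 1 - 24 + 2, n + 1 - 3 + 2))
  expect_true(check_overhang(st, mature, star))
  # mature centred on the loop: no star
  expect_null(predict_star(st, c(24L, 38L)))
})

test_that("overhang check rejects blunt and 1-nt overhang duplexes", {
  half <- "GCAGTCCAGGTACGGATCCGAGCTAGG"
  hp <- paste0(half, "AAAA", revcomp(half))
  st <- mfe_fold(hp)
  n <- nchar(hp)
  mature <- c(3L, 24L)
  perfect <- c(n + 1 - 24 + 2, n + 1 - 3 + 2)
  expect_true(check_overhang(st, mature, perfect))
  expect_false(check_overhang(st, mature, perfect - 2L)) # blunt
  expect_false(check_overhang(st, mature, perfect - 1L)) # 1-nt overhang
})

test_that("precursor definition stops at the first bulge", {
  # stem with a planted 2-nt bulge 8 bp outside the mature 5' end
  hp <- make_hairpin(mature_len = 22L, loop_len = 4L, bulges = 2L,
                     upper_len = 4L)
  st <- mfe_fold(hp$precursor)
  def <- define_precursor(st, hp$mature)
  expect_false(is.null(def))
  expect_equal(def$bounded_by, "bulge")
  expect_false(def$min_len_rule_used)
  expect_lte(max(abs(def$pre - hp$pre)), 2)
  expect_gte(def$pre[2] - def$pre[1] + 1, 65)
})

test_that("bulge-free stems fall back to the 65-nt minimum rule", {
  set.seed(21)
  # long perfect stem (50-bp arms), mature on the 5' arm
  hp <- make_hairpin(mature_len = 22L, loop_len = 4L, bulges = NULL,
                     upper_len = 4L)
  # pad the basal stem to ~50 bp arms
  pad <- random_dna(1, 20)
  prec <- paste0(pad, hp$precursor, revcomp(pad))
  st <- mfe_fold(prec)
  mature <- hp$mature + nchar(pad)
  def <- define_precursor(st, mature)
  expect_true(def$min_len_rule_used)
  len <- def$pre[2] - def$pre[1] + 1
  expect_gte(len, 65)
  expect_lte(len, 69) # innermost stem position reaching the minimum
})

test_that("precursor boundaries recover planted truth within 2 nt", {
  set.seed(77)
  n_ok <- 0L; n_tot <- 0L
  for (i in 1:50) {
    hp <- make_hairpin(mature_len = sample(18:26, 1),
                       loop_len = sample(4:8, 1),
                       bulges = sample(1:3, 1))
    st <- mfe_fold(hp$precursor)
    def <- define_precursor(st, hp$mature)
    n_tot <- n_tot + 1L
    if (!is.null(def) && max(abs(def$pre - hp$pre)) <= 2) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_tot, 0.9)
})

test_that("expression gate boundary behaviour is exact", {
  expect_true(expression_gate(rep(10, 18))) # mean exactly 10 kept
  counts <- c(rep(10, 17), 9); sum(counts) # 179 over 18 samples
  expect_false(expression_gate(counts)) # mean 9.94 removed
  expect_true(expression_gate(10, min_per_sample = 10)) # one sample at 10
  expect_false(expression_gate(rep(9, 18), min_per_sample = 10,
                               mode = "all_samples"))
  expect_true(expression_gate(rep(10, 18), mode = "all_samples"))
})

test_that("annotation masking uses >= 1 nt overlap, strand-blind", {
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  expect_false(mask_overlap("chr1", 150, 250, ann))
  expect_true(mask_overlap("chr1", 201, 250, ann)) # adjacency passes
  expect_false(mask_overlap("chr1", 200, 250, ann)) # 1-nt overlap rejects
  expect_true(mask_overlap("chr2", 150, 250, ann))
  expect_true(mask_overlap("chr1", 150, 250, NULL)) # no annotation
})

test_that("low-complexity filter rejects repeats and keeps hairpins", {
  expect_false(low_complexity_filter(strrep("AT", 40)))
  expect_false(low_complexity_filter(strrep("A", 80)))
  expect_false(low_complexity_filter(strrep("CAG", 27)))
  set.seed(12)
  for (i in 1:20) {
    hp <- make_hairpin(mature_len = sample(18:26, 1))
    expect_true(low_complexity_filter(hp$precursor), info = i)
  }
})

test_that("planted genes are accepted with all criteria flags set", {
  run <- small_run()
  expect_gte(length(run$disc$genes), 1)
  tg <- run$sim$truth$genes
  for (g in run$disc$genes) {
    expect_false(is.na(match_truth(g, tg)))
    expect_true(all(g$criteria_flags[1:4]))
    # structural invariants: intervals nested, mature in window
    expect_true(g$pre[1] >= g$pri[1] && g$pre[2] <= g$pri[2])
    expect_true(g$mature[1] >= g$pre[1] && g$mature[2] <= g$pre[2])
    expect_true(g$star[1] >= g$pre[1] - 2 && g$star[2] <= g$pre[2] + 2)
    expect_gte(nchar(g$mature_seq), 16)
    expect_lte(nchar(g$mature_seq), 28)
  }
})

test_that("jittered 5' processing below threshold is rejected", {
  cfg <- sim_config(n_mirna_genes = 4L, n_families = 4L,
                    reads_per_sample = 2000L, n_samples = 4L,
                    genome_length = 20000L, five_prime_jitter = 0.9,
                    star_fraction = 0, decoy_read_fraction = 0, seed = 41L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg, file.path(tempdir(), "jitter"))
  pp <- preprocess_run(rd$manifest)
  idx <- index_genome(sim$genome)
  disc <- discover_mirnas(pp$collapsed, idx, sim$annotation)
  # with 90% jitter the modal 5' fraction is ~0.47: all loci fail
  expect_gte(sum(disc$rejections["criterion4_five_prime"]), 1)
  expect_equal(length(disc$genes), 0L)
})

test_that("decoy loci are removed by masking or complexity filters", {
  cfg <- sim_config(n_mirna_genes = 4L, n_families = 4L,
                    reads_per_sample = 6000L, n_samples = 4L,
                    genome_length = 20000L, decoy_read_fraction = 0.35,
                    seed = 51L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, cfg, file.path(tempdir(), "decoyheavy"))
  pp <- preprocess_run(rd$manifest)
  idx <- index_genome(sim$genome)
  disc <- discover_mirnas(pp$collapsed, idx, sim$annotation)
  # specificity: no accepted gene overlaps a planted decoy
  dc <- sim$truth$decoys
  for (g in disc$genes) {
    ov <- any(dc$start <= g$pri[2] & dc$end >= g$pri[1])
    expect_false(ov)
  }
  expect_gte(sum(disc$rejections["criterion3_annotation_overlap"]), 1)
})

test_that("rejection reasons partition the discarded loci", {
  run <- small_run()
  n_loci <- length(run$disc$loci)
  expect_equal(length(run$disc$genes) + sum(run$disc$rejections), n_loci)
  led <- run$disc$ledger
  expect_true(all(diff(led) <= 0)) # funnel is monotone non-increasing
})
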