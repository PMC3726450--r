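test_that("family clustering links by seed identity and distance", {
  set.seed(5)
  base <- random_dna(1, 22)
  same <- c(base, base)
  cl <- cluster_families(same)
  expect_equal(cl[1], cl[2])

  # a seed mismatch at position 3 separates families
  other <- base
  substr(other, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 3, 3))[1]
  cl2 <- cluster_families(c(base, other))
  expect_false(cl2[1] == cl2[2])

  # a 5-copy family (base + <= 2 substitutions outside the seed per copy)
  # clusters as one: single linkage bridges variants through the base
  members <- c(base, vapply(1:4, function(i) {
    m <- base
    for (p in sample(c(1, 9:22), 2)) {
      substr(m, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(m, p, p)), 1)
    }
    m
  }, character(1)))
  cl3 <- cluster_families(members)
  expect_equal(length(unique(cl3)), 1L)

  # homology hints label the cluster
  cl4 <- cluster_families(c(base, base), family_hints = c("miR-7", NA))
  expect_equal(attr(cl4, "labels")[cl4[1]], "miR-7")
})

test_that("duplicate counting uses pairs within identity groups", {
  expect_equal(find_duplicates(c("A", "A", "B"))$n_pairs, 1L)
  expect_equal(find_duplicates(c("A", "A", "A"))$n_pairs, 3L) # C(3,2)
  expect_equal(find_duplicates(character(0))$n_pairs, 0L)
  # duplicating a whole catalogue turns every singleton into a pair
  set.seed(31)
  s <- replicate(8, random_dna(1, 60))
  base_pairs <- find_duplicates(s)$n_pairs
  expect_equal(base_pairs, 0L)
  expect_equal(find_duplicates(c(s, s))$n_pairs, 8L)
})

test_that("family abundance shares sum to one and dedupe duplicates", {
  mk <- function(mature, counts) list(mature_seq = mature,
                                      mature_counts = counts)
  set.seed(8)
  m1 <- random_dna(1, 22); m2 <- random_dna(1, 22)
  catalogue <- list(mk(m1, c(50, 25)), mk(m2, c(20, 5)))
  cl <- cluster_families(c(m1, m2))
  tab <- family_abundance(catalogue, cl)
  expect_equal(sum(tab$relative_abundance), 1, tolerance = 1e-9)
  expect_equal(sort(tab$relative_abundance), c(0.25, 0.75))

  # identical duplicate matures are counted once per family
  catalogue2 <- list(mk(m1, c(50, 25)), mk(m1, c(50, 25)), mk(m2, c(20, 5)))
  cl2 <- cluster_families(c(m1, m1, m2))
  tab2 <- family_abundance(catalogue2, cl2)
  expect_equal(tab2$copy_number[tab2$abundance == 75], 2L)
  expect_equal(sort(tab2$relative_abundance), c(0.25, 0.75))

  # single family: relative abundance 1
  tab3 <- family_abundance(list(mk(m1, c(9, 1))), cluster_families(m1))
  expect_equal(tab3$relative_abundance, 1)
})

test_that("Spearman rho matches hand-computed midranks and permutation p", {
  # strictly increasing: rho = 1
  expect_equal(spearman_perm(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  # worked 5-point set with one tie in y:
  # x = 1..5, y = (3, 3, 5, 8, 9) -> rank(y) = (1.5, 1.5, 3, 4, 5)
  # rho = cov/sds computed by hand = 0.9746794
  sp <- spearman_perm(1:5, c(3, 3, 5, 8, 9))
  expect_equal(sp$rho, 0.9746794, tolerance = 1e-6)
  expect_lt(sp$p_value, 0.05)
  # invariant under strictly monotone transforms
  x <- c(2, 9, 4, 7, 1, 5); y <- c(10, 50, 20, 45, 5, 22)
  r1 <- spearman_perm(x, y, seed = 3)$rho
  r2 <- spearman_perm(exp(x / 2), y^3, seed = 3)$rho
  expect_equal(r1, r2)
  # independent variables: small rho, non-significant p
  set.seed(12)
  sp0 <- spearman_perm(rnorm(100), rnorm(100), n_perm = 2000)
  expect_lt(abs(sp0$rho), 0.25)
  expect_gt(sp0$p_value, 0.01)
})

test_that("copy-number/abundance coupling is recovered from truth weights", {
  # strong coupling in the generator yields a high rank correlation
  rhos <- vapply(1:3, function(s) {
    cfg <- sim_config(n_mirna_genes = 60L, n_families = 25L,
                      abundance_coupling = 1, genome_length = 120000L,
                      seed = 100L + s)
    sim <- simulate_genome(cfg)
    fam <- sim$truth$families
    spearman_perm(fam$copy_number, fam$weight, n_perm = 500L,
                  seed = s)$rho
  }, numeric(1))
  expect_gt(mean(rhos), 0.5)
})

test_that("recovered duplicate count equals truth at full recovery", {
  run <- small_run()
  tg <- run$sim$truth$genes
  matched <- vapply(run$disc$genes, match_truth, integer(1),
                    truth_genes = tg)
  # only meaningful when recovery is complete
  expect_equal(sort(unique(matched)), seq_len(nrow(tg)))
  dup <- find_duplicates(vapply(run$disc$genes, `[[`, character(1),
                                "pri_seq"))
  expect_equal(dup$n_pairs, run$sim$truth$n_duplicate_pairs)
})
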