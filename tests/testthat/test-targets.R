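test_that("seed sites follow the k >= 7, start 1-2 rule", {
  set.seed(6)
  mi <- random_dna(1, 22)
  # plant revcomp of miRNA[2..8] (7 nt, s = 2)
  utr <- random_dna(1, 80)
  site <- revcomp(substr(mi, 2, 8))
  substr(utr, 40, 46) <- site
  hits <- seed_sites(mi, utr)
  h2 <- hits[hits$s == 2 & hits$end == 46, ]
  expect_gte(nrow(h2), 1)
  expect_gte(h2$k[1], 7)

  # a 6-nt complement only: no site (fixed miRNA so the flanking A's
  # cannot extend the match to 7 nt)
  mi6 <- "ACGTACGTACGTACGTACGTAC"
  utr6 <- paste0(strrep("A", 30), revcomp(substr(mi6, 1, 6)),
                 strrep("A", 30))
  expect_equal(nrow(seed_sites(mi6, utr6)), 0L)
})

test_that("seed sites equal the brute-force enumeration on random inputs", {
  set.seed(66)
  for (i in 1:60) {
    mi <- random_dna(1, sample(19:23, 1))
    utr <- random_dna(1, 150)
    if (i %% 2 == 0) {
      k <- sample(8:12, 1); s <- sample(1:2, 1)
      p <- sample(10:(150 - k - 10), 1)
      substr(utr, p, p + k - 1) <- revcomp(substr(mi, s, s + k - 1))
    }
    a <- seed_sites(mi, utr)
    b <- seed_sites_brute(mi, utr)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) expect_true(all(a == b))
  }
})

test_that("duplex energies are exact for full complements and empty cases", {
  set.seed(2)
  mi <- random_dna(1, 22)
  d <- duplex_mfe(mi, revcomp(mi))
  # full duplex: energy is the sum of the 22 pair scores
  sc <- c(A = -2, C = -3, G = -3, T = -2)
  expect_equal(d$energy, sum(sc[strsplit(mi, "")[[1]]]))
  expect_equal(nrow(d$duplex), 22L)
  # no pairable bases at all
  expect_equal(duplex_mfe(strrep("A", 8), strrep("G", 8))$energy, 0)
  expect_error(duplex_mfe(mi, random_dna(1, 51)), "window")
})

test_that("duplex DP equals brute-force enumeration on short pairs", {
  set.seed(23)
  for (i in 1:60) {
    mi <- random_dna(1, sample(5:8, 1))
    w <- random_dna(1, sample(5:10, 1))
    expect_equal(duplex_mfe(mi, w)$energy, duplex_mfe_brute(mi, w)$energy,
                 info = paste(mi, w))
  }
})

test_that("whole-UTR scan agrees with the windowed DP and locates sites", {
  set.seed(31)
  for (i in 1:25) {
    mi <- random_dna(1, 20); w <- random_dna(1, 45)
    expect_equal(best_duplex_energy(mi, w)$energy, duplex_mfe(mi, w)$energy)
  }
  # never above the best single pair when any complement exists
  mi <- "ACGTACGTACGTACGTACGT"
  utr <- random_dna(1, 200)
  e <- best_duplex_energy(mi, utr)$energy
  expect_lte(e, -2)
  # located interval contains a planted perfect site
  k <- 12
  substr(utr, 100, 100 + k - 1) <- revcomp(substr(mi, 1, k))
  bd <- best_duplex_energy(mi, utr, locate = TRUE)
  expect_lte(bd$start, 100 + k - 1)
  expect_gte(bd$end, 100)
})

test_that("Gumbel fit recovers parameters and rejects degenerate input", {
  set.seed(15)
  xi <- 2.327203; theta <- 0.216961
  x <- xi - theta * log(-log(stats::runif(500)))
  f <- fit_gumbel(x)
  expect_lt(abs(f$xi - xi) / xi, 0.1)
  expect_lt(abs(f$theta - theta) / theta, 0.1)
  expect_error(fit_gumbel(rep(1, 100)), "degenerate")
  expect_error(calibrate_evd(random_dna(5, 100), random_dna(1, 22),
                             n_shuffles = 10), "n_shuffles")
})

test_that("calibration on shuffled UTRs controls the null positive rate", {
  set.seed(44)
  mi <- random_dna(1, 22)
  utrs <- replicate(30, random_dna(1, 250))
  ev <- calibrate_evd(utrs, mi, n_shuffles = 150, seed = 5)
  expect_equal(ev$source, "calibrated")
  expect_gt(ev$theta, 0)
  # fraction of fresh null UTRs passing p < 0.05 stays near 0.05
  hits <- mean(vapply(1:120, function(i) {
    u <- random_dna(1, 250)
    e <- best_duplex_energy(mi, u)$energy
    site_pvalue(e, 250, ev) < 0.05
  }, logical(1)))
  expect_lt(hits, 0.15)
})

test_that("site p-values satisfy the Gumbel identities and monotonicity", {
  ev <- evd_params()
  expect_equal(ev$xi, 2.327203)
  expect_equal(ev$theta, 0.216961)
  # x == xi gives p = 1 - exp(-1)
  L <- 300
  e_at_xi <- -ev$xi * log(L)
  expect_equal(site_pvalue(e_at_xi, L, ev), 1 - exp(-1), tolerance = 1e-12)
  # p is monotone increasing in energy (less stable -> larger p)
  es <- seq(-60, -5, by = 5)
  ps <- site_pvalue(es, L, ev)
  expect_true(all(diff(ps) > 0))
  # limits: very stable -> 0, unstable -> 1
  expect_lt(site_pvalue(-1000, L, ev), 1e-10)
  expect_gt(site_pvalue(50, L, ev), 1 - 1e-10)
})

test_that("predictor intersection keeps only doubly-supported sites", {
  seed_hits <- data.frame(mirna_id = c("m1", "m1", "m2"),
                          utr_id = c("u1", "u2", "u1"),
                          start = c(10L, 50L, 40L), end = c(20L, 60L, 48L))
  energy_hits <- data.frame(mirna_id = c("m1", "m2"),
                            utr_id = c("u1", "u3"),
                            start = c(15L, 40L), end = c(35L, 48L),
                            energy = c(-30, -25), p_value = c(0.01, 0.02))
  both <- intersect_predictions(seed_hits, energy_hits)
  expect_equal(nrow(both), 1L)
  expect_equal(both$mirna_id, "m1")
  expect_equal(both$utr_id, "u1")
  expect_equal(both$supported_by, "both")
  # empty inputs give an empty intersection
  expect_equal(nrow(intersect_predictions(seed_hits[0, ], energy_hits)), 0L)
  expect_equal(nrow(intersect_predictions(seed_hits, energy_hits[0, ])), 0L)
})

test_that("planted target sites are recovered with bounded false calls", {
  cfg <- small_cfg(seed = 61L)
  sim <- simulate_genome(cfg)
  tx <- simulate_transcriptome(sim, cfg)
  mirnas <- unique(tx$sites[, c("mirna_id", "mirna_seq")])
  mirnas <- mirnas[seq_len(min(4, nrow(mirnas))), ]
  mv <- stats::setNames(mirnas$mirna_seq, mirnas$mirna_id)
  keep_sites <- tx$sites[tx$sites$mirna_id %in% names(mv), ]
  pt <- predict_targets(mv, tx$utrs, n_shuffles = 100, seed = 9)
  rec <- vapply(seq_len(nrow(keep_sites)), function(i) {
    s <- keep_sites[i, ]
    any(pt$sites$mirna_id == s$mirna_id & pt$sites$utr_id == s$utr_id &
          pt$sites$start <= s$end & pt$sites$end >= s$start)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
  # false calls: intersected sites at positions with no planted site
  fp <- vapply(seq_len(nrow(pt$sites)), function(i) {
    h <- pt$sites[i, ]
    !any(tx$sites$utr_id == h$utr_id & tx$sites$start <= h$end &
           tx$sites$end >= h$start)
  }, logical(1))
  expect_lte(sum(fp), ceiling(0.05 * length(tx$utrs) * length(mv)))
})
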