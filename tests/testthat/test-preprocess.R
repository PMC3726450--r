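write_fastq <- function(path, seqs, quals = NULL) {
  if (length(seqs) == 0) {
    writeLines(character(0), path)
    return(path)
  }
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             quals)), path)
  path
}

test_that("paired-read reconciliation keeps agreeing mates only", {
  ins <- c("ACGTACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAATTTTG")
  r1 <- write_fastq(tempfile(), ins)
  bad2 <- revcomp(ins)
  substr(bad2[2], 5, 5) <- if (substr(bad2[2], 5, 5) == "A") "C" else "A"
  r2 <- write_fastq(tempfile(), bad2)
  rec <- reconcile_pairs(r1, r2)
  expect_equal(rec$seq, ins[1])
  expect_equal(rec$stats$n_discarded, 1L)
  expect_equal(rec$stats$discard_fraction, 0.5)

  # empty inputs give an empty stream with zero discard
  e1 <- write_fastq(tempfile(), character(0))
  e2 <- write_fastq(tempfile(), character(0))
  rec0 <- reconcile_pairs(e1, e2)
  expect_length(rec0$seq, 0)
  expect_equal(rec0$stats$discard_fraction, 0)

  # record-count mismatch is an input error
  r3 <- write_fastq(tempfile(), revcomp(ins[1]))
  expect_error(reconcile_pairs(r1, r3), "unequal")
})

test_that("quality and ambiguity filtering follows the stated rules", {
  reads <- list(seq = c("ACGTN", "ACGTA", "ACGTA"),
                qual = c("IIIII", "IIII!", "IIIII"))
  kept <- quality_filter(reads, min_q = 20, max_n = 0)
  expect_equal(kept$seq, "ACGTA")
  expect_equal(kept$stats$n_dropped, 2L)
  # no-op bounds are the identity
  all_kept <- quality_filter(reads, min_q = 0, max_n = 37)
  expect_equal(all_kept$seq, reads$seq)
  # all-Q40 reads pass
  q40 <- quality_filter(list(seq = c("AAAA", "CCCC"),
                             qual = c("IIII", "IIII")))
  expect_length(q40$seq, 2)
})

test_that("adapter trimming removes the longest matching suffix", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTAC" # 22 nt
  read <- substr(paste0(insert, adapter), 1, 37)
  expect_equal(trim_adapter(read, adapter), insert)
  # no adapter -> unchanged
  expect_equal(trim_adapter("ACGTACGTCCAACGT", adapter), "ACGTACGTCCAACGT")
  # a 4-nt adapter prefix is below min_overlap and is left alone
  four <- paste0("ACGTACGTCC", substr(adapter, 1, 4))
  expect_equal(trim_adapter(four, adapter, min_overlap = 5), four)
  five <- paste0("ACGTACGTCC", substr(adapter, 1, 5))
  expect_equal(trim_adapter(five, adapter, min_overlap = 5), "ACGTACGTCC")
})

test_that("collapsing builds per-sample count vectors that conserve reads", {
  col <- collapse_reads(list(c("AAA", "AAA", "AAA", "CCC"), c("AAA", "AAA")))
  i <- which(col$sequence == "AAA")
  expect_equal(unname(col$counts[i, ]), c(3L, 2L))
  expect_equal(col$total[i], 5L)
  expect_equal(sum(col$total), 6L)

  # all distinct reads give unit totals
  d <- collapse_reads(list(c("AA", "CC", "GG")))
  expect_true(all(d$total == 1L))

  # conservation on a random multiset
  set.seed(8)
  samples <- lapply(1:3, function(s)
    sample(c("ACGT", "TTTT", "GGCC"), 50, replace = TRUE))
  cc <- collapse_reads(samples)
  expect_equal(sum(cc$total), 150L)
  expect_equal(colSums(cc$counts), c(S1 = 50L, S2 = 50L, S3 = 50L))
})

test_that("length window bounds are inclusive", {
  col <- collapse_reads(list(c(strrep("A", 15), strrep("C", 16),
                               strrep("G", 28), strrep("T", 29))))
  w <- length_window(col)
  expect_setequal(w$sequence, c(strrep("C", 16), strrep("G", 28)))
  # [5, 37] is the identity on valid reads
  w2 <- length_window(col, 5, 37)
  expect_equal(length(w2$sequence), 4L)
  # empty in, empty out
  e <- length_window(collapse_reads(list(character(0))))
  expect_length(e$sequence, 0)
})

test_that("stage order matters: trimming must precede windowing", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- "ACGTACGTACGTACGTACGTAC" # 22 nt after trimming
  read <- substr(paste0(insert, adapter), 1, 37) # 37 nt before
  # window-first would discard the 37-nt read; trim-first keeps it
  col_untrimmed <- collapse_reads(list(read))
  expect_length(length_window(col_untrimmed)$sequence, 0)
  col_trimmed <- collapse_reads(list(trim_adapter(read, adapter)))
  expect_length(length_window(col_trimmed)$sequence, 1)
})

test_that("preprocess_run ledger accounts for every input pair", {
  run <- small_run()
  led <- run$pp$ledger
  expect_equal(unname(led["input_pairs"]),
               run$cfg$reads_per_sample * run$cfg$n_samples)
  expect_true(all(diff(led[c("input_pairs", "reconciled",
                             "post_quality")]) <= 0))
  expect_equal(unname(led["windowed_reads"]), sum(run$pp$collapsed$total))
})
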