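make_index <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  index_genome(ss)
}

test_that("genome index supports exact queries on both strands", {
  g <- "ACGTACGGTTACCGGAAATTTCCCGGGACGT"
  idx <- make_index(c(chrA = g))
  col <- structure(list(sequence = c(substr(g, 5, 24),
                                     revcomp(substr(g, 3, 22)),
                                     strrep("T", 20)),
                        counts = matrix(1L, 3, 1),
                        total = c(1L, 1L, 1L)),
                   class = "collapsed_reads")
  hits <- map_reads(col, idx)
  h1 <- hits[hits$seq_id == 1, ]
  expect_equal(h1$start, 5L)
  expect_equal(h1$strand, "+")
  h2 <- hits[hits$seq_id == 2, ]
  expect_equal(h2$start, 3L)
  expect_equal(h2$strand, "-")
  expect_false(3L %in% hits$seq_id) # absent query: no hits
  expect_error(index_genome(Biostrings::DNAStringSet(c(a = "ACGT",
                                                       a = "ACGT"))),
               "duplicate")
})

test_that("multi-mapped reads are flagged but remain countable", {
  unit <- "ACGGTTAACCGGTTAACCGGTAGA"
  g <- paste0(strrep("A", 30), paste(rep(unit, 25), collapse = ""),
              strrep("C", 30))
  idx <- make_index(c(chr = g))
  col <- structure(list(sequence = unit, counts = matrix(10L, 1, 1),
                        total = 10L),
                   class = "collapsed_reads")
  hits <- map_reads(col, idx, max_hits = 20L)
  expect_gt(nrow(hits), 20)
  expect_true(all(hits$multimapped))
  expect_length(build_loci(hits, col), 0) # cannot seed a locus
  # with a higher cap, hits seed loci normally
  hits2 <- map_reads(col, idx, max_hits = 30L)
  expect_false(any(hits2$multimapped))
})

test_that("reads planted at two identical gene copies map to both", {
  run <- small_run()
  tg <- run$sim$truth$genes
  dup <- tg[!is.na(tg$duplicate_of), ][1, ]
  mat_seq <- dup$mature_seq
  sid <- which(run$pp$collapsed$sequence == mat_seq)
  hits <- map_reads(run$pp$collapsed, run$idx)
  expect_gte(sum(hits$seq_id == sid), 2)
  expect_false(any(hits$multimapped[hits$seq_id == sid]))
})

test_that("locus building merges by gap and separates strands", {
  hits <- data.frame(
    seq_id = 1:4,
    chrom = "c",
    start = c(100L, 130L, 300L, 100L),
    end = c(120L, 150L, 320L, 120L),
    strand = c("+", "+", "+", "-"),
    n_hits = 1L, multimapped = FALSE, stringsAsFactors = FALSE)
  col <- structure(list(sequence = c("A", "B", "C", "D"),
                        counts = matrix(1L, 4, 1), total = rep(1L, 4)),
                   class = "collapsed_reads")
  loci <- build_loci(hits, col, merge_gap = 30L)
  expect_length(loci, 3) # two reads 10 nt apart merge; strands separate
  spans <- vapply(loci, function(l) paste0(l$strand, l$start), character(1))
  expect_setequal(spans, c("+100", "+300", "-100"))
  merged <- loci[[which(vapply(loci, function(l)
    l$start == 100 && l$strand == "+", logical(1)))]]
  expect_equal(nrow(merged$reads), 2L)
  expect_equal(merged$total, 2L)
})

test_that("window extraction is strand aware and edge safe", {
  g <- paste(rep("ACGT", 50), collapse = "")
  idx <- make_index(c(chr = g))
  plus <- structure(list(chrom = "chr", start = 81L, end = 100L,
                         strand = "+", reads = data.frame(),
                         counts = 1, total = 1), class = "locus")
  minus <- plus; minus$strand <- "-"
  wp <- extract_window(plus, idx, flank = 10L)
  wm <- extract_window(minus, idx, flank = 10L)
  expect_equal(wp$seq, substr(g, 71, 110))
  expect_equal(wm$seq, revcomp(substr(g, 71, 110)))
  # coordinate converters round-trip
  expect_equal(wp$to_genomic(wp$to_local(85L)), 85L)
  expect_equal(wm$to_genomic(wm$to_local(85L)), 85L)
  # locus at the contig start gets a truncated window
  eg <- structure(list(chrom = "chr", start = 3L, end = 22L, strand = "+",
                       reads = data.frame(), counts = 1, total = 1),
                  class = "locus")
  we <- extract_window(eg, idx, flank = 10L)
  expect_equal(we$gstart, 1L)
  expect_equal(we$seq, substr(g, 1, 32))
})

test_that("hit and locus tables are written in tabular/BED form", {
  run <- small_run()
  hits <- map_reads(run$pp$collapsed, run$idx)
  loci <- build_loci(hits, run$pp$collapsed)
  hp <- tempfile(fileext = ".tsv")
  bp <- tempfile(fileext = ".bed")
  cp <- tempfile(fileext = ".tsv")
  write_hits(hits, hp)
  write_loci(loci, bp, cp)
  expect_equal(length(readLines(bp)), length(loci))
  cnt <- utils::read.delim(cp)
  expect_equal(nrow(cnt), length(loci))
  expect_equal(ncol(cnt), 1L + run$cfg$n_samples)
  ht <- utils::read.delim(hp)
  expect_named(ht, c("seq_id", "chrom", "start", "strand"))
})

test_that("every expressed planted gene yields exactly one locus", {
  run <- small_run()
  hits <- map_reads(run$pp$collapsed, run$idx)
  loci <- build_loci(hits, run$pp$collapsed)
  tg <- run$sim$truth$genes
  for (i in seq_len(nrow(tg))) {
    n_at <- sum(vapply(loci, function(l)
      l$strand == tg$strand[i] && l$start <= tg$pre_end[i] &&
        l$end >= tg$pre_start[i], logical(1)))
    expect_equal(n_at, 1L, info = tg$gene_id[i])
  }
})
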