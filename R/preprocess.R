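# Read-level preprocessing: paired-read reconciliation, quality/ambiguity
# filtering, adapter trimming, collapsing to unique sequences with
# per-sample counts, and length windowing. The stage order is fixed:
# reconcile -> quality -> trim -> collapse -> window.

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ file (phred+33).
#' @return list with `seq` and `qual` character vectors.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(list(seq = character(0), qual = character(0)))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Reconcile mates of a paired-end small-RNA run
#'
#' Small-RNA inserts are shorter than the read length, so both mates read
#' the same fragment and mate 2 is the reverse complement of mate 1. Pairs
#' whose mates disagree at any base (after reverse-complementing mate 2) are
#' discarded; agreement doubles effective base accuracy.
#'
#' @param r1,r2 FASTQ file paths, or lists as returned by [read_fastq()].
#' @return list with `seq`, `qual` (mate-1 view of the kept inserts) and
#'   `stats` (n_pairs, n_discarded, discard_fraction).
#' @export
reconcile_pairs <- function(r1, r2) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (length(r1$seq) != length(r2$seq))
    stop("mate files have unequal record counts")
  n <- length(r1$seq)
  if (n == 0) {
    return(list(seq = character(0), qual = character(0),
                stats = list(n_pairs = 0L, n_discarded = 0L,
                             discard_fraction = 0)))
  }
  ok <- r1$seq == revcomp(r2$seq)
  list(seq = r1$seq[ok], qual = r1$qual[ok],
       stats = list(n_pairs = n, n_discarded = sum(!ok),
                    discard_fraction = sum(!ok) / n))
}

#' Quality and ambiguity filter
#'
#' Drops reads containing any base below `min_q` or more than `max_n`
#' ambiguous (non-ACGT) bases.
#'
#' @param reads list with `seq`, `qual` (phred+33).
#' @param min_q minimum per-base phred quality.
#' @param max_n maximum number of ambiguous bases tolerated.
#' @return filtered `reads` list, with `stats$n_dropped` attached.
#' @export
quality_filter <- function(reads, min_q = 20L, max_n = 0L) {
  if (length(reads$seq) == 0) {
    reads$stats <- list(n_dropped = 0L)
    return(reads)
  }
  # qualities are highly redundant; evaluate unique strings only
  uq <- unique(reads$qual)
  minq_u <- vapply(uq, function(q) min(utf8ToInt(q)) - 33L, integer(1))
  minq <- minq_u[match(reads$qual, uq)]
  n_amb <- nchar(gsub("[ACGT]", "", reads$seq))
  keep <- minq >= min_q & n_amb <= max_n
  list(seq = reads$seq[keep], qual = reads$qual[keep],
       stats = list(n_dropped = sum(!keep)))
}

#' Trim a 3' adapter
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, requiring at least `min_overlap` matching bases; reads without
#' such a suffix are untouched.
#'
#' @param seqs character vector of insert sequences.
#' @param adapter adapter sequence (default: the TruSeq small-RNA 3'
#'   adapter used by the read simulator).
#' @param min_overlap minimum adapter prefix length.
#' @return character vector of trimmed sequences.
#' @export
trim_adapter <- function(seqs, adapter = TRUSEQ_ADAPTER, min_overlap = 5L) {
  if (length(seqs) == 0) return(seqs)
  us <- unique(seqs)
  lens <- nchar(us)
  trim_len <- rep(0L, length(us))
  for (k in seq(min_overlap, nchar(adapter))) {
    pre <- substr(adapter, 1L, k)
    hit <- lens >= k & substring(us, lens - k + 1L, lens) == pre
    trim_len[hit] <- k
  }
  trimmed <- substring(us, 1L, lens - trim_len)
  trimmed[match(seqs, us)]
}

#' Collapse per-sample reads to unique sequences with count vectors
#'
#' @param samples list of character vectors, one per sample (insert
#'   sequences after trimming).
#' @return object of class `collapsed_reads`: list with `sequence`
#'   (character), `counts` (matrix, sequences x samples) and `total`.
#' @export
collapse_reads <- function(samples) {
  stopifnot(length(samples) >= 1)
  tabs <- lapply(samples, function(s) table(s))
  all_seq <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  counts <- matrix(0L, length(all_seq), length(samples),
                   dimnames = list(NULL, paste0("S", seq_along(samples))))
  for (j in seq_along(tabs)) {
    idx <- match(names(tabs[[j]]), all_seq)
    counts[idx, j] <- as.integer(tabs[[j]])
  }
  structure(list(sequence = all_seq, counts = counts,
                 total = as.integer(rowSums(counts))),
            class = "collapsed_reads")
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat("collapsed_reads:", length(x$sequence), "unique sequences,",
      ncol(x$counts), "samples,", sum(x$total), "reads\n")
  invisible(x)
}

#' Length window on collapsed reads
#'
#' Keeps sequences with `lo <= length <= hi` (inclusive on both ends).
#'
#' @param collapsed a `collapsed_reads` object.
#' @param lo,hi inclusive bounds in nt.
#' @return filtered `collapsed_reads`.
#' @export
length_window <- function(collapsed, lo = 16L, hi = 28L) {
  len <- nchar(collapsed$sequence)
  keep <- len >= lo & len <= hi
  structure(list(sequence = collapsed$sequence[keep],
                 counts = collapsed$counts[keep, , drop = FALSE],
                 total = collapsed$total[keep]),
            class = "collapsed_reads")
}

#' Run the preprocessing chain over a sample manifest
#'
#' reconcile -> quality filter -> adapter trim -> collapse -> length window,
#' with a per-stage count ledger.
#'
#' @param manifest data.frame with columns `r1`, `r2` (FASTQ paths), one row
#'   per sample.
#' @param min_q,max_n,adapter,min_overlap,lo,hi stage parameters.
#' @return list with `collapsed` (windowed `collapsed_reads`),
#'   `collapsed_all` (pre-window) and `ledger` (named numeric vector of
#'   read counts at each gate).
#' @export
preprocess_run <- function(manifest, min_q = 20L, max_n = 0L,
                           adapter = TRUSEQ_ADAPTER, min_overlap = 5L,
                           lo = 16L, hi = 28L) {
  per_sample <- vector("list", nrow(manifest))
  n_input <- 0L; n_reconciled <- 0L; n_quality <- 0L
  for (s in seq_len(nrow(manifest))) {
    rec <- reconcile_pairs(manifest$r1[s], manifest$r2[s])
    n_input <- n_input + rec$stats$n_pairs
    n_reconciled <- n_reconciled + length(rec$seq)
    qf <- quality_filter(rec, min_q = min_q, max_n = max_n)
    n_quality <- n_quality + length(qf$seq)
    per_sample[[s]] <- trim_adapter(qf$seq, adapter = adapter,
                                    min_overlap = min_overlap)
  }
  collapsed <- collapse_reads(per_sample)
  windowed <- length_window(collapsed, lo = lo, hi = hi)
  ledger <- c(input_pairs = n_input,
              reconciled = n_reconciled,
              post_quality = n_quality,
              unique_sequences = length(collapsed$sequence),
              windowed_sequences = length(windowed$sequence),
              windowed_reads = sum(windowed$total))
  list(collapsed = windowed, collapsed_all = collapsed, ledger = ledger)
}

#' Write collapsed reads as FASTA plus a count matrix TSV
#'
#' FASTA headers follow the `>seq<i>_x<total>` convention.
#'
#' @param collapsed a `collapsed_reads` object.
#' @param fasta,tsv output paths.
#' @return invisibly, the FASTA path.
#' @export
write_collapsed <- function(collapsed, fasta, tsv) {
  ids <- sprintf("seq%d_x%d", seq_along(collapsed$sequence),
                 collapsed$total)
  ss <- Biostrings::DNAStringSet(collapsed$sequence)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, fasta)
  df <- data.frame(id = ids, sequence = collapsed$sequence,
                   collapsed$counts, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}
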