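# Exact mapping of collapsed reads to both genome strands, clustering of
# hits into expressed loci, and extraction of candidate precursor windows.

#' Build a genome index for exact short-read matching
#'
#' @param genome FASTA path or a named [Biostrings::DNAStringSet].
#' @return object of class `genome_index`.
#' @export
index_genome <- function(genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome)) || anyNA(names(genome)))
    stop("genome sequences must be named")
  nms <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(nms)) stop("duplicate sequence names in genome")
  names(genome) <- nms
  structure(list(genome = genome,
                 lengths = stats::setNames(Biostrings::width(genome), nms)),
            class = "genome_index")
}

#' Map collapsed reads to the genome (exact, full-length, both strands)
#'
#' Reads with more placements than `max_hits` are flagged multi-mapped:
#' their hits are retained in the table (they still contribute counts to any
#' locus they fall in) but they do not seed loci.
#'
#' @param collapsed a `collapsed_reads` object.
#' @param index a [index_genome()] result.
#' @param max_hits multi-mapping cap.
#' @return data.frame with columns `seq_id` (row in `collapsed`), `chrom`,
#'   `start`, `end` (1-based inclusive), `strand`, `n_hits`, `multimapped`.
#' @export
map_reads <- function(collapsed, index, max_hits = 20L) {
  seqs <- collapsed$sequence
  if (length(seqs) == 0) {
    return(data.frame(seq_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      multimapped = logical(0)))
  }
  hits <- list()
  lens <- nchar(seqs)
  for (L in sort(unique(lens))) {
    ids <- which(lens == L)
    fwd <- Biostrings::DNAStringSet(seqs[ids])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (chrom in names(index$genome)) {
      subj <- index$genome[[chrom]]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subj)
        starts <- Biostrings::startIndex(m)
        for (q in seq_along(ids)) {
          st <- starts[[q]]
          if (is.null(st) || length(st) == 0) next
          hits[[length(hits) + 1L]] <- data.frame(
            seq_id = ids[q], chrom = chrom, start = st,
            end = st + L - 1L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seq_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      multimapped = logical(0)))
  }
  ht <- do.call(rbind, hits)
  nh <- table(ht$seq_id)
  ht$n_hits <- as.integer(nh[as.character(ht$seq_id)])
  ht$multimapped <- ht$n_hits > max_hits
  ht <- ht[order(ht$chrom, ht$strand, ht$start, ht$seq_id), ]
  rownames(ht) <- NULL
  ht
}

#' Cluster mapped reads into expressed loci
#'
#' Same-strand hits whose intervals lie within `merge_gap` nt of each other
#' are merged into one locus; multi-mapped reads never seed a locus but are
#' counted once in every locus they fall in.
#'
#' @param hits hit table from [map_reads()].
#' @param collapsed the mapped `collapsed_reads`.
#' @param merge_gap maximum gap between merged hit intervals.
#' @return list of `locus` objects: chrom, start, end, strand, `reads`
#'   (data.frame seq_id/start/end), `counts` (per-sample vector), `total`.
#' @export
build_loci <- function(hits, collapsed, merge_gap = 30L) {
  seed <- hits[!hits$multimapped, , drop = FALSE]
  loci <- list()
  if (nrow(seed) == 0) return(loci)
  for (chrom in unique(seed$chrom)) {
    for (strand in c("+", "-")) {
      h <- seed[seed$chrom == chrom & seed$strand == strand, , drop = FALSE]
      if (nrow(h) == 0) next
      h <- h[order(h$start), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(h$start[-1] >
                                       cummax(h$end)[-nrow(h)] + merge_gap)))
      for (g in unique(grp)) {
        hg <- h[grp == g, , drop = FALSE]
        lstart <- min(hg$start); lend <- max(hg$end)
        # add multi-mapped hits falling inside the locus (count once each)
        mm <- hits[hits$multimapped & hits$chrom == chrom &
                     hits$strand == strand & hits$start >= lstart &
                     hits$end <= lend, , drop = FALSE]
        mm <- mm[!duplicated(mm$seq_id), , drop = FALSE]
        members <- rbind(hg[, c("seq_id", "start", "end")],
                         mm[, c("seq_id", "start", "end")])
        members <- members[!duplicated(members$seq_id), , drop = FALSE]
        cnt <- colSums(collapsed$counts[members$seq_id, , drop = FALSE])
        loci[[length(loci) + 1L]] <- structure(
          list(chrom = chrom, start = lstart, end = lend, strand = strand,
               reads = members, counts = cnt, total = sum(cnt)),
          class = "locus")
      }
    }
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s:%d-%d(%s) %d reads, %d counts\n", x$chrom, x$start,
              x$end, x$strand, nrow(x$reads), x$total))
  invisible(x)
}

#' Write hit and locus tables
#'
#' Hits go out as an unsorted SAM-like TSV (read id, chrom, pos, strand);
#' loci as BED6 plus a per-sample count TSV.
#'
#' @param hits hit table from [map_reads()].
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, c("seq_id", "chrom", "start", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @param loci list of loci from [build_loci()].
#' @param bed,tsv output paths for the BED6 intervals and the per-sample
#'   count matrix.
#' @export
write_loci <- function(loci, bed, tsv) {
  if (length(loci) == 0) {
    writeLines(character(0), bed)
    writeLines("locus\ttotal", tsv)
    return(invisible(bed))
  }
  gr <- GenomicRanges::GRanges(
    vapply(loci, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(loci, `[[`, integer(1), "start"),
                     vapply(loci, `[[`, integer(1), "end")),
    strand = vapply(loci, `[[`, character(1), "strand"),
    name = sprintf("locus%03d", seq_along(loci)),
    score = vapply(loci, function(l) as.numeric(l$total), numeric(1)))
  rtracklayer::export(gr, bed, format = "BED")
  counts <- do.call(rbind, lapply(loci, `[[`, "counts"))
  df <- data.frame(locus = sprintf("locus%03d", seq_along(loci)), counts,
                   check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed)
}

#' Extract the flanked genomic window around a locus
#'
#' Returns the locus sequence plus `flank` nt on each side, reverse
#' complemented for minus-strand loci so the window reads 5'->3' on the
#' transcribed strand; truncated at contig edges.
#'
#' @param locus a `locus` from [build_loci()].
#' @param index a `genome_index`.
#' @param flank flank size in nt.
#' @return list with `seq`, `gstart`, `gend` (genomic bounds of the window)
#'   and coordinate converters `to_local(gpos)` / `to_genomic(lpos)`.
#' @export
extract_window <- function(locus, index, flank = 70L) {
  clen <- index$lengths[[locus$chrom]]
  gstart <- max(1L, locus$start - flank)
  gend <- min(clen, locus$end + flank)
  seq <- as.character(Biostrings::subseq(index$genome[[locus$chrom]],
                                         gstart, gend))
  if (locus$strand == "-") seq <- revcomp(seq)
  strand <- locus$strand
  to_local <- function(gpos) {
    if (strand == "+") gpos - gstart + 1L else gend - gpos + 1L
  }
  to_genomic <- function(lpos) {
    if (strand == "+") gstart + lpos - 1L else gend - lpos + 1L
  }
  list(seq = seq, gstart = gstart, gend = gend, strand = strand,
       to_local = to_local, to_genomic = to_genomic)
}
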