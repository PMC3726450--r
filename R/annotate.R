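# Annotation of candidate loci under the deep-sequencing miRNA criteria:
# mature/star calling from the read signature, Dicer 2-nt 3' overhang
# geometry, bulge-bounded precursor definition with the 65-nt minimum,
# expression gating, annotation masking and low-complexity filtering.

#' Call the mature miRNA of a locus from its read signature
#'
#' The mature is the most abundant member sequence (summed over samples;
#' ties broken towards the lexicographically smaller sequence) and its
#' length defines the mature length. 5' processing consistency is the
#' count-weighted fraction of locus reads sharing the mature's 5' genomic
#' position.
#'
#' @param locus a `locus` from [build_loci()].
#' @param collapsed the `collapsed_reads` the locus was built from.
#' @return list with `seq_id`, `sequence`, `start`, `end` (genomic),
#'   `counts` (per-sample), `five_prime_consistency`.
#' @export
call_mature <- function(locus, collapsed) {
  stopifnot(nrow(locus$reads) >= 1)
  ids <- locus$reads$seq_id
  totals <- collapsed$total[ids]
  seqs <- collapsed$sequence[ids]
  best <- order(-totals, seqs)[1]
  five_pos <- if (locus$strand == "+") locus$reads$start else locus$reads$end
  w <- totals
  cons <- sum(w[five_pos == five_pos[best]]) / sum(w)
  list(seq_id = ids[best], sequence = seqs[best],
       start = locus$reads$start[best], end = locus$reads$end[best],
       counts = collapsed$counts[ids[best], ],
       five_prime_consistency = cons)
}

# nearest-paired extrapolated duplex partner: returns the partner position
# of `pos`, walking inward over `within` (an interval containing pos) to the
# nearest paired base and extrapolating across skipped (bulged) positions.
.partner_hat <- function(pairs, pos, within) {
  cand <- within[1]:within[2]
  cand <- cand[!is.na(pairs[cand])]
  if (length(cand) == 0) return(NA_integer_)
  q <- cand[which.min(abs(cand - pos))]
  pairs[q] + (q - pos)
}

#' Predict the star interval of a mature miRNA on a folded hairpin
#'
#' Dicer geometry: the star spans the duplex partners of the mature with
#' both strands' 3' ends extending 2 nt beyond the partner of the opposite
#' 5' end, computed from the pair map with bulged positions skipped.
#'
#' @param struct a `secondary_structure` of the candidate window.
#' @param mature integer c(start, end), 1-based on the folded sequence.
#' @param max_loop_overlap maximum tolerated overlap of the mature with the
#'   hairpin loop; beyond this no star is predicted.
#' @return integer c(start, end) or NULL when no star can be placed.
#' @export
predict_star <- function(struct, mature, max_loop_overlap = 4L) {
  pairs <- struct$pairs
  n <- length(pairs)
  idx <- mature[1]:mature[2]
  if (all(is.na(pairs[idx]))) return(NULL)
  dec <- hairpin_decompose(struct)
  loop_overlap <- sum(dec$labels[idx] == "hairpin_loop")
  if (loop_overlap > max_loop_overlap) return(NULL)
  p1 <- .partner_hat(pairs, mature[1], mature)
  p2 <- .partner_hat(pairs, mature[2], mature)
  if (is.na(p1) || is.na(p2)) return(NULL)
  star <- sort(c(p1, p2)) + 2L
  if (star[1] < 1L || star[2] > n) return(NULL)
  if (star[1] <= mature[2] && star[2] >= mature[1]) return(NULL)
  as.integer(star)
}

#' Check the Dicer 2-nt 3' overhang of a mature/star duplex
#'
#' TRUE iff both strands' 3' ends extend exactly 2 nt beyond the duplex
#' partner of the other strand's 5' end (pair-map partners, bulges skipped).
#'
#' @param struct a `secondary_structure`.
#' @param mature,star integer c(start, end) intervals on the folded
#'   sequence.
#' @return logical flag.
#' @export
check_overhang <- function(struct, mature, star) {
  pairs <- struct$pairs
  if (star[1] > mature[2]) { # mature 5' arm, star 3' arm
    o_star <- star[2] - .partner_hat(pairs, mature[1], mature)
    o_mat <- mature[2] - .partner_hat(pairs, star[1], star)
  } else {
    o_mat <- mature[2] - .partner_hat(pairs, star[1], star)
    o_star <- star[2] - .partner_hat(pairs, mature[1], mature)
  }
  isTRUE(o_star == 2L) && isTRUE(o_mat == 2L)
}

# stem path from the mature outward: ordered paired positions with bulge
# marks at stem discontinuities. dir = -1 walks 5' (mature on 5' arm),
# dir = +1 walks 3'.
.stem_path <- function(pairs, from, dir, n) {
  # start: nearest paired position at/inward of `from`
  p <- as.integer(from)
  while (p >= 1 && p <= n && is.na(pairs[p])) p <- p - dir
  if (p < 1 || p > n) return(NULL)
  path <- list(list(pos = p, bulge_before = FALSE))
  q <- p + dir
  repeat {
    if (q < 1 || q > n) break
    if (is.na(pairs[q])) { # unpaired on this strand: potential bulge, skip
      q <- q + dir
      next
    }
    encloses <- if (dir == -1L) pairs[q] > pairs[p] else pairs[q] < pairs[p]
    if (!encloses) break # a sibling stem or exterior: stem exhausted
    bulge <- abs(q - p) != 1L || abs(pairs[q] - pairs[p]) != 1L
    path[[length(path) + 1L]] <- list(pos = q, bulge_before = bulge)
    p <- q
    q <- q + dir
  }
  path
}

#' Define the precursor interval from the folded structure
#'
#' The precursor starts at the first bulge or internal loop encountered
#' walking outward (away from the hairpin loop) from the mature's outer end
#' and ends at the base-pairing partner of that boundary. When the
#' bulge-bounded interval is shorter than 65 nt it is extended outward along
#' the stem until it reaches 65 nt, unless the next bulge is reached first;
#' with no bulge at all the 65-nt minimum rule applies directly (full stem
#' if the stem is shorter).
#'
#' @param struct a `secondary_structure` of the candidate window.
#' @param mature integer c(start, end) on the folded sequence.
#' @param min_len minimum precursor length.
#' @return list with `pre` (integer c(start, end)), `min_len_rule_used`,
#'   `bounded_by` (one of "bulge", "min_len", "stem"), or NULL when the
#'   mature has no paired base.
#' @export
define_precursor <- function(struct, mature, min_len = 65L) {
  pairs <- struct$pairs
  n <- length(pairs)
  idx <- mature[1]:mature[2]
  pm <- idx[!is.na(pairs[idx])]
  if (length(pm) == 0) return(NULL)
  on5 <- stats::median(pairs[pm]) > stats::median(pm)
  dir <- if (on5) -1L else 1L
  from <- if (on5) mature[1] else mature[2]
  path <- .stem_path(pairs, from, dir, n)
  if (is.null(path)) return(NULL)
  pos <- vapply(path, `[[`, integer(1), "pos")
  bulge <- vapply(path, `[[`, logical(1), "bulge_before")
  iv <- function(p) sort(c(p, pairs[p]))
  span <- function(p) abs(pairs[p] - p) + 1L
  spans <- vapply(pos, span, integer(1))
  first_bulge <- which(bulge)[1]

  if (!is.na(first_bulge)) {
    b <- first_bulge - 1L # last stem position before the bulge
    if (b >= 1 && spans[b] >= min_len) {
      return(list(pre = iv(pos[b]), min_len_rule_used = FALSE,
                  bounded_by = "bulge"))
    }
    # too short: extend outward through the bulge to 65 nt or the next bulge
    later <- if (first_bulge <= length(pos)) first_bulge:length(pos) else
      integer(0)
    second_bulge <- later[which(bulge[later] & later > first_bulge)][1]
    for (t in later) {
      if (!is.na(second_bulge) && t >= second_bulge) {
        return(list(pre = iv(pos[t - 1L]), min_len_rule_used = FALSE,
                    bounded_by = "bulge"))
      }
      if (spans[t] >= min_len) {
        return(list(pre = iv(pos[t]), min_len_rule_used = TRUE,
                    bounded_by = "min_len"))
      }
    }
    return(list(pre = iv(pos[length(pos)]), min_len_rule_used = TRUE,
                bounded_by = "stem"))
  }
  # no bulge: minimum-length rule along the clean stem
  ok <- which(spans >= min_len)
  if (length(ok) > 0) {
    return(list(pre = iv(pos[ok[1]]), min_len_rule_used = TRUE,
                bounded_by = "min_len"))
  }
  list(pre = iv(pos[length(pos)]), min_len_rule_used = TRUE,
       bounded_by = "stem")
}

#' Expression gate
#'
#' Keeps a candidate iff its mature counts reach `min_per_sample` reads per
#' sample — by default on the per-sample mean (total >= min x n_samples);
#' `mode = "all_samples"` requires the minimum in every sample.
#'
#' @param counts per-sample mature count vector.
#' @param min_per_sample threshold in reads per sample.
#' @param mode "mean" or "all_samples".
#' @return logical flag (TRUE = keep).
#' @export
expression_gate <- function(counts, min_per_sample = 10,
                            mode = c("mean", "all_samples")) {
  mode <- match.arg(mode)
  if (mode == "mean") mean(counts) >= min_per_sample
  else all(counts >= min_per_sample)
}

#' Annotation-overlap mask
#'
#' Rejects a candidate whose pri interval overlaps any annotated record
#' (tRNA/rRNA/piRNA/mRNA/repeat classes) by at least 1 nt on either strand.
#'
#' @param chrom,start,end pri interval (1-based inclusive).
#' @param annotation a [GenomicRanges::GRanges] of annotated transcripts and
#'   repeats, or NULL (no filtering).
#' @return TRUE when the candidate passes (no overlap).
#' @export
mask_overlap <- function(chrom, start, end, annotation) {
  if (is.null(annotation) || length(annotation) == 0) return(TRUE)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(q, annotation, ignore.strand = TRUE))
  length(ov) == 0
}

#' Low-complexity and tandem-repeat filter
#'
#' DUST-style triplet score (sum over triplet types of c(c-1)/2, normalised
#' by sequence length minus 3) plus a tandem periodicity scan: for periods
#' k <= 6, the fraction of positions repeating at lag k.
#'
#' @param seq candidate pri sequence.
#' @param dust_t DUST score threshold.
#' @param tandem_max maximum tolerated tandem coverage.
#' @return TRUE when the sequence passes (is complex enough).
#' @export
low_complexity_filter <- function(seq, dust_t = 2.0, tandem_max = 0.8) {
  L <- nchar(seq)
  if (L < 10) return(TRUE)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  tri <- paste0(ch[1:(L - 2)], ch[2:(L - 1)], ch[3:L])
  cnt <- table(tri)
  dust <- sum(cnt * (cnt - 1) / 2) / (L - 3)
  if (dust > dust_t) return(FALSE)
  for (k in 1:6) {
    cov <- mean(ch[1:(L - k)] == ch[(k + 1):L])
    if (cov > tandem_max) return(FALSE)
  }
  TRUE
}

#' Apply the annotation criteria to one locus
#'
#' Evaluates, in funnel order: minimum read support, the expression gate,
#' the annotation mask, the low-complexity filter, then the structural
#' criteria on two candidate fold windows (mature on the 5' or the 3' arm):
#' single stem-loop with a paired mature, 5'-processing consistency, star
#' placement with an exact 2-nt 3' overhang, and the bulge-bounded
#' precursor with the 65-nt minimum. Star-read support is recorded
#' (criterion 5) and only enforced when `require_star_reads` is TRUE.
#'
#' @param locus a `locus`.
#' @param collapsed the `collapsed_reads`.
#' @param index a `genome_index`.
#' @param annotation GRanges of annotated transcripts/repeats or NULL.
#' @param params list of tunables (see [discovery_params()]).
#' @return list: either `gene` (an accepted record) or `reason` (the first
#'   failing criterion).
#' @export
apply_criteria <- function(locus, collapsed, index, annotation = NULL,
                           params = discovery_params()) {
  if (locus$total < params$min_reads)
    return(list(reason = "criterion1_read_support"))
  mat <- call_mature(locus, collapsed)
  if (!expression_gate(mat$counts, params$min_per_sample, params$gate_mode))
    return(list(reason = "low_expression"))
  win <- extract_window(locus, index, flank = params$flank)
  # provisional pri span for masking/complexity: locus +/- 20 nt
  pri_lo <- max(win$gstart, locus$start - 20L)
  pri_hi <- min(win$gend, locus$end + 20L)
  if (!mask_overlap(locus$chrom, pri_lo, pri_hi, annotation))
    return(list(reason = "criterion3_annotation_overlap"))
  span_seq <- if (locus$strand == "+") {
    subseq_chr(win$seq, win$to_local(pri_lo), win$to_local(pri_hi))
  } else {
    subseq_chr(win$seq, win$to_local(pri_hi), win$to_local(pri_lo))
  }
  if (!low_complexity_filter(span_seq, params$dust_t, params$tandem_max))
    return(list(reason = "low_complexity"))
  if (mat$five_prime_consistency < params$min_five_prime_consistency)
    return(list(reason = "criterion4_five_prime"))

  # mature in window-local (transcribed) coordinates; two candidate fold
  # windows (mature on the 5' or the 3' arm), plus tighter fallbacks that
  # exclude more flanking context when the generous windows mis-fold
  ml <- sort(c(win$to_local(mat$start), win$to_local(mat$end)))
  wlen <- nchar(win$seq)
  geom <- list(c(params$arm_margin, params$hairpin_reach),
               c(15L, 80L))
  cand <- list()
  for (m in geom) {
    cand[[length(cand) + 1L]] <- c(max(1L, ml[1] - m[1]),
                                   min(wlen, ml[2] + m[2]))
    cand[[length(cand) + 1L]] <- c(max(1L, ml[1] - m[2]),
                                   min(wlen, ml[2] + m[1]))
  }
  best <- NULL
  for (cw in cand) {
    sub <- subseq_chr(win$seq, cw[1], cw[2])
    st <- mfe_fold(sub, params$model)
    msub <- ml - cw[1] + 1L
    pre_def <- define_precursor(st, msub)
    if (is.null(pre_def)) next
    if (!is_single_hairpin(st, mature = msub,
                           min_paired_fraction = params$min_paired_fraction,
                           region = pre_def$pre)) next
    star <- predict_star(st, msub)
    if (is.null(star)) next
    if (!check_overhang(st, msub, star)) next
    pre_len <- pre_def$pre[2] - pre_def$pre[1] + 1L
    if (pre_len < 65L && pre_def$bounded_by != "bulge") next
    sc <- st$energy
    if (is.null(best) || sc < best$score) {
      best <- list(score = sc, struct = st, offset = cw[1], sub_end = cw[2],
                   mature = msub, star = star, pre = pre_def)
    }
  }
  if (is.null(best)) return(list(reason = "criterion2_hairpin"))

  # boundary refinement: re-fold a context-limited window around the
  # accepted precursor so boundaries depend on the local hairpin only.
  # Identical gene copies then get identical annotations regardless of
  # their (different) flanking genomic context.
  pre_w0 <- best$pre$pre + best$offset - 1L
  ref <- c(max(1L, pre_w0[1] - params$pri_margin),
           min(wlen, pre_w0[2] + params$pri_margin))
  if (ml[1] > ref[1] && ml[2] < ref[2]) {
    sub2 <- subseq_chr(win$seq, ref[1], ref[2])
    st2 <- mfe_fold(sub2, params$model)
    m2 <- ml - ref[1] + 1L
    pre2 <- define_precursor(st2, m2)
    if (!is.null(pre2) &&
        is_single_hairpin(st2, mature = m2,
                          min_paired_fraction = params$min_paired_fraction,
                          region = pre2$pre)) {
      star2 <- predict_star(st2, m2)
      if (!is.null(star2) && check_overhang(st2, m2, star2)) {
        len2 <- pre2$pre[2] - pre2$pre[1] + 1L
        if (len2 >= 65L || pre2$bounded_by == "bulge") {
          best <- list(score = st2$energy, struct = st2, offset = ref[1],
                       sub_end = ref[2], mature = m2, star = star2,
                       pre = pre2)
        }
      }
    }
  }

  off <- best$offset
  to_win <- function(iv) iv + off - 1L # subwindow -> window local
  pre_w <- to_win(best$pre$pre)
  star_w <- to_win(best$star)
  # pri: precursor +/- pri_margin, clipped to the locus window
  pri_w <- c(max(1L, pre_w[1] - params$pri_margin),
             min(wlen, pre_w[2] + params$pri_margin))
  g <- function(iv) sort(c(win$to_genomic(iv[1]), win$to_genomic(iv[2])))
  pre_g <- g(pre_w); star_g <- g(star_w); pri_g <- g(pri_w)

  # star-read support: member reads whose 5' end lies within 1 nt of the
  # predicted star 5' end
  star5 <- if (locus$strand == "+") star_g[1] else star_g[2]
  five_pos <- if (locus$strand == "+") locus$reads$start else locus$reads$end
  star_ids <- locus$reads$seq_id[abs(five_pos - star5) <= 1L]
  star_counts <- if (length(star_ids) > 0) {
    colSums(collapsed$counts[star_ids, , drop = FALSE])
  } else rep(0L, ncol(collapsed$counts))
  has_star_reads <- sum(star_counts) > 0
  if (params$require_star_reads && !has_star_reads)
    return(list(reason = "criterion5_no_star_reads"))

  wseq <- win$seq
  flags <- c(criterion1_reads = TRUE, criterion2_hairpin = TRUE,
             criterion3_no_overlap = TRUE, criterion4_five_prime = TRUE,
             criterion5_star = has_star_reads)
  gene <- list(
    chrom = locus$chrom, strand = locus$strand,
    pri = pri_g, pre = pre_g,
    mature = c(mat$start, mat$end), star = star_g,
    pri_seq = subseq_chr(wseq, pri_w[1], pri_w[2]),
    pre_seq = subseq_chr(wseq, pre_w[1], pre_w[2]),
    mature_seq = mat$sequence,
    star_seq = subseq_chr(wseq, star_w[1], star_w[2]),
    mature_counts = mat$counts, star_counts = star_counts,
    five_prime_consistency = mat$five_prime_consistency,
    criteria_flags = flags,
    arm = if (best$mature[1] < best$star[1]) "5p" else "3p",
    dotbracket = {
      # structure over the pri; positions outside the folded window are
      # unpaired context and shown as dots
      db <- strsplit(best$struct$dotbracket, "", fixed = TRUE)[[1]]
      out <- rep(".", pri_w[2] - pri_w[1] + 1L)
      lo <- max(pri_w[1], off); hi <- min(pri_w[2], best$sub_end)
      out[(lo:hi) - pri_w[1] + 1L] <- db[(lo:hi) - off + 1L]
      paste(out, collapse = "")
    },
    # the folded candidate window with local mature/star coordinates, so
    # the accepted structure can be reproduced exactly (the fold is
    # deterministic in the sequence)
    fold_seq = best$struct$sequence,
    fold_mature = best$mature, fold_star = best$star,
    fold_pre = best$pre$pre,
    energy = best$struct$energy,
    min_len_rule_used = best$pre$min_len_rule_used,
    bounded_by = best$pre$bounded_by,
    locus_total = locus$total)
  list(gene = gene)
}

#' Tunable parameters of the discovery chain
#'
#' @param min_reads criterion-1 minimum total read count of a locus.
#' @param min_per_sample expression-gate threshold (reads per sample).
#' @param gate_mode "mean" (total >= threshold x samples) or "all_samples".
#' @param min_five_prime_consistency criterion-4 threshold on the
#'   count-weighted modal 5' fraction.
#' @param min_paired_fraction minimum fraction of paired mature bases.
#' @param require_star_reads enforce observed star reads (criterion 5);
#'   the 2-nt overhang geometry is always enforced.
#' @param flank locus window flank in nt.
#' @param arm_margin,hairpin_reach candidate fold-window geometry around the
#'   mature (short side / far side).
#' @param pri_margin pri flank beyond the precursor.
#' @param dust_t,tandem_max low-complexity thresholds.
#' @param model folding [energy_model()].
#' @return named list of parameters.
#' @export
discovery_params <- function(min_reads = 2L, min_per_sample = 10,
                             gate_mode = "mean",
                             min_five_prime_consistency = 0.66,
                             min_paired_fraction = 0.5,
                             require_star_reads = FALSE,
                             flank = 70L, arm_margin = 25L,
                             hairpin_reach = 95L, pri_margin = 20L,
                             dust_t = 2.0, tandem_max = 0.8,
                             model = energy_model()) {
  list(min_reads = min_reads, min_per_sample = min_per_sample,
       gate_mode = gate_mode,
       min_five_prime_consistency = min_five_prime_consistency,
       min_paired_fraction = min_paired_fraction,
       require_star_reads = require_star_reads, flank = flank,
       arm_margin = arm_margin, hairpin_reach = hairpin_reach,
       pri_margin = pri_margin, dust_t = dust_t, tandem_max = tandem_max,
       model = model)
}

#' Discover miRNA genes from collapsed reads
#'
#' Maps the collapsed reads, builds loci and applies the annotation
#' criteria, returning the accepted catalogue and a rejection ledger.
#'
#' @param collapsed windowed `collapsed_reads`.
#' @param index `genome_index`.
#' @param annotation GRanges or NULL.
#' @param params [discovery_params()].
#' @param max_hits multi-mapping cap (see [map_reads()]).
#' @param merge_gap locus merge gap (see [build_loci()]).
#' @return list with `genes` (list of accepted records), `rejections`
#'   (table of reasons), `ledger` (funnel counts), `loci`.
#' @export
discover_mirnas <- function(collapsed, index, annotation = NULL,
                            params = discovery_params(), max_hits = 20L,
                            merge_gap = 30L) {
  hits <- map_reads(collapsed, index, max_hits = max_hits)
  loci <- build_loci(hits, collapsed, merge_gap = merge_gap)
  genes <- list()
  reasons <- character(0)
  for (lc in loci) {
    res <- apply_criteria(lc, collapsed, index, annotation, params)
    if (!is.null(res$gene)) {
      genes[[length(genes) + 1L]] <- res$gene
    } else {
      reasons <- c(reasons, res$reason)
    }
  }
  funnel_order <- c("criterion1_read_support", "low_expression",
                    "criterion3_annotation_overlap", "low_complexity",
                    "criterion4_five_prime", "criterion2_hairpin",
                    "criterion5_no_star_reads")
  rej <- table(factor(reasons, levels = funnel_order))
  n <- length(loci)
  ledger <- c(candidate_loci = n,
              post_read_support = n - sum(rej["criterion1_read_support"]),
              post_expression_gate = n - sum(rej[1:2]),
              post_mask = n - sum(rej[1:3]),
              post_complexity = n - sum(rej[1:4]),
              final_genes = length(genes))
  list(genes = genes, rejections = rej, ledger = ledger, loci = loci)
}
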