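# Synthetic small RNA-seq study generator: toy genome with planted pre-miRNA
# hairpins (including identical duplicate copies and multi-copy families),
# decoy tRNA-like/repeat loci, per-sample read pileups with dominant
# 5'-consistent mature reads, minor star reads and Dicer 2-nt 3' overhangs,
# and 3' UTRs with planted seed-complementary target sites.

TRUSEQ_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: an 18-animal
#' small-RNA sequencing design with 37-nt paired-end reads, multi-copy miRNA
#' families whose abundance is monotonically coupled to copy number, and a
#' background of decoy structured/repetitive loci.
#'
#' @param genome_length genome size in nt.
#' @param n_mirna_genes number of planted miRNA genes.
#' @param n_families number of miRNA families the genes are partitioned into.
#' @param duplicate_pair_fraction fraction of genes forming identical-sequence
#'   pri duplicated pairs (rounded down to whole pairs).
#' @param copy_number_zeta exponent of the zeta-like law family copy numbers
#'   are drawn from (larger = more skewed).
#' @param abundance_coupling strength in `[0,1]` of the monotone coupling
#'   between family copy number and family expression weight.
#' @param n_samples number of sequenced individuals.
#' @param reads_per_sample read pairs per sample.
#' @param mature_length_range inclusive range of mature miRNA lengths.
#' @param star_fraction fraction of a locus's reads coming from the star arm.
#' @param five_prime_jitter probability that a read's 5' end shifts by 1 nt.
#' @param error_rate per-base substitution probability applied independently
#'   to each mate.
#' @param decoy_read_fraction fraction of each sample's reads drawn from
#'   decoy loci.
#' @param n_decoy_trna,n_decoy_repeats decoy locus counts.
#' @param utr_count,utr_length,planted_sites_per_utr transcriptome simulation
#'   sizes.
#' @param seed RNG seed; all generator outputs are deterministic in it.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 50000L,
                       n_mirna_genes = 20L,
                       n_families = 12L,
                       duplicate_pair_fraction = 0.2,
                       copy_number_zeta = 1.5,
                       abundance_coupling = 0.7,
                       n_samples = 18L,
                       reads_per_sample = 50000L,
                       mature_length_range = c(18L, 26L),
                       star_fraction = 0.15,
                       five_prime_jitter = 0.02,
                       error_rate = 0,
                       decoy_read_fraction = 0.05,
                       n_decoy_trna = 3L,
                       n_decoy_repeats = 3L,
                       utr_count = 50L,
                       utr_length = 300L,
                       planted_sites_per_utr = 1L,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_mirna_genes = as.integer(n_mirna_genes),
              n_families = as.integer(n_families),
              duplicate_pair_fraction = duplicate_pair_fraction,
              copy_number_zeta = copy_number_zeta,
              abundance_coupling = abundance_coupling,
              n_samples = as.integer(n_samples),
              reads_per_sample = as.integer(reads_per_sample),
              mature_length_range = as.integer(mature_length_range),
              star_fraction = star_fraction,
              five_prime_jitter = five_prime_jitter,
              error_rate = error_rate,
              decoy_read_fraction = decoy_read_fraction,
              n_decoy_trna = as.integer(n_decoy_trna),
              n_decoy_repeats = as.integer(n_decoy_repeats),
              utr_count = as.integer(utr_count),
              utr_length = as.integer(utr_length),
              planted_sites_per_utr = as.integer(planted_sites_per_utr),
              seed = as.integer(seed))
  fr <- c(cfg$duplicate_pair_fraction, cfg$abundance_coupling,
          cfg$star_fraction, cfg$five_prime_jitter, cfg$error_rate,
          cfg$decoy_read_fraction)
  stopifnot(all(fr >= 0 & fr <= 1),
            cfg$mature_length_range[1] >= 16L,
            cfg$mature_length_range[2] <= 28L,
            cfg$mature_length_range[1] <= cfg$mature_length_range[2],
            cfg$reads_per_sample > 0L, cfg$n_samples >= 1L,
            cfg$n_families >= 1L, cfg$n_families <= cfg$n_mirna_genes)
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a pre-miRNA hairpin with Dicer geometry
#'
#' Builds a precursor whose mature/star duplex carries exact 2-nt 3'
#' overhangs on both strands: the precursor is a (near-)perfect inverted
#' repeat with the star interval placed 2 nt 3' of the mature's pairing
#' partners, optionally interrupted by one-sided bulges planted in the basal
#' stem outside the duplex. The basal stem is sized so the bulge-bounded
#' precursor is at least 65 nt.
#'
#' @param mature_len mature length in nt, within `[18, 26]`.
#' @param loop_len hairpin loop length, >= 3.
#' @param bulges integer vector of basal bulge sizes (each 1-4, at most 2
#'   bulges), or NULL/empty for a perfect stem.
#' @param upper_len stem bases between the mature and the loop.
#' @param mature_seq optional mature sequence (DNA); random if NULL.
#' @param wobbles number of G-U wobble pairs planted in the stem (converted
#'   from Watson-Crick pairs opposite mature G/T bases). Wobbles make the
#'   stem non-palindromic, as in real precursors; `wobbles = 0` gives a
#'   perfect inverted repeat whose star sequence is the reverse complement
#'   of the mature shifted 2 nt.
#' @return list with `precursor` (DNA string), `mature`, `star`, `pre`
#'   (1-based inclusive intervals on the precursor), `pairs` (constructed
#'   pair map), `min_len_rule_used`.
#' @export
make_hairpin <- function(mature_len = 22L, loop_len = 4L, bulges = c(2L),
                         upper_len = 4L, mature_seq = NULL, wobbles = 2L) {
  mature_len <- as.integer(mature_len)
  loop_len <- as.integer(loop_len)
  if (mature_len < 18L || mature_len > 26L)
    stop("mature_len must be in [18, 26]")
  if (loop_len < 3L) stop("loop_len must be >= 3")
  if (is.null(bulges)) bulges <- integer(0)
  bulges <- as.integer(bulges)
  if (length(bulges) > 2L || any(bulges < 1L | bulges > 4L))
    stop("unsatisfiable bulge spec: at most 2 basal bulges of size 1-4")

  if (is.null(mature_seq)) mature_seq <- random_dna(1, mature_len)
  stopifnot(nchar(mature_seq) == mature_len)

  # distance (in stem bases) from the mature 5' end to the first basal bulge,
  # chosen so the bulge-bounded precursor reaches 65 nt
  d <- max(8L, as.integer(ceiling((65 - loop_len) / 2)) - mature_len -
             upper_len)
  b5 <- if (length(bulges) > 0) d + 3L * length(bulges) + 3L else
    max(2L, as.integer(ceiling((65 - loop_len) / 2)) - mature_len -
          upper_len + 2L)

  # GC-enriched stems (as in real precursors) so the planted basal pairing
  # dominates alternative local foldings around the bulges
  basal5 <- paste(sample(DNA_BASES_, b5, replace = TRUE,
                         prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")
  upper5 <- paste(sample(DNA_BASES_, upper_len, replace = TRUE,
                         prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")
  arm5 <- paste0(basal5, mature_seq, upper5)
  a <- nchar(arm5)
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  precursor <- paste0(arm5, loop, revcomp(arm5))
  n0 <- 2L * a + loop_len

  m1 <- b5 + 1L
  m2 <- b5 + mature_len

  # convert stem pairs opposite mature G/T bases into G-U wobbles so reads
  # from either arm cannot exact-map to the opposite strand
  if (wobbles > 0L) {
    mch <- strsplit(mature_seq, "", fixed = TRUE)[[1]]
    eligible <- which(mch %in% c("G", "T"))
    # spread wobbles across the mature so any >= 16-nt read spans one
    if (length(eligible) > 0) {
      want <- unique(round(seq(0.3, 0.7, length.out = min(wobbles,
                                                          length(eligible))) *
                             mature_len))
      pick <- vapply(want, function(w) eligible[which.min(abs(eligible - w))],
                     integer(1))
      pick <- unique(pick)
      for (q in pick) {
        u <- m1 + q - 1L # mature position on the 5' arm
        t <- n0 + 1L - u # its perfect-stem partner on the 3' arm
        substr(precursor, t, t) <- if (mch[q] == "G") "T" else "G"
      }
    }
  }
  s1 <- n0 + 1L - m2 + 2L
  s2 <- n0 + 1L - m1 + 2L

  # constructed pair map of the perfect stem
  pairs <- rep(NA_integer_, n0)
  pairs[seq_len(a)] <- n0 + 1L - seq_len(a)
  pairs[(n0 - a + 1L):n0] <- a:1L

  # plant one-sided bulges on the 3' arm, outward of the star
  min_rule <- FALSE
  if (length(bulges) > 0) {
    for (bi in seq_along(bulges)) {
      g <- bulges[bi]
      p0 <- b5 - d - 3L * (bi - 1L) # 5'-arm stem base just outside the bulge
      t <- which(pairs == p0 + 1L) # partner of the first stem base kept
      stopifnot(length(t) == 1)
      ins <- paste(rep("C", g), collapse = "")
      precursor <- paste0(subseq_chr(precursor, 1L, t), ins,
                          subseq_chr(precursor, t + 1L, nchar(precursor)))
      shift <- function(x) ifelse(x > t, x + g, x)
      newpairs <- rep(NA_integer_, nchar(precursor))
      idx <- which(!is.na(pairs))
      newpairs[shift(idx)] <- shift(pairs[idx])
      pairs <- newpairs
    }
    pre1 <- b5 - d + 1L
    pre <- c(pre1, pairs[pre1])
    stopifnot(pre[2] - pre[1] + 1L >= 65L)
  } else {
    # no bulge: innermost stem base whose span reaches 65 nt (minimum-length
    # rule), capped at the full stem
    spans <- 2L * (a - seq_len(a) + 1L) + loop_len
    ok <- which(spans >= 65L & seq_len(a) <= m1 - 2L)
    if (length(ok) > 0) {
      p <- max(ok)
      pre <- c(p, pairs[p])
      min_rule <- TRUE
    } else {
      pre <- c(1L, pairs[1L])
      min_rule <- TRUE
    }
  }
  list(precursor = precursor, mature = c(m1, m2), star = c(s1, s2),
       pre = as.integer(pre), pairs = pairs, loop_len = loop_len,
       min_len_rule_used = min_rule)
}

# zeta-law family sizes summing to n_genes, each >= 1
family_sizes <- function(n_genes, n_families, zeta) {
  w <- (seq_len(n_families))^(-zeta)
  sizes <- pmax(1L, as.integer(floor(w / sum(w) * n_genes)))
  # distribute the remainder over the largest families
  i <- 1L
  while (sum(sizes) < n_genes) {
    sizes[(i - 1L) %% n_families + 1L] <- sizes[(i - 1L) %% n_families + 1L] + 1L
    i <- i + 1L
  }
  while (sum(sizes) > n_genes) {
    j <- which(sizes > 1L)
    sizes[j[length(j)]] <- sizes[j[length(j)]] - 1L
  }
  sizes
}

# mutate <= n_sub positions outside the seed (positions 2-8) so family
# members keep identical seeds and Hamming distance <= 2
mutate_outside_seed <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- setdiff(seq_along(s), 2:8)
  pos <- sample(cand, min(n_sub, length(cand)))
  for (p in pos) s[p] <- sample(setdiff(DNA_BASES_, s[p]), 1)
  paste(s, collapse = "")
}

#' Simulate a genome with planted miRNA genes and decoy loci
#'
#' Plants one hairpin per gene (identical duplicate pairs are exact copies of
#' the whole pri region), random strands, plus tRNA-like, tandem-repeat and
#' low-complexity decoy loci recorded in a BED-style annotation. Family copy
#' numbers follow a zeta-like law and family expression weights are
#' monotonically coupled to copy number with strength `abundance_coupling`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `annotation.bed` and `truth_genes.tsv`.
#' @return list with `genome` (named [Biostrings::DNAStringSet]), `truth`
#'   (list: `genes` data.frame, `families` data.frame, `decoys` data.frame,
#'   `n_duplicate_pairs`), and `annotation` ([GenomicRanges::GRanges]).
#' @export
simulate_genome <- function(cfg = sim_config(), out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 1L))

  pri_flank <- 25L
  n_genes <- cfg$n_mirna_genes
  sizes <- family_sizes(n_genes, cfg$n_families, cfg$copy_number_zeta)
  fam_of_gene <- rep(seq_along(sizes), sizes)

  # family expression weights: rank-coupled to copy number with noise
  cn_rank <- rank(sizes, ties.method = "average")
  noise <- stats::rnorm(length(sizes), 0, 1)
  score <- cfg$abundance_coupling * (cn_rank / length(sizes)) +
    (1 - cfg$abundance_coupling) * stats::pnorm(noise)
  w <- exp(3 * score)
  w <- w / sum(w)
  # floor per-gene weight so every gene is comfortably expressed
  gene_w <- w[fam_of_gene] / sizes[fam_of_gene]
  gene_w <- pmax(gene_w, 0.004)
  gene_w <- gene_w / sum(gene_w)
  fam_w <- tapply(gene_w, fam_of_gene, sum)

  # duplicate pairs: both members of a pair belong to the same family;
  # pick pair slots from families with >= 2 members
  n_pairs <- as.integer(floor(cfg$duplicate_pair_fraction * n_genes / 2))
  dup_of <- rep(NA_integer_, n_genes)
  if (n_pairs > 0) {
    avail <- which(sizes >= 2)
    pair_done <- 0L
    for (f in avail) {
      if (pair_done >= n_pairs) break
      members <- which(fam_of_gene == f)
      free <- members[is.na(dup_of[members])]
      while (length(free) >= 2 && pair_done < n_pairs) {
        dup_of[free[2]] <- free[1]
        pair_done <- pair_done + 1L
        free <- free[-(1:2)]
      }
    }
    if (pair_done < n_pairs)
      stop("cannot satisfy duplicate_pair_fraction with these family sizes")
  }

  # family base matures; members differ by <= 2 substitutions outside seed
  base_mature <- character(length(sizes))
  mlr <- cfg$mature_length_range
  mature_len_f <- sample(seq(max(18L, mlr[1]), min(26L, mlr[2])),
                         length(sizes), replace = TRUE)
  for (f in seq_along(sizes)) base_mature[f] <- random_dna(1, mature_len_f[f])

  genes <- vector("list", n_genes)
  first_of_family <- !duplicated(fam_of_gene)
  for (g in seq_len(n_genes)) {
    if (!is.na(dup_of[g])) next
    f <- fam_of_gene[g]
    # the first member carries the family's base mature, so single-linkage
    # clustering can bridge any two <=2-substitution variants through it
    mseq <- if (first_of_family[g]) base_mature[f] else
      mutate_outside_seed(base_mature[f], sample(0:2, 1))
    hp <- make_hairpin(mature_len = nchar(mseq),
                       loop_len = sample(4:8, 1),
                       bulges = if (stats::runif(1) < 0.8)
                         sample(1:3, 1) else NULL,
                       upper_len = sample(3:5, 1),
                       mature_seq = mseq)
    genes[[g]] <- hp
  }
  for (g in which(!is.na(dup_of))) genes[[g]] <- genes[[dup_of[g]]]

  # decoys: tRNA-like (random structured-ish), tandem repeats, homopolymer
  decoy <- list()
  for (i in seq_len(cfg$n_decoy_trna)) {
    stem <- random_dna(1, 15)
    decoy[[length(decoy) + 1L]] <- list(
      class = "tRNA",
      seq = paste0(stem, random_dna(1, 20), revcomp(stem), random_dna(1, 25)))
  }
  for (i in seq_len(cfg$n_decoy_repeats)) {
    unit <- sample(c("AT", "CAG", "TG", "AAG"), 1)
    cls <- if (nchar(unit) == 1) "low_complexity" else "repeat"
    decoy[[length(decoy) + 1L]] <- list(
      class = cls,
      seq = paste(rep(unit, ceiling(80 / nchar(unit))), collapse = ""))
  }
  if (cfg$n_decoy_repeats > 0) {
    decoy[[length(decoy) + 1L]] <- list(
      class = "low_complexity", seq = strrep("A", 80))
  }

  # placement: pri regions (hairpin +/- pri_flank) and decoys, non-overlapping
  elements <- c(
    lapply(seq_len(n_genes), function(g) {
      list(kind = "gene", id = g,
           seq = paste0(random_dna(1, pri_flank), genes[[g]]$precursor,
                        random_dna(1, pri_flank)))
    }),
    lapply(seq_along(decoy), function(i) {
      list(kind = "decoy", id = i, seq = decoy[[i]]$seq,
           class = decoy[[i]]$class)
    })
  )
  # identical duplicates share the full pri sequence (flanks included)
  for (g in which(!is.na(dup_of))) {
    elements[[g]]$seq <- elements[[dup_of[g]]]$seq
  }
  ord <- sample(seq_along(elements)) # random order along the genome
  elements <- elements[ord]
  lens <- vapply(elements, function(e) nchar(e$seq), integer(1))
  k <- length(elements)
  gap <- 80L # minimum spacing so neighbouring loci never merge
  slack <- cfg$genome_length - sum(lens) - gap * (k + 1L)
  if (slack < k)
    stop("genome_length too small to place all planted elements")
  cuts <- sort(sample.int(slack, k))
  starts <- cuts + gap * seq_len(k) +
    c(0L, cumsum(lens))[seq_len(k)] + 1L

  genome_chars <- strsplit(random_dna(1, cfg$genome_length), "",
                           fixed = TRUE)[[1]]
  strand_of_gene <- sample(c("+", "-"), n_genes, replace = TRUE)
  gene_rows <- list()
  decoy_rows <- list()
  for (e in seq_along(elements)) {
    el <- elements[[e]]
    gstart <- starts[e]
    gend <- gstart + nchar(el$seq) - 1L
    if (el$kind == "gene") {
      g <- el$id
      strand <- strand_of_gene[g]
      planted <- if (strand == "+") el$seq else revcomp(el$seq)
      hp <- genes[[g]]
      # local (transcribed) coordinates within the pri element
      loc <- function(iv) iv + pri_flank
      tolocal <- function(iv) {
        if (strand == "+") c(gstart + iv[1] - 1L, gstart + iv[2] - 1L)
        else c(gend - iv[2] + 1L, gend - iv[1] + 1L)
      }
      pl <- nchar(el$seq)
      m <- tolocal(loc(hp$mature)); s <- tolocal(loc(hp$star))
      p <- tolocal(loc(hp$pre))
      gene_rows[[g]] <- data.frame(
        gene_id = sprintf("gene%02d", g), family = fam_of_gene[g],
        chrom = "chr1", strand = strand,
        pri_start = gstart, pri_end = gend,
        pre_start = p[1], pre_end = p[2],
        mature_start = m[1], mature_end = m[2],
        star_start = s[1], star_end = s[2],
        mature_seq = subseq_chr(el$seq, loc(hp$mature)[1], loc(hp$mature)[2]),
        star_seq = subseq_chr(el$seq, loc(hp$star)[1], loc(hp$star)[2]),
        pri_seq = el$seq,
        pre_seq = subseq_chr(el$seq, loc(hp$pre)[1], loc(hp$pre)[2]),
        duplicate_of = ifelse(is.na(dup_of[g]), NA_character_,
                              sprintf("gene%02d", dup_of[g])),
        weight = gene_w[g],
        min_len_rule_used = hp$min_len_rule_used,
        stringsAsFactors = FALSE)
      genome_chars[gstart:gend] <- strsplit(planted, "", fixed = TRUE)[[1]]
    } else {
      genome_chars[gstart:gend] <- strsplit(el$seq, "", fixed = TRUE)[[1]]
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        decoy_id = sprintf("decoy%02d", el$id), class = el$class,
        chrom = "chr1", start = gstart, end = gend, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  genome_seq <- paste(genome_chars, collapse = "")
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chr1"

  genes_df <- do.call(rbind, gene_rows)
  rownames(genes_df) <- NULL
  decoys_df <- do.call(rbind, decoy_rows)
  fam_df <- data.frame(family = seq_along(sizes), copy_number = sizes,
                       weight = as.numeric(fam_w),
                       base_mature = base_mature,
                       stringsAsFactors = FALSE)
  annotation <- GenomicRanges::GRanges(
    seqnames = decoys_df$chrom,
    ranges = IRanges::IRanges(decoys_df$start, decoys_df$end),
    strand = "*", name = decoys_df$class)
  truth <- list(genes = genes_df, families = fam_df, decoys = decoys_df,
                n_duplicate_pairs = n_pairs)
  out <- list(genome = genome, truth = truth, annotation = annotation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
    rtracklayer::export(annotation, file.path(out_dir, "annotation.bed"),
                        format = "BED")
    utils::write.table(genes_df, file.path(out_dir, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- list(genome = file.path(out_dir, "genome.fa"),
                      annotation = file.path(out_dir, "annotation.bed"))
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate paired-end small RNA reads
#'
#' Emits 37-nt read pairs per sample: inserts are mature/star fragments
#' (with optional 1-nt 5' jitter and per-base substitution errors applied to
#' each mate independently), padded with a fixed 3' adapter; mate 2 is the
#' reverse complement of mate 1. Per-sample gene counts are multinomial in
#' the planted per-gene weights. A small fraction of reads originates from
#' decoy loci.
#'
#' @param sim output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @param out_dir directory for `sample_XX_R{1,2}.fastq` files.
#' @return list with `manifest` (data.frame: sample, r1, r2) and
#'   `true_counts` (genes x samples matrix of emitted mature-arm read
#'   counts).
#' @export
simulate_reads <- function(sim, cfg = sim_config(), out_dir) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 2L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- sim$truth$genes
  n_genes <- nrow(genes)
  decoys <- sim$truth$decoys
  gw <- genes$weight / sum(genes$weight)
  genome_seq <- as.character(sim$genome[["chr1"]])

  # insert sequences per (gene, arm, shift) in transcribed orientation
  variant_seq <- function(g, arm, shift) {
    pri <- genes$pri_seq[g]
    iv <- if (arm == "mature") {
      c(genes$mature_start[g], genes$mature_end[g])
    } else c(genes$star_start[g], genes$star_end[g])
    # local coords within pri (transcribed orientation)
    if (genes$strand[g] == "+") {
      l1 <- iv[1] - genes$pri_start[g] + 1L
    } else {
      l1 <- genes$pri_end[g] - iv[2] + 1L
    }
    l2 <- l1 + (iv[2] - iv[1])
    subseq_chr(pri, l1 + shift, l2 + shift)
  }

  manifest <- data.frame(sample = seq_len(cfg$n_samples),
                         r1 = character(cfg$n_samples),
                         r2 = character(cfg$n_samples),
                         stringsAsFactors = FALSE)
  true_counts <- matrix(0L, n_genes, cfg$n_samples,
                        dimnames = list(genes$gene_id, NULL))
  shifts <- c(-1L, 0L, 1L)
  j <- cfg$five_prime_jitter
  shift_p <- c(j / 2, 1 - j, j / 2)

  for (s in seq_len(cfg$n_samples)) {
    n_decoy <- as.integer(round(cfg$reads_per_sample *
                                  cfg$decoy_read_fraction))
    n_gene_reads <- cfg$reads_per_sample - n_decoy
    cnt <- as.integer(stats::rmultinom(1, n_gene_reads, gw))
    seqs <- character(0)
    for (g in seq_len(n_genes)) {
      if (cnt[g] == 0) next
      n_star <- stats::rbinom(1, cnt[g], cfg$star_fraction)
      n_mat <- cnt[g] - n_star
      true_counts[g, s] <- n_mat
      for (arm in c("mature", "star")) {
        n_arm <- if (arm == "mature") n_mat else n_star
        if (n_arm == 0) next
        per_shift <- as.integer(stats::rmultinom(1, n_arm, shift_p))
        for (v in 1:3) {
          if (per_shift[v] == 0) next
          seqs <- c(seqs, rep(variant_seq(g, arm, shifts[v]), per_shift[v]))
        }
      }
    }
    if (n_decoy > 0 && nrow(decoys) > 0) {
      dd <- sample(nrow(decoys), n_decoy, replace = TRUE)
      off <- sample(0:6, n_decoy, replace = TRUE)
      dstart <- decoys$start[dd] + 10L + off
      dseqs <- substring(genome_seq, dstart, dstart + 23L)
      seqs <- c(seqs, dseqs)
    }
    # 37-nt reads: insert + adapter pad
    reads <- substr(paste0(seqs, TRUSEQ_ADAPTER, TRUSEQ_ADAPTER), 1, 37)
    if (cfg$error_rate > 0) {
      reads1 <- .inject_errors(reads, cfg$error_rate)
      reads2 <- revcomp(.inject_errors(reads, cfg$error_rate))
    } else {
      reads1 <- reads
      reads2 <- revcomp(reads)
    }
    perm <- sample(length(reads1))
    reads1 <- reads1[perm]; reads2 <- reads2[perm]
    qual <- strrep("I", 37)
    ids <- sprintf("@s%d_r%d", s, seq_along(reads1))
    r1_path <- file.path(out_dir, sprintf("sample_%02d_R1.fastq", s))
    r2_path <- file.path(out_dir, sprintf("sample_%02d_R2.fastq", s))
    writeLines(as.vector(rbind(ids, reads1, "+", qual)), r1_path)
    writeLines(as.vector(rbind(ids, reads2, "+", qual)), r2_path)
    manifest$r1[s] <- r1_path
    manifest$r2[s] <- r2_path
  }
  list(manifest = manifest, true_counts = true_counts)
}

# one random substitution in each read selected by a per-read Bernoulli with
# probability 1 - (1-rate)^len (single substitution per erroneous read)
.inject_errors <- function(reads, rate) {
  len <- nchar(reads[1])
  p <- 1 - (1 - rate)^len
  hit <- which(stats::runif(length(reads)) < p)
  if (length(hit) == 0) return(reads)
  pos <- sample.int(len, length(hit), replace = TRUE)
  for (k in seq_along(hit)) {
    i <- hit[k]
    old <- substr(reads[i], pos[k], pos[k])
    substr(reads[i], pos[k], pos[k]) <- sample(setdiff(DNA_BASES_, old), 1)
  }
  reads
}

#' Simulate a 3' UTR set with planted miRNA target sites
#'
#' Generates UTRs from a first-order (dinucleotide) Markov model estimated
#' from the simulated genome and embeds, per UTR, seed-complementary sites:
#' the reverse complement of miRNA positions s..s+k-1 with s in {1,2} and
#' k in 9-12.
#'
#' @param sim output of [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory (`utrs.fa`, `planted_sites.tsv`).
#' @return list with `utrs` (named character vector), `sites` (data.frame:
#'   utr_id, mirna_id, start, end, k, s).
#' @export
simulate_transcriptome <- function(sim, cfg = sim_config(), out_dir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, 3L))

  genes <- sim$truth$genes
  matures <- unique(genes$mature_seq)
  mirna_ids <- genes$gene_id[match(matures, genes$mature_seq)]

  trans <- dinucleotide_transitions(as.character(sim$genome))
  utrs <- character(cfg$utr_count)
  sites <- list()
  for (u in seq_len(cfg$utr_count)) {
    bg <- markov_seq(cfg$utr_length, trans)
    if (cfg$planted_sites_per_utr > 0 && length(matures) > 0) {
      for (ps in seq_len(cfg$planted_sites_per_utr)) {
        mi <- sample(length(matures), 1)
        s <- sample(1:2, 1)
        k <- .planted_site_k(matures[mi], s)
        site <- revcomp(subseq_chr(matures[mi], s, s + k - 1L))
        pos <- sample(seq(10L, cfg$utr_length - k - 10L), 1)
        substr(bg, pos, pos + k - 1L) <- site
        sites[[length(sites) + 1L]] <- data.frame(
          utr_id = sprintf("utr%03d", u), mirna_id = mirna_ids[mi],
          mirna_seq = matures[mi],
          start = pos, end = pos + k - 1L, k = k, s = s,
          stringsAsFactors = FALSE)
      }
    }
    utrs[u] <- bg
  }
  names(utrs) <- sprintf("utr%03d", seq_len(cfg$utr_count))
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(utr_id = character(0), mirna_id = character(0),
               mirna_seq = character(0), start = integer(0),
               end = integer(0), k = integer(0), s = integer(0))
  out <- list(utrs = utrs, sites = sites)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ss <- Biostrings::DNAStringSet(utrs)
    Biostrings::writeXStringSet(ss, file.path(out_dir, "utrs.fa"))
    utils::write.table(sites, file.path(out_dir, "planted_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# planted site length: smallest k (from seed start s) whose guaranteed
# duplex score reaches the stability floor, clamped to [10, 16]. Functional
# sites are selected for comparable duplex stability, so AU-rich miRNAs get
# longer complementary stretches (3'-supplementary pairing) than GC-rich
# ones.
.planted_site_k <- function(mature, s, floor_score = -32, kmin = 10L,
                            kmax = 16L) {
  sc <- c(A = -2, C = -3, G = -3, T = -2)[strsplit(mature, "",
                                                   fixed = TRUE)[[1]]]
  cum <- cumsum(sc[s:length(sc)])
  k <- which(cum <= floor_score)[1]
  if (is.na(k)) k <- length(cum)
  max(kmin, min(kmax, k, length(cum)))
}

#' Dinucleotide transition matrix of a sequence set
#' @param seqs character vector of DNA sequences.
#' @return 4x4 row-stochastic matrix over ACGT.
#' @export
dinucleotide_transitions <- function(seqs) {
  tab <- matrix(1, 4, 4, dimnames = list(DNA_BASES_, DNA_BASES_))
  for (s in seqs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch <- ch[ch %in% DNA_BASES_]
    if (length(ch) < 2) next
    t2 <- table(factor(ch[-length(ch)], DNA_BASES_),
                factor(ch[-1], DNA_BASES_))
    tab <- tab + as.matrix(t2)
  }
  tab / rowSums(tab)
}

# sample a sequence from a first-order Markov chain over ACGT
markov_seq <- function(len, trans) {
  out <- character(len)
  out[1] <- sample(DNA_BASES_, 1)
  for (i in 2:len) out[i] <- sample(DNA_BASES_, 1, prob = trans[out[i - 1], ])
  paste(out, collapse = "")
}

#' Synthetic reference mature-miRNA set
#'
#' Builds a miRBase-style reference: for a fraction of the planted families a
#' near-identical (<= 1 substitution) mature entry under a reference-species
#' name, plus unrelated random entries. Used to exercise homology
#' classification with known expected labels.
#'
#' @param sim output of [simulate_genome()].
#' @param conserved_fraction fraction of families present in the reference.
#' @param n_random number of unrelated reference entries.
#' @param seed RNG seed.
#' @return named character vector of reference mature sequences (DNA).
#' @export
simulate_reference <- function(sim, conserved_fraction = 0.5, n_random = 20L,
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 4L))
  fams <- sim$truth$families
  n_cons <- as.integer(round(conserved_fraction * nrow(fams)))
  pick <- sort(sample(nrow(fams), n_cons))
  refs <- character(0)
  for (i in seq_along(pick)) {
    f <- pick[i]
    seq <- mutate_outside_seed(fams$base_mature[f], sample(0:1, 1))
    nm <- sprintf("dre-miR-%d-5p", 100 + fams$family[f])
    refs[nm] <- seq
  }
  for (i in seq_len(n_random)) {
    refs[sprintf("dre-miR-%d-3p", 500 + i)] <- random_dna(1, 22)
  }
  refs
}
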