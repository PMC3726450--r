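# Family clustering of mature miRNAs, duplicate counting, abundance
# aggregation and the copy-number/abundance association test.

# Hamming distance over the overlap of the shorter sequence at offsets
# -1, 0, +1; Inf when lengths are incompatible
.best_offset_dist <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  na <- nchar(a); nb <- nchar(b)
  best <- Inf
  for (off in -1:1) {
    i <- max(1L, 1L - off):min(na, nb - off)
    if (length(i) < na - 1L) next
    av <- strsplit(a, "", fixed = TRUE)[[1]][i]
    bv <- strsplit(b, "", fixed = TRUE)[[1]][i + off]
    d <- sum(av != bv) + (na - length(i)) # unaligned overhang counts
    best <- min(best, d)
  }
  best
}

#' Cluster mature miRNAs into families
#'
#' Single-linkage clustering: two matures link iff their seed regions
#' (positions 2-8) are identical and the full-length Hamming distance (over
#' the shorter sequence, best offset in -1/0/+1) is at most `max_dist`.
#' Clusters containing homology-named members take that family label.
#'
#' @param matures character vector of mature sequences.
#' @param family_hints optional character vector of homology-derived family
#'   labels (NA where novel); a cluster inherits its most frequent hint.
#' @param max_dist maximum full-length distance.
#' @return integer cluster index per mature, with a `labels` attribute
#'   (cluster id -> family name).
#' @export
cluster_families <- function(matures, family_hints = NULL, max_dist = 3L) {
  n <- length(matures)
  if (n == 0) return(structure(integer(0), labels = character(0)))
  seeds <- substring(matures, 2, 8)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (seeds[i] != seeds[j]) next
    if (.best_offset_dist(matures[i], matures[j]) > max_dist) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, unique(roots))
  labels <- character(max(cl))
  for (k in seq_len(max(cl))) {
    hints <- if (is.null(family_hints)) character(0) else
      family_hints[cl == k & !is.na(family_hints)]
    labels[k] <- if (length(hints) > 0) names(sort(table(hints),
                                                   decreasing = TRUE))[1]
    else sprintf("fam-%d", k)
  }
  structure(cl, labels = labels)
}

#' Count identical duplicate pri sequences
#'
#' Groups identical pri sequences and reports the number of identical pairs
#' (sum over groups of choose(size, 2)) plus the fraction of genes lying in
#' multi-copy groups.
#'
#' @param pri_seqs character vector of pri sequences.
#' @return list with `n_pairs`, `n_genes_in_duplicates`, `fraction`.
#' @export
find_duplicates <- function(pri_seqs) {
  if (length(pri_seqs) == 0)
    return(list(n_pairs = 0L, n_genes_in_duplicates = 0L, fraction = 0))
  tab <- table(pri_seqs)
  n_pairs <- sum(choose(as.integer(tab), 2))
  in_dup <- sum(tab[tab > 1])
  list(n_pairs = as.integer(n_pairs),
       n_genes_in_duplicates = as.integer(in_dup),
       fraction = in_dup / length(pri_seqs))
}

#' Family copy number and abundance table
#'
#' Aggregates a named catalogue into family records: copy number (member
#' genes), abundance (summed mature counts, with reads of identical
#' duplicate matures counted once) and relative abundance.
#'
#' @param catalogue list of gene records with `mature_seq`, `mature_counts`
#'   and `gene_id`.
#' @param clusters result of [cluster_families()] on the catalogue matures.
#' @return data.frame: family, copy_number, abundance, relative_abundance.
#' @export
family_abundance <- function(catalogue, clusters) {
  stopifnot(length(catalogue) == length(clusters))
  labels <- attr(clusters, "labels")
  fam <- labels[clusters]
  # identical duplicate matures carry the same reads: count once per family
  mat_seq <- vapply(catalogue, `[[`, character(1), "mature_seq")
  tot <- vapply(catalogue, function(g) sum(g$mature_counts), numeric(1))
  dfa <- data.frame(family = fam, mature = mat_seq, total = tot,
                    stringsAsFactors = FALSE)
  dedup <- dfa[!duplicated(dfa[, c("family", "mature")]), , drop = FALSE]
  ab <- tapply(dedup$total, dedup$family, sum)
  cn <- table(fam)
  fams <- sort(unique(fam))
  out <- data.frame(family = fams,
                    copy_number = as.integer(cn[fams]),
                    abundance = as.numeric(ab[fams]),
                    stringsAsFactors = FALSE)
  out$relative_abundance <- out$abundance / sum(out$abundance)
  out[order(-out$abundance), , drop = FALSE]
}

#' Spearman correlation with permutation p-value
#'
#' Rank correlation using midranks for ties; the two-sided p-value is
#' estimated by random permutation: p = (1 + #{|rho*| >= |rho|}) /
#' (n_perm + 1).
#'
#' @param x,y numeric vectors (length >= 3).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draw.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 5L))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  perm <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
  p <- (1 + sum(perm >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n = length(x))
}
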