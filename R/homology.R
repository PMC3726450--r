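# Homology classification of mature miRNAs against reference sets by
# exhaustive ungapped local alignment with Karlin-Altschul E-values, and
# miRBase-style catalogue naming.

#' Best ungapped local alignment score between two short sequences
#'
#' Exhaustive scan over all diagonals and both query orientations: the
#' maximum-scoring contiguous segment under a match/mismatch scheme. Exact
#' for the short sequences involved (no word seeding needed).
#'
#' @param query,subject DNA sequences (<= 40 nt).
#' @param match,mismatch scoring scheme.
#' @return list with `score` (0 when no positive segment exists), `length`
#'   (aligned length of the best segment) and `strand` ("+"/"-").
#' @export
ungapped_align <- function(query, subject, match = 1L, mismatch = -3L) {
  if (nchar(query) == 0 || nchar(subject) == 0)
    stop("empty sequence")
  if (nchar(query) > 40 || nchar(subject) > 40)
    stop("sequences longer than 40 nt")
  s <- strsplit(toupper(as_dna(subject)), "", fixed = TRUE)[[1]]
  best <- list(score = 0L, length = 0L, strand = "+")
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") toupper(as_dna(query)) else
      revcomp(as_dna(query))
    q <- strsplit(qs, "", fixed = TRUE)[[1]]
    nq <- length(q); ns <- length(s)
    for (off in (-(nq - 1L)):(ns - 1L)) {
      i <- max(1L, 1L - off):min(nq, ns - off)
      if (length(i) == 0) next
      sc <- ifelse(q[i] == s[i + off], match, mismatch)
      # maximum contiguous subsegment (Kadane) and its length
      run <- 0L; run_len <- 0L
      for (v in seq_along(sc)) {
        cand <- run + sc[v]
        if (cand <= 0) { run <- 0L; run_len <- 0L } else {
          run <- cand; run_len <- run_len + 1L
        }
        if (run > best$score) {
          best <- list(score = run, length = run_len, strand = strand)
        }
      }
    }
  }
  best
}

#' Karlin-Altschul expectation for an ungapped alignment score
#'
#' E = K * m * n * exp(-lambda * S). The default K and lambda are the
#' standard ungapped DNA values for the +1/-3 match/mismatch scheme.
#'
#' @param score alignment score.
#' @param m query length.
#' @param n total subject database length.
#' @param K,lambda Karlin-Altschul parameters.
#' @return expectation value.
#' @export
evalue <- function(score, m, n, K = 0.711, lambda = 1.374) {
  stopifnot(K > 0, lambda > 0)
  K * m * n * exp(-lambda * score)
}

#' Classify a mature miRNA against reference sets
#'
#' Searches a miRBase-style reference and a second species-specific set,
#' in that precedence order: `conserved_mirbase` if the best miRBase hit has
#' E below `e_max`, else `conserved_omy` on the second set, else `novel`.
#' Ties are broken by lowest E then lexicographic subject id.
#'
#' @param mature mature sequence.
#' @param mirbase_set,omy_set named character vectors of reference mature
#'   sequences (either may be NULL/empty).
#' @param e_max E-value threshold.
#' @param match,mismatch,K,lambda alignment/statistics parameters.
#' @return list with `classification`, `subject`, `score`, `e_value`.
#' @export
classify <- function(mature, mirbase_set = NULL, omy_set = NULL,
                     e_max = 0.5, match = 1L, mismatch = -3L,
                     K = 0.711, lambda = 1.374) {
  best_hit <- function(refs) {
    if (is.null(refs) || length(refs) == 0) return(NULL)
    n_db <- sum(nchar(refs))
    ord <- order(names(refs))
    refs <- refs[ord]
    hits <- lapply(seq_along(refs), function(i) {
      al <- ungapped_align(mature, refs[[i]], match, mismatch)
      e <- evalue(al$score, nchar(mature), n_db, K, lambda)
      list(subject = names(refs)[i], score = al$score, e_value = e)
    })
    ev <- vapply(hits, `[[`, numeric(1), "e_value")
    hits[[order(ev, names(refs))[1]]]
  }
  hb <- best_hit(mirbase_set)
  if (!is.null(hb) && hb$score > 0 && hb$e_value < e_max) {
    return(c(list(classification = "conserved_mirbase"), hb))
  }
  ho <- best_hit(omy_set)
  if (!is.null(ho) && ho$score > 0 && ho$e_value < e_max) {
    return(c(list(classification = "conserved_omy"), ho))
  }
  best <- if (!is.null(hb) && (is.null(ho) || hb$e_value <= ho$e_value))
    hb else ho
  c(list(classification = "novel"),
    if (is.null(best)) list(subject = NA_character_, score = NA_integer_,
                            e_value = NA_real_) else best)
}

# parse the family core from a miRBase-style name:
# "omy-miR-nov79-5p" -> "nov-79"; "dre-miR-145-5p" -> "miR-145";
# "xla-let-7a-3p" -> "let-7a"
.family_from_name <- function(name) {
  core <- sub("^[a-z]{3,4}-", "", name)
  core <- sub("-[35]p$", "", core)
  novel <- regmatches(core, regexec("^miR-nov([0-9A-Za-z]+)$", core))[[1]]
  if (length(novel) == 2) return(paste0("nov-", novel[2]))
  core
}

#' Assign miRBase-style names to a discovered catalogue
#'
#' Conserved genes inherit the family core of their best reference hit with
#' the species prefix and an arm suffix (-5p/-3p from which precursor arm
#' holds the mature); novel genes are numbered `<prefix>-nov-N` in
#' discovery order. Genes sharing an identical mature share the mature
#' name; their gene ids get -1, -2, ... suffixes.
#'
#' @param catalogue list of gene records (from [discover_mirnas()]).
#' @param classifications list of [classify()] results, parallel to
#'   `catalogue` (NULL entries allowed).
#' @param prefix species prefix.
#' @return the catalogue with `name`, `gene_id`, `classification`,
#'   `homology_subject`, `homology_evalue` fields filled in.
#' @export
assign_names <- function(catalogue, classifications = NULL,
                         prefix = "ssa") {
  nov_counter <- 0L
  names_out <- character(length(catalogue))
  for (i in seq_along(catalogue)) {
    g <- catalogue[[i]]
    cl <- if (is.null(classifications)) NULL else classifications[[i]]
    if (!is.null(cl) && cl$classification != "novel" &&
        !is.na(cl$subject)) {
      fam <- .family_from_name(cl$subject)
      base <- if (grepl("^(nov|let)", fam)) paste0(prefix, "-", fam) else
        paste0(prefix, "-", fam)
      g$classification <- cl$classification
      g$homology_subject <- cl$subject
      g$homology_evalue <- cl$e_value
      g$family_hint <- fam
    } else {
      # share the novel number among identical matures seen before
      prev <- which(vapply(catalogue[seq_len(i - 1L)], function(x)
        identical(x$mature_seq, g$mature_seq), logical(1)))
      prev <- prev[nzchar(names_out[prev])]
      if (length(prev) > 0 && grepl("-nov-", names_out[prev[1]])) {
        base <- sub("-[35]p$", "", names_out[prev[1]])
      } else {
        nov_counter <- nov_counter + 1L
        base <- paste0(prefix, "-nov-", nov_counter)
      }
      g$classification <- if (is.null(cl)) "novel" else cl$classification
      g$homology_subject <- if (is.null(cl)) NA_character_ else cl$subject
      g$homology_evalue <- if (is.null(cl)) NA_real_ else cl$e_value
      g$family_hint <- sub(paste0("^", prefix, "-"), "", base)
    }
    nm <- paste0(base, "-", g$arm)
    names_out[i] <- nm
    g$name <- nm
    catalogue[[i]] <- g
  }
  # gene ids: mature-name with -1/-2 suffixes for shared names
  tab <- table(names_out)
  seen <- stats::setNames(rep(0L, length(tab)), names(tab))
  for (i in seq_along(catalogue)) {
    nm <- names_out[i]
    if (tab[nm] > 1L) {
      seen[nm] <- seen[nm] + 1L
      catalogue[[i]]$gene_id <- paste0(nm, "-", seen[nm])
    } else {
      catalogue[[i]]$gene_id <- nm
    }
  }
  catalogue
}
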