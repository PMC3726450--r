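#' Base-pair energy model for hairpin folding
#'
#' A deliberately simple nearest-neighbour-free energy model: every allowed
#' base pair contributes a fixed negative score and every unpaired base that
#' is enclosed by at least one pair pays a fixed penalty (unpaired bases in
#' the exterior loop are free). Lower energies are more stable. The model
#' preserves what the discovery pipeline needs from a thermodynamic folder —
#' hairpin topology and relative stem stability — without the full Turner
#' parameter set.
#'
#' @param pair_scores named numeric vector of pair scores (negative), names
#'   are the 6 canonical/wobble pairs.
#' @param min_loop minimum hairpin loop size in nt: a pair (i, j) requires
#'   j - i - 1 >= min_loop.
#' @param bulge_penalty penalty per enclosed unpaired base.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(pair_scores = c(GC = -3, CG = -3, AU = -2, UA = -2,
                                         GU = -1, UG = -1),
                         min_loop = 3L, bulge_penalty = 1L) {
  stopifnot(all(pair_scores < 0), min_loop >= 0, bulge_penalty >= 0)
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  for (nm in names(pair_scores)) {
    a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
    m[a, b] <- as.integer(pair_scores[[nm]])
  }
  structure(list(pair_scores = pair_scores, score_matrix = m,
                 min_loop = as.integer(min_loop),
                 bulge_penalty = as.integer(bulge_penalty)),
            class = "energy_model")
}

new_secondary_structure <- function(sequence, dotbracket, energy, model) {
  structure(list(sequence = sequence, dotbracket = dotbracket,
                 energy = energy, pairs = pairs_from_dotbracket(dotbracket),
                 model = model),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", format(x$energy), ")\n", sep = "")
  invisible(x)
}

#' Minimum-free-energy nested secondary structure
#'
#' Dynamic-programming fold of a single RNA (or DNA, converted to RNA)
#' sequence under [energy_model()], returning the optimal nested structure in
#' dot-bracket notation. Among co-optimal structures the traceback is
#' deterministic: pairing the 5'-most base is preferred over leaving it
#' unpaired, and the smallest pairing partner is preferred.
#'
#' @param seq character scalar, ACGU (T accepted and converted).
#' @param model an [energy_model()].
#' @return a `secondary_structure` with fields `sequence`, `dotbracket`,
#'   `energy` and `pairs` (1-based partner index per position, NA if
#'   unpaired).
#' @export
mfe_fold <- function(seq, model = energy_model()) {
  stopifnot(is.character(seq), length(seq) == 1)
  rna <- as_rna(seq)
  code <- encode_rna(rna)
  res <- .fold_dp(code, model$score_matrix, model$min_loop,
                  model$bulge_penalty)
  new_secondary_structure(rna, res$dotbracket, res$energy, model)
}

#' Pair map from dot-bracket notation
#'
#' @param db dot-bracket string over "()." .
#' @return integer vector of 1-based pairing partners (NA where unpaired).
#' @export
pairs_from_dotbracket <- function(db) {
  s <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(s)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (s[i] == "(") {
      stack <- c(stack, i)
    } else if (s[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (s[i] != ".") {
      stop("invalid dot-bracket character: ", s[i])
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  partner
}

#' @rdname pairs_from_dotbracket
#' @param pairs integer partner vector as returned by `pairs_from_dotbracket`.
#' @export
dotbracket_from_pairs <- function(pairs) {
  out <- rep(".", length(pairs))
  idx <- which(!is.na(pairs))
  out[idx[pairs[idx] > idx]] <- "("
  out[idx[pairs[idx] < idx]] <- ")"
  paste(out, collapse = "")
}

#' Structure energy by direct evaluation
#'
#' Computes the energy of an explicit structure from the model definition
#' (sum of pair scores plus the enclosed-unpaired penalty), independently of
#' the folding recursion. Used as the scoring half of the brute-force oracle.
#'
#' @param code integer-encoded RNA (A=0,C=1,G=2,U=3).
#' @param pairs integer partner vector (NA unpaired).
#' @param model an [energy_model()].
#' @return numeric energy.
#' @export
structure_energy <- function(code, pairs, model = energy_model()) {
  n <- length(code)
  if (n == 0) return(0)
  e <- 0L
  opened <- which(!is.na(pairs) & pairs > seq_along(pairs))
  for (i in opened) {
    e <- e + model$score_matrix[code[i] + 1L, code[pairs[i]] + 1L]
  }
  # an unpaired base pays the penalty iff its closest enclosing pair
  # encloses at least one other pair (bulge/internal/multibranch loop);
  # hairpin-loop and exterior bases are free
  paired <- !is.na(pairs)
  for (i in which(!paired)) {
    enc <- opened[opened < i & pairs[opened] > i]
    if (length(enc) == 0) next
    a <- max(enc)
    b <- pairs[a]
    inside <- (a + 1L):(b - 1L)
    if (any(paired[inside])) e <- e + model$bulge_penalty
  }
  as.numeric(e)
}

#' Exhaustive folding oracle
#'
#' Enumerates every valid nested structure of a short sequence (allowed
#' pairs, minimum loop size) and scores each with [structure_energy()],
#' returning the global optimum. Exponential — refuses sequences longer than
#' `max_len`.
#'
#' @inheritParams mfe_fold
#' @param max_len hard length cap for the enumeration.
#' @return list with `energy` (optimal) and `structures` (dot-bracket strings
#'   of all co-optimal structures).
#' @export
brute_force_fold <- function(seq, model = energy_model(), max_len = 18L) {
  rna <- as_rna(seq)
  n <- nchar(rna)
  if (n > max_len) stop("sequence longer than max_len = ", max_len)
  if (n == 0) return(list(energy = 0, structures = ""))
  code <- encode_rna(rna)
  pairable <- outer(seq_len(n), seq_len(n), function(i, j) {
    model$score_matrix[cbind(code[i] + 1L, code[j] + 1L)] < 0 &
      (j - i - 1L) >= model$min_loop
  })
  # recursively enumerate pair sets of [i, j]; each structure is an integer
  # vector c(i1, j1, i2, j2, ...)
  enum <- function(i, j) {
    if (i >= j) return(list(integer(0)))
    out <- lapply(enum(i + 1L, j), identity) # i unpaired
    ks <- which(pairable[i, ])
    ks <- ks[ks <= j]
    for (k in ks) {
      left <- enum(i + 1L, k - 1L)
      right <- enum(k + 1L, j)
      for (L in left) for (R in right) {
        out[[length(out) + 1L]] <- c(i, k, L, R)
      }
    }
    out
  }
  structs <- enum(1L, n)
  energies <- vapply(structs, function(p) {
    partner <- rep(NA_integer_, n)
    if (length(p) > 0) {
      ii <- p[seq(1, length(p), by = 2)]
      jj <- p[seq(2, length(p), by = 2)]
      partner[ii] <- jj
      partner[jj] <- ii
    }
    structure_energy(code, partner, model)
  }, numeric(1))
  best <- min(energies)
  opt <- structs[energies == best]
  dbs <- vapply(opt, function(p) {
    partner <- rep(NA_integer_, n)
    if (length(p) > 0) {
      ii <- p[seq(1, length(p), by = 2)]
      jj <- p[seq(2, length(p), by = 2)]
      partner[ii] <- jj
      partner[jj] <- ii
    }
    dotbracket_from_pairs(partner)
  }, character(1))
  list(energy = best, structures = unique(dbs))
}

#' Decompose a folded structure into loop elements
#'
#' Labels each position of a structure as part of a stem, hairpin loop,
#' bulge, internal loop, multiloop or the exterior, and (for single-hairpin
#' structures) reports the 5' arm, loop and 3' arm intervals.
#'
#' @param struct a `secondary_structure`.
#' @return list with `elements` (data.frame: type, start, end), `n_hairpins`,
#'   and, when the structure has exactly one hairpin loop, `arm5`, `loop`,
#'   `arm3` (integer c(start, end), 1-based inclusive) plus `pairs`.
#' @export
hairpin_decompose <- function(struct) {
  pairs <- struct$pairs
  n <- length(pairs)
  paired <- !is.na(pairs)
  enclosed <- rep(FALSE, n)
  opened <- which(paired & pairs > seq_len(n))
  for (i in opened) enclosed[(i + 1L):(pairs[i] - 1L)] <- TRUE

  labels <- rep("exterior", n)
  labels[paired] <- "stem"

  # classify every loop by its closing pair
  elements <- list()
  add_el <- function(type, start, end) {
    elements[[length(elements) + 1L]] <<- data.frame(
      type = type, start = start, end = end, stringsAsFactors = FALSE)
  }
  n_hairpins <- 0L
  for (i in opened) {
    j <- pairs[i]
    inner <- if (i + 1L <= j - 1L) (i + 1L):(j - 1L) else integer(0)
    kids_open <- inner[paired[inner] & pairs[inner] > inner &
                         pairs[inner] <= j]
    # direct children: opened pairs inside not nested under another child
    if (length(kids_open) > 1) {
      keep <- rep(TRUE, length(kids_open))
      for (a in seq_along(kids_open)) {
        for (b in seq_along(kids_open)) {
          if (a != b && kids_open[b] < kids_open[a] &&
              kids_open[a] < pairs[kids_open[b]]) keep[a] <- FALSE
        }
      }
      kids_open <- kids_open[keep]
    }
    unp <- inner[is.na(pairs[inner])]
    if (length(kids_open) > 0) {
      under_kid <- rep(FALSE, length(unp))
      for (k in kids_open) {
        under_kid <- under_kid | (unp > k & unp < pairs[k])
      }
      unp <- unp[!under_kid]
    }
    if (length(kids_open) == 0) {
      n_hairpins <- n_hairpins + 1L
      if (length(unp)) {
        labels[unp] <- "hairpin_loop"
        add_el("hairpin_loop", min(unp), max(unp))
      }
    } else if (length(kids_open) == 1) {
      k <- kids_open
      left <- unp[unp < k]
      right <- unp[unp > pairs[k]]
      if (length(left) > 0 && length(right) > 0) {
        labels[c(left, right)] <- "internal_loop"
        add_el("internal_loop", min(left), max(left))
        add_el("internal_loop", min(right), max(right))
      } else if (length(left) + length(right) > 0) {
        side <- c(left, right)
        labels[side] <- "bulge"
        add_el("bulge", min(side), max(side))
      }
    } else {
      if (length(unp)) labels[unp] <- "multiloop"
      if (length(unp)) add_el("multiloop", min(unp), max(unp))
    }
  }
  # stem runs and exterior runs as elements
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (q in seq_along(r$values)) {
    if (r$values[q] %in% c("stem", "exterior")) {
      add_el(r$values[q], starts[q], ends[q])
    }
  }
  elements <- do.call(rbind, elements)
  elements <- elements[order(elements$start), , drop = FALSE]
  rownames(elements) <- NULL

  out <- list(elements = elements, labels = labels, n_hairpins = n_hairpins,
              pairs = pairs)
  if (n_hairpins == 1L && any(paired)) {
    loop_pos <- which(labels == "hairpin_loop")
    if (length(loop_pos) == 0) { # zero-length loop impossible (min_loop>=3)
      loop_pos <- integer(0)
    }
    lstart <- min(loop_pos); lend <- max(loop_pos)
    p5 <- which(paired & seq_len(n) < lstart)
    p3 <- which(paired & seq_len(n) > lend)
    out$arm5 <- c(min(p5), max(p5))
    out$loop <- c(lstart, lend)
    out$arm3 <- c(min(p3), max(p3))
  }
  out
}

#' Single-hairpin test with mature-arm pairing requirement
#'
#' TRUE iff the structure (optionally restricted to `region`) contains
#' exactly one hairpin loop and, when a mature interval is supplied, at least
#' `min_paired_fraction` of the mature bases are paired.
#'
#' @param struct a `secondary_structure`.
#' @param mature optional integer c(start, end), 1-based inclusive, of the
#'   mature miRNA on the folded sequence.
#' @param min_paired_fraction minimum fraction of paired mature bases.
#' @param region optional integer c(start, end) restricting the hairpin-count
#'   to a subinterval (pairs with a partner outside the region count as
#'   unpaired context but loops are only counted inside).
#' @return logical flag.
#' @export
is_single_hairpin <- function(struct, mature = NULL,
                              min_paired_fraction = 0.5, region = NULL) {
  dec <- hairpin_decompose(struct)
  if (is.null(region)) {
    nh <- dec$n_hairpins
  } else {
    # count hairpin loops lying entirely inside the region; loops in the
    # flanking context (or straddling the boundary) fold independently and
    # do not disqualify the precursor
    loop_pos <- which(dec$labels == "hairpin_loop")
    nh <- 0L
    if (length(loop_pos) > 0) {
      grp <- cumsum(c(1L, as.integer(diff(loop_pos) > 1L)))
      for (g in unique(grp)) {
        lp <- loop_pos[grp == g]
        if (min(lp) >= region[1] && max(lp) <= region[2]) nh <- nh + 1L
      }
    }
  }
  if (nh != 1L) return(FALSE)
  if (!is.null(mature)) {
    idx <- mature[1]:mature[2]
    frac <- mean(!is.na(struct$pairs[idx]))
    if (frac < min_paired_fraction) return(FALSE)
  }
  TRUE
}

#' Write structures in dot-bracket text format
#'
#' One record per structure: a header line, the sequence line, then the
#' dot-bracket line with the energy in parentheses.
#'
#' @param structs list of `secondary_structure` objects (or a single one).
#' @param path output file path.
#' @param names optional record names.
#' @return invisibly, the path.
#' @export
write_dotbracket <- function(structs, path, names = NULL) {
  if (inherits(structs, "secondary_structure")) structs <- list(structs)
  if (is.null(names)) names <- paste0("structure_", seq_along(structs))
  lines <- unlist(lapply(seq_along(structs), function(i) {
    s <- structs[[i]]
    c(paste0(">", names[i]), s$sequence,
      paste0(s$dotbracket, " (", format(s$energy), ")"))
  }))
  writeLines(lines, path)
  invisible(path)
}
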