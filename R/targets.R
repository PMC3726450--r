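# miRNA target prediction on 3' UTRs: strict seed matching, intermolecular
# duplex hybridisation energy by dynamic programming, Gumbel-calibrated
# p-values, and the intersection of the two predictors.

#' Seed-match sites of a miRNA on a UTR
#'
#' Reports every UTR position where the reverse complement of miRNA
#' positions s..s+k-1 matches exactly, with k >= `min_seed` and the seed
#' starting at miRNA position 1 or 2. Seed pairs are strict Watson-Crick
#' (no G-U) unless `allow_gu`; overlapping matches are reported maximal
#' (not contained in a longer match with the same s).
#'
#' @param mirna mature miRNA sequence (5'->3').
#' @param utr UTR sequence (5'->3', DNA).
#' @param min_seed minimum seed length in nt.
#' @param allow_gu allow G-U wobbles in the seed.
#' @return data.frame: start, end (1-based on the UTR), k, s.
#' @export
seed_sites <- function(mirna, utr, min_seed = 7L, allow_gu = FALSE) {
  mirna <- as_dna(mirna)
  utr <- toupper(utr)
  mch <- strsplit(mirna, "", fixed = TRUE)[[1]]
  uch <- strsplit(utr, "", fixed = TRUE)[[1]]
  nm <- length(mch); nu <- length(uch)
  out <- list()
  pairs_ok <- function(mb, ub) {
    # miRNA base mb pairing UTR base ub (RNA rules on DNA letters)
    wc <- (mb == "A" & ub == "T") | (mb == "T" & ub == "A") |
      (mb == "G" & ub == "C") | (mb == "C" & ub == "G")
    if (!allow_gu) return(wc)
    wc | (mb == "G" & ub == "T") | (mb == "T" & ub == "G")
  }
  for (s in 1:2) {
    if (s + min_seed - 1L > nm) next
    core <- revcomp(subseq_chr(mirna, s, s + min_seed - 1L))
    starts <- integer(0)
    if (!allow_gu) {
      m <- gregexpr(core, utr, fixed = TRUE)[[1]]
      if (m[1] != -1) starts <- as.integer(m)
    } else {
      # wobble-tolerant core scan
      for (p in seq_len(nu - min_seed + 1L)) {
        ok <- all(pairs_ok(mch[s:(s + min_seed - 1L)],
                           uch[(p + min_seed - 1L):p]))
        if (ok) starts <- c(starts, p)
      }
    }
    for (p in starts) {
      # extend: site grows leftward on the UTR as k grows
      k <- min_seed
      end <- p + min_seed - 1L
      start <- p
      while (s + k <= nm && start - 1L >= 1L &&
             pairs_ok(mch[s + k], uch[start - 1L])) {
        k <- k + 1L
        start <- start - 1L
      }
      out[[length(out) + 1L]] <- data.frame(start = start, end = end,
                                            k = k, s = s)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0), k = integer(0),
                      s = integer(0)))
  df <- do.call(rbind, out)
  # keep maximal sites: drop those contained in a longer site with same s
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- df$s == df$s[i] & df$start <= df$start[i] &
      df$end >= df$end[i] & df$k > df$k[i]
    if (any(contained)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df <- df[!duplicated(df), , drop = FALSE]
  df[order(df$start, df$s), , drop = FALSE]
}

#' Brute-force seed-site oracle
#'
#' Direct enumeration of all (s, k, position) combinations; used to verify
#' [seed_sites()].
#' @inheritParams seed_sites
#' @return data.frame like [seed_sites()].
#' @export
seed_sites_brute <- function(mirna, utr, min_seed = 7L) {
  mirna <- as_dna(mirna)
  nm <- nchar(mirna); nu <- nchar(utr)
  hits <- list()
  for (s in 1:2) {
    for (k in min_seed:(nm - s + 1L)) {
      pat <- revcomp(subseq_chr(mirna, s, s + k - 1L))
      if (nchar(pat) > nu) next
      for (p in seq_len(nu - k + 1L)) {
        if (substring(utr, p, p + k - 1L) == pat) {
          hits[[length(hits) + 1L]] <- data.frame(start = p,
                                                  end = p + k - 1L,
                                                  k = k, s = s)
        }
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0), k = integer(0),
                      s = integer(0)))
  df <- do.call(rbind, hits)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (any(df$s == df$s[i] & df$start <= df$start[i] &
            df$end >= df$end[i] & df$k > df$k[i])) keep[i] <- FALSE
  }
  df <- unique(df[keep, , drop = FALSE])
  df[order(df$start, df$s), , drop = FALSE]
}

# duplex pair score between a miRNA base and a UTR base (hybridisation):
# returns the energy-model score of the RNA pair, 0 if unpairable
.duplex_score_matrix <- function(model) {
  # rows: miRNA base ACGU, cols: target base ACGU; hybridising pairs are
  # (A,U),(U,A),(G,C),(C,G),(G,U),(U,G)
  model$score_matrix
}

#' Intermolecular duplex minimum free energy
#'
#' Hybridisation-only dynamic programme: non-crossing intermolecular pairs
#' between the miRNA and a target window (antiparallel), no intramolecular
#' pairs, with `gap_penalty` per interior unpaired base on either strand.
#' Deterministic traceback (5'-most pairing preferred).
#'
#' @param mirna miRNA sequence (5'->3').
#' @param window target window (5'->3'), <= 50 nt.
#' @param model an [energy_model()].
#' @param gap_penalty energy cost per interior unpaired base on either
#'   strand. The default (4) makes interior loops dearer than the pairs
#'   they could buy, keeping predicted duplexes compact, as in full
#'   hybridisation thermodynamics.
#' @return list with `energy` and `duplex` (data.frame of paired positions:
#'   mirna_pos, window_pos).
#' @export
duplex_mfe <- function(mirna, window, model = energy_model(),
                       gap_penalty = 4L) {
  if (nchar(window) > 50) stop("window longer than 50 nt")
  mi <- encode_rna(as_rna(mirna))
  # antiparallel: index the window 3'->5'
  wr <- rev(encode_rna(as_rna(window)))
  n <- length(mi); m <- length(wr)
  S <- model$score_matrix
  P <- as.integer(gap_penalty)
  E <- matrix(0L, n, m) # best energy of a duplex ending with pair (i,j)
  back <- matrix(0L, n, m) # encoded predecessor (i' * (m+1) + j'), 0 = start
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- S[mi[i] + 1L, wr[j] + 1L]
      if (sc >= 0L) { E[i, j] <- 0L; next }
      best <- 0L; bb <- 0L
      if (i > 1L && j > 1L) {
        sub <- E[1:(i - 1L), 1:(j - 1L), drop = FALSE]
        gap <- outer((i - 1L) - (1:(i - 1L)), (j - 1L) - (1:(j - 1L)), "+")
        tot <- sub + P * gap
        k <- arrayInd(which.min(tot), dim(tot))
        if (tot[k] < 0L && E[k[1], k[2]] < 0L) {
          best <- tot[k[1], k[2]]
          bb <- k[1] * (m + 1L) + k[2]
        }
      }
      E[i, j] <- sc + best
      back[i, j] <- bb
    }
  }
  if (all(E >= 0L)) {
    return(list(energy = 0,
                duplex = data.frame(mirna_pos = integer(0),
                                    window_pos = integer(0))))
  }
  k <- arrayInd(which.min(E), dim(E))
  pairs <- list()
  i <- k[1]; j <- k[2]
  repeat {
    pairs[[length(pairs) + 1L]] <- c(i, j)
    b <- back[i, j]
    if (b == 0L) break
    i <- b %/% (m + 1L); j <- b %% (m + 1L)
  }
  pm <- do.call(rbind, rev(pairs))
  list(energy = as.numeric(min(E)),
       duplex = data.frame(mirna_pos = pm[, 1],
                           window_pos = m - pm[, 2] + 1L))
}

#' Brute-force intermolecular duplex oracle
#'
#' Enumerates all monotone non-crossing intermolecular pairings of two short
#' sequences and scores each directly (pair scores plus the gap penalty per
#' interior unpaired base on either strand). Exponential; both sequences
#' must be <= 10 nt.
#'
#' @inheritParams duplex_mfe
#' @return list with `energy`.
#' @export
duplex_mfe_brute <- function(mirna, window, model = energy_model(),
                             gap_penalty = 4L) {
  mi <- encode_rna(as_rna(mirna))
  wr <- rev(encode_rna(as_rna(window)))
  n <- length(mi); m <- length(wr)
  if (n > 10 || m > 10) stop("brute-force duplex limited to 10 nt")
  S <- model$score_matrix
  best <- 0
  enum <- function(i, j, pairs) {
    # score current pairing
    if (nrow(pairs) > 0) {
      sc <- sum(S[cbind(mi[pairs[, 1]] + 1L, wr[pairs[, 2]] + 1L)])
      interior <- (max(pairs[, 1]) - min(pairs[, 1]) + 1L - nrow(pairs)) +
        (max(pairs[, 2]) - min(pairs[, 2]) + 1L - nrow(pairs))
      best <<- min(best, sc + gap_penalty * interior)
    }
    if (i > n || j > m) return(invisible())
    for (ii in i:n) for (jj in j:m) {
      if (S[mi[ii] + 1L, wr[jj] + 1L] < 0L) {
        enum(ii + 1L, jj + 1L, rbind(pairs, c(ii, jj)))
      }
    }
    invisible()
  }
  enum(1L, 1L, matrix(integer(0), 0, 2))
  list(energy = best)
}

#' Best duplex energy of a miRNA against a whole UTR
#'
#' Row-vectorised O(nm) version of the duplex DP (energies only), used for
#' whole-UTR scans and null-score calibration. Also reports the UTR
#' interval of the best duplex via a bounded re-run of [duplex_mfe()].
#'
#' @param mirna miRNA sequence.
#' @param utr UTR sequence.
#' @param model an [energy_model()].
#' @param locate when TRUE, also return the best-site UTR interval.
#' @return list with `energy` and (when `locate`) `start`, `end`.
#' @export
best_duplex_energy <- function(mirna, utr, model = energy_model(),
                               gap_penalty = 4L, locate = FALSE) {
  mi <- encode_rna(as_rna(mirna))
  wr <- rev(encode_rna(as_rna(utr)))
  n <- length(mi); m <- length(wr)
  S <- model$score_matrix
  P <- as.numeric(gap_penalty)
  sc_rows <- lapply(seq_len(n), function(i) S[mi[i] + 1L, wr + 1L])
  G_prev <- rep(Inf, m) # min over i'<=i, j'<=j of E[i',j'] - P*(i' + j')
  Emin <- 0; Eargmin <- c(NA_integer_, NA_integer_)
  for (i in seq_len(n)) {
    sc <- sc_rows[[i]]
    ext <- c(Inf, G_prev[-m]) + P * (i + seq_len(m) - 2)
    Ei <- sc + pmin(0, ext)
    Ei[sc >= 0] <- 0
    rowmin <- min(Ei)
    if (rowmin < Emin) {
      Emin <- rowmin
      Eargmin <- c(i, which.min(Ei))
    }
    G_prev <- cummin(pmin(G_prev, Ei - P * (i + seq_len(m))))
  }
  out <- list(energy = as.numeric(Emin))
  if (locate && !is.na(Eargmin[1])) {
    # the chain's last pair (minimum cell) joins the miRNA 3' side to the
    # 5'-most UTR position of the site; re-run the windowed DP rightward
    site_start <- m - Eargmin[2] + 1L
    win_lo <- max(1L, site_start - 5L)
    win_hi <- min(m, win_lo + 49L)
    dm <- duplex_mfe(mirna, subseq_chr(utr, win_lo, win_hi), model,
                     gap_penalty = gap_penalty)
    if (nrow(dm$duplex) > 0) {
      out$start <- win_lo + min(dm$duplex$window_pos) - 1L
      out$end <- win_lo + max(dm$duplex$window_pos) - 1L
    } else {
      out$start <- site_start; out$end <- site_start
    }
  }
  out
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location xi and scale theta of a Gumbel (type-I extreme value)
#' distribution by maximising the log-likelihood with [stats::optim()],
#' initialised from moment estimates.
#'
#' @param x numeric sample.
#' @return list with `xi`, `theta`, `convergence`.
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  if (stats::sd(x) < 1e-12) stop("degenerate sample: constant scores")
  theta0 <- stats::sd(x) * sqrt(6) / pi
  xi0 <- mean(x) - 0.5772156649 * theta0
  nll <- function(par) {
    th <- exp(par[2])
    z <- (x - par[1]) / th
    sum(log(th) + z + exp(-z))
  }
  fit <- stats::optim(c(xi0, log(theta0)), nll, method = "BFGS")
  list(xi = fit$par[1], theta = exp(fit$par[2]),
       convergence = fit$convergence)
}

#' Extreme-value parameters for duplex-score calibration
#'
#' Either the published defaults for the salmon transcriptome
#' (xi = 2.327203, theta = 0.216961, derived from dinucleotide frequencies)
#' or a fresh calibration via [calibrate_evd()].
#'
#' @param xi,theta Gumbel location and scale.
#' @param source provenance label.
#' @return `evd_params` list.
#' @export
evd_params <- function(xi = 2.327203, theta = 0.216961,
                       source = "paper_default") {
  stopifnot(theta > 0)
  structure(list(xi = xi, theta = theta, source = source),
            class = "evd_params")
}

#' Calibrate the extreme-value law of null duplex scores
#'
#' Generates `n_shuffles` synthetic UTRs from the first-order (dinucleotide)
#' Markov model of the input UTR set, computes each one's best duplex score
#' against the miRNA (negated, log-length-normalised) and fits a Gumbel law
#' by maximum likelihood.
#'
#' @param utrs character vector of UTR sequences (the background model
#'   source).
#' @param mirna miRNA sequence.
#' @param n_shuffles number of synthetic UTRs (>= 30).
#' @param seed RNG seed.
#' @param model an [energy_model()].
#' @return `evd_params` with source "calibrated".
#' @export
calibrate_evd <- function(utrs, mirna, n_shuffles = 500L, seed = 1L,
                          model = energy_model(), gap_penalty = 4L) {
  if (n_shuffles < 30L) stop("n_shuffles < 30: fit would be unstable")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 6L))
  trans <- dinucleotide_transitions(utrs)
  lens <- nchar(utrs)
  scores <- vapply(seq_len(n_shuffles), function(i) {
    L <- sample(lens, 1)
    bg <- markov_seq(L, trans)
    e <- best_duplex_energy(mirna, bg, model,
                            gap_penalty = gap_penalty)$energy
    -e / log(L)
  }, numeric(1))
  fit <- fit_gumbel(scores)
  evd_params(fit$xi, fit$theta, source = "calibrated")
}

#' P-value of a duplex energy under the calibrated extreme-value law
#'
#' The site score is x = -energy / log(utr_length); its null tail
#' probability is P = 1 - exp(-exp(-(x - xi)/theta)). P increases with
#' energy: weaker (less negative) duplexes get larger p-values.
#'
#' @param energy duplex energy (model units, <= 0 for reported sites).
#' @param utr_length length of the scanned UTR.
#' @param evd an [evd_params()].
#' @return p-value in (0, 1).
#' @export
site_pvalue <- function(energy, utr_length, evd = evd_params()) {
  x <- -energy / log(utr_length)
  1 - exp(-exp(-(x - evd$xi) / evd$theta))
}

#' Intersect seed-based and energy-based target predictions
#'
#' A site is supported by "both" iff a seed site and a significant energy
#' site for the same miRNA overlap on the same UTR by at least
#' `min_overlap` nt; the final gene-level call set is the UTRs with at
#' least one "both" site.
#'
#' @param seed_hits data.frame: mirna_id, utr_id, start, end (seed sites).
#' @param energy_hits data.frame: mirna_id, utr_id, start, end, energy,
#'   p_value (energy sites, already thresholded).
#' @param min_overlap minimum overlap in nt.
#' @return data.frame of intersected sites with `supported_by = "both"`.
#' @export
intersect_predictions <- function(seed_hits, energy_hits, min_overlap = 1L) {
  empty <- data.frame(mirna_id = character(0), utr_id = character(0),
                      start = integer(0), end = integer(0),
                      energy = numeric(0), p_value = numeric(0),
                      supported_by = character(0))
  if (nrow(seed_hits) == 0 || nrow(energy_hits) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(seed_hits))) {
    sh <- seed_hits[i, ]
    cand <- energy_hits[energy_hits$mirna_id == sh$mirna_id &
                          energy_hits$utr_id == sh$utr_id, , drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- pmin(cand$end, sh$end) - pmax(cand$start, sh$start) + 1L
    hit <- which(ov >= min_overlap)
    if (length(hit) == 0) next
    j <- hit[which.min(cand$p_value[hit])]
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = sh$mirna_id, utr_id = sh$utr_id,
      start = min(sh$start, cand$start[j]), end = max(sh$end, cand$end[j]),
      energy = cand$energy[j], p_value = cand$p_value[j],
      supported_by = "both", stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  unique(do.call(rbind, out))
}

#' Predict targets of a miRNA set on a UTR set
#'
#' Runs the seed predictor and the duplex-energy predictor (whole-UTR best
#' site, Gumbel p-value) for every miRNA x UTR pair and intersects them.
#'
#' @param mirnas named character vector of mature sequences.
#' @param utrs named character vector of UTR sequences.
#' @param evd an [evd_params()]; when NULL, calibrated per miRNA from the
#'   UTR set.
#' @param p_max p-value threshold for energy sites.
#' @param min_seed minimum seed length.
#' @param model an [energy_model()].
#' @param n_shuffles,seed calibration controls (used when `evd` is NULL).
#' @return list with `sites` (the "both" call set), `seed_hits`,
#'   `energy_hits`, `evd`.
#' @export
predict_targets <- function(mirnas, utrs, evd = NULL, p_max = 0.05,
                            min_seed = 7L, model = energy_model(),
                            gap_penalty = 4L, n_shuffles = 200L,
                            seed = 1L) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(utrs)))
  seed_rows <- list(); energy_rows <- list()
  evds <- list()
  for (mi in names(mirnas)) {
    evd_mi <- if (is.null(evd)) {
      calibrate_evd(utrs, mirnas[[mi]], n_shuffles = n_shuffles,
                    seed = seed, model = model, gap_penalty = gap_penalty)
    } else evd
    evds[[mi]] <- evd_mi
    for (ui in names(utrs)) {
      ss <- seed_sites(mirnas[[mi]], utrs[[ui]], min_seed = min_seed)
      if (nrow(ss) > 0) {
        seed_rows[[length(seed_rows) + 1L]] <- data.frame(
          mirna_id = mi, utr_id = ui, start = ss$start, end = ss$end,
          k = ss$k, s = ss$s, stringsAsFactors = FALSE)
      }
      bd <- best_duplex_energy(mirnas[[mi]], utrs[[ui]], model,
                               gap_penalty = gap_penalty, locate = TRUE)
      if (bd$energy < 0) {
        p <- site_pvalue(bd$energy, nchar(utrs[[ui]]), evd_mi)
        if (p <= p_max) {
          energy_rows[[length(energy_rows) + 1L]] <- data.frame(
            mirna_id = mi, utr_id = ui, start = bd$start, end = bd$end,
            energy = bd$energy, p_value = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  seed_hits <- if (length(seed_rows)) do.call(rbind, seed_rows) else
    data.frame(mirna_id = character(0), utr_id = character(0),
               start = integer(0), end = integer(0), k = integer(0),
               s = integer(0))
  energy_hits <- if (length(energy_rows)) do.call(rbind, energy_rows) else
    data.frame(mirna_id = character(0), utr_id = character(0),
               start = integer(0), end = integer(0), energy = numeric(0),
               p_value = numeric(0))
  sites <- intersect_predictions(seed_hits, energy_hits)
  list(sites = sites, seed_hits = seed_hits, energy_hits = energy_hits,
       evd = evds)
}
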