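# End-to-end orchestration: configuration handling, the discovery pipeline
# from FASTQ to catalogue/family/target tables, output writers and the run
# ledger.

#' Pipeline configuration
#'
#' Materialises every stage default into one validated list; unknown keys
#' are rejected. The effective configuration is dumped into the run
#' directory by [run_all()].
#'
#' @param ... overrides for any of the defaults (see the function body for
#'   the full set: simulation config, preprocessing thresholds, discovery
#'   parameters, homology/e-value settings, target-prediction controls,
#'   paths and seed).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = sim_config(),
    min_q = 20L, max_n = 0L, adapter = TRUSEQ_ADAPTER, min_overlap = 5L,
    window_lo = 16L, window_hi = 28L,
    max_hits = 20L, merge_gap = 30L, flank = 70L,
    min_reads = 2L, min_per_sample = 10, gate_mode = "mean",
    min_five_prime_consistency = 0.66, min_paired_fraction = 0.5,
    require_star_reads = FALSE,
    dust_t = 2.0, tandem_max = 0.8,
    e_max = 0.5, match = 1L, mismatch = -3L, K = 0.711, lambda = 1.374,
    species_prefix = "ssa",
    p_max = 0.05, min_seed = 7L, duplex_gap_penalty = 4L,
    n_shuffles = 200L,
    n_perm = 10000L,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  class(defaults) <- "pipeline_config"
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] (a `sim`
#'   block maps to [sim_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the full discovery pipeline
#'
#' Simulation (unless inputs are supplied) -> preprocessing -> mapping and
#' locus building -> annotation criteria -> homology classification ->
#' family statistics -> target prediction, writing the catalogue (GFF3,
#' FASTA, TSV), the family table, the target table and a JSON stats ledger
#' into `out_dir`. Counts at every gate are recorded so the discovery
#' funnel is reproducible.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @param sim optional pre-built [simulate_genome()] output; when NULL a
#'   simulation is generated from `config$sim`.
#' @param mirbase_set,omy_set optional named reference sets for homology
#'   classification; when NULL a synthetic reference is generated.
#' @param utrs optional named UTR set for target prediction; when NULL a
#'   transcriptome is simulated (with planted sites).
#' @return list with `catalogue`, `families`, `family_table`, `targets`,
#'   `ledger`, `spearman`, `truth`, `paths`.
#' @export
run_all <- function(config = pipeline_config(), out_dir,
                    sim = NULL, mirbase_set = NULL, omy_set = NULL,
                    utrs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$sim
  if (is.null(sim)) sim <- simulate_genome(cfg, out_dir = out_dir)
  reads <- simulate_reads(sim, cfg, file.path(out_dir, "reads"))
  pp <- preprocess_run(reads$manifest, min_q = config$min_q,
                       max_n = config$max_n, adapter = config$adapter,
                       min_overlap = config$min_overlap,
                       lo = config$window_lo, hi = config$window_hi)
  index <- index_genome(sim$genome)
  params <- discovery_params(
    min_reads = config$min_reads, min_per_sample = config$min_per_sample,
    gate_mode = config$gate_mode,
    min_five_prime_consistency = config$min_five_prime_consistency,
    min_paired_fraction = config$min_paired_fraction,
    require_star_reads = config$require_star_reads, flank = config$flank,
    dust_t = config$dust_t, tandem_max = config$tandem_max)
  disc <- discover_mirnas(pp$collapsed, index, sim$annotation, params,
                          max_hits = config$max_hits,
                          merge_gap = config$merge_gap)

  if (is.null(mirbase_set))
    mirbase_set <- simulate_reference(sim, seed = cfg$seed)
  cls <- lapply(disc$genes, function(g)
    classify(g$mature_seq, mirbase_set, omy_set, e_max = config$e_max,
             match = config$match, mismatch = config$mismatch,
             K = config$K, lambda = config$lambda))
  catalogue <- assign_names(disc$genes, cls, prefix = config$species_prefix)

  matures <- vapply(catalogue, `[[`, character(1), "mature_seq")
  hints <- vapply(catalogue, function(g)
    if (is.null(g$family_hint)) NA_character_ else g$family_hint,
    character(1))
  clusters <- cluster_families(matures, hints)
  fam_table <- family_abundance(catalogue, clusters)
  dup <- find_duplicates(vapply(catalogue, `[[`, character(1), "pri_seq"))
  sp <- if (nrow(fam_table) >= 3) {
    spearman_perm(fam_table$copy_number, fam_table$abundance,
                  n_perm = config$n_perm, seed = config$seed)
  } else NULL

  if (is.null(utrs)) {
    tx <- simulate_transcriptome(sim, cfg, out_dir = out_dir)
    utrs <- tx$utrs
  }
  mir_set <- stats::setNames(matures, vapply(catalogue, `[[`, character(1),
                                             "gene_id"))
  mir_set <- mir_set[!duplicated(matures)]
  tg <- predict_targets(mir_set, utrs, p_max = config$p_max,
                        min_seed = config$min_seed,
                        gap_penalty = config$duplex_gap_penalty,
                        n_shuffles = config$n_shuffles, seed = config$seed)

  n_cons <- sum(vapply(catalogue, function(g)
    g$classification != "novel", logical(1)))
  ledger <- c(pp$ledger, disc$ledger,
              conserved_genes = n_cons,
              novel_genes = length(catalogue) - n_cons,
              duplicate_pairs = dup$n_pairs,
              families = nrow(fam_table),
              target_sites_both = nrow(tg$sites),
              target_utrs = length(unique(tg$sites$utr_id)))

  paths <- write_run_outputs(out_dir, config, catalogue, fam_table, tg,
                             ledger, sp)
  list(catalogue = catalogue, families = clusters,
       family_table = fam_table, targets = tg, ledger = ledger,
       spearman = sp, duplicates = dup, truth = sim$truth,
       collapsed = pp$collapsed, paths = paths)
}

#' Write catalogue, family and target outputs of a run
#'
#' @param out_dir run directory.
#' @param config the effective [pipeline_config()].
#' @param catalogue named gene records.
#' @param fam_table family table from [family_abundance()].
#' @param tg target predictions from [predict_targets()].
#' @param ledger named numeric funnel ledger.
#' @param sp Spearman result or NULL.
#' @return named list of file paths.
#' @export
write_run_outputs <- function(out_dir, config, catalogue, fam_table, tg,
                              ledger, sp = NULL) {
  paths <- list()
  # GFF3 with Parent links
  if (length(catalogue) > 0) {
    feats <- list()
    for (g in catalogue) {
      id <- g$gene_id
      feats[[length(feats) + 1L]] <- data.frame(
        type = c("miRNA_primary_transcript", "miRNA_precursor", "miRNA",
                 "miRNA_star"),
        start = c(g$pri[1], g$pre[1], g$mature[1], g$star[1]),
        end = c(g$pri[2], g$pre[2], g$mature[2], g$star[2]),
        ID = paste0(id, c("", ".pre", ".mature", ".star")),
        Parent = c(NA, id, paste0(id, ".pre"), paste0(id, ".pre")),
        Name = c(id, paste0(id, ".pre"), g$name, paste0(g$name, "*")),
        chrom = g$chrom, strand = g$strand, stringsAsFactors = FALSE)
    }
    fd <- do.call(rbind, feats)
    gr <- GenomicRanges::GRanges(fd$chrom,
                                 IRanges::IRanges(fd$start, fd$end),
                                 strand = fd$strand, type = fd$type,
                                 ID = fd$ID, Name = fd$Name,
                                 Parent = fd$Parent)
    paths$gff3 <- file.path(out_dir, "catalogue.gff3")
    suppressWarnings(rtracklayer::export(gr, paths$gff3, format = "GFF3"))
    # FASTA of pri/pre/mature
    for (what in c("pri", "pre", "mature")) {
      ss <- Biostrings::DNAStringSet(vapply(catalogue, `[[`, character(1),
                                            paste0(what, "_seq")))
      names(ss) <- vapply(catalogue, `[[`, character(1), "gene_id")
      paths[[paste0(what, "_fasta")]] <-
        file.path(out_dir, paste0(what, ".fa"))
      Biostrings::writeXStringSet(ss, paths[[paste0(what, "_fasta")]])
    }
    # catalogue TSV with dot-bracket structure
    cat_df <- do.call(rbind, lapply(catalogue, function(g) data.frame(
      gene_id = g$gene_id, name = g$name, chrom = g$chrom,
      strand = g$strand, pri_start = g$pri[1], pri_end = g$pri[2],
      pre_start = g$pre[1], pre_end = g$pre[2],
      mature_start = g$mature[1], mature_end = g$mature[2],
      star_start = g$star[1], star_end = g$star[2],
      classification = g$classification,
      homology_subject = g$homology_subject,
      homology_evalue = g$homology_evalue,
      mature_total = sum(g$mature_counts),
      star_total = sum(g$star_counts),
      five_prime_consistency = g$five_prime_consistency,
      mature_seq = g$mature_seq, pri_seq = g$pri_seq,
      structure = g$dotbracket, energy = g$energy,
      stringsAsFactors = FALSE)))
    paths$catalogue <- file.path(out_dir, "catalogue.tsv")
    utils::write.table(cat_df, paths$catalogue, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths$families <- file.path(out_dir, "families.tsv")
  utils::write.table(fam_table, paths$families, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$targets <- file.path(out_dir, "targets.tsv")
  utils::write.table(tg$sites, paths$targets, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stats <- list(ledger = as.list(ledger))
  if (!is.null(sp)) stats$spearman <- sp
  paths$ledger <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats, paths$ledger, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$config <- file.path(out_dir, "config.yaml")
  cfg_dump <- config
  cfg_dump$sim <- unclass(cfg_dump$sim)
  yaml::write_yaml(unclass(cfg_dump), paths$config)
  paths
}

#' Recompute headline repertoire statistics from supplementary-style tables
#'
#' Consumes two CSV tables of a published repertoire — a catalogue table
#' (names, mature and pri sequences, structures, locations) and a family
#' table (gene copy number and relative abundance) — and recomputes: the
#' number of identical pri duplicate pairs, the copy-number/abundance
#' Spearman rho, the combined abundance share of the top 3 families, the
#' miR-181 family share, and the let-7 copy number. Column names are
#' matched case-insensitively by pattern.
#'
#' @param s2_csv catalogue CSV (must contain a pri-sequence column; a
#'   family/name column is used for family labels when present).
#' @param s3_csv family CSV (family name, gene copy number, relative
#'   abundance columns).
#' @param n_perm permutations for the Spearman p-value.
#' @param seed RNG seed.
#' @return list with `duplicate_pairs`, `spearman_rho`, `spearman_p`,
#'   `top3_share`, `mir181_share`, `let7_copies`.
#' @export
repro_supplementary <- function(s2_csv, s3_csv, n_perm = 10000L,
                                seed = 1L) {
  find_col <- function(df, patterns) {
    for (p in patterns) {
      hit <- grep(p, names(df), ignore.case = TRUE)
      if (length(hit) > 0) return(names(df)[hit[1]])
    }
    NULL
  }
  out <- list(duplicate_pairs = NA_integer_, spearman_rho = NA_real_,
              spearman_p = NA_real_, top3_share = NA_real_,
              mir181_share = NA_real_, let7_copies = NA_integer_)
  if (!is.null(s2_csv) && file.exists(s2_csv)) {
    s2 <- utils::read.csv(s2_csv, stringsAsFactors = FALSE)
    pri_col <- find_col(s2, c("pri.*seq", "precursor.*seq", "^pri"))
    if (!is.null(pri_col)) {
      out$duplicate_pairs <- find_duplicates(toupper(s2[[pri_col]]))$n_pairs
    }
  }
  if (!is.null(s3_csv) && file.exists(s3_csv)) {
    s3 <- utils::read.csv(s3_csv, stringsAsFactors = FALSE)
    fam_col <- find_col(s3, c("famil", "^name"))
    cn_col <- find_col(s3, c("copy", "gene.*number", "count"))
    ab_col <- find_col(s3, c("relative", "abundance", "expression"))
    if (!is.null(cn_col) && !is.null(ab_col)) {
      cn <- as.numeric(s3[[cn_col]])
      ab <- as.numeric(s3[[ab_col]])
      sp <- spearman_perm(cn, ab, n_perm = n_perm, seed = seed)
      out$spearman_rho <- sp$rho
      out$spearman_p <- sp$p_value
      rel <- ab / sum(ab)
      out$top3_share <- sum(sort(rel, decreasing = TRUE)[1:3]) * 100
      if (!is.null(fam_col)) {
        fam <- s3[[fam_col]]
        m181 <- grepl("mir-?181", fam, ignore.case = TRUE)
        if (any(m181)) out$mir181_share <- sum(rel[m181]) * 100
        let7 <- grepl("let-?7", fam, ignore.case = TRUE)
        if (any(let7)) out$let7_copies <- as.integer(sum(cn[let7]))
      }
    }
  }
  out
}
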