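# smoltmir

An R package implementing an end-to-end small RNA-seq miRNA discovery
pipeline for salmonid-style genomes: from paired-end FASTQ reads to a
validated catalogue of pri/pre/mature/star miRNA records, family
copy-number and abundance statistics, and predicted 3' UTR target sites —
with a synthetic-data generator that provides exact ground truth for every
stage.

## Who this is for

Researchers building or auditing miRNA repertoires from deep-sequencing
data who want every step of the standard discovery procedure available as
testable, deterministic functions rather than a chain of external tools:
read preprocessing, exact genome mapping, hairpin folding, the
deep-sequencing annotation criteria (Dicer 2-nt 3' overhang, 5'-processing
consistency, 65-nt precursor minimum, expression gate, repeat masking),
homology classification, family statistics and seed+energy target
prediction.

## The models at the core

* **Folding.** A dynamic programme over nested secondary structures with
  base-pair scores (GC −3, AU −2, GU −1), minimum loop 3 and a +1 penalty
  per stem-interrupting unpaired base. An exhaustive enumeration oracle
  (`brute_force_fold`) verifies the DP exactly on short sequences.
* **Annotation.** Mature = most abundant read of a locus; star placed by
  Dicer geometry from the pair map (both 3' ends overhang their partner's
  duplex by exactly 2 nt); precursor bounded by the first bulge outward of
  the mature, with a 65-nt minimum; gates for expression (mean ≥ 10 reads
  per sample), annotation overlap, and DUST/tandem low complexity.
* **Homology.** Exhaustive ungapped local alignment (+1/−3) with
  Karlin–Altschul expectation E = K·m·n·e^(−λS) (K = 0.711, λ = 1.374);
  classification threshold E < 0.5.
* **Targets.** Strict seed rule (revcomp of miRNA positions s..s+k−1,
  k ≥ 7, s ∈ {1,2}) intersected with an intermolecular duplex-energy
  predictor; energies are converted to p-values by a Gumbel law
  p = 1 − exp(−exp(−(x − ξ)/θ)) on the normalised score x = −E/ln L, with
  published defaults ξ = 2.327203, θ = 0.216961 or maximum-likelihood
  calibration from dinucleotide-shuffled UTRs.

## Worked example

```r
library(smoltmir)

cfg <- pipeline_config(sim = sim_config(
  n_mirna_genes = 6, n_families = 4, reads_per_sample = 2500,
  n_samples = 4, genome_length = 25000, utr_count = 10, seed = 71),
  n_shuffles = 60, n_perm = 500)
res <- run_all(cfg, out_dir = "demo_run")
res$ledger
```

```
         input_pairs           reconciled         post_quality
               10000                10000                10000
    unique_sequences   windowed_sequences       windowed_reads
                  61                   61                10000
      candidate_loci    post_read_support post_expression_gate
                  10                   10                    6
           post_mask      post_complexity          final_genes
                   6                    6                    6
     conserved_genes          novel_genes      duplicate_pairs
                   4                    2                    0
            families    target_sites_both          target_utrs
                   4                   15                   10
```

Reading the funnel: 10,000 simulated read pairs collapse to 61 unique
16–28-nt sequences which map into 10 candidate loci; the four decoy loci
fall below the 10-reads-per-sample expression gate, and the 6 planted
genes survive every structural criterion. Four are classified conserved
against the synthetic reference set, and target prediction calls 15
doubly-supported (seed ∩ energy) sites across the 10 simulated UTRs —
including the planted ones.

```r
res$catalogue[[1]]$name          # e.g. "ssa-miR-101-5p"
mfe_fold("GGGAAACCC")            # (((...)))  (-9)
```

Run directories contain `catalogue.gff3` (miRNA_primary_transcript /
miRNA_precursor / miRNA / miRNA_star features with Parent links),
`catalogue.tsv` with dot-bracket structures, `pri/pre/mature.fa`,
`families.tsv`, `targets.tsv`, `stats.json` (the funnel ledger) and the
effective `config.yaml`.

A thin command-line wrapper ships in `inst/scripts/smolt-mir`
(`simulate`, `run-all`, `repro-supplementary` subcommands).

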