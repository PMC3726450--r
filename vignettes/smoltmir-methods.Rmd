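---
title: "smoltmir: models and methods of the miRNA discovery pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smoltmir: models and methods of the miRNA discovery pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoltmir)
```

# Overview

`smoltmir` re-implements, as one tested pipeline, the procedure used to
build a salmonid miRNA repertoire from small RNA sequencing: paired 37-nt
reads are reconciled, filtered, adapter-trimmed and collapsed into unique
sequences with per-sample counts; 16–28-nt sequences are exactly mapped to
the genome; read pileups are clustered into loci; each locus is folded and
judged against the community annotation criteria for deep-sequencing miRNA
discovery (read support, hairpin topology, no overlap with annotated
transcripts, 5'-processing consistency, and the Dicer duplex with its 2-nt
3' overhangs); accepted genes are classified against reference mature sets
by ungapped alignment with Karlin–Altschul statistics, clustered into
families and quantified; finally, targets are predicted on 3' UTRs by a
strict seed rule intersected with a hybridisation-energy predictor whose
scores are converted to p-values through a Gumbel (extreme-value) law.

Every stage has a synthetic ground-truth counterpart: `simulate_genome()`
plants hairpin genes (including identical duplicate copies and multi-copy
families) and decoy loci in a toy genome, `simulate_reads()` emits the
18-sample paired-end read pileups, and `simulate_transcriptome()` plants
seed-complementary target sites in Markov-background UTRs. The generator's
output is the reference against which recall, precision, boundary accuracy
and target sensitivity are measured in the test suite.

# The folding model

Secondary structure is predicted by a dynamic programme over nested
structures with a deliberately simple energy model (`energy_model()`):

* pair scores: GC/CG −3, AU/UA −2, GU/UG −1;
* minimum hairpin loop of 3 nt (a pair *(i, j)* requires *j − i − 1 ≥ 3*);
* a penalty of +1 for every unpaired base that interrupts a stem — that is,
  a base whose closest enclosing pair also encloses at least one other pair
  (bulges, internal loops, multibranch loops). Hairpin-loop bases and
  exterior bases are free.

This is not the Turner nearest-neighbour model, on purpose. The pipeline
needs two things from a folder: hairpin **topology** (is there a single
stem-loop, where are the bulges?) and **relative** stem stability. Both are
preserved by the base-pair-level model, and it admits a small exhaustive
oracle: `brute_force_fold()` enumerates *every* valid nested structure of a
short sequence and scores each directly from the model definition, so the
DP can be checked against an independent enumeration (500 random sequences
in the test suite agree exactly). Co-optimal structures are resolved by a
deterministic traceback that prefers pairing the 5'-most base with the
smallest partner, so folds are reproducible across runs.

Because the model maximises pairing aggressively, random flanking genomic
sequence folds into incidental small stems. The annotation stage therefore
judges hairpin topology on the bulge-bounded precursor interval rather
than the whole extracted window, and folds two candidate windows per locus
(mature on the 5' arm or on the 3' arm), keeping the better-scoring valid
candidate.

# Annotation criteria

A locus is accepted as a miRNA gene when, in funnel order:

1. it has at least 2 reads (criterion 1: multiple reads);
2. the mature read passes the expression gate — by default **mean** count
   per sample ≥ 10, i.e. total ≥ 10 × *n* samples. The source criterion
   ("10 read count per samples") is ambiguous between mean-per-sample and
   in-every-sample; both are implemented (`gate_mode = "mean"` /
   `"all_samples"`) and the mean reading is the default. The boundary is
   inclusive: a mean of exactly 10.0 is kept, 179 reads over 18 samples
   (mean 9.94) is removed;
3. its pri interval overlaps no annotated transcript or repeat
   (BED annotation, ≥ 1 nt overlap on either strand rejects);
4. its sequence passes a DUST-style triplet complexity score (threshold
   2.0) and a tandem-periodicity scan (no period ≤ 6 covering > 80% of the
   sequence) — this stands in for library-based repeat masking, which
   needs curated repeat libraries out of scope here;
5. the count-weighted fraction of reads sharing the modal 5' end is
   ≥ 0.66 (criterion 4; the source states the criterion but no number —
   two thirds is our choice, meaning the modal 5' end must dominate all
   alternatives combined);
6. the candidate window folds into a single stem-loop whose precursor
   contains the mature with ≥ 50% of its bases paired (criterion 2), a
   star can be placed by Dicer geometry, and the mature/star duplex shows
   **exact** 2-nt 3' overhangs on both strands (criterion 5's geometric
   half). Star-*read* support is recorded but not required by default
   (`require_star_reads = FALSE`), because the star strand is usually
   degraded in vivo; the geometry is always enforced.

The precursor is defined from the pair map: walking outward from the
mature's outer end, the boundary is the last stem position before the
first bulge or internal loop, and the other boundary is its pairing
partner. If the bulge-bounded interval is shorter than 65 nt it is
extended along the stem to 65 nt unless the next bulge is reached first;
with no bulge at all the 65-nt minimum applies directly (full stem if the
stem is shorter). Accepted genes report whether the minimum-length rule
was used.

Two windowing details matter for robustness. First, each locus is folded
in up to four candidate windows — mature on either arm, at a generous and
at a tighter margin — because the aggressive pairing of the simplified
model occasionally lets a long flanking context "capture" stem bases and
destroy the hairpin call that a tighter window recovers. Second, once a
candidate is accepted, its boundaries are **refined** by re-folding a
context-limited window (the precursor ± the pri margin): the final
annotation then depends only on the local hairpin, not on however much
flanking genome the locus happened to drag in. This also guarantees that
identical duplicated gene copies, which sit in different genomic
neighbourhoods, receive identical pri/pre annotations — without it,
duplicate-pair counts undercount whenever a boundary shifts by a few
nucleotides between copies.

Coordinates are 1-based inclusive internally (the R/Bioconductor
convention used by `GRanges` and `Biostrings`); BED output is written
through `rtracklayer`, which performs the 0-based half-open conversion,
and GFF3 is 1-based as the format requires.

# Homology and naming

Mature sequences (≤ 28 nt) are compared to reference sets by exhaustive
ungapped local alignment — every diagonal of both query orientations —
with +1/−3 match/mismatch scores. For such short sequences this is exact
and fast, so no word seeding is needed; as a consequence E-values are
computed from the ungapped Karlin–Altschul formula *E = K·m·n·e^(−λS)*
(K = 0.711, λ = 1.374, the standard ungapped DNA values) rather than
BLASTN's internals. The classification threshold E < 0.5 retains the
semantic of the original analysis, with the caveat that the numeric
E-values differ from BLASTN's. Precedence is fixed: miRBase-style set
first, then the species-specific set, else novel. Conserved genes inherit
the family core of their best hit with an arm suffix taken from which
precursor arm holds the mature; novel genes are numbered in discovery
order; identical duplicates share the mature name with suffixed gene ids.

# Families and the copy-number/abundance association

Family clustering is a documented stand-in for curated family databases:
two matures link when their seed regions (positions 2–8) are identical and
their full-length Hamming distance (best offset −1/0/+1) is at most 3;
single-linkage closure defines the family, and homology-derived names take
precedence for labelling. Abundance sums mature counts over members with
identical duplicate matures counted once (their reads are the same reads).
The copy-number/abundance association uses Spearman's rho on midranks with
a permutation p-value (10,000 permutations by default) rather than the
asymptotic approximation, because family counts are small in synthetic
runs.

# Target prediction

Two predictors are intersected, mirroring a two-tool consensus design:

* **Seed rule**: all UTR positions where the reverse complement of miRNA
  positions *s..s+k−1* matches exactly, *k ≥ 7*, *s ∈ {1, 2}*, strict
  Watson–Crick in the seed (a `--allow-gu` style flag exists but G·U is
  excluded by default). Maximal matches are reported.
* **Hybridisation energy**: the best intermolecular duplex between the
  miRNA and the UTR under the pair scores above, non-crossing and
  antiparallel, with a penalty per interior unpaired base on either
  strand, computed by an O(nm) dynamic programme with an exhaustive
  enumeration oracle for short inputs.

The interior-gap penalty defaults to **4** per base. This constant was
chosen after measurement, and the reasoning is worth recording: with the
pair scores at −2/−3 and a +1 gap cost, chaining pairs across gaps is
nearly always profitable, so the best "duplex" against *any* ~300-nt
background sequence pairs essentially the whole miRNA (null best-site
energies ≈ −35), and no planted site can be distinguished from background
— the predictor has no power. At a gap cost of 4 a skipped base costs more
than a typical pair gains, duplexes stay compact, and planted sites
separate cleanly from the dinucleotide background (null 5th percentile
≈ −22 to −30 depending on composition vs planted ≈ −33 to −36; measured
sensitivity 1.0). Full thermodynamic models achieve the same effect with
large loop penalties.

Energies are converted to p-values through a Gumbel law on the
length-normalised score *x = −E / ln L*: *p = 1 − exp(−exp(−(x − ξ)/θ))*,
which increases with energy (weak sites → large p). The defaults
ξ = 2.327203, θ = 0.216961 are the published transcriptome-calibrated
values; `calibrate_evd()` refits both by maximum likelihood from the best
scores of UTRs generated under a first-order (dinucleotide) Markov model
of the input set, which is the calibration used for synthetic data (the
model units here differ from thermodynamic kcal/mol, so the published
location/scale applies to the published setting, and fresh calibration
applies to ours). A site enters the final call set only when a seed site
and a significant energy site (p ≤ 0.05 by default) overlap on the same
UTR for the same miRNA.

The trained machine-learning half of the original two-predictor consensus
is not reproducible from its description; its structural role — an
independent second predictor intersected with the energy predictor — is
played by the strict seed rule.

# The synthetic-data generator as study design

The generator's defaults encode the emulated study conditions: 18
samples, 50,000 read pairs per sample, 37-nt paired reads with a fixed
TruSeq-style 3' adapter pad, 20 miRNA genes in 12 families with zeta-law
(exponent 1.5) copy numbers, 20% of genes forming identical-sequence pri
duplicate pairs, a star-arm read fraction of 0.15, 2% 1-nt 5' jitter, and
substitution-error rate 0 (paired-end reconciliation plus fixed Q40
qualities emulate the exact-sequence collapsing of the original protocol;
indels and quality profiles are out of scope). Family expression weights
are rank-coupled to copy number with strength 0.7, the regime in which the
recovered Spearman rho lands near the reported positive association; a
coupling of 1 yields rho > 0.5 despite copy-number ties.

Two generator details are deliberate departures from the most naive
construction, both discovered by measurement:

* **Wobble pairs.** A perfect inverted-repeat hairpin is exactly
  palindromic, so every mature read also exact-maps to the opposite strand
  at the star arm, creating a spurious mirrored locus. Real precursor
  stems contain G·U wobbles; the generator plants two per stem (opposite
  mature G/T bases), which breaks the palindrome without weakening the
  hairpin. `wobbles = 0` restores the textbook perfect construction.
* **Adaptive planted-site length.** Planted target sites are the reverse
  complement of miRNA positions *s..s+k−1* with *k* chosen as the smallest
  length whose guaranteed duplex score reaches −32 (clamped to 10–16), so
  AU-rich miRNAs get longer complementary stretches — mirroring the
  3'-supplementary pairing of real functional sites — and all planted
  sites have comparable stability.

What passing tests on this generator do **not** show: performance on real
reads with indels, quality decay, cross-mapping to a large repetitive
genome, or RNA editing; robustness of the folding model's absolute
energies (only topology and ranking are exercised); and any claim about
the original study's specific counts, which depend on its sequencing data
and database snapshots.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at the
study's sample design (18 samples × 50,000 read pairs, 20 genes, 3
replicate seeds — about 2.7 million read pairs end to end), the folding
oracle on 500 random sequences up to 18 nt, the target oracles on 100
random pairs, and Gumbel recovery at 500 draws; these sizes keep each
suite comfortably within a desktop-scale run while leaving no stage
untested at its default configuration. All randomness flows from a single
integer seed through fixed per-stage stream offsets, so every artefact —
FASTA, FASTQ, catalogue tables, the JSON ledger — is byte-reproducible.

Known limitations: exact-match mapping only (reads from variant alleles
would be lost); one best energy site per miRNA×UTR pair (suboptimal
repeated sites are not enumerated); the family rule is sequence-only and
will split families whose members diverge in the seed; and E-values are
calibrated for the ungapped +1/−3 scheme only.
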