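#' @useDynLib smoltmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Internal sequence helpers. Genomic sequences are DNA (ACGT) throughout;
# folding and duplex views convert to RNA (ACGU) on entry.

DNA_BASES_ <- c("A", "C", "G", "T")

#' Reverse complement of DNA character strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp
#' @export
revcomp_rna <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

# DNA -> RNA view (T to U), uppercased
as_rna <- function(x) chartr("tT", "uU", toupper(x))
as_dna <- function(x) chartr("uU", "tT", toupper(x))

# 0-based integer codes A=0 C=1 G=2 U/T=3; stops on anything else
encode_rna <- function(seq) {
  s <- strsplit(as_rna(seq), "", fixed = TRUE)[[1]]
  code <- match(s, c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    stop("invalid character(s) in sequence: ",
         paste(unique(s[is.na(code)]), collapse = ", "))
  }
  code
}

# random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES_, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Watson-Crick + wobble complement test on RNA characters
can_pair_rna <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  if (allow_gu) wc | gu else wc
}

# substring without the substr copy dance
subseq_chr <- function(x, start, end) substring(x, start, end)

# deterministic child seed streams derived from one integer seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 1009L) %% 2147480009L
}
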