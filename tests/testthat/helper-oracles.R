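# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive everything from first principles (direct
# formula evaluation; DNA-alphabet genetic code) rather than calling the
# package's own code paths.

oracle_entropy <- function(p) {
  ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

oracle_info <- function(p) 1 - oracle_entropy(p)

oracle_posterior <- function(odds, prior) {
  odds * prior / ((odds - 1) * prior + 1)
}

# Information delta of one record: baseline odds and MAVE odds given
# numerically, evaluated straight from the formulas.
oracle_record_delta <- function(prior, base_odds, mave_odds) {
  oracle_info(oracle_posterior(base_odds * mave_odds, prior)) -
    oracle_info(oracle_posterior(base_odds, prior))
}

# Single-nucleotide substitution classifier built on the DNA-alphabet
# standard code shipped with Biostrings (the package works in RNA).
oracle_codon_counts <- function(codon_rna) {
  code <- Biostrings::GENETIC_CODE
  codon <- chartr("U", "T", codon_rna)
  aa <- code[[codon]]
  out <- c(missense = 0L, nonsense = 0L, synonymous = 0L)
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      alt <- codon
      substr(alt, pos, pos) <- b
      alt_aa <- code[[alt]]
      key <- if (alt_aa == "*") "nonsense" else
        if (alt_aa == aa) "synonymous" else "missense"
      out[key] <- out[key] + 1L
    }
  }
  out
}

sense_codons_rna <- function() {
  gc <- Biostrings::RNA_GENETIC_CODE
  names(gc)[gc != "*"]
}

# Default-table odds used when an oracle needs a numeric evidence weight.
oracle_default_odds <- c(
  very_strong = 350, strong = 18.7, moderate = 4.33, supporting = 2.08
)

# Absolute-tolerance comparison for values the source material prints
# rounded (testthat's `tolerance` is relative).
expect_abs_equal <- function(object, expected, tol = 5e-3) {
  testthat::expect_lt(max(abs(object - expected)), tol)
  invisible(object)
}
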