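#' The standard genetic code as an RNA codon table
#'
#' Named character vector mapping the 64 RNA codons (alphabet A/C/G/U) to
#' one-letter amino-acid symbols, with `"*"` for the three stop codons.
#' Thin wrapper around the standard code shipped with Biostrings.
#'
#' @return Named character vector of length 64.
#' @export
rna_codon_table <- function() {
  Biostrings::RNA_GENETIC_CODE
}

rna_bases <- c("A", "C", "G", "U")

normalize_codon <- function(codon) {
  codon <- toupper(trimws(codon))
  codon <- gsub("T", "U", codon, fixed = TRUE)  # accept DNA input
  bad <- nchar(codon) != 3L | grepl("[^ACGU]", codon)
  if (any(bad)) {
    stop(sprintf("Invalid codon(s): %s (need 3 letters over A/C/G/U or T).",
                 paste(unique(codon[bad]), collapse = ", ")), call. = FALSE)
  }
  codon
}

#' Classify all single-nucleotide substitutions of a codon
#'
#' Each sense codon has 9 possible single-nucleotide substitutions (3
#' positions x 3 alternative bases). Every substitution is classified
#' against the genetic code as missense (different amino acid), nonsense
#' (stop gained), or synonymous (same amino acid); the three counts always
#' sum to 9. Nonsense changes are counted separately and excluded from
#' missense information, since truncating variants are conventionally
#' assumed pathogenic and sit outside the missense accounting.
#'
#' @param codon Character vector of sense codons (RNA alphabet; `T` is
#'   accepted and read as `U`). Stop codons are an error.
#' @param table Codon table as from [rna_codon_table()].
#' @return A data.frame with columns `codon`, `missense`, `nonsense`,
#'   `synonymous`, one row per input codon.
#' @examples
#' codon_substitution_counts(c("AUG", "UGG", "GGG"))
#' @export
codon_substitution_counts <- function(codon, table = rna_codon_table()) {
  codon <- normalize_codon(codon)
  if (any(table[codon] == "*")) {
    stop(sprintf("Stop codon(s) not allowed: %s.",
                 paste(unique(codon[table[codon] == "*"]), collapse = ", ")),
         call. = FALSE)
  }
  one <- function(cd) {
    aa <- table[[cd]]
    m <- n <- s <- 0L
    for (pos in 1:3) {
      for (b in rna_bases) {
        if (b == substr(cd, pos, pos)) next
        alt <- cd
        substr(alt, pos, pos) <- b
        alt_aa <- table[[alt]]
        if (alt_aa == "*") {
          n <- n + 1L
        } else if (alt_aa == aa) {
          s <- s + 1L
        } else {
          m <- m + 1L
        }
      }
    }
    c(m, n, s)
  }
  counts <- t(vapply(codon, one, integer(3)))
  data.frame(
    codon = codon,
    missense = counts[, 1L],
    nonsense = counts[, 2L],
    synonymous = counts[, 3L],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

canonical_aas <- function(table = rna_codon_table()) {
  sort(unique(table[table != "*"]))
}

#' Average missense substitution count of an amino acid
#'
#' The mean number of missense single-nucleotide substitutions over all
#' codons encoding the amino acid. This codon-averaged count is what a
#' protein sequence (without its actual CDS) supports: each residue is
#' treated as equally likely to be encoded by any of its codons.
#'
#' @param aa Character vector of one-letter amino-acid symbols (20 canonical
#'   residues). Non-canonical symbols (`B`, `Z`, `X`, `U`, `O`, ...) are an
#'   error.
#' @inheritParams codon_substitution_counts
#' @return Numeric vector of average missense counts.
#' @examples
#' aa_average_missense(c("M", "W", "L"))
#' @export
aa_average_missense <- function(aa, table = rna_codon_table()) {
  aa <- toupper(trimws(aa))
  known <- canonical_aas(table)
  bad <- !aa %in% known
  if (any(bad)) {
    stop(sprintf(
      "Non-canonical amino-acid symbol(s): %s (expected one of %s).",
      paste(unique(aa[bad]), collapse = ", "), paste(known, collapse = "")
    ), call. = FALSE)
  }
  sense <- names(table)[table != "*"]
  counts <- codon_substitution_counts(sense, table)
  avg <- vapply(
    split(counts$missense, table[sense]),
    mean,
    numeric(1)
  )
  unname(avg[aa])
}

#' Total possible missense information of a gene
#'
#' Each possible missense variant is one binary pathogenic/benign question
#' and therefore one bit, so the total missense information of a gene is the
#' number of missense variants reachable by single-nucleotide substitution.
#' From a protein sequence this is the sum over residues of the
#' codon-averaged missense count ([aa_average_missense()]); the total is then
#' generally fractional and is also reported rounded to the nearest integer
#' for display. From a coding sequence (`type = "cds"`) the per-codon counts
#' are exact integers.
#'
#' @param seq A single protein sequence (default) or in-frame coding
#'   sequence (`type = "cds"`, with or without the terminal stop codon), as
#'   a character string; an `AAString`/`RNAString`/`DNAString` is accepted.
#' @param type `"protein"` for codon-averaged counting from amino acids,
#'   `"cds"` for exact counting from the actual codons.
#' @param noncanonical For protein input, `"error"` (default) rejects
#'   non-canonical residue symbols; `"skip"` drops them with a warning.
#' @param id Optional identifier carried into the summary.
#' @inheritParams codon_substitution_counts
#' @return An object of class `gene_info_summary`: list with `gene`,
#'   `type`, `length_aa`, `total_missense_bits` (unrounded),
#'   `total_missense_bits_display` (nearest integer), and `per_residue`
#'   (numeric vector of per-residue missense counts).
#' @examples
#' gene_total_missense_bits("MW")            # 9 + 7 = 16 bits
#' gene_total_missense_bits("AUGUGG", type = "cds")
#' @export
gene_total_missense_bits <- function(seq, type = c("protein", "cds"),
                                     table = rna_codon_table(),
                                     noncanonical = c("error", "skip"),
                                     id = NULL) {
  type <- match.arg(type)
  noncanonical <- match.arg(noncanonical)
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)))
  if (length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a single non-empty sequence.", call. = FALSE)
  }
  if (type == "protein") {
    residues <- strsplit(seq, "")[[1L]]
    known <- canonical_aas(table)
    bad <- !residues %in% known
    if (any(bad)) {
      if (noncanonical == "error") {
        stop(sprintf(
          "Sequence contains %d non-canonical residue(s) (%s) at position(s) %s; use noncanonical = \"skip\" to drop them.",
          sum(bad), paste(unique(residues[bad]), collapse = ", "),
          paste(utils::head(which(bad), 10L), collapse = ", ")
        ), call. = FALSE)
      }
      warning(sprintf("Skipping %d non-canonical residue(s): %s.",
                      sum(bad), paste(unique(residues[bad]), collapse = ", ")),
              call. = FALSE)
      residues <- residues[!bad]
    }
    if (length(residues) == 0) {
      stop("No canonical residues left in `seq`.", call. = FALSE)
    }
    per_residue <- aa_average_missense(residues, table)
    names(per_residue) <- residues
  } else {
    cds <- gsub("T", "U", seq, fixed = TRUE)
    if (nchar(cds) %% 3 != 0) {
      stop("CDS length must be a multiple of 3.", call. = FALSE)
    }
    codons <- substring(cds, seq(1, nchar(cds), by = 3),
                        seq(3, nchar(cds), by = 3))
    codons <- normalize_codon(codons)
    is_stop <- table[codons] == "*"
    if (any(is_stop)) {
      if (sum(is_stop) > 1 || !is_stop[length(codons)]) {
        stop("CDS contains an internal stop codon.", call. = FALSE)
      }
      codons <- codons[-length(codons)]  # drop terminal stop
    }
    counts <- codon_substitution_counts(codons, table)
    per_residue <- counts$missense
    names(per_residue) <- table[codons]
  }
  total <- sum(per_residue)
  structure(
    list(
      gene = if (is.null(id)) NA_character_ else as.character(id),
      type = type,
      length_aa = length(per_residue),
      total_missense_bits = total,
      total_missense_bits_display = round(total),
      per_residue = per_residue
    ),
    class = "gene_info_summary"
  )
}

#' @export
print.gene_info_summary <- function(x, ...) {
  cat("Gene missense information",
      if (!is.na(x$gene)) paste0("(", x$gene, ")"), "\n")
  cat(sprintf("  residues            : %d (%s counting)\n",
              x$length_aa, x$type))
  cat(sprintf("  total missense bits : %.2f (~%d)\n",
              x$total_missense_bits, x$total_missense_bits_display))
  cat(sprintf("  mean per residue    : %.3f\n",
              x$total_missense_bits / x$length_aa))
  invisible(x)
}

#' MAVE yield as a percentage of a gene's total missense information
#'
#' @param mave_bits Information produced by the assay, in bits.
#' @param total_bits Total possible missense information of the gene, in
#'   bits; must be positive.
#' @return `100 * mave_bits / total_bits` (percent).
#' @examples
#' percent_information(813.2, 12351) # ~6.58
#' @export
percent_information <- function(mave_bits, total_bits) {
  stopifnot(is.numeric(mave_bits), is.numeric(total_bits))
  if (any(!is.na(total_bits) & total_bits <= 0)) {
    stop("`total_bits` must be positive.", call. = FALSE)
  }
  100 * mave_bits / total_bits
}
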