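#' Read a variant evidence table
#'
#' Reads a delimited text table of variant records (tab-separated by
#' default; comma-separated for `.csv` paths). A header row is required,
#' with at least `variant_id` and one of `mave_code` / `functional_class`.
#' Recognised optional columns: `gene`, `prior`, `baseline_codes`
#' (semicolon-separated evidence codes), `is_vus`, `single_substitution`.
#' `"."` marks a missing value. Unknown columns are preserved untouched as
#' annotations. Row-level problems (malformed probabilities, unknown
#' functional classes, unparsable flags) are reported together with their
#' file line numbers.
#'
#' @param path Path to the table.
#' @param sep Field separator; inferred from the file extension when `NULL`.
#' @return A validated data.frame of variant records, suitable for
#'   [variant_info_delta()] and [mave_score()].
#' @export
read_variant_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(
    path, header = TRUE, sep = sep, quote = "\"",
    colClasses = "character", na.strings = c(".", "NA", ""),
    check.names = FALSE, comment.char = "", stringsAsFactors = FALSE
  )
  if (nrow(raw) == 0) {
    stop(sprintf("No data rows in '%s'.", path), call. = FALSE)
  }
  if (!"variant_id" %in% names(raw)) {
    stop(sprintf("'%s' is missing the required `variant_id` column.", path),
         call. = FALSE)
  }
  if (!any(c("mave_code", "functional_class") %in% names(raw))) {
    stop(sprintf(
      "'%s' must have a `mave_code` or `functional_class` column.", path
    ), call. = FALSE)
  }

  # row-level validation with file line numbers (header is line 1)
  line_of <- function(i) i + 1L
  problems <- character(0)
  if ("prior" %in% names(raw)) {
    p <- suppressWarnings(as.numeric(raw$prior))
    bad <- which(!is.na(raw$prior) & (is.na(p) | p < 0 | p > 1))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "line %d: malformed prior '%s'", line_of(bad), raw$prior[bad]
      ))
    }
  }
  if ("functional_class" %in% names(raw)) {
    fc <- tolower(raw$functional_class)
    bad <- which(!is.na(fc) & !fc %in% functional_classes)
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "line %d: unknown functional_class '%s'",
        line_of(bad), raw$functional_class[bad]
      ))
    }
  }
  for (col in c("is_vus", "single_substitution")) {
    if (!col %in% names(raw)) next
    v <- tolower(trimws(raw[[col]]))
    ok <- is.na(v) | v %in% c("true", "t", "1", "yes", "y",
                              "false", "f", "0", "no", "n")
    if (any(!ok)) {
      problems <- c(problems, sprintf(
        "line %d: unparsable %s '%s'", line_of(which(!ok)), col,
        raw[[col]][!ok]
      ))
    }
  }
  if (length(problems)) {
    stop(sprintf("Invalid rows in '%s':\n  %s", path,
                 paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  records <- as_variant_records(raw)
  message(sprintf("Read %d variant record(s) from '%s'.", nrow(records), path))
  records
}

#' Write a variant evidence table
#'
#' Inverse of [read_variant_table()]: tab-separated, header row, `"."` for
#' missing values.
#'
#' @param records A data.frame of variant records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  records <- as_variant_records(records)
  out <- records
  for (col in names(out)) {
    v <- out[[col]]
    if (is.logical(v)) v <- c("FALSE", "TRUE")[v + 1L]
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read protein (or coding) sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercased sequences, in file order,
#'   named by the full FASTA headers. Non-canonical residues are accepted at
#'   parse time; [gene_total_missense_bits()] applies its own cleaning
#'   policy.
#' @export
read_protein_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("'%s' is not readable as FASTA: %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (length(set) == 0) {
    stop(sprintf("No FASTA records in '%s'.", path), call. = FALSE)
  }
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop(sprintf("Empty sequence record(s) in '%s'.", path), call. = FALSE)
  }
  stats::setNames(seqs, names(set))
}

#' Write a MAVE score report to JSON and/or TSV
#'
#' The JSON file carries the summary (gene, counts, total/relative/absolute/
#' VUS-only bits) together with the per-variant table; the TSV carries the
#' per-variant table alone.
#'
#' @param report A `mave_score_report` from [mave_score()].
#' @param json,tsv Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_mave_report <- function(report, json = NULL, tsv = NULL) {
  stopifnot(inherits(report, "mave_score_report"))
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  }
  if (!is.null(tsv)) {
    utils::write.table(report$per_variant, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(report)
}
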