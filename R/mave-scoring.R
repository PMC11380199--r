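#' Map MAVE functional classes to evidence codes
#'
#' A MAVE reports each assayed variant as functionally `normal`,
#' `intermediate`, or `abnormal`; clinical use then assigns an evidence code
#' to each class (for example, functionally normal = strong benign evidence
#' BS3, loss of function = strong pathogenic evidence PS3; an assay with
#' weaker validation may warrant only moderate or supporting strengths).
#' `intermediate` conventionally maps to `"none"`: it carries no evidence and
#' contributes 0 bits.
#'
#' @param normal,abnormal Evidence-code labels (see [evidence_odds()]) for
#'   the functionally normal and abnormal classes.
#' @param intermediate Evidence-code label for the intermediate class;
#'   defaults to `"none"`.
#' @return A named character vector of class `functional_class_map`.
#' @examples
#' functional_class_map(normal = "BS3", abnormal = "PS3")   # BRCA1-style
#' functional_class_map(normal = "BM", abnormal = "PS")     # TP53-style
#' @export
functional_class_map <- function(normal, abnormal, intermediate = "none") {
  map <- c(normal = as.character(normal),
           intermediate = as.character(intermediate),
           abnormal = as.character(abnormal))
  structure(map, class = "functional_class_map")
}

functional_classes <- c("normal", "intermediate", "abnormal")

# Normalise a variant data.frame: ensure expected columns exist with the
# right types, "." treated as missing. Shared by the reader, the scorer and
# the generator so every entry point enforces the same contract.
as_variant_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data.frame of variant records.",
         call. = FALSE)
  }
  if (!"variant_id" %in% names(records)) {
    stop("`records` must have a `variant_id` column.", call. = FALSE)
  }
  if (!any(c("mave_code", "functional_class") %in% names(records))) {
    stop("`records` must have a `mave_code` or `functional_class` column.",
         call. = FALSE)
  }
  blank_to_na <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", ".")] <- NA_character_
    x
  }
  for (col in c("gene", "baseline_codes", "mave_code", "functional_class")) {
    records[[col]] <- if (col %in% names(records)) {
      blank_to_na(records[[col]])
    } else {
      NA_character_
    }
  }
  records$prior <- if ("prior" %in% names(records)) {
    as.numeric(records$prior)
  } else {
    NA_real_
  }
  for (col in c("is_vus", "single_substitution")) {
    records[[col]] <- if (col %in% names(records)) {
      as_logical_flag(records[[col]], col)
    } else {
      NA
    }
  }
  fc <- records$functional_class
  bad <- !is.na(fc) & !tolower(fc) %in% functional_classes
  if (any(bad)) {
    stop(sprintf(
      "Invalid functional_class value(s): %s (expected %s).",
      paste(unique(fc[bad]), collapse = ", "),
      paste(functional_classes, collapse = "/")
    ), call. = FALSE)
  }
  records$functional_class <- tolower(fc)
  records
}

as_logical_flag <- function(x, col) {
  if (is.logical(x)) {
    return(x)
  }
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  unparsed <- !is.na(x) & !x %in% c("", ".", "na") & is.na(out)
  if (any(unparsed)) {
    stop(sprintf("Cannot parse `%s` value(s) as logical: %s", col,
                 paste(unique(x[unparsed]), collapse = ", ")), call. = FALSE)
  }
  out
}

# Odds of the MAVE evidence for each record: explicit mave_code wins,
# otherwise the functional class is mapped through `class_map`.
resolve_mave_odds <- function(records, class_map, table) {
  odds <- rep(NA_real_, nrow(records))
  has_code <- !is.na(records$mave_code)
  odds[has_code] <- evidence_odds(records$mave_code[has_code], table)
  needs_class <- !has_code
  if (any(needs_class)) {
    fc <- records$functional_class[needs_class]
    if (anyNA(fc)) {
      stop("Record(s) without `mave_code` or `functional_class`: ",
           paste(records$variant_id[needs_class][is.na(fc)], collapse = ", "),
           call. = FALSE)
    }
    if (is.null(class_map)) {
      stop("Records use `functional_class`; supply a `functional_class_map`.",
           call. = FALSE)
    }
    stopifnot(inherits(class_map, "functional_class_map"))
    odds[needs_class] <- evidence_odds(unname(class_map[fc]), table)
  }
  odds
}

resolve_baseline_odds <- function(codes, table) {
  vapply(codes, function(x) {
    if (is.na(x)) {
      return(1)
    }
    combine_odds(evidence_odds(strsplit(x, ";", fixed = TRUE)[[1L]], table))
  }, numeric(1), USE.NAMES = FALSE)
}

resolve_priors <- function(records, default_prior) {
  prior <- ifelse(is.na(records$prior), default_prior, records$prior)
  check_probability(prior, "prior")
  degenerate <- prior %in% c(0, 1)
  if (any(degenerate)) {
    warning(sprintf(
      "%d record(s) have prior 0 or 1; their information deltas are identically 0.",
      sum(degenerate)
    ), call. = FALSE)
  }
  prior
}

#' Per-variant information gained from MAVE evidence
#'
#' For each variant, computes the posterior probability of pathogenicity and
#' information content with and without the MAVE-derived evidence, and the
#' difference in bits. The baseline combines the prior with any pre-existing
#' evidence codes (`baseline_codes`, semicolon-separated); the MAVE evidence
#' is then multiplied in on the odds scale. A negative delta is a real
#' result: evidence that conflicts with the existing picture moves the
#' posterior toward 0.5 and loses information.
#'
#' @param records A data.frame of variant records with columns `variant_id`,
#'   and `mave_code` or `functional_class`; optional `gene`, `prior`,
#'   `baseline_codes`, `is_vus`, `single_substitution`. See
#'   [read_variant_table()].
#' @param class_map A [functional_class_map()]; required when any record
#'   supplies `functional_class` instead of `mave_code`.
#' @param table An [odds_table()].
#' @param default_prior Prior probability of pathogenicity used for records
#'   without their own `prior`; 0.1 is the framework's suggested missense
#'   prior.
#' @return A data.frame with one row per record: `variant_id`, `prior`,
#'   `posterior_before`, `posterior_after`, `info_before`, `info_after`,
#'   `delta_bits`.
#' @examples
#' recs <- data.frame(
#'   variant_id = c("BRCA1 c.5120T>C", "BRCA1 c.5288G>T"),
#'   baseline_codes = "PM2_supporting",
#'   mave_code = c("BS3", "PS3")
#' )
#' variant_info_delta(recs)
#' @export
variant_info_delta <- function(records, class_map = NULL,
                               table = odds_table(), default_prior = 0.1) {
  records <- as_variant_records(records)
  prior <- resolve_priors(records, default_prior)
  base_odds <- resolve_baseline_odds(records$baseline_codes, table)
  mave_odds <- resolve_mave_odds(records, class_map, table)
  posterior_before <- posterior_probability(base_odds, prior)
  posterior_after <- posterior_probability(base_odds * mave_odds, prior)
  info_before <- information_content(posterior_before)
  info_after <- information_content(posterior_after)
  data.frame(
    variant_id = records$variant_id,
    prior = prior,
    posterior_before = posterior_before,
    posterior_after = posterior_after,
    info_before = info_before,
    info_after = info_after,
    delta_bits = info_after - info_before,
    stringsAsFactors = FALSE
  )
}

#' Total information yield of a MAVE
#'
#' Sums per-variant information deltas over all scored variants of an assay
#' — counting evidence whether or not it reclassifies anything — and
#' contrasts that with the conventional VUS-reclassification-only
#' accounting.
#'
#' Two accounting modes are reported:
#' * **relative** (default `total_bits`): each variant's delta at its own
#'   prior, with baseline evidence in place; conflicting evidence can
#'   contribute negative bits.
#' * **absolute** (`absolute_bits`): the information of the MAVE evidence
#'   alone at a prior of 0.5 (no prior information), i.e.
#'   `I(posterior(odds_mave, 0.5))` per variant. This is non-negative by
#'   construction, since any evidence moves an uninformative prior toward a
#'   classification.
#'
#' `vus_only_bits` reproduces the accounting this score is designed to
#' replace: relative deltas summed over records flagged `is_vus` whose
#' posterior leaves the uncertain band (defaults: likely pathogenic at
#' posterior >= 0.90, likely benign at <= 0.10). Records without an `is_vus`
#' flag are treated as VUS. Records flagged as requiring more than one
#' nucleotide substitution (`single_substitution = FALSE`) are excluded
#' before scoring.
#'
#' @inheritParams variant_info_delta
#' @param mode Which accounting `total_bits` reports: `"relative"` or
#'   `"absolute"`.
#' @param vus_bounds Length-2 numeric, the likely-benign and
#'   likely-pathogenic posterior boundaries used for `vus_only_bits`.
#' @return An object of class `mave_score_report`: a list with `gene`,
#'   `n_variants`, `n_excluded`, `mode`, `total_bits`, `relative_bits`,
#'   `absolute_bits`, `vus_only_bits`, and the `per_variant` data.frame
#'   (relative accounting, plus `absolute_bits` per variant).
#' @examples
#' tp53_map <- functional_class_map(normal = "BM", abnormal = "PS")
#' recs <- data.frame(
#'   variant_id = c("v1", "v2", "v3"),
#'   functional_class = c("normal", "abnormal", "intermediate")
#' )
#' mave_score(recs, class_map = tp53_map)
#' @export
mave_score <- function(records, class_map = NULL, table = odds_table(),
                       mode = c("relative", "absolute"), default_prior = 0.1,
                       vus_bounds = c(benign = 0.10, pathogenic = 0.90)) {
  mode <- match.arg(mode)
  records <- as_variant_records(records)
  stopifnot(length(vus_bounds) == 2, vus_bounds[1] < vus_bounds[2])

  excluded <- !is.na(records$single_substitution) & !records$single_substitution
  n_excluded <- sum(excluded)
  if (n_excluded > 0) {
    message(sprintf(
      "Excluding %d record(s) requiring more than one nucleotide substitution.",
      n_excluded
    ))
    records <- records[!excluded, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    stop("No scorable records remain.", call. = FALSE)
  }

  per_variant <- variant_info_delta(records, class_map, table, default_prior)
  mave_odds <- resolve_mave_odds(records, class_map, table)
  per_variant$absolute_bits <- information_content(
    posterior_probability(mave_odds, 0.5)
  )

  relative_bits <- sum(per_variant$delta_bits)
  absolute_bits <- sum(per_variant$absolute_bits)
  is_vus <- ifelse(is.na(records$is_vus), TRUE, records$is_vus)
  reclassified <- per_variant$posterior_after <= vus_bounds[[1]] |
    per_variant$posterior_after >= vus_bounds[[2]]
  vus_only_bits <- sum(per_variant$delta_bits[is_vus & reclassified])

  genes <- unique(records$gene[!is.na(records$gene)])
  structure(
    list(
      gene = if (length(genes)) paste(genes, collapse = ",") else NA_character_,
      n_variants = nrow(records),
      n_excluded = n_excluded,
      mode = mode,
      total_bits = if (mode == "relative") relative_bits else absolute_bits,
      relative_bits = relative_bits,
      absolute_bits = absolute_bits,
      vus_only_bits = vus_only_bits,
      per_variant = per_variant
    ),
    class = "mave_score_report"
  )
}

#' @export
print.mave_score_report <- function(x, ...) {
  cat("MAVE information score", if (!is.na(x$gene)) paste0("(", x$gene, ")"),
      "\n")
  cat(sprintf("  variants scored : %d (%d excluded as multi-nucleotide)\n",
              x$n_variants, x$n_excluded))
  cat(sprintf("  total bits      : %.3f (%s accounting)\n",
              x$total_bits, x$mode))
  cat(sprintf("  relative bits   : %.3f\n", x$relative_bits))
  cat(sprintf("  absolute bits   : %.3f (prior 0.5)\n", x$absolute_bits))
  cat(sprintf("  VUS-only bits   : %.3f\n", x$vus_only_bits))
  fold <- suppressWarnings(fold_increase(x$relative_bits, x$vus_only_bits))
  if (!is.na(fold)) {
    cat(sprintf("  fold increase   : %.1f over VUS-only accounting\n", fold))
  }
  invisible(x)
}

#' Fold increase of full information accounting over VUS-only accounting
#'
#' @param total_bits Total information of the assay in bits.
#' @param vus_only_bits Information credited under VUS-reclassification-only
#'   accounting, in bits; must be positive for the ratio to be defined.
#' @return `total_bits / vus_only_bits`, or `NA` (with a warning) when
#'   `vus_only_bits <= 0` — the ratio is reported as not computable rather
#'   than infinite.
#' @examples
#' fold_increase(813.2, 36.9) # ~22
#' @export
fold_increase <- function(total_bits, vus_only_bits) {
  stopifnot(is.numeric(total_bits), is.numeric(vus_only_bits))
  out <- total_bits / vus_only_bits
  bad <- !is.na(vus_only_bits) & vus_only_bits <= 0
  if (any(bad)) {
    warning("`vus_only_bits` <= 0: fold increase is not computable.",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}
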