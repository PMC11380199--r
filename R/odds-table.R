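#' Evidence-strength to odds-of-pathogenicity table
#'
#' Builds the lookup table used to convert ACMG/AMP evidence codes to odds of
#' pathogenicity. Defaults are the Bayesian points-framework values for
#' pathogenic evidence (very strong 350, strong 18.7, moderate 4.33,
#' supporting 2.08); benign odds are the reciprocals of the pathogenic odds
#' at the same strength.
#'
#' @param very_strong,strong,moderate,supporting Pathogenic-side odds for the
#'   four evidence strengths. Must be strictly decreasing and all > 1.
#' @param overrides Optional named numeric vector of per-code odds that take
#'   precedence over strength-based resolution, e.g.
#'   `c(PS3 = 18.8, BS3 = 0.053)` to reproduce a source that rounds its odds.
#' @return An object of class `odds_table`.
#' @seealso [evidence_odds()], [read_odds_config()]
#' @examples
#' odds_table()
#' odds_table(overrides = c(BS3 = 0.053))
#' @export
odds_table <- function(very_strong = 350, strong = 18.7, moderate = 4.33,
                       supporting = 2.08, overrides = NULL) {
  strengths <- c(very_strong = very_strong, strong = strong,
                 moderate = moderate, supporting = supporting)
  check_odds(strengths, "strength odds")
  if (any(strengths <= 1)) {
    stop("All pathogenic-side strength odds must exceed 1.", call. = FALSE)
  }
  if (any(diff(strengths) >= 0)) {
    stop("Strength odds must be strictly decreasing: ",
         "very_strong > strong > moderate > supporting.", call. = FALSE)
  }
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("`overrides` must be a named numeric vector of code -> odds.",
           call. = FALSE)
    }
    overrides <- vapply(overrides, as.numeric, numeric(1))
    check_odds(overrides, "override odds")
    names(overrides) <- toupper(names(overrides))
  }
  structure(
    list(strengths = strengths, overrides = overrides),
    class = "odds_table"
  )
}

#' @export
print.odds_table <- function(x, ...) {
  cat("Evidence odds table (odds of pathogenicity)\n")
  s <- x$strengths
  cat(sprintf("  %-12s pathogenic %8.3f   benign %8.5f\n",
              names(s), s, 1 / s), sep = "")
  if (length(x$overrides)) {
    cat("  per-code overrides:\n")
    cat(sprintf("    %-16s %g\n", names(x$overrides), x$overrides), sep = "")
  }
  invisible(x)
}

# Map an ACMG/AMP code prefix to (side, default strength). BA1 (stand-alone
# benign) is treated as very strong benign; BM/BVS are not standard ACMG/AMP
# categories but appear as hypothetical rule strengths in guideline analyses.
code_prefixes <- function() {
  data.frame(
    prefix   = c("PVS", "PS", "PM", "PP", "BA", "BVS", "BS", "BM", "BP"),
    side     = c("pathogenic", "pathogenic", "pathogenic", "pathogenic",
                 "benign", "benign", "benign", "benign", "benign"),
    strength = c("very_strong", "strong", "moderate", "supporting",
                 "very_strong", "very_strong", "strong", "moderate",
                 "supporting"),
    stringsAsFactors = FALSE
  )
}

strength_levels <- c("very_strong", "strong", "moderate", "supporting")

#' Resolve evidence codes to odds of pathogenicity
#'
#' Converts ACMG/AMP-style evidence codes (`PVS1`, `PS3`, `PM2`, `PP3`,
#' `BS3`, `BP4`, ... or bare category labels `PS`, `BM`, ...) to odds of
#' pathogenicity using an [odds_table()]. Codes are case-insensitive. A
#' strength suffix after an underscore overrides the code's default
#' strength, so `PM2_supporting` resolves at supporting strength (odds 2.08
#' by default) even though `PM2` is nominally moderate. The pseudo-code
#' `"none"` (and `NA` or `""`) means no evidence and resolves to odds 1.
#'
#' @param code Character vector of evidence codes.
#' @param table An [odds_table()].
#' @return Numeric vector of odds, one per code.
#' @examples
#' evidence_odds(c("PM2", "PM2_supporting", "BS3", "none"))
#' @export
evidence_odds <- function(code, table = odds_table()) {
  stopifnot(inherits(table, "odds_table"))
  if (length(code) == 0) {
    return(numeric(0))
  }
  code <- toupper(trimws(as.character(code)))
  vapply(code, resolve_one_code, numeric(1), table = table, USE.NAMES = TRUE)
}

resolve_one_code <- function(code, table) {
  if (is.na(code) || code %in% c("", ".", "NONE")) {
    return(1)
  }
  if (!is.null(table$overrides) && code %in% names(table$overrides)) {
    return(unname(table$overrides[[code]]))
  }
  parts <- strsplit(code, "_", fixed = TRUE)[[1L]]
  base <- parts[1L]
  suffix <- if (length(parts) > 1L) {
    paste(tolower(parts[-1L]), collapse = "_")
  } else {
    NA_character_
  }
  if (!is.null(table$overrides) && base %in% names(table$overrides) &&
      is.na(suffix)) {
    return(unname(table$overrides[[base]]))
  }
  px <- code_prefixes()
  hit <- which(startsWith(base, px$prefix))
  if (length(hit) == 0) {
    stop(sprintf(
      paste0("Unknown evidence code '%s'. Known code prefixes: %s; ",
             "known strength suffixes: %s; 'none' means no evidence."),
      code, paste(px$prefix, collapse = ", "),
      paste(strength_levels, collapse = ", ")
    ), call. = FALSE)
  }
  hit <- hit[which.max(nchar(px$prefix[hit]))]  # PVS before PS, BVS before BS
  strength <- px$strength[hit]
  if (!is.na(suffix)) {
    suffix <- sub("^very.?strong$", "very_strong", suffix)
    if (!suffix %in% strength_levels) {
      stop(sprintf(
        "Unknown strength suffix '%s' in code '%s'; expected one of %s.",
        suffix, code, paste(strength_levels, collapse = ", ")
      ), call. = FALSE)
    }
    strength <- suffix
  }
  odds <- unname(table$strengths[[strength]])
  if (px$side[hit] == "benign") 1 / odds else odds
}

#' Read an odds table from a YAML configuration file
#'
#' The file holds strength-category odds and optional per-code overrides:
#'
#' ```yaml
#' very_strong: 350
#' strong: 18.7
#' moderate: 4.33
#' supporting: 2.08
#' overrides:
#'   PS3: 18.8
#'   BS3: 0.053
#' ```
#'
#' Omitted strengths keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An [odds_table()].
#' @export
read_odds_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) {
    stop("Odds config must be a YAML mapping of category -> odds.",
         call. = FALSE)
  }
  names(cfg) <- gsub("[ -]", "_", tolower(names(cfg)))
  defaults <- formals(odds_table)
  args <- list()
  for (s in strength_levels) {
    args[[s]] <- if (!is.null(cfg[[s]])) as.numeric(cfg[[s]]) else
      eval(defaults[[s]])
  }
  if (!is.null(cfg$overrides)) {
    args$overrides <- unlist(cfg$overrides)
  }
  do.call(odds_table, args)
}
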