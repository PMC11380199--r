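#' Information change of one evidence strength across priors
#'
#' Applies a single evidence code to every prior on a grid and reports the
#' resulting change in information content,
#' `delta(prior) = I(posterior(odds, prior)) - I(prior)`. The curves show
#' when a rule appears to add or lose information: pathogenic evidence
#' applied at a low prior (where the benign interpretation is already
#' near-certain) pulls the posterior toward 0.5 and loses information, and
#' benign evidence does the same at high priors.
#'
#' @param code An evidence-code or category label (see [evidence_odds()]),
#'   e.g. `"PS"`, `"BS3"`, `"PM2_supporting"`.
#' @param priors Numeric grid of prior probabilities, strictly inside
#'   (0, 1). Grid points at exactly 0 or 1 are dropped with a warning (their
#'   baseline information is already 1 and no evidence can move them). The
#'   default is 199 points at 0.005 spacing.
#' @param table An [odds_table()].
#' @return A data.frame with columns `code`, `odds`, `prior`, `delta_bits`.
#' @examples
#' curve <- info_change_curve("PS")
#' curve[curve$prior == 0.5, ] # +0.71 bits on an uninformative prior
#' @export
info_change_curve <- function(code, priors = seq(0.005, 0.995, by = 0.005),
                              table = odds_table()) {
  stopifnot(length(code) == 1L)
  check_probability(priors)
  boundary <- priors %in% c(0, 1)
  if (any(boundary)) {
    warning(sprintf(
      "Dropping %d grid point(s) at prior 0 or 1 (already fully informative).",
      sum(boundary)
    ), call. = FALSE)
    priors <- priors[!boundary]
  }
  if (length(priors) == 0) {
    stop("No usable prior grid points in (0, 1).", call. = FALSE)
  }
  odds <- unname(evidence_odds(code, table))
  delta <- information_content(posterior_probability(odds, priors)) -
    information_content(priors)
  data.frame(
    code = code,
    odds = odds,
    prior = priors,
    delta_bits = delta,
    stringsAsFactors = FALSE
  )
}

#' Audit the gene-wide information effect of a rule-strength change
#'
#' When a guideline committee changes the strength assigned to a rule (say,
#' benign supporting BP evidence is promoted to benign strong BS), the
#' apparent information of every variant scored under that rule changes.
#' This audit recomputes each record's MAVE information delta with the old
#' and the new code substituted as the MAVE evidence, and reports the
#' per-variant difference plus its sum and mean — a global assessment of the
#' information change implied by the rule change.
#'
#' @inheritParams variant_info_delta
#' @param old_code,new_code Evidence codes before and after the rule change.
#' @return An object of class `rule_change_audit`: list with `old_code`,
#'   `new_code`, `n_variants`, `total_change_bits`, `mean_change_bits`, and
#'   a `per_variant` data.frame (`variant_id`, `delta_old`, `delta_new`,
#'   `change_bits`).
#' @examples
#' recs <- data.frame(variant_id = c("v1", "v2"),
#'                    baseline_codes = c(NA, "PM2_supporting"),
#'                    mave_code = "BP")
#' rule_change_audit(recs, "BP", "BS")
#' @export
rule_change_audit <- function(records, old_code, new_code,
                              table = odds_table(), default_prior = 0.1) {
  stopifnot(length(old_code) == 1L, length(new_code) == 1L)
  # validate the codes up front so unknown codes fail as a lookup error
  evidence_odds(c(old_code, new_code), table)

  with_code <- function(code) {
    forced <- records
    forced$mave_code <- code
    forced$functional_class <- NULL
    variant_info_delta(forced, class_map = NULL, table = table,
                       default_prior = default_prior)
  }
  old <- with_code(old_code)
  new <- with_code(new_code)
  per_variant <- data.frame(
    variant_id = old$variant_id,
    delta_old = old$delta_bits,
    delta_new = new$delta_bits,
    change_bits = new$delta_bits - old$delta_bits,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      old_code = old_code,
      new_code = new_code,
      n_variants = nrow(per_variant),
      total_change_bits = sum(per_variant$change_bits),
      mean_change_bits = mean(per_variant$change_bits),
      per_variant = per_variant
    ),
    class = "rule_change_audit"
  )
}

#' @export
print.rule_change_audit <- function(x, ...) {
  cat(sprintf("Rule change audit: %s -> %s over %d variant(s)\n",
              x$old_code, x$new_code, x$n_variants))
  cat(sprintf("  total change : %+.4f bits\n", x$total_change_bits))
  cat(sprintf("  mean change  : %+.4f bits/variant\n", x$mean_change_bits))
  invisible(x)
}
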