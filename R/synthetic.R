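#' Specification for a synthetic MAVE variant table
#'
#' Describes the composition of a simulated MAVE result set: how many
#' variants fall in each functional class, how classes map to evidence
#' codes, the prior, and the per-code frequency of pre-existing (baseline)
#' evidence. The defaults emulate the composition of the combined TP53
#' assays used throughout the package's examples: 5070 functionally normal
#' and 2823 functionally abnormal variants, scored as benign moderate and
#' pathogenic strong evidence respectively, at a missense prior of 0.1, with
#' no baseline evidence.
#'
#' @param n_normal,n_intermediate,n_abnormal Non-negative counts of variants
#'   per functional class.
#' @param class_map A [functional_class_map()].
#' @param prior Prior probability of pathogenicity written to every record.
#' @param baseline_code_frequency Optional named numeric vector of
#'   per-record inclusion probabilities for baseline evidence codes, e.g.
#'   `c(PM2_supporting = 0.6)`: each record independently carries each code
#'   with the given probability.
#' @param seed Integer random seed; the generated table is a pure function
#'   of the spec, so equal spec + seed gives byte-identical tables.
#' @return An object of class `synthetic_mave_spec`.
#' @seealso [generate_synthetic_mave()]
#' @export
synthetic_mave_spec <- function(n_normal = 5070, n_intermediate = 0,
                                n_abnormal = 2823,
                                class_map = functional_class_map(
                                  normal = "BM", abnormal = "PS"
                                ),
                                prior = 0.1,
                                baseline_code_frequency = NULL,
                                seed = 1L) {
  counts <- c(n_normal = n_normal, n_intermediate = n_intermediate,
              n_abnormal = n_abnormal)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Class counts must be non-negative integers.", call. = FALSE)
  }
  check_probability(prior)
  stopifnot(inherits(class_map, "functional_class_map"))
  if (!is.null(baseline_code_frequency)) {
    if (is.null(names(baseline_code_frequency)) ||
        any(!nzchar(names(baseline_code_frequency)))) {
      stop("`baseline_code_frequency` must be named by evidence code.",
           call. = FALSE)
    }
    check_probability(baseline_code_frequency, "baseline_code_frequency")
  }
  structure(
    list(
      n_normal = as.integer(n_normal),
      n_intermediate = as.integer(n_intermediate),
      n_abnormal = as.integer(n_abnormal),
      class_map = class_map,
      prior = prior,
      baseline_code_frequency = baseline_code_frequency,
      seed = as.integer(seed)
    ),
    class = "synthetic_mave_spec"
  )
}

#' Generate a synthetic MAVE variant table
#'
#' Produces a variant table with exactly the class composition of the spec,
#' in shuffled order, with baseline evidence codes sampled independently per
#' record at the configured frequencies. Records are flagged `is_vus = TRUE`
#' and `single_substitution = TRUE`, matching the pre-assay state the
#' scoring examples assume. Generation is deterministic for a given spec.
#'
#' @param spec A [synthetic_mave_spec()].
#' @return A data.frame of variant records (possibly 0-row when all counts
#'   are zero; scoring rejects empty tables downstream).
#' @examples
#' tab <- generate_synthetic_mave(synthetic_mave_spec(
#'   n_normal = 5, n_abnormal = 3, seed = 42
#' ))
#' mave_score(tab, class_map = functional_class_map("BM", "PS"))
#' @export
generate_synthetic_mave <- function(spec) {
  stopifnot(inherits(spec, "synthetic_mave_spec"))
  n <- spec$n_normal + spec$n_intermediate + spec$n_abnormal
  classes <- rep(c("normal", "intermediate", "abnormal"),
                 c(spec$n_normal, spec$n_intermediate, spec$n_abnormal))
  withr::with_seed(spec$seed, {
    if (n > 0) {
      classes <- sample(classes)
    }
    baseline <- rep(NA_character_, n)
    freq <- spec$baseline_code_frequency
    if (!is.null(freq) && n > 0) {
      carried <- vapply(
        seq_len(n),
        function(i) {
          codes <- names(freq)[stats::runif(length(freq)) < freq]
          if (length(codes)) paste(codes, collapse = ";") else NA_character_
        },
        character(1)
      )
      baseline <- carried
    }
  })
  out <- data.frame(
    variant_id = sprintf("synth_v%05d", seq_len(n)),
    gene = rep("synthetic", n),
    prior = rep(spec$prior, n),
    baseline_codes = baseline[seq_len(n)],
    functional_class = classes,
    is_vus = rep(TRUE, n),
    single_substitution = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
  out
}
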