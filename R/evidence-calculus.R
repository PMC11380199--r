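#' Binary Shannon entropy of a probability of pathogenicity
#'
#' Computes `S = -p*log2(p) - (1-p)*log2(1-p)`, the uncertainty in bits of a
#' binary pathogenic/benign call with probability of pathogenicity `p`. The
#' limit convention `0 * log2(0) = 0` applies, so `p = 0` and `p = 1` return
#' exactly 0 without warnings.
#'
#' @param p Numeric vector of probabilities of pathogenicity in \[0, 1\].
#'   Out-of-range values are an error, not clamped: a probability outside
#'   \[0, 1\] signals an upstream bug in evidence combination that silent
#'   clamping would hide.
#' @return Numeric vector of entropies in bits, each in \[0, 1\].
#' @seealso [information_content()]
#' @examples
#' binary_entropy(0.5)    # 1: maximal uncertainty
#' binary_entropy(0.3246) # 0.9093
#' @export
binary_entropy <- function(p) {
  check_probability(p)
  s <- numeric(length(p))
  inner <- p > 0 & p < 1
  q <- p[inner]
  s[inner] <- -q * log2(q) - (1 - q) * log2(1 - q)
  s[is.na(p)] <- NA_real_
  s
}

#' Information content of a probability of pathogenicity
#'
#' Information content is the complement of the binary entropy, `I = 1 - S`:
#' 0 bits at p = 0.5 (no certainty either way) and 1 bit at p = 0 or p = 1
#' (fully classified). One bit is the information needed to completely
#' classify one variant starting from complete uncertainty. The function is
#' symmetric in `p` and `1 - p`: certainty of benignity counts the same as
#' certainty of pathogenicity.
#'
#' @inheritParams binary_entropy
#' @return Numeric vector of information contents in bits, each in \[0, 1\].
#' @examples
#' information_content(0.5)    # 0
#' information_content(0.0059) # 0.9478
#' @export
information_content <- function(p) {
  1 - binary_entropy(p)
}

#' Posterior probability of pathogenicity from odds and prior
#'
#' Combines a (possibly composite) odds of pathogenicity with a prior
#' probability of pathogenicity under the Bayesian classification framework:
#' `posterior = odds * prior / ((odds - 1) * prior + 1)`.
#'
#' A prior of exactly 0 or 1 is a fixed point: no finite odds moves it.
#' `odds = 1` ("no evidence") returns the prior unchanged.
#'
#' @param odds Positive numeric vector of odds-of-pathogenicity multipliers
#'   (points-framework likelihood ratios; values below 1 favour benignity).
#' @param prior Numeric vector of prior probabilities of pathogenicity in
#'   \[0, 1\]. Recycled against `odds`.
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @examples
#' posterior_probability(4.33, 0.1)   # 0.3248, pathogenic moderate evidence
#' posterior_probability(1 / 18.7, 0.1) # 0.0059, benign strong evidence
#' @export
posterior_probability <- function(odds, prior) {
  check_odds(odds)
  check_probability(prior)
  out <- odds * prior / ((odds - 1) * prior + 1)
  # 0/1 priors are exact fixed points; protect them from rounding drift
  prior <- rep_len(prior, length(out))
  out[prior == 0] <- 0
  out[prior == 1] <- 1
  out
}

#' Combine independent evidence items as a product of odds
#'
#' Under the naive-Bayes evidence framework, independent evidence items
#' multiply on the odds scale. An empty set of evidence is odds 1.
#'
#' @param odds Numeric vector (or list) of positive odds multipliers; may be
#'   empty.
#' @return A single positive number, the product of all entries (1 for an
#'   empty input).
#' @examples
#' combine_odds(c(2.08, 1 / 18.7)) # supporting pathogenic + strong benign
#' combine_odds(numeric(0))        # 1
#' @export
combine_odds <- function(odds) {
  odds <- as.numeric(unlist(odds, use.names = FALSE))
  if (length(odds) == 0) {
    return(1)
  }
  check_odds(odds)
  prod(odds)
}

# -- input validation ---------------------------------------------------------

check_probability <- function(p, what = deparse(substitute(p))) {
  if (!is.numeric(p)) {
    stop(sprintf("`%s` must be numeric, got %s.", what, class(p)[1L]),
         call. = FALSE)
  }
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop(sprintf(
      "`%s` must be a probability in [0, 1]; offending value(s): %s",
      what, paste(format(p[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(p)
}

check_odds <- function(odds, what = deparse(substitute(odds))) {
  if (!is.numeric(odds)) {
    stop(sprintf("`%s` must be numeric, got %s.", what, class(odds)[1L]),
         call. = FALSE)
  }
  bad <- !is.na(odds) & odds <= 0
  if (any(bad)) {
    stop(sprintf(
      "`%s` must be strictly positive odds; offending value(s): %s",
      what, paste(format(odds[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(odds)
}
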