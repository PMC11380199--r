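---
title: "Measuring variant-classification evidence in bits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring variant-classification evidence in bits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maveinfo)
```

## The model

For a gene with a single, well-defined gene-disease relationship, each
missense variant is either pathogenic or benign. The state of knowledge about
one variant is a probability of pathogenicity $p$, and the *uncertainty* of
that state is the binary Shannon entropy

$$S(p) = -p \log_2 p - (1 - p)\log_2(1 - p),$$

with the limit convention $0 \log_2 0 = 0$. The *information content* is its
complement, $I(p) = 1 - S(p)$: 0 bits at $p = 0.5$, 1 bit at $p \in \{0,
1\}$, symmetric in $p \leftrightarrow 1 - p$ (certainty of benignity is
worth as much as certainty of pathogenicity). One bit is exactly the
information needed to classify one variant completely, starting from no
information.

Evidence enters through the Bayesian adaptation of the ACMG/AMP guidelines:
each evidence item carries an odds of pathogenicity (a likelihood ratio),
independent items multiply on the odds scale, and a combined odds $O$ updates
a prior $p_0$ as

$$p = \frac{O\,p_0}{(O - 1)\,p_0 + 1}.$$

The information a piece of evidence *adds* to a variant is
$\Delta I = I(p_{\text{after}}) - I(p_{\text{before}})$. Crucially,
$\Delta I$ can be negative: evidence that conflicts with the current picture
pulls the posterior toward 0.5 and genuinely loses certainty. Scoring a
multiplexed assay of variant effect (MAVE) is then just summing $\Delta I$
over every assayed variant, whether or not any variant crosses a
classification boundary.

```{r worked}
recs <- read_variant_table(system.file("extdata",
  "brca1_worked_variants.tsv", package = "maveinfo"))
variant_info_delta(recs)
```

The first variant (functionally normal, strong benign evidence BS3 added to
a supporting-level pathogenic baseline) gains about 0.60 bits. The second
(functionally abnormal, PS3) swings its posterior from 0.188 to 0.812 —
symmetric about 0.5 — and gains essentially nothing: a large probability
change with no gain in certainty.

## Parameters and defaults

* **Odds table** (`odds_table()`): pathogenic very strong 350, strong 18.7,
  moderate 4.33, supporting 2.08; benign odds are the reciprocals of the
  same strengths. These are the Bayesian points-framework calibration
  values; sources that print rounded odds (4.3, 18.8, 0.053) give posteriors
  within 0.005 of the defaults, and `overrides` (or a YAML config via
  `read_odds_config()`) can pin any individual code. Evidence codes are
  case-insensitive and a `_strength` suffix overrides a code's default
  strength (`PM2_supporting` resolves at supporting strength).
* **Prior probability of pathogenicity**: 0.1 per record by default, the
  framework's suggested prior for a rare missense variant, overridable per
  record (a `prior` column) or globally (`default_prior`).
* **Functional class map** (`functional_class_map()`): which evidence code
  each MAVE class earns is an assay-level calibration decision and therefore
  an explicit input, e.g. `normal = "BS3", abnormal = "PS3"` for a
  well-validated assay, or `normal = "BM", abnormal = "PS"` where
  validation supports different strengths. `intermediate` maps to `"none"`
  (odds 1, 0 bits) — intermediate variants are counted but carry no
  evidence.
* **VUS-reclassification bounds** (`vus_bounds` in `mave_score()`): the
  conventional accounting that this score is designed to replace counts only
  variants of uncertain significance that leave the uncertain band. The
  band is explicit and configurable, defaulting to likely benign at
  posterior $\le 0.10$ and likely pathogenic at $\ge 0.90$; `vus_only_bits`
  sums relative deltas over `is_vus` records whose posterior exits it, and
  records without an `is_vus` flag are treated as VUS (the usual pre-assay
  state).

## Relative versus absolute accounting

Relative accounting (the default) answers "how much did this assay change
what we know", at each variant's actual prior and baseline evidence; it can
be negative per variant. Absolute accounting answers "how much information
does the assay's evidence carry on its own": each variant contributes
$I(\mathrm{posterior}(O_{\text{MAVE}}, 0.5))$, the information of the MAVE
evidence alone at an uninformative prior. We deliberately exclude baseline
codes from the absolute mode: starting from $p_0 = 0.5$, *any* evidence item
moves the posterior away from 0.5, so per-variant contributions — and the
total — are non-negative by construction, which is the defining property of
the absolute view. Keeping baseline evidence in place would reintroduce
conflict (and negative contributions) through the back door.

## Gene-wide totals from the genetic code

If every possible missense variant is one binary question, the total
missense information of a gene is simply the number of missense variants
reachable by single-nucleotide substitution. Each sense codon has 9 possible
substitutions (3 positions × 3 bases), each classified against the standard
genetic code as missense, nonsense, or synonymous; the three counts sum to 9
for every codon. Nonsense changes are excluded from the missense total
(truncating variants are conventionally assumed pathogenic and sit outside
this accounting), as are synonymous ones.

Counting proceeds at the nucleotide level: two different substitutions that
produce the same amino-acid change are two variants. When only the protein
sequence is available, each residue contributes the *average* missense count
over the codons that encode it — so totals are generally fractional, and are
also reported rounded for display. When the actual coding sequence is known,
`type = "cds"` counts exactly per codon. The initiator methionine is
included; non-canonical symbols (X, U, B, ...) are rejected by default with
a `noncanonical = "skip"` escape hatch that logs what it drops.

```{r gene}
tp53 <- read_protein_fasta(system.file("extdata", "TP53_P04637.fasta",
                                       package = "maveinfo"))
gene_total_missense_bits(tp53[[1]], id = "TP53")
```

An assay's yield divided by this total (`percent_information()`) expresses
progress toward completely classifying the gene.

## Guideline rule changes

`info_change_curve()` applies one evidence strength across a grid of priors
and reports $\Delta I$ at each. The default grid is 199 points at 0.005
spacing on (0, 1): fine enough for smooth curves, with the endpoints
excluded because a prior of exactly 0 or 1 already carries 1 bit and no
evidence can move it (such grid points are rejected, not evaluated). The
curves make the sign structure of the calculus visible: pathogenic evidence
applied at a low prior loses information, benign evidence at a high prior
likewise, and every strength gains at $p_0 = 0.5$. At 0.5 the gain is
ordered by strength on each side. We report the empirical argmax of each
curve rather than asserting it sits at 0.5: for strong evidence the maximum
information gain sits slightly off-centre, on the side the evidence pushes
away from.

`rule_change_audit()` quantifies a committee decision ("BP3 becomes BS3")
across a variant set by forcing each record's MAVE evidence to the old and
then the new code and differencing the deltas. We apply the counterfactual
to every record rather than filtering to records that currently carry the
old code: the audit asks what the rule change would do to the set it
governs, and the identical-codes case is exactly zero either way.

## The synthetic generator

`generate_synthetic_mave()` emulates the composition of a combined-assay
variant table: exact class counts in shuffled order, per-record baseline
evidence codes sampled independently at configured frequencies, `is_vus`
and `single_substitution` flags set to the typical pre-assay state. Its
defaults are the composition used throughout the examples — 5070
functionally normal and 2823 abnormal variants scored as benign moderate and
pathogenic strong at a 0.1 prior, the combined-TP53-assay setting. Identical
spec and seed give byte-identical tables (`withr::with_seed`, so the
caller's RNG state is untouched).

What the generator does *not* emulate: real functional-score distributions
and the thresholding that turns scores into classes, assay noise or
replicate structure, correlated baseline evidence, position effects along
the protein, or multi-nucleotide amino-acid changes. Tests that pass on
synthetic tables therefore validate the *scoring calculus* — additivity,
permutation invariance, oracle agreement, determinism — not the upstream
assay calibration, which this package takes as input by design.

## Numerical choices and degenerate inputs

* Probabilities are validated, never clamped; out-of-range values error.
* $p \in \{0, 1\}$ return entropy 0 exactly, without floating-point
  warnings; priors of 0 or 1 are exact fixed points of the posterior update
  (protected against rounding drift) and are flagged when scored, since
  their deltas are identically 0.
* An empty evidence list combines to odds 1; `"none"`, `NA`, and `"."` all
  resolve to odds 1.
* `fold_increase()` with a non-positive denominator reports `NA` with a
  warning rather than `Inf`: "no VUS were reclassified" makes the ratio
  meaningless, not infinite.
* Scoring sizes in the shipped tests are kept small (tens to hundreds of
  synthetic records, full 61-codon enumeration, 199-point prior grids);
  every quantity involved is closed-form, so results are identical at any
  scale and the whole suite runs in seconds.

## Limitations

The calculus inherits the assumptions of the Bayesian classification
framework: a binary outcome per variant, a single gene-disease relationship,
evidence independence under odds multiplication, and no modelling of reduced
penetrance. Multi-category outcomes, splice/UTR/synonymous-effect
information, and the derivation of functional-score thresholds from raw
assay data are out of scope; evidence class assignment is an input. When the
true classification of variants is unknown, any information measure —
including this one — estimates certainty about the current probabilistic
summary, not distance to the truth.
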