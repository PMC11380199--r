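# maveinfo

Information-content scoring for clinical variant classification.

The clinical value of a multiplexed assay of variant effect (MAVE) is
usually reported as the number of variants reclassified from uncertain
significance (VUS). That metric discards most of what the assay measured:
evidence that sharpens — or legitimately un-sharpens — a classification
without moving it across a category boundary counts for nothing. `maveinfo`
implements an information-content framework that credits *all* of it, in
bits, for clinical laboratories, assay developers, and the committees that
calibrate classification guidelines.

## The core calculus

A variant's state of knowledge is its probability of pathogenicity *p*.
Its uncertainty is the binary Shannon entropy

    S(p) = −p·log2(p) − (1−p)·log2(1−p)

and its information content is `I(p) = 1 − S(p)`: 0 bits at p = 0.5, 1 bit
at p = 0 or 1. Evidence codes carry odds of pathogenicity under the
Bayesian ACMG/AMP framework (defaults: very strong 350, strong 18.7,
moderate 4.33, supporting 2.08; benign = reciprocals), combine as products,
and update a prior p₀ via

    p = O·p₀ / ((O−1)·p₀ + 1)

The information a MAVE adds to one variant is `I(after) − I(before)`; the
assay's score is the sum over all assayed variants. On top of this sit
gene-wide totals (every possible missense variant is one bit, counted by
enumerating single-nucleotide substitutions over the genetic code) and
audits of guideline rule changes across the full range of priors.

## Worked example

Two BRCA1 variants, both absent from population databases
(`PM2_supporting` baseline) at the standard 0.1 missense prior; the MAVE
calls one functionally normal (BS3) and one abnormal (PS3):

```r
library(maveinfo)
recs <- read_variant_table(system.file("extdata",
  "brca1_worked_variants.tsv", package = "maveinfo"))
variant_info_delta(recs)
#>   variant_id prior posterior_before posterior_after info_before info_after
#> 1  c.5120T>C   0.1        0.1877256      0.01220801   0.3033107  0.9049011
#> 2  c.5288G>T   0.1        0.1877256      0.81209287   0.3033107  0.3029272
#>      delta_bits
#> 1  0.6015904217
#> 2 -0.0003834164
```

The functionally normal variant gains ≈0.602 bits. The abnormal one swings
its posterior from 0.188 to 0.812 — a large probability change that lands
symmetrically about 0.5 — and gains ≈0.000 bits: no added certainty, which
is exactly what VUS-only counting cannot express.

Gene-wide total for TP53 from its canonical protein sequence:

```r
tp53 <- read_protein_fasta(system.file("extdata", "TP53_P04637.fasta",
                                       package = "maveinfo"))
gene_total_missense_bits(tp53[[1]], id = "TP53")
#> Gene missense information (TP53)
#>   residues            : 393 (protein counting)
#>   total missense bits : 2570.92 (~2571)
#>   mean per residue    : 6.542
```

So an assay yielding 160 bits has produced
`percent_information(160, 2571)` ≈ 6.2% of the gene's possible missense
information.

Whole-assay scoring, with relative and absolute (prior 0.5) accounting and
the conventional VUS-only figure for comparison, goes through
`mave_score()`; guideline analyses through `info_change_curve()` and
`rule_change_audit()`. A thin CLI over the same functions is installed at
`exec/maveinfo` (subcommands `score-variant`, `score-mave`, `gene-total`,
`rule-curve`, `simulate`). See the vignette
(`vignettes/information-content.Rmd`) for the model, parameter defaults,
and design decisions.

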