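brca1_records <- function() {
  data.frame(
    variant_id = c("c.5120T>C", "c.5288G>T"),
    gene = "BRCA1",
    baseline_codes = "PM2_supporting",
    mave_code = c("BS3", "PS3"),
    is_vus = TRUE,
    stringsAsFactors = FALSE
  )
}

tp53_map <- function() functional_class_map(normal = "BM", abnormal = "PS")

test_that("published BRCA1 worked examples reproduce", {
  res <- variant_info_delta(brca1_records())
  # functionally normal variant: benign evidence sharpens the classification
  expect_abs_equal(res$posterior_before[1], 0.188, tol = 5e-4)
  expect_abs_equal(res$info_before[1], 0.303, tol = 5e-4)
  expect_abs_equal(res$posterior_after[1], 0.012, tol = 5e-4)
  expect_abs_equal(res$info_after[1], 0.905, tol = 5e-4)
  expect_abs_equal(res$delta_bits[1], 0.602)
  # functionally abnormal variant: the posterior swings 0.188 -> 0.812 but
  # lands symmetrically about 0.5, so no information is gained
  expect_abs_equal(res$posterior_after[2], 0.812, tol = 5e-4)
  expect_abs_equal(res$info_after[2], 0.303, tol = 5e-4)
  expect_abs_equal(res$delta_bits[2], 0.000)
})

test_that("per-class TP53-style deltas match published values at both priors", {
  recs <- data.frame(
    variant_id = c("norm", "abn"),
    functional_class = c("normal", "abnormal")
  )
  rel <- variant_info_delta(recs, class_map = tp53_map())
  expect_abs_equal(rel$delta_bits, c(0.30, -0.44))
  recs$prior <- 0.5
  flat <- variant_info_delta(recs, class_map = tp53_map())
  expect_abs_equal(flat$delta_bits, c(0.30, 0.71))
})

test_that("delta invariants hold: identity with info difference, zero cases", {
  res <- variant_info_delta(brca1_records())
  expect_equal(res$delta_bits, res$info_after - res$info_before,
               tolerance = 1e-12)
  expect_true(all(abs(res$delta_bits) <= 1))
  # odds-1 MAVE evidence (intermediate class mapped to "none") adds nothing
  recs <- data.frame(variant_id = "x", functional_class = "intermediate",
                     baseline_codes = "PM2")
  expect_identical(
    variant_info_delta(recs, class_map = tp53_map())$delta_bits, 0
  )
  # degenerate 0/1 priors are flagged and contribute exactly 0
  recs2 <- data.frame(variant_id = c("a", "b"), prior = c(0, 1),
                      mave_code = "PS3")
  expect_warning(res2 <- variant_info_delta(recs2), "prior 0 or 1")
  expect_identical(res2$delta_bits, c(0, 0))
})

test_that("records without resolvable MAVE evidence fail clearly", {
  recs <- data.frame(variant_id = "v", functional_class = "normal")
  expect_error(variant_info_delta(recs), "functional_class_map")
  expect_error(variant_info_delta(data.frame(variant_id = "v")),
               "mave_code|functional_class")
  expect_error(
    variant_info_delta(data.frame(variant_id = "v", mave_code = "ZZ9")),
    "Unknown evidence code"
  )
  expect_error(mave_score(data.frame()), "non-empty")
})

test_that("scores are additive, permutation-invariant, and scale with copies", {
  spec <- synthetic_mave_spec(n_normal = 30, n_intermediate = 10,
                              n_abnormal = 20,
                              baseline_code_frequency = c(PM2_supporting = 0.5),
                              seed = 202)
  tab <- generate_synthetic_mave(spec)
  map <- tp53_map()
  whole <- mave_score(tab, class_map = map)
  first <- mave_score(tab[1:25, ], class_map = map)
  rest <- mave_score(tab[26:60, ], class_map = map)
  expect_equal(whole$relative_bits, first$relative_bits + rest$relative_bits,
               tolerance = 1e-9)
  expect_equal(whole$absolute_bits, first$absolute_bits + rest$absolute_bits,
               tolerance = 1e-9)
  shuffled <- mave_score(tab[sample(nrow(tab)), ], class_map = map)
  expect_equal(shuffled$relative_bits, whole$relative_bits, tolerance = 1e-12)
  expect_equal(shuffled$vus_only_bits, whole$vus_only_bits, tolerance = 1e-12)
  k <- 3L
  stacked <- mave_score(tab[rep(seq_len(nrow(tab)), k), ], class_map = map)
  expect_equal(stacked$relative_bits, k * whole$relative_bits,
               tolerance = 1e-9)
})

test_that("report totals equal per-variant sums and absolute mode is non-negative", {
  spec <- synthetic_mave_spec(n_normal = 40, n_intermediate = 5,
                              n_abnormal = 55,
                              baseline_code_frequency = c(
                                PM2_supporting = 0.4, PP3 = 0.3, BP4 = 0.2
                              ),
                              seed = 7)
  tab <- generate_synthetic_mave(spec)
  rep_rel <- mave_score(tab, class_map = tp53_map())
  expect_equal(rep_rel$total_bits, sum(rep_rel$per_variant$delta_bits),
               tolerance = 1e-9)
  expect_equal(rep_rel$n_variants, 100L)
  # relative deltas can be negative; absolute contributions never are
  expect_true(any(rep_rel$per_variant$delta_bits < 0))
  expect_true(all(rep_rel$per_variant$absolute_bits >= 0))
  rep_abs <- mave_score(tab, class_map = tp53_map(), mode = "absolute")
  expect_equal(rep_abs$total_bits, rep_abs$absolute_bits)
  expect_gte(rep_abs$total_bits, 0)
})

test_that("per-variant deltas agree with a brute-force oracle on 100 synthetic records", {
  spec <- synthetic_mave_spec(n_normal = 50, n_intermediate = 10,
                              n_abnormal = 40,
                              baseline_code_frequency = c(
                                PM2_supporting = 0.5, BP4 = 0.25
                              ),
                              seed = 909)
  tab <- generate_synthetic_mave(spec)
  report <- mave_score(tab, class_map = tp53_map())
  class_odds <- c(normal = 1 / oracle_default_odds[["moderate"]],
                  intermediate = 1,
                  abnormal = oracle_default_odds[["strong"]])
  base_odds <- vapply(tab$baseline_codes, function(x) {
    if (is.na(x)) return(1)
    codes <- strsplit(x, ";")[[1]]
    prod(vapply(codes, function(cd) {
      switch(cd,
             PM2_supporting = oracle_default_odds[["supporting"]],
             PP3 = oracle_default_odds[["supporting"]],
             BP4 = 1 / oracle_default_odds[["supporting"]],
             stop("unexpected code in fixture"))
    }, numeric(1)))
  }, numeric(1))
  expected <- sum(oracle_record_delta(tab$prior, base_odds,
                                      class_odds[tab$functional_class]))
  expect_equal(report$total_bits, expected, tolerance = 1e-9)
})

test_that("VUS-only accounting counts only reclassifying VUS records", {
  recs <- data.frame(
    variant_id = c("reclass", "stays_vus", "not_vus"),
    baseline_codes = c(NA, "PM2_supporting", NA),
    mave_code = c("BS3", "PS3", "BS3"),
    is_vus = c(TRUE, TRUE, FALSE)
  )
  report <- mave_score(recs)
  # only the first record is a VUS whose posterior leaves (0.10, 0.90)
  expect_equal(report$vus_only_bits, report$per_variant$delta_bits[1],
               tolerance = 1e-12)
  expect_lte(report$per_variant$posterior_after[1], 0.10)
  expect_gt(report$per_variant$posterior_after[2], 0.10)
})

test_that("multi-nucleotide substitutions are excluded when flagged", {
  recs <- data.frame(
    variant_id = c("a", "b", "c"),
    mave_code = "PS3",
    single_substitution = c(TRUE, FALSE, NA)
  )
  expect_message(report <- mave_score(recs), "more than one nucleotide")
  expect_equal(report$n_variants, 2L)
  expect_equal(report$n_excluded, 1L)
})

test_that("fold increase reproduces published ratios and guards zero", {
  expect_abs_equal(fold_increase(813.2, 36.9), 22.0, tol = 0.1)
  expect_abs_equal(fold_increase(893.6, 10.5), 85.1, tol = 0.2)
  expect_abs_equal(fold_increase(160, 46.3), 3.5, tol = 0.05)
  expect_identical(fold_increase(7.7, 7.7), 1)
  expect_warning(out <- fold_increase(10, 0), "not computable")
  expect_true(is.na(out))
})
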