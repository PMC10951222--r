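test_that("RNA QC counts detected genes against the threshold", {
  expect_false(rna_qc_filter(c(rep(1, 7999), rep(0, 100))))
  expect_true(rna_qc_filter(rep(1, 8000)))
  expect_true(rna_qc_filter(rep(1, 150), min_genes = 100))
})

test_that("upper-quartile normalization is scale invariant and rank preserving", {
  set.seed(2)
  base <- matrix(runif(60, 0, 10), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  # sample 2 = sample 1 scaled by a global factor on the TPM scale
  tpm <- 2^base - 1
  tpm[, 2] <- tpm[, 1] * 7
  mat <- log2(tpm + 1)
  norm <- upper_quartile_normalize(mat)
  expect_equal(norm[, 1], norm[, 2], ignore_attr = TRUE)
  # ranks within a sample are unchanged
  expect_equal(order(norm[, 3]), order(mat[, 3]))
  # hand-computed 3-gene check
  toy <- matrix(log2(c(1, 3, 7) + 1), nrow = 3,
                dimnames = list(c("a", "b", "c"), "s"))
  nt <- upper_quartile_normalize(toy, target = 10)
  uq <- quantile(c(1, 3, 7), 0.75, names = FALSE)
  expect_equal(nt[, 1], log2(c(1, 3, 7) * 10 / uq + 1),
               ignore_attr = TRUE)
  # sample already at the target is unchanged
  at_target <- matrix(log2(c(500, 1000, 2000) + 1), nrow = 3,
                      dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(upper_quartile_normalize(at_target, target = 1500)[, 1],
               at_target[, 1], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(upper_quartile_normalize(
    matrix(0, 2, 1, dimnames = list(c("a", "b"), "s"))), "all-zero")
})

test_that("enrichment score is extremal when the set tops the ranking", {
  vals <- setNames(10:1, paste0("g", 1:10))
  top <- ssgsea_score(vals, c("g1", "g2", "g3"))
  # every other placement of a 3-gene set scores lower
  others <- combn(names(vals), 3, function(gs)
    ssgsea_score(vals, gs), simplify = TRUE)
  expect_equal(max(others), top)
  expect_equal(sum(others == top), 1)
})

test_that("enrichment score is invariant to monotone transforms", {
  set.seed(3)
  vals <- setNames(rnorm(30), paste0("g", 1:30))
  gs <- sample(names(vals), 8)
  es1 <- ssgsea_score(vals, gs)
  expect_equal(ssgsea_score(2^vals, gs), es1)
  expect_equal(ssgsea_score(rank(vals), gs), es1)
  expect_error(ssgsea_score(vals, "absent"), "intersect")
  expect_error(ssgsea_score(vals, names(vals)), "whole universe")
})

test_that("unweighted enrichment matches exhaustive hand enumeration", {
  # 5-gene universe, set {g1, g3} at exponent 0: the running difference is
  # fully determined by the rank positions; enumerate by hand
  vals <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  # positions of set genes: 1 and 3; p_in steps 1/2 at pos 1 and 3,
  # p_out steps 1/3 at pos 2, 4, 5
  p_in <- c(1 / 2, 1 / 2, 1, 1, 1)
  p_out <- c(0, 1 / 3, 1 / 3, 2 / 3, 1)
  expect_equal(ssgsea_score(vals, c("g1", "g3"), exponent = 0),
               sum(p_in - p_out))
})

test_that("range-normalized scores keep ratios and warn on zero range", {
  expect_equal(unname(normalize_es(c(1, 2, 4))), c(1, 2, 4) / 3)
  # doubling es doubles the range too: nes unchanged
  expect_equal(normalize_es(c(1, 2, 4) * 2), normalize_es(c(1, 2, 4)),
               ignore_attr = TRUE)
  expect_warning(z <- normalize_es(c(3, 3, 3)), "zero range")
  expect_equal(unname(z), c(0, 0, 0))
  m <- matrix(c(1, 2, 4, 1, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_warning(nm <- normalize_es(m), "zero range")
  expect_equal(nm["a", ], c(1, 2, 4) / 3, ignore_attr = TRUE)
})

test_that("reference quantile categories use ties-inclusive boundaries", {
  ref <- structure(list(
    gene_quantiles = matrix(c(10, 25, 75, 90), nrow = 1,
                            dimnames = list("G1",
                                            c("p10", "p25", "p75", "p90"))),
    signature_quantiles = NULL), class = "reference_cohort")
  expect_equal(reference_quantile_category(75, "G1", ref), "high_quartile")
  expect_equal(reference_quantile_category(90, "G1", ref), "high_decile")
  expect_equal(reference_quantile_category(9, "G1", ref), "low_decile")
  expect_equal(reference_quantile_category(10, "G1", ref), "low_decile")
  expect_equal(reference_quantile_category(25, "G1", ref), "low_quartile")
  expect_equal(reference_quantile_category(50, "G1", ref), "mid")
  expect_equal(reference_quantile_category(80, "G1", ref), "high_quartile")
  expect_error(reference_quantile_category(1, "G2", ref), "unknown feature")
})

test_that("quantile bins partition the reference itself as expected", {
  set.seed(12)
  # enough genes per sample that per-sample normalization creates no exact
  # ties at the quartile boundaries
  mat <- matrix(runif(40 * 50, 1, 10), nrow = 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  ref <- reference_cohort(mat, rep(c("HR+/HER2-", "HR-/HER2-"), 20))
  for (g in rownames(mat)[1:5]) {
    cats <- vapply(seq_len(40), function(j)
      reference_quantile_category(ref$expression[g, j], g, ref),
      character(1))
    tab <- table(factor(cats, levels = c("low_decile", "low_quartile",
                                         "mid", "high_quartile",
                                         "high_decile")))
    expect_true(abs(tab[["high_decile"]] - 4) <= 1)
    expect_true(abs(tab[["low_decile"]] - 4) <= 1)
    expect_true(abs(tab[["high_decile"]] + tab[["high_quartile"]] - 10) <= 1)
    expect_true(abs(tab[["low_decile"]] + tab[["low_quartile"]] - 10) <= 1)
  }
})

test_that("balanced resampling hits the target ER ratio deterministically", {
  mat <- matrix(runif(2 * 133), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("s", 1:133)))
  status <- rep(c("HR+/HER2-", "HR-/HER2-"), c(84, 49))
  ref <- reference_cohort(mat, status)
  idx1 <- balanced_resample(ref, 0.64, seed = 42)
  idx2 <- balanced_resample(ref, 0.64, seed = 42)
  expect_identical(idx1, idx2)
  frac <- mean(startsWith(status[idx1], "HR+"))
  expect_lte(abs(frac - 0.64), 1 / 133)
  # exact split when both classes are large enough
  mat2 <- matrix(runif(2 * 200), nrow = 2,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:200)))
  ref2 <- reference_cohort(mat2, rep(c("HR+/HER2-", "HR-/HER2-"), each = 100))
  idx <- balanced_resample(ref2, 0.5, seed = 1, n_out = 100)
  expect_equal(sum(startsWith(rep(c("HR+/HER2-", "HR-/HER2-"),
                                  each = 100)[idx], "HR+")), 50)
  ref_bad <- reference_cohort(mat2, rep("HR+/HER2-", 200))
  expect_error(balanced_resample(ref_bad), "both ER classes")
})

test_that("subtype assignment self-classifies centroids and respects NC", {
  cents <- synthetic_pam50_centroids()
  set.seed(6)
  mat <- matrix(runif(50 * 30, 4, 8), nrow = 50,
                dimnames = list(pam50_genes(), paste0("s", 1:30)))
  ref <- reference_cohort(mat, rep(c("HR+/HER2-", "HR-/HER2-"), 15))
  med <- apply(ref$expression[pam50_genes(), ], 1, median)
  for (st in colnames(cents)) {
    v <- med + cents[, st]
    names(v) <- pam50_genes()
    r <- pam50_assign(v, cents, ref)
    expect_equal(r$subtype, st)
    expect_equal(max(r$correlations), r$correlations[[st]])
  }
  # monotone transform of the profile leaves the call unchanged
  v <- med + cents[, "Basal"]; names(v) <- pam50_genes()
  r1 <- pam50_assign(v, cents, ref)
  # rank-preserving perturbation: add a tiny epsilon scaled by rank
  v2 <- v + rank(v) * 1e-9
  r2 <- pam50_assign(v2, cents, ref)
  expect_equal(r1$subtype, r2$subtype)
  # a flat profile correlates with nothing
  flat <- setNames(med, pam50_genes())
  expect_equal(pam50_assign(flat, cents, ref)$subtype, "NC")
  # too many missing centroid genes is an error, few is a warning
  expect_error(pam50_assign(v[1:40], cents, ref), "missing")
  expect_warning(r3 <- pam50_assign(v[1:47], cents, ref), "missing")
  expect_equal(r3$subtype, "Basal")
})

test_that("combined signature activity is the mean and is symmetric", {
  expect_equal(combine_signature_activity(c(0.2, 0.4)), 0.3)
  expect_equal(combine_signature_activity(0.7), 0.7)
  expect_equal(combine_signature_activity(c(1, 2, 3)),
               combine_signature_activity(c(3, 1, 2)))
})
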