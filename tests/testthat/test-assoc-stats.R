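test_that("auc_score counts pairs with ties at half weight", {
  a <- auc_score(c(3, 2, 1), c(TRUE, FALSE, FALSE))
  expect_equal(a$auc, 1)
  expect_equal(a$u, 2)
  # perfect separation 6 vs 6
  a <- auc_score(c(7:12, 1:6), rep(c(TRUE, FALSE), each = 6))
  expect_equal(a$auc, 1)
  expect_equal(a$u, 36)
  # all tied -> 0.5
  expect_equal(auc_score(rep(1, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  # random vectors agree with the explicit pair count
  set.seed(11)
  for (i in 1:20) {
    s <- sample(20, 12, replace = TRUE)
    l <- sample(c(TRUE, FALSE), 12, replace = TRUE, prob = c(.5, .5))
    if (length(unique(l)) < 2) next
    pairs <- outer(s[l], s[!l], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc_score(s, l)$u, sum(pairs))
  }
  expect_error(auc_score(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("auc flips to 1 - auc when labels flip", {
  set.seed(4)
  for (i in 1:10) {
    s <- rnorm(10)
    l <- rep(c(TRUE, FALSE), c(4, 6))
    expect_equal(auc_score(s, l)$auc, 1 - auc_score(s, !l)$auc)
  }
})

test_that("exact MW tail matches the reference distribution and brute force", {
  # frozen exact values
  expect_equal(mw_exact_one_sided_p(36, 6, 6)$p, 1 / 924)
  expect_equal(mw_exact_one_sided_p(31, 6, 6)$p, 19 / 924)
  expect_equal(mw_exact_one_sided_p(26, 3, 9)$p, 2 / 220)
  expect_equal(mw_exact_one_sided_p(0, 5, 7)$p, 1.0)
  # agreement with R's exact wilcoxon distribution over a size sweep
  for (sz in list(c(3, 4), c(5, 5), c(2, 9), c(7, 6))) {
    m <- sz[1]; n <- sz[2]
    for (u in 0:(m * n)) {
      expect_equal(mw_exact_one_sided_p(u, m, n)$p,
                   1 - pwilcox(u - 1, m, n), tolerance = 1e-12)
    }
  }
  # brute-force enumeration on a small case
  expect_equal(mw_exact_one_sided_p(10, 3, 5)$p, mw_brute_p(10, 3, 5))
})

test_that("MW null distribution is symmetric", {
  for (sz in list(c(4, 4), c(3, 8), c(6, 6))) {
    m <- sz[1]; n <- sz[2]
    counts <- resistscape:::mw_null_counts(m, n)
    expect_equal(counts, rev(counts))
    expect_equal(sum(counts), choose(m + n, m))
  }
})

test_that("half-integer U and large samples fall back to approximation", {
  r <- mw_exact_one_sided_p(17.5, 5, 7)
  expect_true(r$approximate)
  expect_true(r$p > 0 && r$p <= 1)
  r <- mw_exact_one_sided_p(300, 20, 20)
  expect_true(r$approximate)
})

test_that("exact MW test keeps type-I error at or below nominal level", {
  # labels independent of scores: empirical rejection rate at alpha = 0.05
  set.seed(271)
  m <- 5; n <- 7
  rejections <- 0
  reps <- 10000
  for (i in seq_len(reps)) {
    lab <- sample(rep(c(TRUE, FALSE), c(m, n)))
    s <- seq_len(m + n) # fixed distinct scores, labels permuted
    a <- auc_score(s, lab)
    if (mw_exact_one_sided_p(a$u, m, n)$p <= 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_lte(rejections / reps, 0.05)
})

test_that("two-sided Fisher matches the exhaustive hypergeometric sum", {
  expect_equal(fisher_two_sided(matrix(c(6, 0, 0, 6), 2))$p, 2 / 924)
  expect_equal(fisher_two_sided(matrix(c(3, 1, 0, 8), 2))$p, 4 / 220)
  expect_equal(fisher_two_sided(matrix(c(1, 1, 1, 1), 2))$p, 1.0)
  expect_warning(p <- fisher_two_sided(matrix(c(0, 0, 3, 4), 2))$p,
                 "empty margin")
  expect_equal(p, 1.0)
  set.seed(5)
  for (i in 1:30) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_two_sided(tab)$p, fisher_brute_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("Welch test matches hand computation and behaves monotonically", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 6, 10)
  # hand-computed Welch statistic
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  r <- welch_two_sided(a, b)
  expect_equal(r$t, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df_hand))
  # identical groups
  r0 <- welch_two_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p, 1, tolerance = 1e-12)
  expect_equal(abs(r0$t), 0)
  # p decreases as the shift grows
  base <- c(0, 0.1, 0.2, 0.3)
  ps <- vapply(c(1, 2, 4, 8), function(d)
    welch_two_sided(base, base + d)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("signature screen ranks a benefit-coupled set first", {
  set.seed(9)
  n <- 15
  benefit <- rep(c(TRUE, FALSE), c(3, 12))
  scores <- matrix(rnorm(5 * n, 0, 0.3), nrow = 5,
                   dimnames = list(paste0("SET", 1:5), NULL))
  scores["SET3", benefit] <- scores["SET3", benefit] + 2
  out <- hallmark_screen(scores, benefit)
  expect_equal(out$set[1], "SET3")
  expect_true(all(c("welch_p", "fisher_p", "bh_welch_p") %in% names(out)))
  # single signature -> table of length 1
  one <- hallmark_screen(scores[1, , drop = FALSE], benefit)
  expect_equal(nrow(one), 1)
  # shuffled labels should not systematically favor the planted set
  set.seed(10)
  ranks <- replicate(20, {
    which(hallmark_screen(scores, sample(benefit))$set == "SET3")
  })
  expect_true(mean(ranks) > 1.5)
})

test_that("trial metrics reproduce benefit and control proportions", {
  clin <- data.frame(
    best_response = c(rep("SD", 18), rep("PD", 8), rep("SD", 6)),
    response_duration_weeks = c(rep(30, 6), rep(14, 12), rep(4, 8),
                                rep(8, 6)))
  m <- trial_metrics(clin)
  expect_equal(m$n, 32)
  expect_equal(m$cbr, 18.8)
  expect_equal(m$dcr, 56.3)
  expect_equal(m$orr, 0)
  # all progressive disease
  pd <- data.frame(best_response = rep("PD", 5),
                   response_duration_weeks = rep(2, 5))
  m0 <- trial_metrics(pd)
  expect_equal(c(m0$cbr, m0$dcr, m0$orr), c(0, 0, 0))
  # missing responses stay in the denominator, flagged
  miss <- data.frame(best_response = c("PR", NA),
                     response_duration_weeks = c(30, NA))
  expect_warning(mm <- trial_metrics(miss), "missing")
  expect_equal(mm$orr, 50)
})
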