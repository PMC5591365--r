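test_that("major complications are strictly above Clavien-Dindo 3a", {
  expect_equal(is_major_complication(c("none", "1", "2", "3a", "3b", "4a", "4b", "5")),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_error(is_major_complication("3c"), "unknown Clavien-Dindo")
})

test_that("crosstab orders labels deterministically and rejects missing data", {
  co <- reference_outcome_cohort()
  tab <- crosstab(co, "complexity", "complete_resection")
  expect_equal(rownames(tab), c("low", "moderate", "high"))
  expect_equal(unname(rowSums(tab)), c(14, 45, 29))
  expect_equal(unname(tab[, "1"]), c(7, 7, 1))
  co$complete_resection[3] <- NA
  expect_error(crosstab(co, "complexity", "complete_resection"), "P003")
  expect_error(crosstab(co[0, ], "complexity", "complete_resection"), "empty")
  one <- crosstab(co[1, ], "complexity", "major_complication")
  expect_equal(sum(one), 1)
})

test_that("pearson_chi2 matches the 2x2 closed form and handles edge cases", {
  set.seed(21)
  for (rep in 1:10) {
    t2 <- matrix(sample(1:40, 4, replace = TRUE), 2)
    a <- t2[1, 1]; b <- t2[1, 2]; c <- t2[2, 1]; d <- t2[2, 2]
    n <- sum(t2)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2(t2)$statistic, closed, tolerance = 1e-12)
  }
  # proportional rows: observed equals expected, statistic 0, p = 1
  prop <- rbind(c(10, 20, 30), c(1, 2, 3))
  r <- pearson_chi2(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  expect_equal(r$df, 2L)
  # invariance under permutation and transposition
  t3 <- matrix(c(5, 9, 2, 14, 3, 8), 2)
  expect_equal(pearson_chi2(t3)$statistic,
               pearson_chi2(t3[, c(3, 1, 2)])$statistic)
  expect_equal(pearson_chi2(t3)$statistic, pearson_chi2(t(t3))$statistic)
  # degenerate and empty structures are rejected
  expect_error(pearson_chi2(matrix(0, 2, 2)), "grand total 0")
  expect_error(pearson_chi2(matrix(c(3, 4), 1)), "degenerate")
  expect_warning(pearson_chi2(rbind(c(3, 4), c(0, 0), c(5, 1))), "all-zero")
  # low expected counts flagged, not refused
  expect_true(pearson_chi2(rbind(c(1, 2), c(2, 1)))$warning_low_expected)
  expect_false(pearson_chi2(rbind(c(20, 20), c(20, 20)))$warning_low_expected)
})

test_that("pearson_chi2 p-value agrees with a permutation oracle on a 2x2", {
  tab <- rbind(c(12, 5), c(6, 14))
  r <- pearson_chi2(tab)
  # condition on margins: permute column labels over subjects
  set.seed(8)
  rows <- rep(1:2, rowSums(tab))
  cols <- rep(rep(1:2, 2), as.vector(t(tab)))
  nrep <- 20000L
  stat1 <- r$statistic
  n <- sum(tab)
  chi2_2x2 <- function(a, b, c, d) # closed form, validated above
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  hits <- 0L
  for (i in seq_len(nrep)) {
    cp <- sample(cols)
    a <- sum(rows == 1 & cp == 1); b <- sum(rows == 1 & cp == 2)
    c <- sum(rows == 2 & cp == 1); d <- sum(rows == 2 & cp == 2)
    hits <- hits + (chi2_2x2(a, b, c, d) >= stat1 - 1e-9)
  }
  p_mc <- hits / nrep
  se_mc <- sqrt(p_mc * (1 - p_mc) / nrep)
  # asymptotic and exact-permutation p differ; 3 MC errors plus the
  # chi-square approximation slack at n = 37
  expect_lt(abs(r$p - p_mc), 3 * se_mc + 0.02)
})

test_that("cohens_kappa matches its definition and known fixed points", {
  diag3 <- diag(c(10, 7, 3))
  k1 <- cohens_kappa(diag3)
  expect_equal(k1$kappa, 1)
  # outer product of margins: agreement is exactly chance, kappa 0
  indep <- matrix(c(4, 4, 4, 4), 2)
  expect_equal(cohens_kappa(indep)$kappa, 0)
  set.seed(17)
  for (rep in 1:10) {
    tab <- matrix(sample(0:15, 9, replace = TRUE), 3)
    if (sum(tab) < 2) next
    n <- sum(tab); p <- tab / n
    p_o <- sum(diag(p)); p_e <- sum(rowSums(p) * colSums(p))
    expect_equal(cohens_kappa(tab)$kappa, (p_o - p_e) / (1 - p_e),
                 tolerance = 1e-12)
  }
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
  # degenerate margins: kappa undefined, reported as NA
  expect_true(is.na(cohens_kappa(matrix(c(5, 0, 0, 0), 2))$kappa))
})

test_that("kappa agrees with the independent e1071 implementation", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (rep in 1:5) {
    tab <- matrix(sample(1:20, 16, replace = TRUE), 4)
    expect_equal(cohens_kappa(tab)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
  }
})

test_that("kappa is invariant under identical relabelling of both raters", {
  tab <- matrix(c(11, 2, 1, 3, 9, 2, 0, 4, 8), 3)
  perm <- c(3, 1, 2)
  expect_equal(cohens_kappa(tab[perm, perm])$kappa, cohens_kappa(tab)$kappa)
  expect_equal(cohens_kappa(tab[perm, perm])$se, cohens_kappa(tab)$se)
})

test_that("asymptotic kappa SE is close to a bootstrap standard deviation", {
  tab <- matrix(c(20, 5, 3, 4, 16, 6, 2, 3, 18), 3)
  r <- cohens_kappa(tab)
  n <- sum(tab)
  # resample subjects with replacement from the paired ratings
  pairs <- cbind(rep(rep(1:3, 3), as.vector(tab)),
                 rep(1:3, colSums(matrix(as.vector(tab), 3))))
  idx <- rep(seq_len(n))
  set.seed(19)
  boots <- replicate(10000, {
    s <- sample(n, n, replace = TRUE)
    tt <- table(factor(pairs[s, 1], 1:3), factor(pairs[s, 2], 1:3))
    cohens_kappa(tt)$kappa
  })
  expect_lt(abs(r$se - sd(boots)) / sd(boots), 0.10)
  # the simple formula is the advertised alternative
  simple <- cohens_kappa(tab, se_formula = "simple")
  expect_equal(simple$se,
               sqrt(r$p_o * (1 - r$p_o) / (n * (1 - r$p_e)^2)))
})

test_that("feature and grade summaries reproduce their printed-count identities", {
  co <- reference_feature_cohort()
  fs <- summarize_features(co)
  expect_equal(fs$n_present + fs$n_absent, rep(88L, 5))
  # every percentage is its count over the total, rounded half-up to 1 dp
  expect_equal(fs$pct_present,
               floor(100 * fs$n_present / fs$total * 10 + 0.5) / 10)
  one <- co[1, ]; one[flag_names()] <- 1L
  expect_equal(summarize_features(one)$pct_present, rep(100, 5))
  zero <- co[1:4, ]; zero[flag_names()] <- 0L
  expect_equal(summarize_features(zero)$pct_present, rep(0, 5))

  gs <- summarize_grades(reference_outcome_cohort())
  expect_equal(gs$complexity, c("low", "moderate", "high", "overall"))
  expect_equal(gs$n, c(14, 45, 29, 88))
  expect_equal(gs$pct_complete_resection,
               floor(100 * gs$n_complete_resection / gs$n * 10 + 0.5) / 10)
  # derivation of major status from Clavien-Dindo matches the indicator
  co2 <- reference_outcome_cohort()
  gs2 <- summarize_grades(co2[setdiff(names(co2), "major_complication")])
  expect_equal(gs2$n_major_complication, gs$n_major_complication)
})

test_that("percentages round half-up, not half-even", {
  co <- reference_feature_cohort()[1:8, ]
  co[flag_names()] <- 0L
  co$periventricular[1] <- 1L # 1/8 = 12.5% stays 12.5
  co$eloquent[1:7] <- 1L      # 7/8 = 87.5
  fs <- summarize_features(co)
  expect_equal(fs$pct_present[fs$feature == "periventricular"], 12.5)
  # 0.05 boundaries go up: 4.45 -> 4.5 would be half-even-ambiguous;
  # construct 1/16 on a 16-patient cohort: 6.25 -> 6.3 under half-up
  co16 <- reference_feature_cohort()[1:16, ]
  co16[flag_names()] <- 0L
  co16$large[1] <- 1L
  expect_equal(summarize_features(co16)$pct_present[4], 6.3)
})
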