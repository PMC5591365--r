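test_that("phantom ground truth is recovered exactly on commanded examples", {
  p <- make_phantom(phantom_spec(c(25, 15, 10), oedema_thickness_mm = 15,
                                 ventricle_gap_mm = 12))
  f <- extract_features(p$tumour, p$oedema, p$atlas)
  expect_equal(f$ventricle_distance_mm, 12)
  expect_equal(f$max_diameter_mm, 50)
  expect_equal(f$oedema_extension_mm, 15)
  # commanded overlap gives zero ventricle distance
  p2 <- make_phantom(phantom_spec(c(10, 8, 6), ventricle_gap_mm = -5))
  expect_equal(p2$truth$ventricle_distance_mm, 0)
  f2 <- extract_features(p2$tumour, p2$oedema, p2$atlas)
  expect_equal(f2$ventricle_distance_mm, 0)
  # unilateral phantom stays on one side of the midline
  expect_false(f$bilateral)
})

test_that("a randomised phantom suite is recovered within one voxel diagonal", {
  tol <- sqrt(3) # 1 mm isotropic
  for (seed in 1:12) {
    spec <- random_phantom_spec(seed)
    p <- make_phantom(spec)
    f <- extract_features(p$tumour, p$oedema, p$atlas)
    g <- p$truth
    expect_lt(abs(f$ventricle_distance_mm - g$ventricle_distance_mm), tol)
    expect_lt(abs(f$max_diameter_mm - g$max_diameter_mm), tol)
    expect_lt(abs(f$oedema_extension_mm - g$oedema_extension_mm), tol)
    expect_identical(f$corpus_callosum_involved, g$corpus_callosum_involved)
    expect_identical(f$bilateral, g$bilateral)
    expect_identical(f$eloquent_involved, g$eloquent_involved)
  }
})

test_that("a phantom that cannot fit its grid is rejected", {
  expect_error(phantom_spec(c(30, 20, 15), oedema_thickness_mm = 20,
                            grid_shape = c(20, 20, 20)), "too small")
  expect_error(phantom_spec(c(-3, 5, 5)), "positive")
})

test_that("simulate_cohort is seed-reproducible and distinct across seeds", {
  p <- cohort_sim_params()
  a <- simulate_cohort(p, seed = 42)
  b <- simulate_cohort(p, seed = 42)
  attr(a, "seed") <- NULL; attr(b, "seed") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(p, seed = 43)
  expect_false(identical(a[flag_names()], c2[flag_names()]))
  expect_equal(nrow(a), 88L)
  expect_equal(a$score, as.integer(rowSums(a[flag_names()])))
})

test_that("zero prevalences force every patient to score 0, low complexity", {
  p <- cohort_sim_params(n = 30, feature_prevalences = rep(0, 5))
  co <- simulate_cohort(p, seed = 1)
  expect_true(all(co$score == 0L))
  expect_true(all(co$complexity == "low"))
})

test_that("simulated prevalences and class frequencies match enumeration", {
  p <- cohort_sim_params(n = 20000L)
  co <- simulate_cohort(p, seed = 7)
  pr <- p$feature_prevalences
  for (f in flag_names()) {
    se <- sqrt(pr[[f]] * (1 - pr[[f]]) / p$n)
    expect_lt(abs(mean(co[[f]]) - pr[[f]]), 4 * se)
  }
  want <- enumerate_class_distribution(pr)
  got <- table(co$complexity) / p$n
  for (cl in complexity_levels()) {
    se <- sqrt(want[[cl]] * (1 - want[[cl]]) / p$n)
    expect_lt(abs(got[[cl]] - want[[cl]]), 4 * se)
  }
  # enumeration itself sums to one and matches a direct small check
  expect_equal(sum(want), 1)
  expect_equal(unname(enumerate_class_distribution(rep(0, 5))), c(1, 0, 0))
  expect_equal(unname(enumerate_class_distribution(rep(1, 5))), c(0, 0, 1))
})

test_that("class-conditional outcome rates are recovered in large samples", {
  p <- cohort_sim_params(n = 10000L)
  co <- simulate_cohort(p, seed = 11)
  for (cl in complexity_levels()) {
    sel <- co$complexity == cl
    n_cl <- sum(sel)
    p_res <- p$resection_prob_by_class[[cl]]
    se <- sqrt(max(p_res * (1 - p_res), 1e-4) / n_cl)
    expect_lt(abs(mean(co$complete_resection[sel]) - p_res), 4 * se)
  }
  # Clavien-Dindo is consistent with the major-complication indicator
  expect_equal(is_major_complication(co$clavien_dindo),
               co$major_complication == 1)
})

test_that("a Gaussian-copula dependence matrix induces flag correlation", {
  dep <- diag(5); dep[1, 2] <- dep[2, 1] <- 0.8
  p <- cohort_sim_params(n = 20000L, dependence = dep)
  co <- simulate_cohort(p, seed = 5)
  # marginals preserved
  expect_lt(abs(mean(co$periventricular) - 68 / 88), 0.02)
  r <- cor(co$periventricular, co$callosal_or_bilateral)
  expect_gt(r, 0.3)
  indep <- simulate_cohort(cohort_sim_params(n = 20000L), seed = 5)
  expect_lt(abs(cor(indep$periventricular, indep$callosal_or_bilateral)), 0.03)
  bad <- dep; bad[1, 2] <- 2
  expect_error(cohort_sim_params(dependence = bad), "positive semi-definite|symmetric")
})

test_that("a noiseless second rater agrees perfectly; kappa falls with noise", {
  co <- simulate_cohort(cohort_sim_params(n = 500L), seed = 9)
  r0 <- rater_agreement(simulate_second_rater(co, 0, seed = 2))
  expect_equal(r0$kappa, 1)
  big <- simulate_cohort(cohort_sim_params(n = 20000L), seed = 10)
  eps_grid <- c(0.05, 0.15, 0.30, 0.5)
  kappas <- vapply(eps_grid, function(e)
    rater_agreement(simulate_second_rater(big, e, seed = 3))$kappa, 0)
  expect_true(all(diff(kappas) < 0))
  # at eps = 0.5 rater 2 is independent of rater 1: kappa near zero
  expect_lt(abs(kappas[length(kappas)]), 0.05)
  expect_error(simulate_second_rater(co, 0.6), "epsilon")
})

test_that("score-scale agreement is also available", {
  co <- simulate_second_rater(simulate_cohort(cohort_sim_params(n = 300L), 4),
                              0.1, seed = 5)
  ks <- rater_agreement(co, scale = "score")
  kc <- rater_agreement(co, scale = "class")
  expect_true(ks$kappa <= 1 && ks$kappa >= -1)
  expect_equal(ks$n, 300L)
  expect_equal(kc$n, 300L)
})
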