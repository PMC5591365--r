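#' Parameters for simulating a graded cohort
#'
#' Defaults reproduce the study conditions of the original validation
#' cohort: 88 patients; adverse-feature prevalences 68/88, 29/88, 38/88,
#' 62/88, 61/88 (periventricular, callosal-or-bilateral, eloquent, large,
#' oedema); class-conditional complete-resection probabilities 7/14, 7/45,
#' 1/29 and major-complication probabilities 0/14, 1/45, 2/29 for
#' low/moderate/high complexity.
#'
#' @param n cohort size.
#' @param feature_prevalences named (or ordered as [flag_names()]) numeric
#'   vector of five probabilities.
#' @param resection_prob_by_class,major_complication_prob_by_class numeric
#'   length-3 probabilities for classes low, moderate, high.
#' @param rater_flip_prob probability that the simulated second rater
#'   flips each feature flag, in `[0, 0.5]`.
#' @param dependence optional 5 x 5 latent Gaussian correlation matrix
#'   (symmetric positive semi-definite, unit diagonal) inducing
#'   between-feature dependence via a Gaussian copula; `NULL` for
#'   independent features.
#' @return list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n = 88L,
                              feature_prevalences =
                                c(periventricular = 68 / 88,
                                  callosal_or_bilateral = 29 / 88,
                                  eloquent = 38 / 88,
                                  large = 62 / 88,
                                  oedema = 61 / 88),
                              resection_prob_by_class =
                                c(low = 7 / 14, moderate = 7 / 45, high = 1 / 29),
                              major_complication_prob_by_class =
                                c(low = 0 / 14, moderate = 1 / 45, high = 2 / 29),
                              rater_flip_prob = 0.1,
                              dependence = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L, length(feature_prevalences) == 5L,
            length(resection_prob_by_class) == 3L,
            length(major_complication_prob_by_class) == 3L)
  pr <- as.numeric(feature_prevalences)
  if (any(pr < 0 | pr > 1)) stop("feature prevalences must be in [0, 1]")
  if (any(resection_prob_by_class < 0 | resection_prob_by_class > 1) ||
      any(major_complication_prob_by_class < 0 |
            major_complication_prob_by_class > 1))
    stop("outcome probabilities must be in [0, 1]")
  if (rater_flip_prob < 0 || rater_flip_prob > 0.5)
    stop("rater_flip_prob must be in [0, 0.5]")
  if (!is.null(dependence)) {
    dependence <- as.matrix(dependence)
    if (!all(dim(dependence) == c(5L, 5L)) ||
        max(abs(dependence - t(dependence))) > 1e-8 ||
        max(abs(diag(dependence) - 1)) > 1e-8)
      stop("dependence must be a symmetric 5 x 5 matrix with unit diagonal")
    ev <- eigen(dependence, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("dependence matrix must be positive semi-definite")
  }
  structure(list(n = n,
                 feature_prevalences = stats::setNames(pr, flag_names()),
                 resection_prob_by_class =
                   stats::setNames(as.numeric(resection_prob_by_class),
                                   complexity_levels()),
                 major_complication_prob_by_class =
                   stats::setNames(as.numeric(major_complication_prob_by_class),
                                   complexity_levels()),
                 rater_flip_prob = rater_flip_prob,
                 dependence = dependence),
            class = "cohort_sim_params")
}

#' Simulate a graded cohort with outcomes
#'
#' Draws the five binary feature flags per patient (independent Bernoulli
#' draws, or a Gaussian copula thresholded at the marginal prevalences
#' when a dependence matrix is supplied), derives score and complexity
#' class with the grading rules, then draws complete resection and major
#' complication from the class-conditional probabilities. Major
#' complications receive a Clavien-Dindo value drawn uniformly from
#' \{3b, 4a, 4b, 5\}; others draw uniformly from \{none, 1, 2, 3a\}.
#' Bit-reproducible for a fixed seed.
#'
#' @param params a [cohort_sim_params()].
#' @param seed integer seed.
#' @return data.frame cohort: `subject_id`, five flag columns, `score`,
#'   `complexity`, `complete_resection`, `major_complication`,
#'   `clavien_dindo`; with attributes `seed` and `source = "simulated"`.
#' @export
simulate_cohort <- function(params = cohort_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(as.integer(seed))
  n <- params$n
  pr <- params$feature_prevalences
  if (is.null(params$dependence)) {
    flags <- vapply(pr, function(p) as.integer(stats::runif(n) < p),
                    integer(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1,
                                 dimnames = list(NULL, names(pr)))
  } else {
    # Gaussian copula: correlated latents thresholded at the marginals
    ev <- eigen(params$dependence, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    z <- matrix(stats::rnorm(n * 5L), n, 5L) %*% rt
    flags <- sapply(seq_len(5L), function(j)
      as.integer(z[, j] < stats::qnorm(pr[j])))
    if (n == 1L) flags <- matrix(flags, nrow = 1)
    colnames(flags) <- names(pr)
  }
  flags <- as.data.frame(flags)
  score <- total_score(flags)
  complexity <- classify_score(score)
  p_res <- params$resection_prob_by_class[as.character(complexity)]
  p_maj <- params$major_complication_prob_by_class[as.character(complexity)]
  complete_resection <- as.integer(stats::runif(n) < p_res)
  major_complication <- as.integer(stats::runif(n) < p_maj)
  cd_major <- c("3b", "4a", "4b", "5")
  cd_minor <- c("none", "1", "2", "3a")
  clavien_dindo <- ifelse(major_complication == 1,
                          sample(cd_major, n, replace = TRUE),
                          sample(cd_minor, n, replace = TRUE))
  out <- cbind(data.frame(subject_id = sprintf("S%05d", seq_len(n))),
               flags,
               data.frame(score = score, complexity = complexity,
                          complete_resection = complete_resection,
                          major_complication = major_complication,
                          clavien_dindo = clavien_dindo))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "source") <- "simulated"
  out
}

#' Simulate a noisy second rater
#'
#' The second rater re-reads each feature: every flag of rater 1 is
#' independently flipped with probability `epsilon`, and the second
#' rater's score and complexity class are recomputed from the perturbed
#' flags. Feature-level noise induces class-level disagreement, making
#' agreement calibration a one-parameter problem.
#'
#' @param cohort data.frame holding the five flag columns.
#' @param epsilon per-flag flip probability in `[0, 0.5]`.
#' @param seed integer seed.
#' @return `cohort` with added columns `score_rater2` and `grade_rater2`.
#' @export
simulate_second_rater <- function(cohort, epsilon, seed = 1L) {
  if (epsilon < 0 || epsilon > 0.5)
    stop("epsilon must be in [0, 0.5]")
  miss <- setdiff(flag_names(), names(cohort))
  if (length(miss)) stop("missing flag columns: ", paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  flags2 <- as.data.frame(lapply(cohort[flag_names()], function(x) {
    flip <- stats::runif(n) < epsilon
    as.integer(xor(x == 1, flip))
  }))
  score2 <- total_score(flags2)
  cohort$score_rater2 <- score2
  cohort$grade_rater2 <- classify_score(score2)
  cohort
}

#' Simulated agreement between the two raters
#'
#' Convenience wrapper: cross-tabulates rater 1's and rater 2's grades
#' (complexity classes by default, raw 0-5 scores with
#' `scale = "score"`) and computes Cohen's kappa.
#'
#' @param cohort output of [simulate_second_rater()] (or any cohort with
#'   both raters' grades).
#' @param scale `"class"` (3 levels, default) or `"score"` (6 levels).
#' @param se_formula passed to [cohens_kappa()].
#' @return a `kappa_result`.
#' @export
rater_agreement <- function(cohort, scale = c("class", "score"),
                            se_formula = c("asymptotic", "simple")) {
  scale <- match.arg(scale)
  if (scale == "class") {
    r1 <- factor(as.character(cohort$complexity), levels = complexity_levels())
    r2 <- factor(as.character(cohort$grade_rater2), levels = complexity_levels())
  } else {
    r1 <- factor(cohort$score, levels = 0:5)
    r2 <- factor(cohort$score_rater2, levels = 0:5)
  }
  tab <- table(r1, r2)
  cohens_kappa(matrix(as.integer(tab), nrow(tab), ncol(tab),
                      dimnames = dimnames(tab)),
               se_formula = se_formula)
}

#' Calibrate the rater flip probability to a target kappa
#'
#' Simulated kappa decreases monotonically in the flip probability, so a
#' bisection on `epsilon` in `[0, 0.5]` recovers the noise level whose
#' simulated class-level agreement matches a requested kappa (for
#' instance the published inter-rater value 0.625). The rater cross-table
#' behind the published kappa is not available, so this is a calibration
#' of the simulator, not a reproduction of that number.
#'
#' @param target_kappa desired class-level kappa in `(0, 1)`.
#' @param params a [cohort_sim_params()] for the underlying cohort.
#' @param n cohort size used during calibration (larger = less noisy).
#' @param seed integer seed.
#' @param tol bisection stops when the bracket is narrower than `tol`.
#' @return list: `epsilon`, `achieved_kappa`, `n`.
#' @export
calibrate_rater_noise <- function(target_kappa, params = cohort_sim_params(),
                                  n = 10000L, seed = 1L, tol = 1e-3) {
  stopifnot(target_kappa > 0, target_kappa < 1)
  params$n <- as.integer(n)
  base <- simulate_cohort(params, seed = seed)
  sim_kappa <- function(eps) {
    rater_agreement(simulate_second_rater(base, eps, seed = seed + 1L))$kappa
  }
  lo <- 0; hi <- 0.5
  k_lo <- sim_kappa(lo) # = 1 by construction
  k_hi <- sim_kappa(hi)
  if (target_kappa > k_lo || target_kappa < k_hi)
    stop(sprintf("target kappa %.3f outside achievable range [%.3f, %.3f]",
                 target_kappa, k_hi, k_lo))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sim_kappa(mid) >= target_kappa) lo <- mid else hi <- mid
  }
  eps <- (lo + hi) / 2
  list(epsilon = eps, achieved_kappa = sim_kappa(eps), n = as.integer(n))
}

#' Exact class distribution implied by independent feature prevalences
#'
#' Enumerates all 32 flag combinations, weights each by its Bernoulli
#' probability under independence, and accumulates the probability of
#' each complexity class. Serves as the closed-form check on simulated
#' class frequencies.
#'
#' @param feature_prevalences five probabilities (ordered as
#'   [flag_names()]).
#' @return named numeric length-3: probabilities of low, moderate, high.
#' @export
enumerate_class_distribution <- function(feature_prevalences) {
  p <- as.numeric(feature_prevalences)
  stopifnot(length(p) == 5L, all(p >= 0 & p <= 1))
  combos <- as.matrix(expand.grid(rep(list(0:1), 5)))
  colnames(combos) <- flag_names()
  w <- apply(combos, 1, function(f) prod(ifelse(f == 1, p, 1 - p)))
  cls <- classify_score(rowSums(combos))
  out <- tapply(w, cls, sum, default = 0)
  stats::setNames(as.numeric(out[complexity_levels()]), complexity_levels())
}
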