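#' Clavien-Dindo complication levels in ordinal order
#' @return character vector `none < 1 < 2 < 3a < 3b < 4a < 4b < 5`.
#' @export
clavien_dindo_levels <- function() c("none", "1", "2", "3a", "3b", "4a", "4b", "5")

#' Is a complication "major" (Clavien-Dindo above 3a)?
#'
#' Major complications are those strictly greater than grade 3a on the
#' Clavien-Dindo scale, i.e. 3b, 4a, 4b, or 5. Grade 3a itself is not
#' major.
#'
#' @param grade character vector of Clavien-Dindo values among
#'   [clavien_dindo_levels()].
#' @return logical vector.
#' @export
is_major_complication <- function(grade) {
  grade <- as.character(grade)
  bad <- setdiff(unique(grade), clavien_dindo_levels())
  if (length(bad))
    stop("unknown Clavien-Dindo grade(s): ", paste(bad, collapse = ", "))
  match(grade, clavien_dindo_levels()) > match("3a", clavien_dindo_levels())
}

# round half UP (not half-even) to `digits` decimals, matching how the
# published tables print percentages
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Cross-tabulate two cohort variables
#'
#' Builds an r x c contingency table of counts with deterministic label
#' order: complexity classes low < moderate < high, booleans FALSE < TRUE,
#' otherwise sorted unique values. Records with a missing value in either
#' variable are rejected, naming the offending subjects.
#'
#' @param cohort data.frame with a `subject_id` column.
#' @param row,col names of the two columns to tabulate.
#' @return integer matrix of counts with dimnames.
#' @export
crosstab <- function(cohort, row, col) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  for (v in c(row, col)) {
    if (!v %in% names(cohort)) stop("variable not in cohort: ", v)
    if (anyNA(cohort[[v]])) {
      ids <- cohort$subject_id[is.na(cohort[[v]])]
      stop("missing `", v, "` for subject(s): ", paste(ids, collapse = ", "))
    }
  }
  lev <- function(x) {
    if (is.logical(x)) return(factor(x, levels = c(FALSE, TRUE)))
    if (is.factor(x) || all(unique(as.character(x)) %in% complexity_levels()))
      return(factor(as.character(x), levels =
                      if (is.factor(x)) levels(x) else complexity_levels()))
    factor(x, levels = sort(unique(x)))
  }
  tab <- table(lev(cohort[[row]]), lev(cohort[[col]]), dnn = c(row, col))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square with no continuity correction:
#' `X2 = sum((O - E)^2 / E)` with `E = row_total * col_total / n`, compared
#' to the upper tail of the chi-square distribution on `(r-1)(c-1)` degrees
#' of freedom. All-zero rows or columns are dropped with a warning before
#' testing. Expected counts below 5 set `warning_low_expected` (the test is
#' still run; the flag documents the caveat).
#'
#' @param tab matrix of non-negative counts, at least 2 x 2 after dropping
#'   empty rows/columns.
#' @return list of class `chi2_result`: `statistic`, `df`, `p`, `expected`,
#'   `warning_low_expected`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab))) stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("contingency table has grand total 0")
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero row(s)/column(s) before the chi-square test")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: need at least 2 rows and 2 columns with counts")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 expected = ct$expected,
                 warning_low_expected = any(ct$expected < 5)),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4f%s\n",
              x$statistic, x$df, x$p,
              if (x$warning_low_expected) "  [expected count < 5]" else ""))
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` on a square
#' rater-by-rater contingency table, where `p_o` is the observed proportion
#' of agreement (trace / n) and `p_e` the agreement expected from the
#' margins. The default standard error is the large-sample asymptotic
#' estimator of Fleiss, Cohen and Everitt (not assuming kappa = 0), as
#' major statistics packages report; `se_formula = "simple"` gives
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param tab square matrix of counts, rater 1 in rows, rater 2 in
#'   columns, categories in the same order on both axes; grand total >= 2.
#' @param se_formula `"asymptotic"` (default) or `"simple"`.
#' @return list of class `kappa_result`: `kappa`, `se`, `p_o`, `p_e`, `n`.
#'   `kappa` and `se` are `NA` when `p_e = 1` (all mass in one category for
#'   both raters), where kappa is undefined.
#' @export
cohens_kappa <- function(tab, se_formula = c("asymptotic", "simple")) {
  se_formula <- match.arg(se_formula)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab))
    stop("kappa needs a square rater-by-rater table; got ",
         nrow(tab), " x ", ncol(tab))
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n < 2) stop("kappa needs a grand total of at least 2")
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(pr * pc)
  if (1 - p_e < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, se = NA_real_, p_o = p_o,
                          p_e = p_e, n = n, se_formula = se_formula),
                     class = "kappa_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  if (se_formula == "simple") {
    se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  } else {
    # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
    k <- nrow(p)
    term1 <- 0
    for (i in seq_len(k))
      term1 <- term1 + p[i, i] * ((1 - p_e) - (pr[i] + pc[i]) * (1 - p_o))^2
    term2 <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
      term2 <- term2 + p[i, j] * (pc[i] + pr[j])^2
    term2 <- term2 * (1 - p_o)^2
    term3 <- (p_o * p_e - 2 * p_e + p_o)^2
    se <- sqrt((term1 + term2 - term3) / (n * (1 - p_e)^4))
  }
  structure(list(kappa = unname(kappa), se = unname(se), p_o = unname(p_o),
                 p_e = unname(p_e), n = n, se_formula = se_formula),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (SE %.3f, %s), p_o = %.3f, p_e = %.3f, n = %d\n",
              x$kappa, x$se, x$se_formula, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Prevalence of each adverse grading feature in a cohort
#'
#' Count and percentage of patients with each of the five flags set,
#' mirroring the layout of the published feature table. Percentages are
#' rounded half-up to one decimal so they match printed values exactly.
#'
#' @param cohort data.frame holding the five 0/1 flag columns of
#'   [flag_names()].
#' @return data.frame with columns `feature`, `n_present`, `pct_present`,
#'   `n_absent`, `pct_absent`, `total`.
#' @export
summarize_features <- function(cohort) {
  miss <- setdiff(flag_names(), names(cohort))
  if (length(miss)) stop("missing flag columns: ", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  if (n == 0L) stop("cohort is empty")
  rows <- lapply(flag_names(), function(f) {
    x <- cohort[[f]]
    if (anyNA(x)) stop("missing values in flag `", f, "`")
    np <- sum(x == 1)
    data.frame(feature = f, n_present = np,
               pct_present = round_half_up(100 * np / n),
               n_absent = n - np,
               pct_absent = round_half_up(100 * (n - np) / n),
               total = n)
  })
  do.call(rbind, rows)
}

#' Grade-stratified surgical outcome summary
#'
#' Per complexity class (plus an overall row): number of patients, count
#' and percentage with complete resection of contrast-enhancing tumour,
#' and count and percentage with a major complication (Clavien-Dindo above
#' 3a). Percentages are rounded half-up to one decimal. This mirrors the
#' published grade-by-outcome table.
#'
#' @param cohort data.frame with columns `complexity`,
#'   `complete_resection` (0/1 or logical), and either `major_complication`
#'   (0/1 or logical) or `clavien_dindo` (from which major status is
#'   derived via [is_major_complication()]).
#' @return data.frame with columns `complexity`, `n`,
#'   `n_complete_resection`, `pct_complete_resection`,
#'   `n_major_complication`, `pct_major_complication`; last row `overall`.
#' @export
summarize_grades <- function(cohort) {
  if (!"complexity" %in% names(cohort)) stop("cohort lacks `complexity`")
  if (!"complete_resection" %in% names(cohort))
    stop("cohort lacks `complete_resection`")
  cls <- factor(as.character(cohort$complexity), levels = complexity_levels())
  if (anyNA(cls)) stop("invalid or missing complexity values")
  res <- as.logical(as.integer(cohort$complete_resection))
  if (anyNA(res)) stop("missing `complete_resection` values")
  if ("major_complication" %in% names(cohort)) {
    maj <- as.logical(as.integer(cohort$major_complication))
  } else if ("clavien_dindo" %in% names(cohort)) {
    maj <- is_major_complication(cohort$clavien_dindo)
  } else stop("cohort lacks `major_complication` and `clavien_dindo`")
  if (anyNA(maj)) stop("missing complication values")
  one <- function(sel, label) {
    n <- sum(sel)
    nr <- sum(res[sel]); nm <- sum(maj[sel])
    data.frame(complexity = label, n = n,
               n_complete_resection = nr,
               pct_complete_resection =
                 if (n > 0) round_half_up(100 * nr / n) else NA_real_,
               n_major_complication = nm,
               pct_major_complication =
                 if (n > 0) round_half_up(100 * nm / n) else NA_real_)
  }
  out <- do.call(rbind, lapply(complexity_levels(),
                               function(l) one(cls == l, l)))
  rbind(out, one(rep(TRUE, length(cls)), "overall"))
}
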