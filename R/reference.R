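#' Reconstruct the validation cohort's feature table (88 patients)
#'
#' Rebuilds an 88-record cohort whose per-feature counts equal those
#' reported for the original validation cohort of the grading system:
#' periventricular 68, callosal or bilateral 29, eloquent 38, large
#' (diameter >= 40 mm) 62, significant oedema 61. Only the marginal counts
#' are published, so the joint arrangement of flags across patients is
#' arbitrary (each flag column is filled independently); the cohort is
#' intended for feature-prevalence summaries, not for joint analyses.
#'
#' @return data.frame with `subject_id` and the five 0/1 flag columns.
#' @export
reference_feature_cohort <- function() {
  n <- 88L
  counts <- c(periventricular = 68L, callosal_or_bilateral = 29L,
              eloquent = 38L, large = 62L, oedema = 61L)
  out <- data.frame(subject_id = sprintf("P%03d", seq_len(n)))
  for (f in names(counts))
    out[[f]] <- as.integer(seq_len(n) <= counts[[f]])
  out
}

#' Reconstruct the validation cohort's grade-by-outcome records (88 patients)
#'
#' Rebuilds the 88 per-patient records implied by the published
#' grade-by-outcome table: 14 low-, 45 moderate-, and 29 high-complexity
#' patients with 7/7/1 complete resections and 0/1/2 major complications
#' per class. Major complications are assigned Clavien-Dindo 3b and
#' non-major records Clavien-Dindo "none" (the published analysis only
#' uses the above-3a dichotomy). Complete resection and complication
#' assignments within a class are arbitrary, which is irrelevant for any
#' analysis of class-level counts.
#'
#' @return data.frame with columns `subject_id`, `complexity` (factor
#'   low < moderate < high), `complete_resection` (0/1), `clavien_dindo`,
#'   `major_complication` (0/1).
#' @export
reference_outcome_cohort <- function() {
  class_n <- c(low = 14L, moderate = 45L, high = 29L)
  res_n <- c(low = 7L, moderate = 7L, high = 1L)
  maj_n <- c(low = 0L, moderate = 1L, high = 2L)
  rows <- lapply(names(class_n), function(cl) {
    n <- class_n[[cl]]
    data.frame(
      complexity = cl,
      complete_resection = as.integer(seq_len(n) <= res_n[[cl]]),
      major_complication = as.integer(seq_len(n) > n - maj_n[[cl]])
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out$complexity <- factor(out$complexity, levels = complexity_levels(),
                           ordered = TRUE)
  out$clavien_dindo <- ifelse(out$major_complication == 1, "3b", "none")
  out
}
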