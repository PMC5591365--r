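#' Grading thresholds
#'
#' The three length thresholds of the grading rules, in mm. Defaults are
#' the published values: a tumour is periventricular when the enhancing
#' tumour lies strictly within 10 mm of the ventricles, large when its
#' maximal diameter is 40 mm or more, and has significant associated
#' oedema when oedema extends 10 mm or more beyond the enhancing margin.
#'
#' @param periventricular_mm distance below which the periventricular
#'   point is scored (strict `<`).
#' @param diameter_mm diameter at or above which the size point is scored
#'   (inclusive `>=`).
#' @param oedema_mm oedema extension at or above which the oedema point is
#'   scored (inclusive `>=`).
#' @return list of class `grade_thresholds`.
#' @export
grade_thresholds <- function(periventricular_mm = 10, diameter_mm = 40,
                             oedema_mm = 10) {
  th <- list(periventricular_mm = as.numeric(periventricular_mm),
             diameter_mm = as.numeric(diameter_mm),
             oedema_mm = as.numeric(oedema_mm))
  if (any(!vapply(th, is.finite, TRUE)) || any(unlist(th) <= 0))
    stop("all grading thresholds must be positive finite lengths (mm)")
  structure(th, class = "grade_thresholds")
}

#' Names of the five binary grading flags, in canonical order
#' @return character vector of length 5.
#' @export
flag_names <- function() {
  c("periventricular", "callosal_or_bilateral", "eloquent", "large", "oedema")
}

#' Complexity class labels in increasing order
#' @return `factor` levels `low < moderate < high`.
#' @export
complexity_levels <- function() c("low", "moderate", "high")

#' Binarize raw measurements into the five grading flags
#'
#' Applies the threshold rules to a feature row (as produced by
#' [extract_features()]). Boundary semantics follow the published table
#' exactly: exactly 10 mm from the ventricle does **not** score the
#' periventricular point (strict `<`), while a 40 mm diameter and a 10 mm
#' oedema extension **do** score their points (inclusive `>=`).
#'
#' @param features data.frame with columns `ventricle_distance_mm`,
#'   `corpus_callosum_involved`, `bilateral`, `eloquent_involved`,
#'   `max_diameter_mm`, `oedema_extension_mm` (one or more rows).
#' @param thresholds a [grade_thresholds()].
#' @return data.frame with the five 0/1 flag columns of [flag_names()],
#'   one row per input row.
#' @export
binarize_features <- function(features, thresholds = grade_thresholds()) {
  stopifnot(inherits(thresholds, "grade_thresholds"))
  need <- c("ventricle_distance_mm", "corpus_callosum_involved", "bilateral",
            "eloquent_involved", "max_diameter_mm", "oedema_extension_mm")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  len <- c("ventricle_distance_mm", "max_diameter_mm", "oedema_extension_mm")
  for (col in len) {
    x <- features[[col]]
    if (any(is.na(x)) || any(!is.finite(x)))
      stop("feature `", col, "` has missing or non-finite values; ",
           "records with missing measurements are ungradable")
    if (any(x < 0)) stop("feature `", col, "` has negative lengths")
  }
  data.frame(
    periventricular =
      as.integer(features$ventricle_distance_mm < thresholds$periventricular_mm),
    callosal_or_bilateral =
      as.integer(as.logical(features$corpus_callosum_involved) |
                   as.logical(features$bilateral)),
    eloquent = as.integer(as.logical(features$eloquent_involved)),
    large = as.integer(features$max_diameter_mm >= thresholds$diameter_mm),
    oedema = as.integer(features$oedema_extension_mm >= thresholds$oedema_mm)
  )
}

#' Sum the five grading flags into the 0-5 score
#'
#' @param flags data.frame (or named vector) holding the five 0/1 columns
#'   of [flag_names()].
#' @return integer vector of scores in 0..5.
#' @export
total_score <- function(flags) {
  if (is.null(dim(flags))) flags <- as.data.frame(as.list(flags))
  miss <- setdiff(flag_names(), names(flags))
  if (length(miss)) stop("missing flag columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(flags[flag_names()])
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("flags must be exactly 0 or 1 with no missing values")
  as.integer(rowSums(m))
}

#' Map a 0-5 score to the complexity class
#'
#' Scores 0-1 are low complexity, 2-3 moderate, 4-5 high.
#'
#' @param score integer vector in 0..5.
#' @return factor with ordered levels low < moderate < high.
#' @export
classify_score <- function(score) {
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < 0L | score > 5L))
    stop("score must be an integer between 0 and 5")
  factor(complexity_levels()[findInterval(score, c(0, 2, 4))],
         levels = complexity_levels(), ordered = TRUE)
}

#' Grade one or more feature records
#'
#' Binarizes the measurements, sums the score, and assigns the complexity
#' class, returning all three so the result is self-consistent.
#'
#' @inheritParams binarize_features
#' @return data.frame: input `subject_id` (if present), the five flag
#'   columns, `score`, and `complexity`.
#' @export
grade <- function(features, thresholds = grade_thresholds()) {
  flags <- binarize_features(features, thresholds)
  score <- total_score(flags)
  out <- cbind(
    if ("subject_id" %in% names(features))
      features["subject_id"] else NULL,
    flags,
    data.frame(score = score, complexity = classify_score(score))
  )
  rownames(out) <- NULL
  out
}
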