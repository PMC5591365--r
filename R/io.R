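#' Write a feature table to CSV
#'
#' Fixed schema, one row per subject: `subject_id`,
#' `ventricle_distance_mm`, `corpus_callosum_involved`, `bilateral`,
#' `eloquent_involved`, `max_diameter_mm`, `oedema_extension_mm`.
#' UTF-8, comma-separated, header row, `.` decimal, booleans as 0/1 —
#' the dialect round-trips bit-exactly.
#'
#' @param features data.frame from [extract_features()] (rows may be
#'   stacked across subjects).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  cols <- c("subject_id", "ventricle_distance_mm", "corpus_callosum_involved",
            "bilateral", "eloquent_involved", "max_diameter_mm",
            "oedema_extension_mm")
  miss <- setdiff(cols, names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  out <- features[cols]
  for (b in c("corpus_callosum_involved", "bilateral", "eloquent_involved"))
    out[[b]] <- as.integer(out[[b]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table from CSV
#' @param path path to a CSV written by [write_features_csv()] or
#'   hand-built in the same schema.
#' @return data.frame with boolean columns as logical.
#' @export
read_features_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       fileEncoding = "UTF-8")
  for (b in c("corpus_callosum_involved", "bilateral", "eloquent_involved"))
    if (b %in% names(x)) x[[b]] <- x[[b]] == 1
  x
}

#' Write a cohort table to CSV
#'
#' Schema: `subject_id`, the five flag columns, `score`, `complexity`,
#' optional `grade_rater2`/`score_rater2`, `complete_resection` (0/1),
#' `major_complication` (0/1), `clavien_dindo`. A provenance comment
#' header (`# source=... seed=...`) records how the cohort was made.
#'
#' @param cohort data.frame cohort.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  src <- attr(cohort, "source"); seed <- attr(cohort, "seed")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# source=%s seed=%s",
                     if (is.null(src)) "unspecified" else src,
                     if (is.null(seed)) "NA" else seed), con)
  out <- cohort
  for (col in names(out))
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema (flag columns in 0/1, complexity among
#' low/moderate/high, Clavien-Dindo among its levels) and restores factor
#' types. Violations are reported with the offending column names.
#'
#' @param path path to a cohort CSV.
#' @return data.frame cohort with `seed`/`source` attributes when the
#'   provenance header is present.
#' @export
read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1L)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       fileEncoding = "UTF-8")
  for (f in intersect(flag_names(), names(x))) {
    if (!all(x[[f]] %in% c(0L, 1L)))
      stop("column `", f, "` must contain only 0/1")
    x[[f]] <- as.integer(x[[f]])
  }
  for (col in intersect(c("complexity", "grade_rater2"), names(x))) {
    bad <- setdiff(unique(x[[col]]), complexity_levels())
    if (length(bad))
      stop("column `", col, "` has invalid class value(s): ",
           paste(bad, collapse = ", "))
    x[[col]] <- factor(x[[col]], levels = complexity_levels(), ordered = TRUE)
  }
  if ("clavien_dindo" %in% names(x)) {
    x$clavien_dindo <- as.character(x$clavien_dindo)
    bad <- setdiff(unique(x$clavien_dindo), clavien_dindo_levels())
    if (length(bad))
      stop("column `clavien_dindo` has invalid value(s): ",
           paste(bad, collapse = ", "))
  }
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("source=(\\S+) seed=(\\S+)", first))[[1]]
    if (length(m) == 3L) {
      attr(x, "source") <- m[2]
      if (m[3] != "NA") attr(x, "seed") <- as.integer(m[3])
    }
  }
  x
}

#' Write a statistics result as a JSON record
#'
#' Serialises a `chi2_result` or `kappa_result` (or any named list of
#' scalars/matrices) to JSON with full numeric precision.
#'
#' @param x result object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
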