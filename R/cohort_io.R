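# Cohort tables: one row per (subject, knee, timepoint) with B-score,
# ICRS grade and regional cartilage thicknesses. Missing cells are empty in
# CSV and NA in R; analyses use pairwise deletion, so missingness is a
# first-class state, never coerced to zero.

#' Thickness regions reported per knee
#' @export
thickness_regions <- c("entire_fc", "medial_fc", "lateral_fc",
                       "entire_tf", "medial_tf", "lateral_tf")

cohort_columns <- function() {
  c("subject_id", "knee", "sex", "timepoint_months", "icrs_grade", "bscore",
    paste0("thick_", thickness_regions))
}

#' Validate a cohort table
#'
#' Checks the documented column set, categorical codes, key uniqueness and
#' value ranges. Returns the table invisibly so it can be used in pipes.
#'
#' @param cohort A data frame of knee observations.
#' @return `cohort`, invisibly.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols))
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  bad_knee <- setdiff(unique(cohort$knee), c("index", "control"))
  if (length(bad_knee))
    stop(sprintf("unknown knee code(s): %s", paste(bad_knee, collapse = ", ")))
  bad_sex <- setdiff(unique(cohort$sex), c("female", "male"))
  if (length(bad_sex))
    stop(sprintf("unknown sex code(s): %s", paste(bad_sex, collapse = ", ")))
  if (any(!is.na(cohort$timepoint_months) & cohort$timepoint_months < 0))
    stop("timepoint_months must be non-negative")
  key <- paste(cohort$subject_id, cohort$knee, cohort$timepoint_months)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (subject_id, knee, timepoint_months) key(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  ic <- cohort$icrs_grade
  if (any(!is.na(ic) & !ic %in% 0:4))
    stop("icrs_grade must be in 0..4 or missing")
  for (col in paste0("thick_", thickness_regions)) {
    x <- cohort[[col]]
    if (any(!is.na(x) & x <= 0))
      stop(sprintf("%s must be positive when present", col))
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Expects the exact column set written by [write_cohort()]; empty cells
#' become `NA`.
#'
#' @param path CSV path.
#' @return Validated data frame of knee observations.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  df$subject_id <- as.character(df$subject_id)
  validate_cohort(df)
  df[, cohort_columns()]
}

#' Write a cohort CSV
#'
#' @param cohort Data frame of knee observations.
#' @param path Destination CSV path; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}
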