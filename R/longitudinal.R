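# Per-knee trajectory metrics: OLS slopes, Bland-Altman smallest detectable
# difference (SDD), progressor classification, and group trajectory
# summaries.

#' Per-annum OLS slope of a knee's B-score series
#'
#' @param timepoints_months Acquisition times in months (at least two
#'   distinct values).
#' @param bscores B-scores at those times.
#' @return Ordinary-least-squares slope in B-score units per annum.
#' @export
knee_slope <- function(timepoints_months, bscores) {
  if (length(timepoints_months) != length(bscores))
    stop("timepoints and bscores must have equal length")
  ok <- is.finite(timepoints_months) & is.finite(bscores)
  t_yr <- timepoints_months[ok] / 12
  y <- bscores[ok]
  if (length(unique(t_yr)) < 2L)
    stop("need at least 2 distinct timepoints to fit a slope")
  sum((t_yr - mean(t_yr)) * (y - mean(y))) / sum((t_yr - mean(t_yr))^2)
}

#' Smallest detectable difference from test-retest pairs
#'
#' Bland-Altman 95% limit of agreement of the differences between second and
#' first measurements: `sdd = 1.96 * SD(second - first)` (n-1 denominator).
#' Changes smaller than the SDD are indistinguishable from measurement noise.
#'
#' @param pairs Data frame (or 2-column matrix) with columns `first` and
#'   `second`; at least two pairs.
#' @return Object of class `sdd_result`: `mean_diff`, `sd_diff`, `sdd`,
#'   `n_pairs`.
#' @export
sdd <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$first) || is.null(pairs$second)) {
    if (ncol(pairs) >= 2L) names(pairs)[1:2] <- c("first", "second")
    else stop("pairs must have columns 'first' and 'second'")
  }
  ok <- is.finite(pairs$first) & is.finite(pairs$second)
  d <- pairs$second[ok] - pairs$first[ok]
  if (length(d) < 2L) stop("SDD needs at least 2 complete pairs")
  sd_d <- stats::sd(d)
  structure(list(mean_diff = mean(d), sd_diff = sd_d, sdd = 1.96 * sd_d,
                 n_pairs = length(d)),
            class = "sdd_result")
}

#' @export
print.sdd_result <- function(x, ...) {
  cat(sprintf("SDD (Bland-Altman 95%% limit of agreement): %.4f [mean diff %.4f, SD %.4f, n = %d]\n",
              x$sdd, x$mean_diff, x$sd_diff, x$n_pairs))
  invisible(x)
}

#' Classify a knee as progressor or non-progressor
#'
#' A knee progresses when its projected change over the horizon strictly
#' exceeds `threshold_factor` times the SDD: progressor iff
#' `slope * horizon_years > threshold_factor * sdd` (worsening, i.e.
#' positive, direction by default; set `direction = "absolute"` to classify
#' on |slope|).
#'
#' @param slope_per_annum OLS slope from [knee_slope()].
#' @param sdd_result An [sdd()] result (or a non-negative number).
#' @param horizon_years Projection horizon (default 4 years).
#' @param threshold_factor Fraction of the SDD that must be exceeded
#'   (default 0.95; use 1.0 for the reading in which the SDD itself is the
#'   threshold).
#' @param direction `"signed"` (default; only worsening counts) or
#'   `"absolute"`.
#' @return `"progressor"` or `"non_progressor"`.
#' @export
classify_progressor <- function(slope_per_annum, sdd_result,
                                horizon_years = 4, threshold_factor = 0.95,
                                direction = c("signed", "absolute")) {
  direction <- match.arg(direction)
  if (horizon_years <= 0) stop("horizon_years must be positive")
  s <- if (inherits(sdd_result, "sdd_result")) sdd_result$sdd else as.numeric(sdd_result)
  if (s < 0) stop("sdd must be non-negative")
  change <- slope_per_annum * horizon_years
  if (direction == "absolute") change <- abs(change)
  ifelse(change > threshold_factor * s, "progressor", "non_progressor")
}

#' Group trajectory summary (mean change from baseline with SEM)
#'
#' Per group and timepoint: mean of (B - B_baseline) over knees and its
#' standard error of the mean. Knees with no baseline row are excluded with
#' a message. Reference progression slopes are attached as the
#' `reference_slopes` attribute for plotting against historical
#' non-progressor/progressor trajectories.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param group_by Column(s) of `cohort` defining the groups (default the
#'   knee arm).
#' @param reference_slopes Named slopes (per annum) to attach.
#' @return Data frame: `group`, `timepoint_months`, `mean_change`, `sem`,
#'   `n`; baseline rows are exactly 0 with SEM 0.
#' @export
trajectory_summary <- function(cohort, group_by = "knee",
                               reference_slopes = c(non_progressor = 0.04,
                                                    progressor = 0.24)) {
  validate_cohort(cohort)
  key <- paste(cohort$subject_id, cohort$knee)
  base <- cohort[cohort$timepoint_months == 0, ]
  base_b <- stats::setNames(base$bscore, paste(base$subject_id, base$knee))
  missing_base <- !key %in% names(base_b)
  if (any(missing_base)) {
    message(sprintf("trajectory_summary: excluded %d knee(s) lacking a baseline row",
                    length(unique(key[missing_base]))))
    cohort <- cohort[!missing_base, ]
    key <- key[!missing_base]
  }
  change <- cohort$bscore - base_b[key]
  grp <- do.call(paste, c(cohort[, group_by, drop = FALSE], sep = "/"))
  ok <- is.finite(change)
  agg <- stats::aggregate(change[ok],
                          by = list(group = grp[ok],
                                    timepoint_months = cohort$timepoint_months[ok]),
                          FUN = function(v) c(mean = mean(v),
                                              sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                                              n = length(v)))
  out <- data.frame(group = agg$group, timepoint_months = agg$timepoint_months,
                    mean_change = agg$x[, "mean"], sem = agg$x[, "sem"],
                    n = as.integer(agg$x[, "n"]), stringsAsFactors = FALSE)
  out <- out[order(out$group, out$timepoint_months), ]
  rownames(out) <- NULL
  attr(out, "reference_slopes") <- reference_slopes
  out
}
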