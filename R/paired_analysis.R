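# Trial statistics: change-from-baseline, paired and Welch t-tests, Pearson
# correlations with Fisher z confidence intervals, quartile stratification
# and ICRS-grade subgroup comparisons. Raw two-sided p-values at alpha 0.05
# throughout; missing data handled by pairwise deletion, so n varies by
# analysis.

#' Per-knee change from baseline of one variable
#'
#' `value(timepoint) - value(0)` per (subject, knee); knees missing either
#' row (or with a missing value at either time) are dropped, and the count
#' of dropped knees is attached as attribute `n_dropped`.
#'
#' @param cohort Cohort data frame.
#' @param variable Column to difference (default `"bscore"`).
#' @param timepoint Follow-up time in months.
#' @return Data frame: `subject_id`, `knee`, `sex`, `change`.
#' @export
change_from_baseline <- function(cohort, variable = "bscore", timepoint) {
  validate_cohort(cohort)
  if (!variable %in% names(cohort)) stop(sprintf("no column '%s'", variable))
  base <- cohort[cohort$timepoint_months == 0, c("subject_id", "knee", "sex", variable)]
  fup <- cohort[cohort$timepoint_months == timepoint, c("subject_id", "knee", variable)]
  names(base)[4] <- "v0"
  names(fup)[3] <- "v1"
  m <- merge(base, fup, by = c("subject_id", "knee"))
  m$change <- m$v1 - m$v0
  n_total <- length(unique(paste(cohort$subject_id, cohort$knee)))
  out <- m[is.finite(m$change), c("subject_id", "knee", "sex", "change")]
  out <- out[order(out$subject_id, out$knee), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_total - nrow(out)
  out
}

t_ci <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(m, NA_real_, NA_real_))
  half <- stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
  c(m, m - half, m + half)
}

#' Paired t-test of two matched change series
#'
#' Classic paired Student's t-test on within-pair differences `x - y`,
#' with per-arm means and t-based 95% CIs. If every difference is exactly
#' zero the test is reported as t = 0, p = 1 (no detectable difference);
#' zero variance with a nonzero mean difference is an error (undefined t).
#'
#' @param x,y Numeric vectors of per-knee changes.
#' @param pair_keys Optional keys identifying pairs; when given, `x` and `y`
#'   are matched on the shared keys (pairwise deletion of unmatched keys).
#'   `x` and `y` must otherwise be aligned.
#' @param keys_x,keys_y Keys for `x` and `y` when they differ (defaults to
#'   `pair_keys` for both).
#' @return Object of class `t_test_result` with fields `mean_1`, `mean_2`,
#'   `mean_diff`, per-arm and difference CIs, `t_stat`, `df`, `p_two_sided`,
#'   `n_1`, `n_2`, `flavor = "paired"`.
#' @export
paired_t <- function(x, y, pair_keys = NULL, keys_x = pair_keys,
                     keys_y = pair_keys) {
  if (!is.null(keys_x) && !is.null(keys_y)) {
    common <- intersect(keys_x[!is.na(x)], keys_y[!is.na(y)])
    x <- x[match(common, keys_x)]
    y <- y[match(common, keys_y)]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs")
  d <- x - y
  if (stats::sd(d) < 1e-300) {
    if (abs(mean(d)) > 0)
      stop("zero variance of paired differences with nonzero mean: t undefined")
    tt <- list(statistic = 0, parameter = n - 1L, p.value = 1,
               conf.int = c(0, 0))
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
  }
  structure(list(mean_1 = mean(x), mean_2 = mean(y), mean_diff = mean(d),
                 ci95_1 = t_ci(x)[2:3], ci95_2 = t_ci(y)[2:3],
                 ci95_diff = as.numeric(tt$conf.int),
                 t_stat = as.numeric(tt$statistic),
                 df = as.numeric(tt$parameter),
                 p_two_sided = as.numeric(tt$p.value),
                 n_1 = n, n_2 = n, flavor = "paired"),
            class = "t_test_result")
}

#' Welch unpaired t-test of two change series
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom (unequal
#' variances not assumed equal); `pooled = TRUE` gives the classic
#' equal-variance test.
#'
#' @param x,y Numeric vectors (each at least 2 finite values).
#' @param pooled Use the pooled-variance Student test instead of Welch.
#' @return A `t_test_result` with `flavor` `"welch_unpaired"` (or
#'   `"pooled_unpaired"`).
#' @export
welch_t <- function(x, y, pooled = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("unpaired t-test needs at least 2 values per arm")
  if (stats::sd(x) < 1e-300 && stats::sd(y) < 1e-300) {
    if (abs(mean(x) - mean(y)) > 0)
      stop("zero variance in both arms with different means: t undefined")
    tt <- list(statistic = 0, parameter = length(x) + length(y) - 2L,
               p.value = 1, conf.int = c(0, 0))
  } else {
    tt <- stats::t.test(x, y, var.equal = pooled)
  }
  structure(list(mean_1 = mean(x), mean_2 = mean(y),
                 mean_diff = mean(x) - mean(y),
                 ci95_1 = t_ci(x)[2:3], ci95_2 = t_ci(y)[2:3],
                 ci95_diff = as.numeric(tt$conf.int),
                 t_stat = as.numeric(tt$statistic),
                 df = as.numeric(tt$parameter),
                 p_two_sided = as.numeric(tt$p.value),
                 n_1 = length(x), n_2 = length(y),
                 flavor = if (pooled) "pooled_unpaired" else "welch_unpaired"),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: mean diff %.4f (95%% CI %.4f, %.4f), t = %.3f, df = %.2f, p = %.4g (n = %d/%d)\n",
              x$flavor, x$mean_diff, x$ci95_diff[1], x$ci95_diff[2],
              x$t_stat, x$df, x$p_two_sided, x$n_1, x$n_2))
  invisible(x)
}

#' Pearson correlation with p-value and Fisher z confidence interval
#'
#' Product-moment r; two-sided p from `t = r * sqrt((n-2)/(1-r^2))`; 95% CI
#' from the Fisher z transform. Pairs with a missing member are deleted.
#' A numerically perfect correlation is reported with a degenerate CI
#' `[r, r]` and p = 0.
#'
#' @param x,y Numeric vectors; at least 4 complete pairs.
#' @return Object of class `corr_result`: `r`, `p_two_sided`, `ci95_low`,
#'   `ci95_high`, `n`.
#' @export
pearson_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("Pearson CI needs at least 4 complete pairs")
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    res <- list(r = r, p_two_sided = 0, ci95_low = r, ci95_high = r, n = n)
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    res <- list(r = as.numeric(ct$estimate),
                p_two_sided = as.numeric(ct$p.value),
                ci95_low = ct$conf.int[1], ci95_high = ct$conf.int[2], n = n)
  }
  structure(res, class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (95%% CI %.3f, %.3f), p = %.4g, n = %d\n",
              x$r, x$ci95_low, x$ci95_high, x$p_two_sided, x$n))
  invisible(x)
}

#' Stratify thickness changes by quartile of B-score change
#'
#' Rank-based quartile assignment of index-knee B-score changes (ties broken
#' by stable subject-id order; quartile sizes differ by at most one,
#' Q1 = most negative change, i.e. most improved) with per-quartile mean and
#' SEM of each region's cartilage-thickness change.
#'
#' @param index_changes Data frame with `subject_id` and `change` (B-score
#'   change of index knees); at least 4 rows.
#' @param thickness_changes Data frame aligned by `subject_id`, one column
#'   per region of thickness change (any column set).
#' @return Data frame: `quartile` (1-4), `change_range` (label), `region`,
#'   `n`, `mean_change`, `sem`.
#' @export
quartile_stratify <- function(index_changes, thickness_changes) {
  n <- nrow(index_changes)
  if (n < 4L) stop("quartile stratification needs at least 4 subjects")
  ord <- order(index_changes$change, index_changes$subject_id)
  bounds <- floor(seq(0, n, length.out = 5L))
  q_of <- rep(1:4, diff(bounds))
  quart <- integer(n)
  quart[ord] <- q_of
  m <- merge(index_changes, thickness_changes, by = "subject_id")
  quart <- quart[match(m$subject_id, index_changes$subject_id)]
  regions <- setdiff(names(thickness_changes), "subject_id")
  out <- do.call(rbind, lapply(1:4, function(q) {
    sel <- quart == q
    rng <- range(index_changes$change[match(m$subject_id[sel],
                                            index_changes$subject_id)])
    do.call(rbind, lapply(regions, function(r) {
      v <- m[[r]][sel]
      v <- v[is.finite(v)]
      data.frame(quartile = q,
                 change_range = sprintf("[%.3f, %.3f]", rng[1], rng[2]),
                 region = r, n = length(v),
                 mean_change = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' ICRS-grade subgroup comparison of B-score changes
#'
#' For baseline tibiofemoral ICRS thresholds >= 0 (all knees), >= 2, >= 3
#' and = 4: per-arm knee counts, mean baseline B-scores, mean changes from
#' baseline at `timepoint`, the control - index difference (positive =
#' treatment benefit) and its two-sided p-value. All knees are compared by
#' the paired test; the higher-grade subgroups, whose index and control
#' knees need not belong to the same subjects, by Welch's unpaired test.
#'
#' @param cohort Cohort data frame with `icrs_grade` present.
#' @param timepoint Follow-up time in months.
#' @return Data frame, one row per threshold.
#' @export
icrs_subgroup_analysis <- function(cohort, timepoint) {
  validate_cohort(cohort)
  ch <- change_from_baseline(cohort, "bscore", timepoint)
  base <- cohort[cohort$timepoint_months == 0, ]
  info <- merge(ch, base[, c("subject_id", "knee", "icrs_grade", "bscore")],
                by = c("subject_id", "knee"))
  subsets <- list(">=0" = 0L, ">=2" = 2L, ">=3" = 3L, "=4" = 4L)
  out <- do.call(rbind, lapply(names(subsets), function(lbl) {
    g <- subsets[[lbl]]
    sel <- if (lbl == "=4") !is.na(info$icrs_grade) & info$icrs_grade == 4L
           else !is.na(info$icrs_grade) & info$icrs_grade >= g
    idx <- info[sel & info$knee == "index", ]
    ctl <- info[sel & info$knee == "control", ]
    row <- data.frame(icrs_threshold = lbl, timepoint_months = timepoint,
                      n_index = nrow(idx), n_control = nrow(ctl),
                      baseline_bscore_index = if (nrow(idx)) mean(idx$bscore) else NA_real_,
                      baseline_bscore_control = if (nrow(ctl)) mean(ctl$bscore) else NA_real_,
                      difference = NA_real_, t_flavor = NA_character_,
                      p_two_sided = NA_real_, stringsAsFactors = FALSE)
    if (nrow(idx) < 2L || nrow(ctl) < 2L) {
      warning(sprintf("ICRS subgroup '%s': too few knees for a comparison", lbl))
      return(row)
    }
    if (lbl == ">=0") {
      tt <- paired_t(ctl$change, idx$change,
                     keys_x = ctl$subject_id, keys_y = idx$subject_id)
    } else {
      tt <- welch_t(ctl$change, idx$change)
    }
    row$difference <- tt$mean_diff
    row$t_flavor <- tt$flavor
    row$p_two_sided <- tt$p_two_sided
    row
  }))
  rownames(out) <- NULL
  out
}

#' Full trial analysis report
#'
#' Assembles the complete paired-knee analysis of a cohort: per-arm change
#' summaries with t-based 95% CIs at each follow-up, paired index/control
#' comparisons, ICRS subgroup tables, per-region Pearson correlations of
#' B-score change with thickness change for each arm, the 12-month quartile
#' stratification of index knees, trajectory summaries, and (when an
#' [sdd()] result is supplied) per-knee progressor classification from
#' 0-12-month slopes.
#'
#' @param cohort Cohort data frame.
#' @param timepoints Follow-up times to analyze (months).
#' @param sdd_result Optional [sdd()] result for progressor classification.
#' @param threshold_factor,horizon_years Passed to [classify_progressor()].
#' @param alpha Two-sided significance level (0.05).
#' @return Object of class `trial_report` (a list of data frames and test
#'   results).
#' @export
full_report <- function(cohort, timepoints = c(6, 12), sdd_result = NULL,
                        threshold_factor = 0.95, horizon_years = 4,
                        alpha = 0.05) {
  validate_cohort(cohort)
  arm_rows <- list(); paired <- list()
  corr_index <- list(); corr_control <- list()
  for (tp in timepoints) {
    ch <- change_from_baseline(cohort, "bscore", tp)
    for (arm in c("index", "control")) {
      ci <- t_ci(ch$change[ch$knee == arm])
      arm_rows[[length(arm_rows) + 1L]] <-
        data.frame(knee = arm, timepoint_months = tp,
                   n = sum(ch$knee == arm), mean_change = ci[1],
                   ci95_low = ci[2], ci95_high = ci[3],
                   stringsAsFactors = FALSE)
    }
    idx <- ch[ch$knee == "index", ]
    ctl <- ch[ch$knee == "control", ]
    paired[[as.character(tp)]] <- paired_t(ctl$change, idx$change,
                                           keys_x = ctl$subject_id,
                                           keys_y = idx$subject_id)
    for (r in thickness_regions) {
      cht <- change_from_baseline(cohort, paste0("thick_", r), tp)
      for (arm in c("index", "control")) {
        b <- ch[ch$knee == arm, ]
        th <- cht[cht$knee == arm, ]
        m <- merge(b[, c("subject_id", "change")],
                   th[, c("subject_id", "change")], by = "subject_id")
        cr <- pearson_ci(m$change.x, m$change.y)
        rowc <- data.frame(timepoint_months = tp, region = r,
                           n = cr$n, r = cr$r, p_two_sided = cr$p_two_sided,
                           ci95_low = cr$ci95_low, ci95_high = cr$ci95_high,
                           stringsAsFactors = FALSE)
        if (arm == "index") corr_index[[length(corr_index) + 1L]] <- rowc
        else corr_control[[length(corr_control) + 1L]] <- rowc
      }
    }
  }
  ch12 <- change_from_baseline(cohort, "bscore", 12)
  idx12 <- ch12[ch12$knee == "index", c("subject_id", "change")]
  th12 <- Reduce(function(a, b) merge(a, b, by = "subject_id", all = TRUE),
                 lapply(thickness_regions, function(r) {
                   d <- change_from_baseline(cohort, paste0("thick_", r), 12)
                   d <- d[d$knee == "index", c("subject_id", "change")]
                   names(d)[2] <- r
                   d
                 }))
  quart <- if (nrow(idx12) >= 4L) quartile_stratify(idx12, th12) else NULL
  icrs <- do.call(rbind, lapply(timepoints, function(tp)
    icrs_subgroup_analysis(cohort, tp)))
  progression <- NULL
  if (!is.null(sdd_result)) {
    knees <- unique(cohort[, c("subject_id", "knee")])
    slopes <- vapply(seq_len(nrow(knees)), function(i) {
      rows <- cohort$subject_id == knees$subject_id[i] &
        cohort$knee == knees$knee[i] & is.finite(cohort$bscore)
      knee_slope(cohort$timepoint_months[rows], cohort$bscore[rows])
    }, numeric(1))
    knees$slope_per_annum <- slopes
    knees$classification <- classify_progressor(slopes, sdd_result,
                                                horizon_years, threshold_factor)
    progression <- knees
  }
  structure(list(arm_summary = do.call(rbind, arm_rows),
                 paired_tests = paired,
                 icrs_table = icrs,
                 correlations_index = do.call(rbind, corr_index),
                 correlations_control = do.call(rbind, corr_control),
                 quartiles = quart,
                 trajectories = trajectory_summary(cohort),
                 progression = progression,
                 sdd = sdd_result,
                 alpha = alpha),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Paired-knee trial report\n")
  cat("\nPer-arm B-score change from baseline (t-based 95% CI):\n")
  print(x$arm_summary, row.names = FALSE, digits = 4)
  cat("\nPaired index vs control comparisons (difference = control - index):\n")
  for (tp in names(x$paired_tests)) {
    cat(sprintf("  %s months: ", tp))
    print(x$paired_tests[[tp]])
  }
  cat("\nICRS-grade subgroups:\n")
  print(x$icrs_table, row.names = FALSE, digits = 3)
  if (!is.null(x$progression)) {
    cat("\nProgressor classification (per arm):\n")
    print(table(x$progression$knee, x$progression$classification))
  }
  invisible(x)
}
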