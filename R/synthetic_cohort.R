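# Synthetic study generator: training populations of condyle-like shapes,
# a paired bilateral-knee trial cohort calibrated to the published summary
# statistics, and test-retest replicate pairs. All outputs are pure
# functions of (config, seed).

#' Generator configuration
#'
#' Central calibration object for all synthetic data. Trial defaults are the
#' published summary statistics the generator is calibrated to (per-arm mean
#' B-score changes, mean baseline B-score, reference progression slopes);
#' quantities the publication does not report (standard deviations,
#' correlations) are back-derived from printed confidence intervals and
#' p-values and documented in the methods vignette.
#'
#' @param seed Integer seed; every generated artifact is a pure function of
#'   the config including this seed.
#' @param n_vertices Template resolution (see [make_template()]).
#' @param n_nonOA,n_OA Training-population sizes.
#' @param sex_ratio Proportion female.
#' @param male_size_factor Isotropic size offset applied to male templates.
#' @param oa_deformation_amplitude Outward displacement in mm per latent
#'   B-score unit.
#' @param rim_concentration Exponent sharpening rim localization of the
#'   deformation field (dimensionless).
#' @param flatten_fraction Weight of the uniform (central flattening)
#'   component of the deformation profile.
#' @param n_subjects Trial size (bilateral-knee subjects).
#' @param baseline_bscore_mean,baseline_bscore_sd Latent baseline B-score
#'   distribution (both knees).
#' @param within_subject_baseline_corr Correlation of the two knees'
#'   baseline B-scores within a subject.
#' @param slope_nonprogressor,slope_progressor Reference trajectory slopes,
#'   B-score units per annum.
#' @param mean_change_index_6m,mean_change_control_6m,mean_change_index_12m,mean_change_control_12m
#'   Per-arm mean latent B-score changes from baseline.
#' @param change_sd Marginal SD of per-knee B-score change at each follow-up.
#' @param change_corr_within_subject Correlation of index and control knee
#'   changes within a subject.
#' @param change_corr_temporal Correlation of a knee's 6- and 12-month
#'   changes (12-month change = 6-month change + a consistent increment).
#' @param icrs_thresholds Three increasing cut points on (baseline latent
#'   B-score + grading noise) mapping to ICRS grades 0/2/3/4 (grade 1 does
#'   not occur, matching the trial's grade table).
#' @param icrs_noise_sd SD of the grading noise.
#' @param thickness_baseline_by_region Named mean baseline cartilage
#'   thicknesses (mm) for the six summary regions.
#' @param thickness_baseline_sd SD of between-knee baseline thickness.
#' @param thickness_change_sd SD of 12-month regional thickness change (mm).
#' @param thickness_change_corr_index Named per-region correlation between
#'   thickness change and B-score change in index knees at 12 months
#'   (negative medially, zero laterally).
#' @param thickness_corr_6m_factor Multiplier giving the weaker 6-month
#'   correlations.
#' @param measurement_noise_sd Measurement noise SD: per-coordinate mesh
#'   noise in mm (shape level) and B-score noise in trajectory simulations.
#' @param retest_noise_sd SD of the test-retest measurement difference
#'   (B-score units); sets the smallest detectable difference.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_vertices = 500L,
                             n_nonOA = 30L,
                             n_OA = 30L,
                             sex_ratio = 0.615,
                             male_size_factor = 1.06,
                             oa_deformation_amplitude = 0.4,
                             rim_concentration = 2,
                             flatten_fraction = 0.2,
                             n_subjects = 78L,
                             baseline_bscore_mean = 1.48,
                             baseline_bscore_sd = 2.0,
                             within_subject_baseline_corr = 0.85,
                             slope_nonprogressor = 0.04,
                             slope_progressor = 0.24,
                             mean_change_index_6m = 0.0298,
                             mean_change_control_6m = 0.1246,
                             mean_change_index_12m = 0.0856,
                             mean_change_control_12m = 0.1969,
                             change_sd = 0.30,
                             change_corr_within_subject = 0.3,
                             change_corr_temporal = 0.7,
                             icrs_thresholds = c(-0.08, 1.09, 2.30),
                             icrs_noise_sd = 0.5,
                             thickness_baseline_by_region = c(
                               entire_fc = 1.7, medial_fc = 1.6, lateral_fc = 1.8,
                               entire_tf = 3.5, medial_tf = 3.3, lateral_tf = 3.7),
                             thickness_baseline_sd = 0.15,
                             thickness_change_sd = 0.08,
                             thickness_change_corr_index = c(
                               entire_fc = -0.303, medial_fc = -0.329, lateral_fc = 0,
                               entire_tf = -0.296, medial_tf = -0.320, lateral_tf = 0),
                             thickness_corr_6m_factor = 0.65,
                             measurement_noise_sd = 0.1,
                             retest_noise_sd = 0.26) {
  cfg <- list(seed = as.integer(seed), n_vertices = as.integer(n_vertices),
              n_nonOA = as.integer(n_nonOA), n_OA = as.integer(n_OA),
              sex_ratio = sex_ratio, male_size_factor = male_size_factor,
              oa_deformation_amplitude = oa_deformation_amplitude,
              rim_concentration = rim_concentration,
              flatten_fraction = flatten_fraction,
              n_subjects = as.integer(n_subjects),
              baseline_bscore_mean = baseline_bscore_mean,
              baseline_bscore_sd = baseline_bscore_sd,
              within_subject_baseline_corr = within_subject_baseline_corr,
              slope_nonprogressor = slope_nonprogressor,
              slope_progressor = slope_progressor,
              mean_change_index_6m = mean_change_index_6m,
              mean_change_control_6m = mean_change_control_6m,
              mean_change_index_12m = mean_change_index_12m,
              mean_change_control_12m = mean_change_control_12m,
              change_sd = change_sd,
              change_corr_within_subject = change_corr_within_subject,
              change_corr_temporal = change_corr_temporal,
              icrs_thresholds = icrs_thresholds,
              icrs_noise_sd = icrs_noise_sd,
              thickness_baseline_by_region = thickness_baseline_by_region,
              thickness_baseline_sd = thickness_baseline_sd,
              thickness_change_sd = thickness_change_sd,
              thickness_change_corr_index = thickness_change_corr_index,
              thickness_corr_6m_factor = thickness_corr_6m_factor,
              measurement_noise_sd = measurement_noise_sd,
              retest_noise_sd = retest_noise_sd)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  sds <- c("baseline_bscore_sd", "change_sd", "icrs_noise_sd",
           "thickness_baseline_sd", "thickness_change_sd",
           "measurement_noise_sd", "retest_noise_sd")
  for (nm in sds)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("%s must be a non-negative number", nm))
  cors <- c("within_subject_baseline_corr", "change_corr_within_subject",
            "change_corr_temporal")
  for (nm in cors)
    if (abs(cfg[[nm]]) >= 1)
      stop(sprintf("%s must lie in (-1, 1)", nm))
  if (any(abs(cfg$thickness_change_corr_index) >= 1))
    stop("thickness_change_corr_index values must lie in (-1, 1)")
  if (cfg$n_subjects < 2L) stop("n_subjects must be at least 2")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1)
    stop("sex_ratio must be in [0, 1]")
  if (is.unsorted(cfg$icrs_thresholds, strictly = TRUE))
    stop("icrs_thresholds must be strictly increasing")
  miss <- setdiff(thickness_regions, names(cfg$thickness_baseline_by_region))
  if (length(miss))
    stop(sprintf("thickness_baseline_by_region lacks region(s): %s",
                 paste(miss, collapse = ", ")))
  miss <- setdiff(thickness_regions, names(cfg$thickness_change_corr_index))
  if (length(miss))
    stop(sprintf("thickness_change_corr_index lacks region(s): %s",
                 paste(miss, collapse = ", ")))
  invisible(cfg)
}

# inverse-CDF truncated normal (deterministic given RNG stream)
rtnorm_min <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Generate the shape-model training population
#'
#' Non-OA shapes at latent B ~ Normal(0, 1); OA shapes at latent B ~
#' Normal(3, 1) truncated below at 1.5. Sex is assigned by `sex_ratio`;
#' male templates carry an isotropic size offset, so sex is a genuine
#' confounder the per-sex B-score origin/unit must absorb.
#'
#' @param config A [generator_config()].
#' @return List with `shapes` (list of [corresponded_shape()]), `meta`
#'   (data frame: shape_id, sex, group), `latent` (data frame: shape_id,
#'   latent_b), and `templates`/`rim_weights` for reuse.
#' @export
generate_training_population <- function(config) {
  validate_generator_config(config)
  tpl <- make_template(config$n_vertices, config$seed)
  tpl_male <- tpl
  tpl_male$shape <- corresponded_shape(tpl$shape$vertices * config$male_size_factor,
                                       tpl$shape$topology, "template_male")
  normals <- list(female = vertex_normals(tpl$shape),
                  male = vertex_normals(tpl_male$shape))
  n <- config$n_nonOA + config$n_OA
  with_seed(config$seed + 101L, {
    latent <- c(stats::rnorm(config$n_nonOA, 0, 1),
                rtnorm_min(config$n_OA, 3, 1, 1.5))
    # per-group sex counts at the configured ratio (clamped so each sex has
    # at least 2 non-OA shapes, which the per-sex B-score unit requires)
    sex_counts <- function(n_grp, min_each) {
      nf <- round(config$sex_ratio * n_grp)
      nf <- min(max(nf, min_each), n_grp - min_each)
      c(female = nf, male = n_grp - nf)
    }
    cn <- sex_counts(config$n_nonOA, min(2L, config$n_nonOA %/% 2L))
    co <- sex_counts(config$n_OA, 0L)
    sex <- c(sample(rep(c("female", "male"), cn)),
             sample(rep(c("female", "male"), co)))
    group <- rep(c("non_OA", "OA"), c(config$n_nonOA, config$n_OA))
    ids <- sprintf("train_%03d", seq_len(n))
    shapes <- lapply(seq_len(n), function(i) {
      t_i <- if (sex[i] == "female") tpl else tpl_male
      deform_to_bscore(t_i, tpl$rim_weights, latent[i], config,
                       normals = normals[[sex[i]]], shape_id = ids[i])
    })
    list(shapes = shapes,
         meta = data.frame(shape_id = ids, sex = sex, group = group,
                           stringsAsFactors = FALSE),
         latent = data.frame(shape_id = ids, latent_b = latent,
                             stringsAsFactors = FALSE),
         templates = list(female = tpl, male = tpl_male),
         rim_weights = tpl$rim_weights)
  })
}

#' Generate the paired bilateral-knee trial cohort (score level)
#'
#' For each subject: a sex; two knees (index = treated, control =
#' contralateral placebo) with correlated latent baseline B-scores;
#' 6- and 12-month latent changes that are jointly Gaussian with the
#' configured per-arm means, marginal SD `change_sd`, within-subject
#' correlation and within-knee temporal correlation (the 12-month change is
#' the 6-month change plus a consistent second-interval increment); an ICRS
#' grade from thresholding noisy baseline B-score (higher grades have higher
#' mean baseline B-score); and regional cartilage-thickness changes whose
#' correlation with B-score change matches the configured per-region values
#' in index knees and is zero in control knees.
#'
#' Score-level B-scores in the returned table equal the latent values; the
#' `change_sd` calibration is back-derived from published confidence
#' intervals, which already include measurement noise.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (validated cohort data frame, 3 timepoints per
#'   knee) and `truth` (one row per knee: latent baseline, changes, grading
#'   and thickness-change ground truth).
#' @export
generate_trial_cohort <- function(config) {
  validate_generator_config(config)
  ns <- config$n_subjects
  with_seed(config$seed + 202L, {
    sex <- ifelse(stats::runif(ns) < config$sex_ratio, "female", "male")
    subject_id <- sprintf("S%03d", seq_len(ns))
    rho_b <- config$within_subject_baseline_corr
    ub <- stats::rnorm(ns)
    b0 <- sapply(1:2, function(k)
      config$baseline_bscore_mean + config$baseline_bscore_sd *
        (sqrt(rho_b) * ub + sqrt(1 - rho_b) * stats::rnorm(ns)))
    rho_c <- config$change_corr_within_subject
    tau <- config$change_corr_temporal
    u6 <- stats::rnorm(ns); u12 <- stats::rnorm(ns)
    std6 <- std12 <- matrix(0, ns, 2)
    for (k in 1:2) {
      std6[, k] <- sqrt(rho_c) * u6 + sqrt(1 - rho_c) * stats::rnorm(ns)
      raw12 <- sqrt(rho_c) * u12 + sqrt(1 - rho_c) * stats::rnorm(ns)
      std12[, k] <- tau * std6[, k] + sqrt(1 - tau^2) * raw12
    }
    arm <- c("index", "control")
    m6 <- c(index = config$mean_change_index_6m,
            control = config$mean_change_control_6m)
    m12 <- c(index = config$mean_change_index_12m,
             control = config$mean_change_control_12m)
    icrs_noise <- matrix(stats::rnorm(2 * ns, 0, config$icrs_noise_sd), ns, 2)
    thr <- config$icrs_thresholds
    grade_of <- function(x) c(0L, 2L, 3L, 4L)[findInterval(x, thr) + 1L]
    truth <- NULL
    rows <- NULL
    for (k in 1:2) {
      change6 <- m6[arm[k]] + config$change_sd * std6[, k]
      change12 <- m12[arm[k]] + config$change_sd * std12[, k]
      icrs <- grade_of(b0[, k] + icrs_noise[, k])
      th_base <- sapply(thickness_regions, function(r)
        config$thickness_baseline_by_region[[r]] +
          stats::rnorm(ns, 0, config$thickness_baseline_sd))
      dth6 <- dth12 <- matrix(0, ns, length(thickness_regions),
                              dimnames = list(NULL, thickness_regions))
      for (r in thickness_regions) {
        rho_r <- if (arm[k] == "index") config$thickness_change_corr_index[[r]] else 0
        rho_r6 <- rho_r * config$thickness_corr_6m_factor
        dth12[, r] <- config$thickness_change_sd *
          (rho_r * std12[, k] + sqrt(1 - rho_r^2) * stats::rnorm(ns))
        dth6[, r] <- config$thickness_change_sd *
          (rho_r6 * std6[, k] + sqrt(1 - rho_r6^2) * stats::rnorm(ns))
      }
      truth <- rbind(truth, data.frame(
        subject_id = subject_id, knee = arm[k], sex = sex,
        latent_baseline = b0[, k], latent_change_6m = change6,
        latent_change_12m = change12, icrs_grade = icrs,
        stringsAsFactors = FALSE))
      for (tp in c(0, 6, 12)) {
        bs <- switch(as.character(tp), "0" = b0[, k],
                     "6" = b0[, k] + change6, "12" = b0[, k] + change12)
        dth <- switch(as.character(tp), "0" = 0 * dth6, "6" = dth6, "12" = dth12)
        row <- data.frame(subject_id = subject_id, knee = arm[k], sex = sex,
                          timepoint_months = tp, icrs_grade = icrs,
                          bscore = bs, stringsAsFactors = FALSE)
        for (r in thickness_regions)
          row[[paste0("thick_", r)]] <- th_base[, r] + dth[, r]
        rows <- rbind(rows, row)
      }
    }
    rows <- rows[order(rows$subject_id, rows$knee, rows$timepoint_months), ]
    rownames(rows) <- NULL
    validate_cohort(rows)
    list(cohort = rows, truth = truth)
  })
}

#' Generate test-retest B-score replicate pairs
#'
#' Pairs (b, b + e) with e ~ Normal(0, `retest_noise_sd`), emulating first
#' and second image measurements of unchanged knees; input to [sdd()].
#'
#' @param config A [generator_config()].
#' @param n_pairs Number of replicate pairs.
#' @return Data frame with columns `first` and `second`.
#' @export
generate_test_retest <- function(config, n_pairs = 50L) {
  validate_generator_config(config)
  with_seed(config$seed + 303L, {
    b <- stats::rnorm(n_pairs, config$baseline_bscore_mean,
                      config$baseline_bscore_sd)
    e <- if (config$retest_noise_sd > 0)
      stats::rnorm(n_pairs, 0, config$retest_noise_sd) else numeric(n_pairs)
    data.frame(first = b, second = b + e)
  })
}

#' Simulate noisy B-score trajectories at a fixed progression slope
#'
#' Long-format yearly B-score series `b0 + slope * years + noise`, used for
#' slope-recovery checks and reference progressor/non-progressor curves.
#'
#' @param config A [generator_config()] (supplies the baseline distribution
#'   and measurement noise).
#' @param n_knees Number of knees.
#' @param slope_per_annum True slope, B-score units per annum.
#' @param timepoints_months Acquisition times (default yearly over 4 years).
#' @param noise_sd Measurement noise SD; defaults to
#'   `config$measurement_noise_sd`.
#' @param seed Seed offset base; defaults to `config$seed`.
#' @return Data frame with `knee_id`, `timepoint_months`, `bscore`,
#'   and attribute-free `true_slope` column.
#' @export
simulate_knee_trajectories <- function(config, n_knees, slope_per_annum,
                                       timepoints_months = c(0, 12, 24, 36, 48),
                                       noise_sd = config$measurement_noise_sd,
                                       seed = config$seed) {
  with_seed(seed + 404L, {
    b0 <- stats::rnorm(n_knees, config$baseline_bscore_mean,
                       config$baseline_bscore_sd)
    grid <- expand.grid(timepoint_months = timepoints_months,
                        knee_id = seq_len(n_knees))
    grid$bscore <- b0[grid$knee_id] +
      slope_per_annum * grid$timepoint_months / 12 +
      stats::rnorm(nrow(grid), 0, noise_sd)
    grid$true_slope <- slope_per_annum
    grid[, c("knee_id", "timepoint_months", "bscore", "true_slope")]
  })
}
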