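# Synthetic template, training population, trial cohort, test-retest.

test_that("the template is deterministic, closed and rim-weighted", {
  t1 <- make_template(200)
  t2 <- make_template(200)
  expect_identical(t1$shape$vertices, t2$shape$vertices)
  expect_identical(t1$shape$topology$triangles, t2$shape$topology$triangles)
  expect_equal(max(t1$rim_weights), 1)
  expect_true(all(t1$rim_weights >= 0))
  expect_lte(nrow(t1$shape$vertices), 200)
  expect_error(make_template(20), "at least 50")
  # watertight lat-long triangulation: Euler characteristic of a sphere
  v <- nrow(t1$shape$vertices); f <- nrow(t1$shape$topology$triangles)
  expect_equal(v - (3 * f / 2) + f, 2)
})

test_that("zero latent B with zero noise leaves the template unchanged", {
  cfg <- generator_config(measurement_noise_sd = 0, n_vertices = 100)
  tpl <- make_template(100)
  out <- deform_to_bscore(tpl, tpl$rim_weights, 0, cfg)
  expect_equal(out$vertices, tpl$shape$vertices, tolerance = 1e-12)
})

test_that("surface area increases strictly with latent B at zero noise", {
  cfg <- generator_config(measurement_noise_sd = 0, n_vertices = 150)
  tpl <- make_template(150)
  areas <- vapply(c(0, 1, 2, 3), function(b)
    sum(triangle_areas(deform_to_bscore(tpl, tpl$rim_weights, b, cfg))),
    numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("training population matches its config and seed", {
  cfg <- generator_config(seed = 42, n_vertices = 80, n_nonOA = 8, n_OA = 7)
  p1 <- generate_training_population(cfg)
  p2 <- generate_training_population(cfg)
  expect_identical(sum(p1$meta$group == "non_OA"), 8L)
  expect_identical(sum(p1$meta$group == "OA"), 7L)
  expect_identical(p1$latent$latent_b, p2$latent$latent_b)  # bit-identical
  expect_identical(p1$shapes[[3]]$vertices, p2$shapes[[3]]$vertices)
  m_oa <- mean(p1$latent$latent_b[p1$meta$group == "OA"])
  m_non <- mean(p1$latent$latent_b[p1$meta$group == "non_OA"])
  expect_gt(m_oa - m_non, 1)
  expect_true(all(p1$latent$latent_b[p1$meta$group == "OA"] >= 1.5))
})

test_that("measured B-scores track latent values after unit calibration", {
  cfg <- generator_config(seed = 27, n_vertices = 200, n_nonOA = 100, n_OA = 100)
  pop <- generate_training_population(cfg)
  gpa <- generalized_procrustes(pop$shapes)
  model <- fit_shape_model(gpa$aligned)
  coords <- t(sapply(pop$shapes, function(s) project_to_space(s, model)))
  oa <- fit_oa_vector(coords, pop$meta)
  scored <- bscore_cohort(pop$shapes, pop$meta, model, oa)
  fit <- stats::lm(scored$bscore ~ pop$latent$latent_b + pop$meta$sex)
  slope <- unname(stats::coef(fit)["pop$latent$latent_b"])
  expect_lt(abs(slope - 1), 0.1)
  r2 <- summary(stats::lm(scored$bscore ~ pop$latent$latent_b * pop$meta$sex))$r.squared
  expect_gt(r2, 0.9)
})

test_that("degenerate change_sd gives exactly the configured arm means", {
  cfg <- generator_config(seed = 3, change_sd = 0, n_subjects = 10)
  sim <- generate_trial_cohort(cfg)
  ch12 <- change_from_baseline(sim$cohort, "bscore", 12)
  expect_equal(ch12$change[ch12$knee == "index"],
               rep(cfg$mean_change_index_12m, 10), tolerance = 1e-12)
  expect_equal(ch12$change[ch12$knee == "control"],
               rep(cfg$mean_change_control_12m, 10), tolerance = 1e-12)
  ch6 <- change_from_baseline(sim$cohort, "bscore", 6)
  expect_equal(ch6$change[ch6$knee == "control"],
               rep(cfg$mean_change_control_6m, 10), tolerance = 1e-12)
})

test_that("trial cohorts are reproducible and structurally valid", {
  cfg <- generator_config(seed = 9, n_subjects = 20)
  s1 <- generate_trial_cohort(cfg)
  s2 <- generate_trial_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(nrow(s1$cohort), 20L * 2L * 3L)
  expect_silent(validate_cohort(s1$cohort))
  # every subject has both knees at baseline (paired design)
  base <- s1$cohort[s1$cohort$timepoint_months == 0, ]
  expect_true(all(table(base$subject_id) == 2))
})

test_that("index-knee thickness changes carry the configured correlation", {
  cfg <- generator_config(seed = 11, n_subjects = 5000)
  sim <- generate_trial_cohort(cfg)
  chb <- change_from_baseline(sim$cohort, "bscore", 12)
  cht <- change_from_baseline(sim$cohort, "thick_medial_tf", 12)
  m <- merge(chb, cht, by = c("subject_id", "knee"))
  r_index <- stats::cor(m$change.x[m$knee == "index"],
                        m$change.y[m$knee == "index"])
  r_control <- stats::cor(m$change.x[m$knee == "control"],
                          m$change.y[m$knee == "control"])
  expect_lt(abs(r_index - cfg$thickness_change_corr_index[["medial_tf"]]), 0.03)
  expect_lt(abs(r_control), 0.05)
  # lateral regions carry no association in index knees
  chl <- change_from_baseline(sim$cohort, "thick_lateral_tf", 12)
  ml <- merge(chb, chl, by = c("subject_id", "knee"))
  expect_lt(abs(stats::cor(ml$change.x[ml$knee == "index"],
                           ml$change.y[ml$knee == "index"])), 0.05)
})

test_that("ICRS grades rise with baseline B-score", {
  cfg <- generator_config(seed = 13, n_subjects = 500)
  sim <- generate_trial_cohort(cfg)
  mean_by_grade <- tapply(sim$truth$latent_baseline, sim$truth$icrs_grade, mean)
  expect_true(all(diff(mean_by_grade) > 0))
  expect_true(all(sim$truth$icrs_grade %in% c(0L, 2L, 3L, 4L)))
})

test_that("test-retest pairs have the configured difference spread", {
  cfg0 <- generator_config(seed = 1, retest_noise_sd = 0)
  p0 <- generate_test_retest(cfg0, 100)
  expect_true(all(p0$second - p0$first == 0))
  cfg <- generator_config(seed = 1, retest_noise_sd = 0.26)
  p1 <- generate_test_retest(cfg, 10000)
  expect_lt(abs(stats::sd(p1$second - p1$first) - 0.26) / 0.26, 0.05)
  expect_identical(generate_test_retest(cfg, 50), generate_test_retest(cfg, 50))
})

test_that("the paired analysis recovers generator truth within 2 SE", {
  cfg <- generator_config(seed = 29)
  sim <- generate_trial_cohort(cfg)
  ch <- change_from_baseline(sim$cohort, "bscore", 12)
  for (arm in c("index", "control")) {
    v <- ch$change[ch$knee == arm]
    truth <- if (arm == "index") cfg$mean_change_index_12m else cfg$mean_change_control_12m
    expect_lt(abs(mean(v) - truth), 2 * stats::sd(v) / sqrt(length(v)))
  }
})

test_that("generator config validation catches inconsistencies", {
  expect_error(generator_config(change_sd = -1), "non-negative")
  expect_error(generator_config(within_subject_baseline_corr = 1), "-1, 1")
  expect_error(generator_config(n_subjects = 1), "at least 2")
  expect_error(generator_config(icrs_thresholds = c(2, 1, 3)), "increasing")
})
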