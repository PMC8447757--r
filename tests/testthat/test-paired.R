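# Paired/Welch t-tests, Pearson correlations, quartiles, ICRS subgroups.

test_that("paired t reproduces the hand-computed example", {
  # pairs (2,1), (4,2), (6,3): differences {1,2,3}, t = 2/(1/sqrt(3))
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_two_sided, 2 * stats::pt(-2 * sqrt(3), 2), tolerance = 1e-10)
  expect_equal(res$p_two_sided, 0.0742, tolerance = 1e-3)
  expect_equal(res$mean_diff, 2, tolerance = 1e-12)
  # invariant to pair ordering
  perm <- c(3, 1, 2)
  res2 <- paired_t(c(2, 4, 6)[perm], c(1, 2, 3)[perm])
  expect_equal(res2$t_stat, res$t_stat, tolerance = 1e-12)
  expect_equal(res2$p_two_sided, res$p_two_sided, tolerance = 1e-12)
})

test_that("identical pairs give no detectable difference; constant offset errors", {
  res <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$mean_diff, 0)
  expect_equal(res$p_two_sided, 1)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(1, 1), "at least 2")
})

test_that("paired t matches keys and detects a constant shift as n grows", {
  set.seed(41)
  n <- 60
  x <- rnorm(n)
  shift <- 0.5 + rnorm(n, 0, 0.01)
  keys <- sprintf("k%02d", 1:n)
  res <- paired_t(x + shift, x[n:1], keys_x = keys, keys_y = keys[n:1])
  expect_equal(res$mean_diff, mean(shift), tolerance = 1e-12)
  expect_lt(res$p_two_sided, 1e-10)
})

test_that("Welch test matches the brute-force formula", {
  a <- c(1.2, 0.8, 1.5, 1.1)
  b <- c(2.0, 2.6, 1.9, 2.4, 2.2)
  res <- welch_t(a, b)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(res$t_stat, t_hand, tolerance = 1e-10)
  expect_equal(res$df, df_hand, tolerance = 1e-10)
  expect_equal(res$p_two_sided, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-10)
  # identical arms: p = 1; separated arms: decisive
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1, tolerance = 1e-12)
  expect_lt(welch_t(c(0, 1), c(10, 11))$p_two_sided, 0.01)
})

test_that("Pearson correlation matches hand-computed r, p and Fisher CI", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  res <- pearson_ci(x, y)
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  t_hand <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(res$p_two_sided, 2 * stats::pt(-t_hand, 2), tolerance = 1e-10)
  z <- atanh(0.6)
  half <- stats::qnorm(0.975) / sqrt(4 - 3)
  expect_equal(res$ci95_low, tanh(z - half), tolerance = 1e-10)
  expect_equal(res$ci95_high, tanh(z + half), tolerance = 1e-10)
  # symmetry, perfect correlation, degenerate input
  res_yx <- pearson_ci(y, x)
  expect_equal(res_yx$r, res$r, tolerance = 1e-12)
  perfect <- pearson_ci(x, 2 * x + 1)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_equal(c(perfect$ci95_low, perfect$ci95_high), c(1, 1))
  expect_equal(perfect$p_two_sided, 0)
  expect_error(pearson_ci(c(1, 1, 1, 1), y), "zero variance")
  expect_error(pearson_ci(x[1:3], y[1:3]), "at least 4")
  # missing pairs are deleted, n reflects it
  res_na <- pearson_ci(c(x, NA, 5), c(y, 2, NA))
  expect_equal(res_na$n, 4L)
})

test_that("quartile stratification equals a brute-force group-by", {
  set.seed(43)
  n <- 10
  idx <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    change = rnorm(n), stringsAsFactors = FALSE)
  th <- data.frame(subject_id = idx$subject_id,
                   medial_tf = rnorm(n), lateral_tf = rnorm(n),
                   stringsAsFactors = FALSE)
  qt <- quartile_stratify(idx, th)
  # brute force: sort, cut into 4 nearly equal blocks, aggregate
  ord <- order(idx$change, idx$subject_id)
  sizes <- diff(floor(seq(0, n, length.out = 5)))
  expect_true(max(sizes) - min(sizes) <= 1)
  assign_q <- integer(n)
  assign_q[ord] <- rep(1:4, sizes)
  for (q in 1:4) {
    ids <- idx$subject_id[assign_q == q]
    for (r in c("medial_tf", "lateral_tf")) {
      v <- th[[r]][th$subject_id %in% ids]
      row <- qt[qt$quartile == q & qt$region == r, ]
      expect_equal(row$mean_change, mean(v), tolerance = 1e-12)
      expect_equal(row$sem, stats::sd(v) / sqrt(length(v)), tolerance = 1e-12)
      expect_equal(row$n, length(v))
    }
  }
  # quartiles ordered by increasing B-score change
  q_means <- tapply(idx$change[ord], rep(1:4, sizes), mean)
  expect_true(all(diff(q_means) >= 0))
  expect_error(quartile_stratify(idx[1:3, ], th), "at least 4")
})

test_that("equal thickness changes give identical quartile means with SEM 0", {
  idx <- data.frame(subject_id = sprintf("S%d", 1:8), change = 1:8 / 10)
  th <- data.frame(subject_id = idx$subject_id, medial_fc = rep(0.05, 8))
  qt <- quartile_stratify(idx, th)
  expect_true(all(qt$n == 2))
  expect_true(all(qt$mean_change == 0.05))
  expect_true(all(qt$sem == 0))
})

test_that("ICRS subgroup analysis is consistent with its building blocks", {
  cfg <- generator_config(seed = 47, n_subjects = 60)
  sim <- generate_trial_cohort(cfg)
  tab <- icrs_subgroup_analysis(sim$cohort, 12)
  expect_identical(tab$icrs_threshold, c(">=0", ">=2", ">=3", "=4"))
  # all-knees row equals the plain paired test on the full cohort
  ch <- change_from_baseline(sim$cohort, "bscore", 12)
  tt <- paired_t(ch$change[ch$knee == "control"], ch$change[ch$knee == "index"],
                 keys_x = ch$subject_id[ch$knee == "control"],
                 keys_y = ch$subject_id[ch$knee == "index"])
  expect_equal(tab$difference[1], tt$mean_diff, tolerance = 1e-12)
  expect_equal(tab$p_two_sided[1], tt$p_two_sided, tolerance = 1e-12)
  expect_identical(tab$t_flavor, c("paired", rep("welch_unpaired", 3)))
  # subgroup means equal brute-force filtering
  base <- sim$cohort[sim$cohort$timepoint_months == 0, ]
  sel <- base$icrs_grade >= 3 & base$knee == "index"
  expect_equal(tab$baseline_bscore_index[3], mean(base$bscore[sel]),
               tolerance = 1e-12)
  expect_equal(tab$n_index[3], sum(sel))
  # counts are monotone over nested thresholds
  expect_true(all(diff(tab$n_index[1:3]) <= 0))
})

test_that("a uniform ICRS grade makes all subgroup rows identical in counts", {
  cohort <- toy_cohort()
  cohort$icrs_grade <- 4L
  tab <- suppressWarnings(icrs_subgroup_analysis(cohort, 12))
  expect_true(all(tab$n_index == 2))
  expect_true(all(tab$n_control == 2))
})

test_that("change_from_baseline drops incomplete knees and counts them", {
  cohort <- toy_cohort()
  ch <- change_from_baseline(cohort, "bscore", 12)
  expect_equal(nrow(ch), 4)
  expect_equal(attr(ch, "n_dropped"), 0)
  expect_true(all(abs(ch$change - 0.2) < 1e-12))
  cohort$bscore[cohort$subject_id == "S01" & cohort$knee == "index" &
                  cohort$timepoint_months == 12] <- NA
  ch2 <- change_from_baseline(cohort, "bscore", 12)
  expect_equal(nrow(ch2), 3)
  expect_equal(attr(ch2, "n_dropped"), 1)
})

test_that("correlation analyses tolerate missing thickness values (pairwise n)", {
  cfg <- generator_config(seed = 51, n_subjects = 30)
  sim <- generate_trial_cohort(cfg)
  cohort <- sim$cohort
  drop_row <- which(cohort$knee == "control" & cohort$timepoint_months == 12)[1:2]
  cohort$thick_entire_tf[drop_row] <- NA
  rep <- full_report(cohort)
  tab5 <- rep$correlations_control
  n_tf <- tab5$n[tab5$region == "entire_tf" & tab5$timepoint_months == 12]
  expect_equal(n_tf, 28L)
  n_fc <- tab5$n[tab5$region == "entire_fc" & tab5$timepoint_months == 12]
  expect_equal(n_fc, 30L)
})

test_that("the 12-month paired test has power against the configured truth", {
  rejections <- 0L
  direction_ok <- 0L
  for (seed in 1:20) {
    sim <- generate_trial_cohort(generator_config(seed = seed))
    ch <- change_from_baseline(sim$cohort, "bscore", 12)
    tt <- paired_t(ch$change[ch$knee == "control"], ch$change[ch$knee == "index"],
                   keys_x = ch$subject_id[ch$knee == "control"],
                   keys_y = ch$subject_id[ch$knee == "index"])
    rejections <- rejections + (tt$p_two_sided < 0.05)
    direction_ok <- direction_ok + (tt$mean_diff > 0)
  }
  expect_gt(rejections, 10)       # majority of replicates reject
  expect_gt(direction_ok, 16)     # control knees worsen faster
})
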