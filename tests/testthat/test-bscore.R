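# OA vector fitting and B-score computation.

meta_1sex <- function(groups) {
  data.frame(shape_id = sprintf("s%d", seq_along(groups)),
             sex = "female", group = groups, stringsAsFactors = FALSE)
}

test_that("hand-computed OA vector: direction, origin and unit", {
  coords <- rbind(c(0, 0), c(2, 0), c(4, 0), c(6, 0))
  oa <- fit_oa_vector(coords, meta_1sex(c("non_OA", "non_OA", "OA", "OA")))
  expect_equal(as.numeric(oa$direction), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(oa$origin_by_sex["female"]), 1, tolerance = 1e-12)
  expect_equal(unname(oa$scale_by_sex["female"]), sqrt(2), tolerance = 1e-12)
  expect_equal(bscore_of(c(1, 5), "female", oa), 0, tolerance = 1e-12)
})

test_that("zero spread of non-OA projections is a degenerate-scale error", {
  coords <- rbind(c(0, 0), c(0, 2), c(3, 1), c(5, 1))
  expect_error(fit_oa_vector(coords, meta_1sex(c("non_OA", "non_OA", "OA", "OA"))),
               "degenerate scale")
})

test_that("swapping group labels flips the direction sign exactly", {
  set.seed(14)
  coords <- matrix(rnorm(40), 10, 4)
  grp <- rep(c("non_OA", "OA"), each = 5)
  m1 <- meta_1sex(grp)
  m2 <- meta_1sex(rev(grp))
  d1 <- fit_oa_vector(coords, m1)$direction
  d2 <- fit_oa_vector(coords, m2)$direction
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("B-score definition: origin, unit, linearity, orthogonal invariance", {
  set.seed(15)
  k <- 5
  coords <- rbind(matrix(rnorm(20 * k), 20, k),
                  matrix(rnorm(10 * k, mean = 2), 10, k))
  meta <- data.frame(shape_id = sprintf("s%d", 1:30),
                     sex = rep(c("female", "male"), 15),
                     group = rep(c("non_OA", "OA"), c(20, 10)),
                     stringsAsFactors = FALSE)
  oa <- fit_oa_vector(coords, meta)
  expect_equal(sum(oa$direction^2), 1, tolerance = 1e-10)

  for (s in c("female", "male")) {
    origin_pt <- oa$direction * oa$origin_by_sex[[s]]
    expect_equal(bscore_of(origin_pt, s, oa), 0, tolerance = 1e-10)
    unit_pt <- origin_pt + oa$scale_by_sex[[s]] * oa$direction
    expect_equal(bscore_of(unit_pt, s, oa), 1, tolerance = 1e-10)
    for (c0 in c(-2, 0.5, 3, 10))
      expect_equal(bscore_of(origin_pt + c0 * oa$scale_by_sex[[s]] * oa$direction,
                             s, oa), c0, tolerance = 1e-9)
  }
  # displacement orthogonal to the direction leaves the B-score unchanged
  x <- rnorm(k)
  perp <- rnorm(k)
  perp <- perp - sum(perp * oa$direction) * oa$direction
  expect_equal(bscore_of(x + perp, "female", oa),
               bscore_of(x, "female", oa), tolerance = 1e-10)
  expect_error(bscore_of(x, "unknown", oa), "unknown sex")
})

test_that("non-OA training B-scores have per-sex mean 0 and SD 1 by construction", {
  set.seed(16)
  coords <- matrix(rnorm(40 * 6, sd = 3), 40, 6)
  meta <- data.frame(shape_id = sprintf("s%d", 1:40),
                     sex = rep(c("female", "male"), 20),
                     group = rep(c("non_OA", "OA"), each = 20),
                     stringsAsFactors = FALSE)
  oa <- fit_oa_vector(coords, meta)
  for (s in c("female", "male")) {
    idx <- meta$group == "non_OA" & meta$sex == s
    b <- bscore_of(coords[idx, ], s, oa)
    expect_equal(mean(b), 0, tolerance = 1e-8)
    expect_equal(stats::sd(b), 1, tolerance = 1e-8)
  }
})

test_that("bscore_cohort equals the map of per-shape scores", {
  set.seed(17)
  pop <- generate_training_population(generator_config(
    seed = 17, n_vertices = 80, n_nonOA = 6, n_OA = 6))
  gpa <- generalized_procrustes(pop$shapes)
  model <- fit_shape_model(gpa$aligned)
  coords <- t(sapply(pop$shapes, function(s) project_to_space(s, model)))
  oa <- fit_oa_vector(coords, pop$meta)

  empty <- bscore_cohort(list(), pop$meta[0, ], model, oa)
  expect_identical(nrow(empty), 0L)

  batch <- bscore_cohort(pop$shapes, pop$meta, model, oa)
  single <- bscore_of(project_to_space(pop$shapes[[4]], model),
                      pop$meta$sex[4], oa)
  expect_equal(batch$bscore[4], single, tolerance = 1e-12)
  loop <- vapply(seq_along(pop$shapes), function(i)
    bscore_of(project_to_space(pop$shapes[[i]], model), pop$meta$sex[i], oa),
    numeric(1))
  expect_equal(batch$bscore, loop, tolerance = 1e-12)
})

test_that("OA vectors survive a JSON round trip", {
  set.seed(18)
  coords <- matrix(rnorm(40), 10, 4)
  meta <- data.frame(shape_id = sprintf("s%d", 1:10),
                     sex = rep(c("female", "male"), 5),
                     group = rep(c("non_OA", "OA"), each = 5),
                     stringsAsFactors = FALSE)
  oa <- fit_oa_vector(coords, meta)
  path <- withr::local_tempfile(fileext = ".json")
  write_oa_vector(oa, path)
  back <- read_oa_vector(path)
  expect_equal(back$direction, oa$direction, tolerance = 1e-12)
  expect_equal(back$origin_by_sex, oa$origin_by_sex, tolerance = 1e-12)
  expect_equal(back$scale_by_sex, oa$scale_by_sex, tolerance = 1e-12)
})
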