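# Clock construction: age transforms, elastic-net training, prediction,
# published coefficient tables, serialization.

test_that("loglog transform round-trips relative age", {
  tr <- age_transform("loglog", max_age = 67)
  a <- 1:66
  rel <- inverse_transform_age(tr, transform_age(tr, a))
  expect_equal(rel, a / 67, tolerance = 1e-10)
  ## boundary inputs are clipped rather than Inf
  expect_true(is.finite(transform_age(tr, 67)))
  expect_error(age_transform("loglog"), "max_age")
})

test_that("minmax transform round-trips after fitting on training ages", {
  ages <- 1:73
  tr <- stochclock:::fit_transform(age_transform("minmax"), ages)
  y <- transform_age(tr, ages)
  expect_equal(range(y), c(-120, 280))  # x400 - 120 on [0, 1]
  expect_equal(inverse_transform_age(tr, y), as.numeric(ages))
  ## unfitted use errors
  expect_error(transform_age(age_transform("minmax"), ages), "not fitted")
})

test_that("multiply and horvath transforms invert", {
  tr2 <- age_transform("multiply", k = 2)
  expect_equal(inverse_transform_age(tr2, transform_age(tr2, 1:16)), 1:16)
  trh <- age_transform("horvath")
  a <- c(0.5, 5, 20, 21, 80)
  expect_equal(inverse_transform_age(trh, transform_age(trh, a)), a,
               tolerance = 1e-10)
})

test_that("trained clocks are sparse and predict well within the design", {
  ex <- small_experiment("bulk", n_features = 300, sd = 0.03, seed = 1)
  expect_gt(ex$report$pearson_r, 0.85)
  nz <- ex$model$training_meta$n_nonzero
  expect_true(nz >= 1 && nz <= 300)
  expect_lt(nz, 300)  # elastic net shrinks some coefficients to exactly 0
})

test_that("training validates its inputs", {
  g <- make_ground_state(20, seed = 2)
  d <- generate_dataset(g, max_age = 10, n_sets = 2, noise_config(0.05, seed = 3))
  one_age <- split_sets(d, 1)
  one_age$ages <- rep(5, length(one_age$ages))
  expect_error(train_clock(one_age), "distinct ages")
  ## loglog domain violation: age equal to max_age
  expect_error(train_clock(split_sets(d, 1),
                           transform = age_transform("loglog", max_age = 10)),
               "domain")
})

test_that("prediction applies the inverse transform and checks features", {
  tab <- data.frame(feature_id = c("cg1", "cg2", "(Intercept)"),
                    coefficient = c(0.5, -0.5, 10))
  m <- load_clock_coefficients(tab)
  x <- matrix(c(1, 0), 1, dimnames = list(NULL, c("cg1", "cg2")))
  expect_equal(predict(m, x), 10.5)
  ## all-zero coefficients predict the (inverse-transformed) intercept
  m0 <- load_clock_coefficients(
    data.frame(feature_id = c("cg1", "cg2", "(Intercept)"),
               coefficient = c(0, 0, 7)))
  expect_equal(predict(m0, x), 7)
  ## missing features are reported by name
  expect_error(predict(m, matrix(1, 1, dimnames = list(NULL, "cg1"))), "cg2")
})

test_that("coefficient tables are validated on load", {
  expect_error(load_clock_coefficients(data.frame()), "empty")
  expect_error(load_clock_coefficients(
    data.frame(feature_id = c("cg1", "cg1"), coefficient = c(1, 2))),
    "duplicate")
  expect_warning(load_clock_coefficients(
    data.frame(feature_id = "cg1", coefficient = 1)), "intercept")
})

test_that("a published-style table with a year-scale transform applies to flat 0.5 input", {
  ## pan-tissue-style clocks transform the linear predictor through a
  ## piecewise log-linear year scale; flat 0.5 methylation then maps to one
  ## prediction determined entirely by the table
  tab <- data.frame(feature_id = c("cg1", "cg2", "cg3", "(Intercept)"),
                    coefficient = c(2, -1, 0.5, 0.7))
  m <- load_clock_coefficients(tab, transform = age_transform("horvath"))
  x05 <- matrix(0.5, 1, 3, dimnames = list(NULL, c("cg1", "cg2", "cg3")))
  lp <- 0.7 + 0.5 * (2 - 1 + 0.5)
  expect_equal(predict(m, x05), (1 + 20) * lp + 20)
})

test_that("clock serialization round-trips through TSV", {
  ex <- small_experiment("bulk", n_features = 50, max_age = 20, n_sets = 2,
                         seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_clock(ex$model, path)
  m2 <- read_clock(path)
  expect_equal(unname(m2$coefficients), unname(ex$model$coefficients),
               tolerance = 1e-10)
  expect_equal(m2$intercept, ex$model$intercept, tolerance = 1e-10)
  expect_equal(predict(m2, ex$ground$values |>
                         matrix(1, dimnames = list(NULL, ex$ground$feature_ids))),
               predict(ex$model, matrix(ex$ground$values, 1,
                                        dimnames = list(NULL, ex$ground$feature_ids))))
})

test_that("fixed-penalty training honours the supplied grid", {
  g <- make_ground_state(100, seed = 5)
  d <- generate_dataset(g, max_age = 73, n_sets = 1, noise_config(0.03, seed = 6))
  m <- train_clock(d, transform = "minmax", alphas = 1, seed = 7)
  expect_equal(m$training_meta$chosen_lambda, 1)
  expect_identical(m$transform$type, "minmax")
})

test_that("coefficients scale with the transformed target (affine equivariance)", {
  g <- make_ground_state(150, seed = 8)
  d <- generate_dataset(g, max_age = 40, n_sets = 2, noise_config(0.03, seed = 9))
  m1 <- train_clock(d, transform = "identity", seed = 10)
  m2 <- train_clock(d, transform = age_transform("multiply", k = 3), seed = 10)
  ## same foldid and relative lambda path: coefficients scale by 3
  expect_equal(unname(m2$coefficients), unname(3 * m1$coefficients),
               tolerance = 1e-6)
  expect_equal(m2$intercept, 3 * m1$intercept, tolerance = 1e-6)
})

test_that("independently trained clocks share coefficient geometry", {
  ## two clocks trained on independent data from the same ground state
  ## agree on their coefficients well beyond chance, and the coefficients
  ## associate positively with (0.5 - ground value): low-start features
  ## get positive weights, high-start features negative (regression to
  ## the mean). The full-strength reproducibility bound is exercised at
  ## the benchmark scale in the acceptance suite.
  g <- make_ground_state(800, seed = 11)
  cfg1 <- noise_config(0.03, seed = 12)
  cfg2 <- noise_config(0.03, seed = 13)
  d1 <- generate_dataset(g, max_age = 100, n_sets = 3, cfg1)
  d2 <- generate_dataset(g, max_age = 100, n_sets = 3, cfg2)
  m1 <- train_clock(d1, seed = 14)
  m2 <- train_clock(d2, seed = 15)
  expect_gt(cor(m1$coefficients, m2$coefficients), 0.4)
  nz <- m1$coefficients != 0
  expect_gt(cor(0.5 - g$values[nz], m1$coefficients[nz]), 0)
  expect_gt(cor(0.5 - g$values[nz], m2$coefficients[nz]), 0)
})
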