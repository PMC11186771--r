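# Transcriptome binarization, cell-type adjustment, covariate regression.

test_that("binarization follows the log10 / min-max / masked-median pipeline", {
  ## hand-computed, sample s1: counts (0, 9, 99, 999) -> log10+1 =
  ## (0,1,2,3) -> per-sample min-max (0, 1/3, 2/3, 1); median over
  ## nonzero-masked values (1/3, 2/3, 1) = 2/3; strictly greater than the
  ## median -> (0, 0, 0, 1). s2: (9, 9, 99, 999) -> (0, 0, 0.5, 1),
  ## median 0.25 -> (0, 0, 1, 1).
  m <- matrix(c(0, 9, 99, 999,
                9, 9, 99, 999), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  b <- binarize_expression(m)
  expect_equal(unname(b[, "s1"]), c(0L, 0L, 0L, 1L))
  expect_equal(unname(b[, "s2"]), c(0L, 0L, 1L, 1L))
})

test_that("binarization output is binary and drops all-zero genes only", {
  set.seed(1)
  counts <- matrix(rnbinom(200 * 10, mu = 20, size = 1), 200, 10,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  counts[5, ] <- 0                      # all-zero gene
  counts[6, 1] <- 0                     # zero in one sample only
  b <- binarize_expression(counts)
  expect_true(all(b %in% c(0L, 1L)))
  expect_equal(ncol(b), 10)             # sample count preserved
  expect_false("g5" %in% rownames(b))   # absent from output
  expect_true("g6" %in% rownames(b))
  ## ties with the median binarize to 0 (strict inequality)
  tied <- matrix(c(0, 10, 10, 10), 4, 1, dimnames = list(paste0("g", 1:4), "s"))
  expect_equal(sum(binarize_expression(tied)), 0L)
  ## degenerate sample errors
  expect_error(binarize_expression(matrix(7, 3, 1)), "distinct")
})

test_that("transcriptomic aging simulation uses the 16x10 design", {
  ## the ground state is a binarized expression sample: every feature sits
  ## at a bound, so even sd = 0.01 noise drifts inward measurably
  set.seed(2)
  counts <- matrix(rnbinom(300 * 4, mu = 50, size = 1), 300, 4)
  g <- ground_state(binarize_expression(counts)[, 1],
                    origin = "binarized-sample")
  d <- simulate_transcriptome_aging(g, noise_config(0.01, seed = 3))
  expect_equal(nrow(d$matrix), 160)
  expect_equal(sort(unique(d$ages)), 1:16)
  expect_equal(as.vector(table(d$ages)), rep(10L, 16))
  ## clock on such data recovers held-out simulated age (x2 rescale)
  train <- split_sets(d, 1:5)
  valid <- split_sets(d, 6:10)
  m <- train_clock(train, transform = age_transform("multiply", k = 2),
                   seed = 4)
  expect_gt(score_predictions(valid$ages, predict(m, valid))$pearson_r, 0.9)
})

test_that("cell-type adjustment preserves feature means and removes fraction-driven variance", {
  set.seed(5)
  n <- 50
  f <- celltype_fractions(t(vapply(seq_len(n), function(i) {
    g <- rgamma(7, c(2, 2, 6, 4, 3, 20, 1)); g / sum(g)
  }, numeric(7))))
  colnames(f) <- c("B", "NK", "CD4T", "CD8T", "Mono", "Neutro", "Eosino")
  ## mid-range betas: the [0,1] clip never binds, so means are preserved
  ## exactly (residuals sum to zero with an intercept)
  betas <- matrix(runif(n * 20, 0.3, 0.7), n, 20)
  adj <- celltype_adjust(betas, f)
  expect_equal(colMeans(adj), colMeans(betas), tolerance = 1e-12)
  expect_true(all(adj >= 0 & adj <= 1))
  ## boundary-heavy betas are clipped into range
  extreme <- matrix(rep(c(0.01, 0.99), length.out = n * 4), n, 4)
  expect_true(all(celltype_adjust(extreme, f) >= 0 &
                  celltype_adjust(extreme, f) <= 1))
  ## beta that is an exact linear function of fractions collapses to its mean
  lin <- 0.2 + f %*% c(0.1, 0.2, 0.05, 0.1, 0, 0.02, 0.3)
  adj_lin <- celltype_adjust(cbind(lin, betas), f)[, 1]
  expect_equal(adj_lin, rep(mean(lin), n), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## identical fractions across samples explain nothing: adjustment is a
  ## no-op (regression explains nothing beyond the mean)
  adj_const <- celltype_adjust(betas, matrix(1 / 7, n, 7))
  expect_equal(adj_const, betas, tolerance = 1e-10)
  ## genuinely collinear cell types are rejected
  f_dup <- f
  f_dup[, 2] <- f_dup[, 1]
  f_dup <- f_dup / rowSums(f_dup)
  expect_error(celltype_adjust(betas, f_dup), "collinear")
  expect_error(celltype_fractions(matrix(0.5, 4, 7)), "sums")
})

test_that("covariate regression recovers coefficients and calibrates p-values", {
  ## single covariate equal to the response: slope 1, zero residuals
  y <- rnorm(20)
  tab <- suppressWarnings(covariate_regression(y, data.frame(x = y)))
  expect_equal(tab$estimate[tab$term == "x"], 1, tolerance = 1e-12)

  ## parameter recovery: known interaction slope, 500 replicates;
  ## the 2-SE interval should cover the truth ~95% of the time
  set.seed(6)
  n <- 60; b_int <- 0.5
  cover <- logical(500)
  for (i in seq_len(500)) {
    age <- runif(n, 1, 50)
    treated <- rep(0:1, n / 2)
    y <- 1 + 0.8 * age - 2 * treated + b_int * age * treated + rnorm(n)
    tab <- covariate_regression(y, data.frame(age = age, treated = treated),
                                interactions = "age:treated")
    row <- tab[tab$term == "age:treated", ]
    cover[i] <- abs(row$estimate - b_int) <= 2 * row$std_error
  }
  expect_gte(mean(cover), 0.93)

  ## null calibration: p-values of a zero-effect covariate are uniform
  set.seed(7)
  pvals <- replicate(500, {
    y <- rnorm(30)
    covariate_regression(y, data.frame(x = rnorm(30)))$p_value[2]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  ## rank deficiency errors
  expect_error(
    covariate_regression(rnorm(10), data.frame(a = 1:10, b = 1:10)),
    "rank")
})
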