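# Single-cell methylation simulator: equilibrium algebra, rate
# estimation, population dynamics, dataset assembly.

test_that("equilibrium follows M_eq = E_d / (1 + E_d - E_m)", {
  expect_equal(as.numeric(equilibrium(maintenance_rates(0.999, 0.001))), 0.5)
  expect_equal(as.numeric(equilibrium(maintenance_rates(0.96, 0))), 0)
  expect_equal(as.numeric(equilibrium(maintenance_rates(1, 0.05))), 1)
  ## perfectly maintained site: 0/0 flagged, not a number
  meq <- equilibrium(maintenance_rates(c(1, 0.999), c(0, 0.001)))
  expect_true(is.na(meq[1]))
  expect_identical(attr(meq, "perfectly_maintained"), c(TRUE, FALSE))
  expect_equal(meq[2], 0.5)
})

test_that("rate limits are enforced", {
  expect_error(maintenance_rates(0.94, 0.01), "E_m")
  expect_error(maintenance_rates(0.99, 0.23), "E_d")
  ## improved limits are stricter
  expect_error(maintenance_rates(0.96, 0.01, rate_limits(0.97, 1, 0, 0.05)),
               "E_m")
  expect_silent(maintenance_rates(0.98, 0.01, rate_limits(0.97, 1, 0, 0.05)))
})

test_that("estimate_rates inverts the equilibrium equation", {
  ## algebraic spot check: M_eq = 0.5 with E_m fixed at 0.999 forces E_d = 0.001
  set.seed(1)
  lim <- rate_limits(0.999 - 1e-9, 0.999 + 1e-9, 0, 0.23)
  r <- estimate_rates(0.5, limits = lim, fix_side = "fix_em", seed = 2)
  expect_equal(r$e_d, 0.001, tolerance = 1e-6)

  ## round trip: equilibrium(estimate_rates(m)) == m to 1e-12, both fix sides
  m <- runif(1000, 0.01, 0.99)
  for (side in c("fix_em", "fix_ed")) {
    est <- estimate_rates(m, fix_side = side, seed = 3)
    expect_equal(as.numeric(equilibrium(est)), m, tolerance = 1e-12)
    expect_identical(est$provenance, "estimated")
  }

  ## degenerate equilibria short-circuit
  est0 <- estimate_rates(c(0, 1), seed = 4)
  expect_equal(est0$e_d[1], 0)
  expect_equal(est0$e_m[2], 1)
  expect_equal(as.numeric(equilibrium(est0)), c(0, 1))
})

test_that("population initialization rounds half-up", {
  expect_equal(init_population(ground_state(0.13), 1000)$methylated_counts, 130L)
  expect_equal(init_population(ground_state(c(0, 1)), 500)$methylated_counts,
               c(0L, 500L))
  expect_equal(init_population(ground_state(0.5005), 1000)$methylated_counts,
               501L)
})

test_that("perfect maintenance leaves the population unchanged", {
  g <- make_ground_state(50, seed = 5)
  pop <- init_population(g, 200)
  r <- maintenance_rates(1, 0)
  p2 <- pop
  for (i in 1:20) p2 <- step_population(p2, r)
  expect_identical(p2$methylated_counts, pop$methylated_counts)
})

test_that("counts are conserved within [0, n_cells]", {
  g <- make_ground_state(100, seed = 6)
  pop <- init_population(g, 100)
  r <- maintenance_rates(0.96, 0.2)
  set.seed(7)
  for (i in 1:50) {
    pop <- step_population(pop, r)
    expect_true(all(pop$methylated_counts >= 0 &
                    pop$methylated_counts <= 100))
  }
})

test_that("binomial update matches the per-cell Bernoulli oracle", {
  ## n_cells = 50, 1e4 replicates: mean and variance of the one-step count
  ## must agree between the aggregate binomial update and literal
  ## per-cell coin flips, within Monte-Carlo error
  pop <- init_population(ground_state(c(0.2, 0.5, 0.9)), 50)
  r <- maintenance_rates(0.97, 0.1)
  set.seed(8)
  agg <- replicate(1e4, step_population(pop, r)$methylated_counts)
  percell <- replicate(1e4, stochclock:::step_population_percell(pop, r)$methylated_counts)
  for (i in 1:3) {
    se_mean <- sd(percell[i, ]) / sqrt(1e4)
    expect_lt(abs(mean(agg[i, ]) - mean(percell[i, ])), 5 * se_mean)
    expect_lt(abs(var(agg[i, ]) / var(percell[i, ]) - 1), 0.1)
  }
  ## analytic expectation: E[m'] = m E_m + (N - m) E_d
  expect_equal(mean(agg[2, ]), 25 * 0.97 + 25 * 0.1,
               tolerance = 5 * sd(agg[2, ]) / sqrt(1e4) / 25)
})

test_that("expected beta approaches equilibrium geometrically", {
  ## E[beta_t] - M_eq = (beta_0 - M_eq) * (E_m - E_d)^t, checked on 100
  ## random admissible rate pairs via large-population one-shot simulation
  set.seed(9)
  for (i in 1:100) {
    em <- runif(1, 0.951, 0.999)
    ed <- runif(1, 0.001, 0.2)
    beta0 <- runif(1, 0.05, 0.95)
    meq <- ed / (1 + ed - em)
    t_steps <- sample(1:20, 1)
    n_cells <- 20000  # large population: empirical beta ~= expectation
    pop <- init_population(ground_state(beta0), n_cells)
    r <- maintenance_rates(em, ed)
    for (s in seq_len(t_steps)) pop <- step_population(pop, r)
    expected <- meq + (beta0 - meq) * (em - ed)^t_steps
    expect_equal(pop$methylated_counts / n_cells, expected,
                 tolerance = 6 / sqrt(n_cells))
  }
})

test_that("methylation datasets have the 0..max_age-1 per-set design", {
  g <- make_ground_state(30, seed = 10)
  r <- maintenance_rates(0.999, 0.001)
  d <- simulate_methylation_dataset(g, r, max_age = 20, n_sets = 3,
                                    n_cells = 100, seed = 11)
  expect_equal(sort(unique(d$ages)), 0:19)
  expect_equal(as.vector(table(d$set_label)), rep(20L, 3))
  ## age 0 equals the rounded ground state
  age0 <- d$matrix[d$ages == 0, , drop = FALSE]
  expect_equal(unname(age0[1, ]), floor(g$values * 100 + 0.5) / 100)
  ## reproducible
  d2 <- simulate_methylation_dataset(g, r, max_age = 20, n_sets = 3,
                                     n_cells = 100, seed = 11)
  expect_identical(d$matrix, d2$matrix)
  ## betas always in [0, 1]
  expect_true(all(d$matrix >= 0 & d$matrix <= 1))
})

test_that("high universal maintenance keeps age-100 samples near the ground state", {
  ## with E_m = E_u = 99.9% the expected drift after 100 steps is
  ## |beta_0 - 0.5| * (1 - 0.998^100) toward 0.5 -- small
  g <- make_ground_state(200, seed = 12)
  r <- maintenance_rates(0.999, 0.001)
  d <- simulate_methylation_dataset(g, r, max_age = 100, n_sets = 1,
                                    n_cells = 1000, seed = 13)
  old <- d$matrix[d$ages == 99, ]
  expect_lt(mean(abs(old - g$values)), 0.06)
  ## and the drift direction is toward 0.5 on average
  drift <- (old - g$values)[abs(g$values - 0.5) > 0.2]
  expect_gt(cor(drift, (0.5 - g$values)[abs(g$values - 0.5) > 0.2]), 0.5)
})
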