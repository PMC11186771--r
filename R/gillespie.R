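# Event-based (Gillespie) variant of the single-cell simulator. Each
# cell-site is a two-state continuous-time chain with one reaction per
# direction (methylation / demethylation); waiting times between state
# switches are exponential at the configured rates, so time steps are not
# uniform but drawn until the observation time, tmax, or the event budget
# is reached.

#' Configuration for the event-based simulator
#'
#' @param switch_rate_on rate of unmethylated -> methylated switching.
#' @param switch_rate_off rate of methylated -> unmethylated switching.
#' @param tmax simulation end time (arbitrary units).
#' @param nrmax maximum number of switch events per site trajectory;
#'   reaching it truncates the simulation with a warning (the default is
#'   a safety bound that never binds at the default rates).
#' @param seed optional integer root seed.
#' @return An object of class `gillespie_config`. Defaults: both rates
#'   0.1, `tmax = 5`, `nrmax = 8000`.
#' @export
gillespie_config <- function(switch_rate_on = 0.1, switch_rate_off = 0.1,
                             tmax = 5, nrmax = 8000, seed = NULL) {
  check_scalar_number(switch_rate_on, "switch_rate_on")
  check_scalar_number(switch_rate_off, "switch_rate_off")
  if (switch_rate_on <= 0 || switch_rate_off <= 0)
    stop_arg("switch rates must be > 0")
  check_scalar_number(tmax, "tmax", min = 0)
  check_scalar_number(nrmax, "nrmax", min = 1, integerish = TRUE)
  structure(list(switch_rate_on = switch_rate_on,
                 switch_rate_off = switch_rate_off,
                 tmax = tmax, nrmax = as.integer(nrmax), seed = seed),
            class = "gillespie_config")
}

## Evolve a vector of binary states to time `t_obs` by drawing exponential
## waiting times; returns the states at t_obs. `nrmax` caps the number of
## switch events per site trajectory; trajectories that exhaust it are
## frozen at their last state (with a warning).
gillespie_states_at <- function(states, t_obs, cfg) {
  t <- numeric(length(states))
  active <- seq_along(states)
  events <- 0L
  truncated <- FALSE
  while (length(active)) {
    events <- events + 1L
    if (events > cfg$nrmax) {
      truncated <- TRUE
      break
    }
    rate <- ifelse(states[active] == 1L, cfg$switch_rate_off,
                   cfg$switch_rate_on)
    dt <- stats::rexp(length(active), rate)
    t[active] <- t[active] + dt
    flip <- t[active] <= t_obs
    idx <- active[flip]
    states[idx] <- 1L - states[idx]
    active <- idx
  }
  if (truncated)
    warning(sprintf(
      "event budget nrmax = %d reached before t = %g for %d site(s); states truncated",
      cfg$nrmax, t_obs, length(active)), call. = FALSE)
  states
}

#' Simulate a dataset with the event-based algorithm
#'
#' Each replicate set is one binary cell population whose states are
#' recorded at an evenly spaced observation grid over \[0, tmax\]
#' (including both ends); between observation times the population
#' evolves by exponential waiting times (the two-state chain is
#' memoryless, so segment-wise evolution is exact). The arbitrary
#' observation times are min-max rescaled to `age_range` for reporting,
#' mirroring how the event-based time axis is mapped onto the same range
#' as a step-based simulated age (this rescaling does not affect
#' correlation results).
#'
#' @param ground a [ground_state()] of methylated fractions.
#' @param cfg a [gillespie_config()].
#' @param n_sets number of independent replicate populations (each
#'   observed at every grid time).
#' @param n_times number of observation times (evenly spaced, including
#'   0 and `tmax`).
#' @param n_cells cells per feature.
#' @param age_range numeric length-2; reported ages are the observation
#'   times min-max scaled into this range (default `c(0, 100)`).
#' @return A [labeled_dataset()] of bulk betas; `set_label` indexes the
#'   replicate population.
#' @export
gillespie_dataset <- function(ground, cfg = gillespie_config(),
                              n_sets = 3, n_times = 34,
                              n_cells = 100, age_range = c(0, 100)) {
  stopifnot(inherits(ground, "ground_state"),
            inherits(cfg, "gillespie_config"))
  check_scalar_number(n_sets, "n_sets", min = 1, integerish = TRUE)
  check_scalar_number(n_times, "n_times", min = 2, integerish = TRUE)
  check_scalar_number(n_cells, "n_cells", min = 1, integerish = TRUE)
  obs_times <- seq(0, cfg$tmax, length.out = n_times)
  nfeat <- length(ground$values)
  counts0 <- as.integer(floor(ground$values * n_cells + 0.5 + 1e-9))
  ## initial binary states: for each feature the first `count` cells are 1
  states0 <- unlist(lapply(counts0, function(k)
    c(rep(1L, k), rep(0L, n_cells - k))))
  n_samples <- n_times * n_sets
  betas <- matrix(NA_real_, n_samples, nfeat)
  ages <- numeric(n_samples)
  sets <- integer(n_samples)
  row <- 0L
  for (rep_i in seq_len(n_sets)) {
    if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, rep_i))
    st <- states0
    for (ti in seq_along(obs_times)) {
      if (ti > 1L)
        st <- gillespie_states_at(st, obs_times[ti] - obs_times[ti - 1L], cfg)
      row <- row + 1L
      betas[row, ] <- colSums(matrix(st, nrow = n_cells)) / n_cells
      ages[row] <- obs_times[ti]
      sets[row] <- rep_i
    }
  }
  ## rescale arbitrary times into the reporting age range
  ages <- (ages - min(obs_times)) / (max(obs_times) - min(obs_times)) *
    diff(age_range) + age_range[1]
  colnames(betas) <- ground$feature_ids
  labeled_dataset(betas, ages, sets, mode = "clamped")
}
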