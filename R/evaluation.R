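# Evaluation: prediction scoring, permutation controls, the canonical
# simulate-train-validate experiment, and parameter-sweep harnesses.

#' Score predictions against known ages
#'
#' Reports the two-sided Pearson correlation and the out-of-sample
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` of predictions
#' against the truth. Note this is not a squared correlation: for poor
#' predictors it can be negative.
#'
#' @param truth numeric vector of true ages (length >= 3).
#' @param predicted numeric vector of predictions, same length.
#' @param allow_constant if `TRUE`, constant predictions yield
#'   `pearson_r = NA` (with R^2 still computed) instead of an error; used
#'   by sweep harnesses where a degenerate intercept-only clock is a
#'   legitimate outcome.
#' @return An object of class `eval_report`: list with `pearson_r`,
#'   `pearson_p`, `r_squared`, `n`.
#' @examples
#' score_predictions(1:10, 1:10 + rnorm(10, 0, 0.1))
#' @export
score_predictions <- function(truth, predicted, allow_constant = FALSE) {
  if (length(truth) != length(predicted) || length(truth) < 3L)
    stop_arg("`truth` and `predicted` must be equal-length vectors, length >= 3")
  r2 <- 1 - sum((predicted - truth)^2) / sum((truth - mean(truth))^2)
  if (stats::sd(truth) == 0 || stats::sd(predicted) == 0) {
    if (!allow_constant)
      stop_arg("correlation undefined: zero variance in truth or predictions")
    return(structure(list(pearson_r = NA_real_, pearson_p = NA_real_,
                          r_squared = r2, n = length(truth)),
                     class = "eval_report"))
  }
  ct <- stats::cor.test(truth, predicted, method = "pearson",
                        alternative = "two.sided")
  structure(list(pearson_r = unname(ct$estimate),
                 pearson_p = ct$p.value,
                 r_squared = r2, n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d: Pearson r = %.4f (p = %.3g), R^2 = %.4f\n",
              x$n, x$pearson_r, x$pearson_p, x$r_squared))
  invisible(x)
}

#' Permutation control for a clock
#'
#' Randomly permutes the sample ages of a dataset and correlates the
#' clock's (fixed) predictions with each permutation, yielding the
#' empirical null distribution of the Pearson correlation. Under
#' exchangeability the null is centered at zero regardless of how good
#' the clock is.
#'
#' @param data a [labeled_dataset()].
#' @param model a `clock_model`.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param include_identity if `TRUE`, the first entry is the unpermuted
#'   correlation (sanity check).
#' @return Numeric vector of null correlations (length `n_perm`, plus one
#'   when `include_identity`).
#' @export
permutation_control <- function(data, model, n_perm = 1000, seed = NULL,
                                include_identity = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  check_scalar_number(n_perm, "n_perm", min = 100, integerish = TRUE)
  pred <- predict(model, data)
  maybe_seed(seed)
  r <- vapply(seq_len(n_perm), function(i)
    stats::cor(pred, sample(data$ages)), numeric(1))
  if (include_identity) r <- c(stats::cor(pred, data$ages), r)
  r
}

#' Run one simulate-train-validate clock experiment
#'
#' The canonical benchmark: generate a dataset from a ground state, train
#' an elastic-net clock on the training replicate sets, and score its
#' predictions on the held-out sets. Covers both the bulk pipeline
#' (clamped / unbounded / logit stochastic-variation accumulation) and
#' the single-cell methylation pipeline (binary cell populations under
#' maintenance efficiencies).
#'
#' @param pipeline `"bulk"` or `"methylation"`.
#' @param n_features ground-state size (ignored when `ground` is given).
#' @param cfg a [noise_config()] (bulk pipeline; its `seed` is ignored in
#'   favor of `seed`).
#' @param rates a [maintenance_rates()] (methylation pipeline); default
#'   universal E_m = E_u = 99.9%.
#' @param ground optional [ground_state()]; drawn uniformly when `NULL`.
#' @param max_age ages run 1..`max_age` (bulk) or 0..`max_age - 1`
#'   (methylation).
#' @param n_sets total replicate sets (default 6).
#' @param train_sets set indices used for training (default first half).
#' @param n_cells cells per feature (methylation pipeline).
#' @param samples sampling scheme of the methylation pipeline
#'   (`"trajectory"` or `"independent"`, see
#'   [simulate_methylation_dataset()]).
#' @param transform,l1_ratio,alphas,nfolds passed to [train_clock()].
#' @param test_data optional [labeled_dataset()] to validate on instead of
#'   the held-out sets (used for cross-condition "pace of aging" tests).
#' @param seed root seed for the whole experiment (ground state, data,
#'   CV folds).
#' @return List with `ground`, `model`, `truth`, `predicted`, and the
#'   `report` from [score_predictions()].
#' @examples
#' ex <- clock_experiment("bulk", n_features = 100, cfg = noise_config(0.2),
#'                        max_age = 30, seed = 1)
#' ex$report
#' @export
clock_experiment <- function(pipeline = c("bulk", "methylation"),
                             n_features = 2000,
                             cfg = noise_config(0.2),
                             rates = maintenance_rates(0.999, 0.001),
                             ground = NULL,
                             max_age = 100, n_sets = 6,
                             train_sets = seq_len(ceiling(n_sets / 2)),
                             n_cells = 1000,
                             samples = c("trajectory", "independent"),
                             transform = "identity",
                             l1_ratio = seq(0.1, 0.9, by = 0.1),
                             alphas = NULL, nfolds = 5,
                             test_data = NULL, seed = 1) {
  samples <- match.arg(samples)
  pipeline <- match.arg(pipeline)
  if (is.null(ground))
    ground <- make_ground_state(n_features, seed = derive_seed(seed, 1000))
  data <- if (pipeline == "bulk") {
    cfg$seed <- derive_seed(seed, 2000)
    generate_dataset(ground, max_age = max_age, n_sets = n_sets, cfg)
  } else {
    simulate_methylation_dataset(ground, rates, max_age = max_age,
                                 n_sets = n_sets, n_cells = n_cells,
                                 seed = derive_seed(seed, 2000),
                                 samples = samples)
  }
  train <- split_sets(data, train_sets)
  model <- train_clock(train, transform = transform, l1_ratio = l1_ratio,
                       alphas = alphas, nfolds = nfolds,
                       seed = derive_seed(seed, 3000))
  valid <- if (is.null(test_data))
    split_sets(data, setdiff(unique(data$set_label), train_sets))
  else test_data
  predicted <- predict(model, valid)
  list(ground = ground, model = model, truth = valid$ages,
       predicted = predicted,
       report = score_predictions(valid$ages, predicted,
                                  allow_constant = TRUE))
}

#' Sweep one simulation parameter across a grid
#'
#' Repeats [clock_experiment()] over a grid of one swept parameter with
#' independent replicates per grid point and collects the validation
#' metrics. Supported parameters: `"n_features"`, `"per_step_sd"`
#' (bulk), and `"e_m"` (methylation; E_d is set to `1 - e_m` so
#' E_m = E_u). Results are deterministic given `seed`.
#'
#' @param param name of the swept parameter.
#' @param grid numeric vector of parameter values (nonempty).
#' @param n_reps replicates per grid point: scalar, or vector recycled
#'   along the grid (the feature-count design uses 10 replicates below
#'   1000 features and 3 otherwise).
#' @param pipeline `"bulk"` or `"methylation"`.
#' @param seed root seed; replicate (g, r) uses a child seed.
#' @param ... fixed arguments forwarded to [clock_experiment()].
#' @return Data frame with columns `param`, `value`, `replicate`,
#'   `pearson_r`, `r_squared`.
#' @export
clock_sweep <- function(param = c("n_features", "per_step_sd", "e_m"),
                        grid, n_reps = 3,
                        pipeline = c("bulk", "methylation"),
                        seed = 1, ...) {
  param <- match.arg(param)
  pipeline <- match.arg(pipeline)
  if (length(grid) == 0L) stop_arg("`grid` must be nonempty")
  n_reps <- rep_len(n_reps, length(grid))
  fixed <- list(...)
  rows <- list()
  for (g in seq_along(grid)) {
    for (r in seq_len(n_reps[g])) {
      args <- fixed
      args$pipeline <- pipeline
      args$seed <- derive_seed(seed, g * 1000L + r)
      if (param == "n_features") {
        args$n_features <- grid[g]
      } else if (param == "per_step_sd") {
        base <- if (is.null(args$cfg)) noise_config(0.2) else args$cfg
        base$per_step_sd <- grid[g]
        args$cfg <- base
      } else {
        args$rates <- maintenance_rates(grid[g], 1 - grid[g])
      }
      ex <- do.call(clock_experiment, args)
      rows[[length(rows) + 1L]] <- data.frame(
        param = param, value = grid[g], replicate = r,
        pearson_r = ex$report$pearson_r, r_squared = ex$report$r_squared)
    }
  }
  do.call(rbind, rows)
}
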