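# Bulk simulator: samples are generated by repeatedly adding
# normal-distributed stochastic variation to a fixed ground state. With a
# data-range limit (clamping to [0, 1], or working in logit space) the
# accumulated variation carries an age signal through regression to the
# mean; without a limit it does not.

#' Construct a ground state
#'
#' A ground state is the per-feature baseline ("age zero") vector from which
#' every simulated sample is derived. Values are fractions in \[0, 1\]
#' (e.g. methylation beta values, or min-max normalized expression).
#'
#' @param values numeric vector of baseline fractions, all in \[0, 1\].
#' @param feature_ids unique character labels, one per value.
#' @param origin free-text provenance tag, `"synthetic"` for simulated
#'   ground states or an identifier of the biological sample it was taken
#'   from.
#' @return An object of class `ground_state`: a list with elements
#'   `values`, `feature_ids`, `origin`.
#' @export
ground_state <- function(values, feature_ids = NULL, origin = "synthetic") {
  if (!is.numeric(values) || length(values) < 1L)
    stop_arg("`values` must be a numeric vector of length >= 1")
  if (anyNA(values) || any(!is.finite(values)))
    stop_arg("ground-state values must be finite")
  if (any(values < 0 | values > 1))
    stop_arg("ground-state values must lie in [0, 1]")
  if (is.null(feature_ids)) feature_ids <- default_feature_ids(length(values))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != length(values))
    stop_arg("`feature_ids` must have the same length as `values`")
  if (anyDuplicated(feature_ids))
    stop_arg("`feature_ids` must be unique")
  structure(
    list(values = as.numeric(values), feature_ids = feature_ids,
         origin = origin),
    class = "ground_state"
  )
}

#' @export
print.ground_state <- function(x, ...) {
  cat(sprintf("<ground_state> %d features, origin: %s\n",
              length(x$values), x$origin))
  cat(sprintf("  value range: [%.4f, %.4f], mean %.4f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Draw a uniform random ground state
#'
#' Baseline values are i.i.d. uniform on \[0, 1\]; 2000 features is the
#' default design size used throughout the simulation benchmarks.
#'
#' @param n_features number of features (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return A [ground_state()] object.
#' @examples
#' g <- make_ground_state(2000, seed = 1)
#' range(g$values)
#' @export
make_ground_state <- function(n_features, seed = NULL) {
  check_scalar_number(n_features, "n_features", min = 1, integerish = TRUE)
  maybe_seed(seed)
  ground_state(stats::runif(n_features), origin = "synthetic")
}

#' Noise configuration for the bulk simulator
#'
#' @param per_step_sd standard deviation of the per-step normal noise
#'   (one draw per feature per simulated time step).
#' @param baseline_sd standard deviation of the one-time per-sample jitter
#'   applied before any age steps, emulating inter-individual biological
#'   variation (default 0.01).
#' @param mode `"clamped"` (values forced back into \[0, 1\] after every
#'   addition), `"unbounded"` (no limit; the negative control), or
#'   `"logit"` (jitter and noise accumulate in logit space and the sample
#'   is mapped back through the inverse-logit).
#' @param seed optional root seed; [generate_dataset()] derives one child
#'   stream per replicate set from it.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(per_step_sd, baseline_sd = 0.01,
                         mode = c("clamped", "unbounded", "logit"),
                         seed = NULL) {
  check_scalar_number(per_step_sd, "per_step_sd")
  if (per_step_sd <= 0) stop_arg("`per_step_sd` must be > 0")
  check_scalar_number(baseline_sd, "baseline_sd", min = 0)
  mode <- match.arg(mode)
  structure(
    list(per_step_sd = per_step_sd, baseline_sd = baseline_sd,
         mode = mode, seed = seed),
    class = "noise_config"
  )
}

#' Accumulate stochastic variation on a ground state
#'
#' Produces a single simulated sample: the ground state plus one baseline
#' jitter draw plus `age` sequential independent per-feature draws of
#' N(0, per_step_sd^2). In clamped mode values are forced back into
#' \[0, 1\] after the jitter and after every addition; in logit mode all
#' additions happen in logit space (values are clipped to
#' \[1e-6, 1 - 1e-6\] before the transform) and the result is returned
#' through the inverse logit; in unbounded mode no limit is applied.
#'
#' @param ground a [ground_state()].
#' @param age nonnegative integer; how many times per-step variation is
#'   added ("simulated age").
#' @param cfg a [noise_config()]. If `cfg$seed` is set the draw is
#'   reproducible; otherwise it consumes the current RNG stream.
#' @return Numeric vector of simulated feature values (named by feature id).
#' @examples
#' g <- make_ground_state(100, seed = 1)
#' x <- accumulate_variation(g, age = 10, noise_config(0.2, seed = 7))
#' range(x)
#' @export
accumulate_variation <- function(ground, age, cfg) {
  stopifnot(inherits(ground, "ground_state"), inherits(cfg, "noise_config"))
  check_scalar_number(age, "age", min = 0, integerish = TRUE)
  maybe_seed(cfg$seed)
  n <- length(ground$values)
  x <- ground$values
  if (cfg$mode == "logit") x <- guarded_logit(x)
  if (cfg$baseline_sd > 0) x <- x + stats::rnorm(n, 0, cfg$baseline_sd)
  if (cfg$mode == "clamped") x <- clamp01(x)
  for (step in seq_len(age)) {
    x <- x + stats::rnorm(n, 0, cfg$per_step_sd)
    if (cfg$mode == "clamped") x <- clamp01(x)
  }
  if (cfg$mode == "logit") x <- expit(x)
  names(x) <- ground$feature_ids
  x
}

#' Construct a labeled dataset
#'
#' Container for a samples x features matrix with per-sample simulated
#' (or known) ages and replicate-set labels.
#'
#' @param matrix numeric samples x features matrix with feature ids as
#'   column names.
#' @param ages per-sample nonnegative ages.
#' @param set_label per-sample replicate-set index.
#' @param mode the simulation mode the samples were generated under
#'   (informational).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(matrix, ages, set_label, mode = "clamped") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_arg("`matrix` must be a numeric matrix")
  if (nrow(matrix) != length(ages) || nrow(matrix) != length(set_label))
    stop_arg("rows of `matrix`, `ages`, and `set_label` must align")
  if (any(!is.finite(ages)) || any(ages < 0))
    stop_arg("`ages` must be finite and >= 0")
  if (mode %in% c("clamped", "logit") &&
      (min(matrix) < 0 || max(matrix) > 1))
    stop_arg("in %s mode all values must lie in [0, 1]", mode)
  if (is.null(colnames(matrix)))
    colnames(matrix) <- default_feature_ids(ncol(matrix))
  structure(
    list(matrix = matrix, ages = as.numeric(ages),
         set_label = as.integer(set_label), mode = mode),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features (%s mode)\n",
              nrow(x$matrix), ncol(x$matrix), x$mode))
  cat(sprintf("  ages: %s..%s over %d replicate set(s)\n",
              format(min(x$ages)), format(max(x$ages)),
              length(unique(x$set_label))))
  invisible(x)
}

#' Subset a labeled dataset by replicate set
#'
#' @param data a [labeled_dataset()].
#' @param sets replicate-set indices to keep.
#' @return A [labeled_dataset()] restricted to the selected sets.
#' @export
split_sets <- function(data, sets) {
  stopifnot(inherits(data, "labeled_dataset"))
  keep <- data$set_label %in% sets
  if (!any(keep)) stop_arg("no samples in the requested sets")
  labeled_dataset(data$matrix[keep, , drop = FALSE], data$ages[keep],
                  data$set_label[keep], data$mode)
}

## Generate one replicate set (one sample per age) with step-synchronous
## vectorization: at step t, noise is added to every sample whose age is
## >= t. Samples remain mutually independent because every entry of every
## noise matrix is an independent draw.
generate_bulk_set <- function(ground, ages, cfg) {
  n <- length(ground$values)
  m <- length(ages)
  base <- ground$values
  if (cfg$mode == "logit") base <- guarded_logit(base)
  x <- matrix(base, nrow = m, ncol = n, byrow = TRUE)
  if (cfg$baseline_sd > 0)
    x <- x + matrix(stats::rnorm(m * n, 0, cfg$baseline_sd), m, n)
  if (cfg$mode == "clamped") x <- clamp01(x)
  for (step in seq_len(max(ages))) {
    active <- which(ages >= step)
    if (!length(active)) break
    noise <- matrix(stats::rnorm(length(active) * n, 0, cfg$per_step_sd),
                    length(active), n)
    if (cfg$mode == "clamped") {
      x[active, ] <- clamp01(x[active, , drop = FALSE] + noise)
    } else {
      x[active, ] <- x[active, , drop = FALSE] + noise
    }
  }
  if (cfg$mode == "logit") x <- expit(x)
  colnames(x) <- ground$feature_ids
  x
}

#' Generate a bulk simulation dataset
#'
#' Produces `n_sets` independent replicate sets, each containing exactly
#' one sample per simulated age 1..`max_age` (the default design is 6 sets
#' of 100 samples: 3 for training, 3 for validation). Every sample starts
#' from the same ground state with its own baseline jitter and accumulates
#' its own independent per-step variation.
#'
#' Reproducibility: when `cfg$seed` is set, each replicate set is generated
#' from a child seed derived from it, so a set can be regenerated in
#' isolation with the same result.
#'
#' @param ground a [ground_state()].
#' @param max_age largest simulated age; ages run 1..`max_age`.
#' @param n_sets number of independent replicate sets.
#' @param cfg a [noise_config()].
#' @return A [labeled_dataset()] with `n_sets * max_age` samples.
#' @examples
#' g <- make_ground_state(50, seed = 1)
#' d <- generate_dataset(g, max_age = 20, n_sets = 2, noise_config(0.2, seed = 2))
#' table(d$set_label)
#' @export
generate_dataset <- function(ground, max_age = 100, n_sets = 6, cfg) {
  stopifnot(inherits(ground, "ground_state"), inherits(cfg, "noise_config"))
  check_scalar_number(max_age, "max_age", min = 1, integerish = TRUE)
  check_scalar_number(n_sets, "n_sets", min = 1, integerish = TRUE)
  ages <- seq_len(max_age)
  mats <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    if (!is.null(cfg$seed)) set.seed(derive_seed(cfg$seed, s))
    mats[[s]] <- generate_bulk_set(ground, ages, cfg)
  }
  labeled_dataset(do.call(rbind, mats),
                  ages = rep(ages, n_sets),
                  set_label = rep(seq_len(n_sets), each = max_age),
                  mode = cfg$mode)
}
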