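# Elastic-net clock construction. Hyperparameters are chosen by k-fold
# cross-validation over a grid of mixing parameters (l1_ratio, glmnet's
# alpha) and either an automatic regularization path or a user-fixed
# penalty grid (`alphas`, glmnet's lambda — named after the corresponding
# scikit-learn ElasticNetCV argument so published hyperparameter settings
# carry over directly).

#' Train an elastic-net aging clock
#'
#' Fits a cross-validated elastic net predicting (transformed) age from
#' the feature matrix of a [labeled_dataset()]. The mixing-parameter grid
#' defaults to 0.1..0.9; the penalty strength is selected from an
#' automatic path unless `alphas` fixes it (e.g. `alphas = 1` as used for
#' clocks trained on one sample per age). Coefficients of many features
#' are typically shrunk exactly to zero; this sparsity is expected.
#' Features are not standardized internally: simulated features share the
#' \[0, 1\] scale by construction.
#'
#' @param train a [labeled_dataset()] used for training.
#' @param transform an [age_transform()] or its type string; applied to
#'   ages before fitting and inverted at prediction time. Data-dependent
#'   parameters (minmax bounds) are fitted on the training ages and stored
#'   in the model.
#' @param l1_ratio grid of elastic-net mixing parameters in (0, 1\].
#' @param alphas optional fixed penalty grid (scikit-learn naming; glmnet's
#'   lambda). `NULL` (default) lets cross-validation pick from an
#'   automatic path.
#' @param nfolds number of cross-validation folds (default 5).
#' @param seed seed controlling the fold shuffle (default 1).
#' @return An object of class `clock_model` with named `coefficients`
#'   (including exact zeros), `intercept`, `feature_ids`, `transform`,
#'   and `training_meta` (grids, chosen hyperparameters, CV error, fold
#'   seed, nonzero-coefficient count).
#' @examples
#' g <- make_ground_state(50, seed = 1)
#' d <- generate_dataset(g, max_age = 30, n_sets = 2, noise_config(0.2, seed = 2))
#' m <- train_clock(d)
#' m$training_meta$n_nonzero
#' @export
train_clock <- function(train, transform = "identity",
                        l1_ratio = seq(0.1, 0.9, by = 0.1),
                        alphas = NULL, nfolds = 5, seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (is.character(transform)) transform <- age_transform(transform)
  stopifnot(inherits(transform, "age_transform"))
  if (length(unique(train$ages)) < 2L)
    stop_arg("training data needs >= 2 distinct ages")
  transform <- fit_transform(transform, train$ages)
  y <- transform_age(transform, train$ages)
  if (any(!is.finite(y)))
    stop_arg("age transform produced non-finite training targets")
  if (stats::sd(y) == 0)
    stop_arg("transformed training target is constant")
  x <- train$matrix
  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(x)))

  fixed_lambda <- !is.null(alphas)
  lambda_path <- NULL
  lambda_keep <- NULL
  if (fixed_lambda) {
    lambda_keep <- sort(unique(as.numeric(alphas)), decreasing = TRUE)
    ## pad short user grids with larger values for a stable warm-start path
    lambda_path <- if (length(lambda_keep) < 5)
      c(lambda_keep[1] * c(16, 8, 4, 2), lambda_keep) else lambda_keep
  }

  best <- NULL
  for (a in l1_ratio) {
    cvfit <- glmnet::cv.glmnet(x, y, alpha = a, foldid = foldid,
                               standardize = FALSE, lambda = lambda_path)
    idx <- if (fixed_lambda) which(cvfit$lambda %in% lambda_keep)
           else seq_along(cvfit$lambda)
    j <- idx[which.min(cvfit$cvm[idx])]
    if (is.null(best) || cvfit$cvm[j] < best$cvm) {
      best <- list(cvm = cvfit$cvm[j], lambda = cvfit$lambda[j],
                   l1_ratio = a, fit = cvfit)
    }
  }
  cf <- as.numeric(stats::coef(best$fit, s = best$lambda))
  coefficients <- cf[-1]
  names(coefficients) <- colnames(x)
  structure(
    list(feature_ids = colnames(x),
         coefficients = coefficients,
         intercept = cf[1],
         transform = transform,
         training_meta = list(
           l1_ratio_grid = l1_ratio, alphas = alphas, nfolds = nfolds,
           seed = seed, chosen_l1_ratio = best$l1_ratio,
           chosen_lambda = best$lambda, cv_mse = best$cvm,
           n_nonzero = sum(coefficients != 0),
           n_train = nrow(x))),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %d features (%d nonzero), transform: %s\n",
              length(x$coefficients), sum(x$coefficients != 0),
              x$transform$type))
  if (!is.null(x$training_meta$chosen_l1_ratio))
    cat(sprintf("  CV choice: l1_ratio = %g, penalty = %.4g (CV MSE %.4g)\n",
                x$training_meta$chosen_l1_ratio,
                x$training_meta$chosen_lambda, x$training_meta$cv_mse))
  invisible(x)
}

#' Predict ages with a clock
#'
#' Computes `intercept + sum(coefficient * value)` per sample and applies
#' the model's inverse age transform (for the loglog transform the result
#' is a relative age in (0, 1)).
#'
#' @param object a `clock_model`.
#' @param newdata a [labeled_dataset()] or a samples x features numeric
#'   matrix whose columns cover all model features.
#' @param ... unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.clock_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "labeled_dataset")) newdata$matrix else newdata
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop_arg("`newdata` must be a matrix or labeled_dataset")
  missing <- setdiff(object$feature_ids, colnames(x))
  if (length(missing))
    stop_arg("newdata is missing %d model feature(s): %s%s",
             length(missing), paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) ", ..." else "")
  lp <- drop(x[, object$feature_ids, drop = FALSE] %*% object$coefficients) +
    object$intercept
  unname(inverse_transform_age(object$transform, lp))
}

#' Build a clock from a published coefficient table
#'
#' Accepts a data frame (or TSV/CSV path) with a feature-id column and a
#' coefficient column, plus at most one intercept row (feature id
#' `"(Intercept)"`, `"__intercept__"`, or `"intercept"`). Published clocks
#' that define a nonlinear output transform (e.g. the piecewise
#' log-linear year-scale transform of pan-tissue clocks) must supply it
#' via `transform`.
#'
#' @param table data frame or file path. The first two columns are used
#'   unless columns named `feature_id`/`CpG` and `coefficient`/`coef`
#'   exist.
#' @param transform an [age_transform()] applied inversely to the linear
#'   predictor (default identity).
#' @return A `clock_model` usable with [predict.clock_model()].
#' @examples
#' tab <- data.frame(feature_id = c("cg1", "cg2", "(Intercept)"),
#'                   coefficient = c(0.5, -0.5, 10))
#' m <- load_clock_coefficients(tab)
#' predict(m, matrix(c(1, 0), 1, dimnames = list(NULL, c("cg1", "cg2"))))
#' @export
load_clock_coefficients <- function(table, transform = age_transform("identity")) {
  if (is.character(table)) table <- read_delim_auto(table)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop_arg("coefficient table is empty")
  stopifnot(inherits(transform, "age_transform"))
  id_col <- intersect(c("feature_id", "CpG", "cpg", "probe"), names(table))
  co_col <- intersect(c("coefficient", "coef", "CoefficientTraining"),
                      names(table))
  ids <- as.character(table[[if (length(id_col)) id_col[1] else 1L]])
  cf <- as.numeric(table[[if (length(co_col)) co_col[1] else 2L]])
  if (anyNA(cf)) stop_arg("non-numeric coefficients in table")
  is_int <- tolower(ids) %in% c("(intercept)", "__intercept__", "intercept")
  if (sum(is_int) > 1L) stop_arg("more than one intercept row")
  if (anyDuplicated(ids[!is_int]))
    stop_arg("duplicate feature ids: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  intercept <- if (any(is_int)) cf[is_int] else {
    warning("no intercept row found; assuming intercept 0", call. = FALSE)
    0
  }
  ids <- ids[!is_int]; cf <- cf[!is_int]
  if (length(ids) == 0L) stop_arg("coefficient table has no features")
  names(cf) <- ids
  structure(list(feature_ids = ids, coefficients = cf,
                 intercept = intercept, transform = transform,
                 training_meta = list(source = "coefficient table")),
            class = "clock_model")
}
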