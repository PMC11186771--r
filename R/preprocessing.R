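# Preprocessing utilities: binarized-transcriptome encoding for
# expression-based clocks, a transcriptomic stochastic-aging simulator,
# cell-type residual adjustment of beta matrices, and ordinary
# least-squares covariate/interaction regressions.

#' Binarize an expression count matrix
#'
#' Per sample: counts are log10-transformed after adding one pseudo-count
#' and min-max normalized to \[0, 1\] (per sample, over genes). Genes with
#' zero counts in every sample are dropped. The per-sample median is then
#' computed over the normalized values with raw zeros masked out, and
#' genes strictly greater than that median are set to 1, all others
#' (ties, sub-median, and masked zeros) to 0.
#'
#' @param counts nonnegative integer matrix, genes x samples, with row
#'   (gene) and optionally column (sample) names.
#' @return Binary 0/1 matrix, genes x samples, with all-zero genes
#'   removed.
#' @examples
#' m <- matrix(c(0, 9, 99, 999), 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
#' binarize_expression(m)[, 1]
#' @export
binarize_expression <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop_arg("`counts` must be a nonnegative numeric matrix")
  if (is.null(rownames(counts)))
    rownames(counts) <- default_feature_ids(nrow(counts))
  ## normalize per sample over the full gene set, then drop genes that are
  ## zero in every sample (order matters in principle; in practice an
  ## all-zero gene is always the per-sample minimum)
  v <- log10(counts + 1)
  out <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    rng <- range(v[, j])
    if (rng[1] == rng[2])
      stop_arg("sample %d has < 2 distinct values; min-max normalization undefined",
               j)
    norm <- (v[, j] - rng[1]) / (rng[2] - rng[1])
    med <- stats::median(norm[counts[, j] > 0])  # zeros masked for the median
    out[, j] <- as.integer(norm > med)
  }
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop_arg("all genes are zero in all samples")
  out[keep, , drop = FALSE]
}

#' Simulate transcriptomic aging from a binar-normalized ground state
#'
#' Clamped stochastic-variation accumulation (as in the bulk simulator)
#' tuned to the transcriptomic design: small per-step noise
#' (s.d. ~ 0.01), ages 1..16, and ten independent samples per time step
#' (160 samples by default). The simulated time steps are arbitrary; a
#' beneficial x2 rescaling before clock training is available via
#' `age_transform("multiply", k = 2)`.
#'
#' @param ground a [ground_state()], e.g. a min-max normalized expression
#'   sample in \[0, 1\].
#' @param cfg a [noise_config()]; default clamped with
#'   `per_step_sd = 0.01`.
#' @param max_age number of time steps (default 16).
#' @param n_per_age independent samples per time step (default 10).
#' @return A [labeled_dataset()]; `set_label` indexes the replicate at
#'   each age.
#' @export
simulate_transcriptome_aging <- function(ground,
                                         cfg = noise_config(0.01),
                                         max_age = 16, n_per_age = 10) {
  generate_dataset(ground, max_age = max_age, n_sets = n_per_age, cfg)
}

#' Cell-type fraction table constructor/validator
#'
#' @param fractions data frame or matrix, samples x cell types (the blood
#'   reference uses B, NK, CD4T, CD8T, Mono, Neutro, Eosino). Fractions
#'   must be nonnegative and sum to 1 per sample within \[0.95, 1.05\]
#'   (tolerance for estimation noise).
#' @return A validated numeric matrix.
#' @export
celltype_fractions <- function(fractions) {
  f <- as.matrix(fractions)
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0))
    stop_arg("fractions must be nonnegative numbers")
  s <- rowSums(f)
  if (any(s < 0.95 | s > 1.05))
    stop_arg("per-sample fraction sums must lie in [0.95, 1.05]; offending sample(s): %s",
             paste(utils::head(which(s < 0.95 | s > 1.05), 5), collapse = ", "))
  f
}

#' Cell-type adjustment of a beta matrix
#'
#' Removes the variance explained by cell-type composition: for each
#' feature a linear model `beta ~ fractions` (with intercept) is fitted
#' across samples; the residuals capture the cell-type-independent
#' variance and are added back to the feature mean to give adjusted beta
#' values, which are finally clipped to \[0, 1\]. Per-feature means are
#' preserved exactly (least-squares residuals with an intercept sum to
#' zero).
#'
#' Residuals are computed by projection onto the column space of
#' `(intercept, fractions)`, which is well defined even though fractions
#' sum to ~1 (compositional closure makes the design singular as a
#' parameterization, but not as a projection). Genuinely collinear
#' fraction tables -- two distinct, non-constant cell types with
#' identical columns -- are rejected.
#'
#' @param betas numeric matrix, samples x features, values in \[0, 1\].
#' @param fractions samples x cell-types fractions (see
#'   [celltype_fractions()]).
#' @return Adjusted samples x features matrix.
#' @export
celltype_adjust <- function(betas, fractions) {
  if (!is.matrix(betas)) betas <- as.matrix(betas)
  f <- celltype_fractions(fractions)
  if (nrow(f) != nrow(betas))
    stop_arg("`betas` and `fractions` must have the same number of samples")
  if (nrow(betas) < ncol(f) + 2L)
    stop_arg("need at least n_celltypes + 2 samples to fit the adjustment")
  if (is.null(colnames(f))) colnames(f) <- paste0("ct", seq_len(ncol(f)))
  nonconst <- apply(f, 2, function(x) diff(range(x)) > 1e-12)
  if (ncol(f) > 1) {
    for (i in seq_len(ncol(f) - 1)) for (j in seq(i + 1, ncol(f))) {
      if (nonconst[i] && nonconst[j] && all(abs(f[, i] - f[, j]) < 1e-12))
        stop_arg("fraction matrix is rank deficient: cell types %s and %s are collinear",
                 colnames(f)[i], colnames(f)[j])
    }
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, f), betas)
  resid <- as.matrix(fit$residuals)
  means <- matrix(colMeans(betas), nrow(betas), ncol(betas), byrow = TRUE)
  out <- clamp01(means + resid)
  dimnames(out) <- dimnames(betas)
  out
}

#' Ordinary least-squares covariate regression
#'
#' Fits `response ~ covariates (+ interactions)` by OLS and returns the
#' full coefficient table. This covers the designs used to probe clock
#' predictions: `Age ~ PredictedAge + CellTypeFractions`, and
#' intervention models such as
#' `PredictedAge ~ ChronologicalAge + Treatment + ChronologicalAge:Treatment`
#' with binary treatment indicators. P-values use the t-distribution with
#' residual degrees of freedom (plain OLS, no robust errors).
#'
#' @param response numeric response vector.
#' @param covariates data frame of covariates (numeric or factor), one row
#'   per observation.
#' @param interactions character vector of interaction terms in formula
#'   notation, e.g. `"age:treated"`.
#' @return Data frame with columns `term`, `estimate`, `std_error`,
#'   `t_value`, `p_value`.
#' @examples
#' d <- data.frame(age = 1:20, treated = rep(0:1, 10))
#' y <- 2 + 0.5 * d$age + rnorm(20, 0, 0.1)
#' covariate_regression(y, d, interactions = "age:treated")
#' @export
covariate_regression <- function(response, covariates, interactions = NULL) {
  covariates <- as.data.frame(covariates)
  if (length(response) != nrow(covariates))
    stop_arg("`response` and `covariates` must align")
  dat <- cbind(.response = response, covariates)
  rhs <- c(names(covariates), interactions)
  fml <- stats::as.formula(paste(".response ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop_arg("design matrix is rank deficient; drop collinear covariates")
  tab <- summary(fit)$coefficients
  data.frame(term = rownames(tab), estimate = tab[, 1],
             std_error = tab[, 2], t_value = tab[, 3], p_value = tab[, 4],
             row.names = NULL)
}
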