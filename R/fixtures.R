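# Programmatic fixture generation. All fixtures are synthetic and
# generated in code; the beta fixture emulates the structure observed in
# biological methylation matrices (bimodal beta values whose variance
# shrinks toward the 0/1 extremes, with a young/old sample pair produced
# by running the methylation simulator forward so that rate estimation
# has a self-consistent target).

#' Generate synthetic fixture files
#'
#' @param kind `"beta_matrix"` (bimodal beta-value matrix with ages plus a
#'   `young`/`old` ground-state pair), `"counts"` (negative-binomial gene
#'   counts), or `"fractions"` (Dirichlet cell-type fractions over the
#'   seven blood cell types).
#' @param dir output directory (created if needed).
#' @param seed integer seed; fixed seeds give byte-identical files.
#' @param n_features,n_samples fixture dimensions.
#' @param n_cells,steps methylation-simulator settings used to produce the
#'   old sample of the `beta_matrix` fixture.
#' @param limits maintenance-rate limits for the forward simulation.
#' @return Named character vector of the files written.
#' @examples
#' \donttest{
#' files <- make_fixture("fractions", dir = tempdir(), seed = 1)
#' }
#' @export
make_fixture <- function(kind = c("beta_matrix", "counts", "fractions"),
                         dir = tempdir(), seed = 1,
                         n_features = 300, n_samples = 20,
                         n_cells = 1000, steps = 100,
                         limits = rate_limits(0.97, 1, 0, 0.05)) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  switch(kind,
    beta_matrix = fixture_beta_matrix(dir, n_features, n_samples, n_cells,
                                      steps, limits),
    counts = fixture_counts(dir, n_features, n_samples),
    fractions = fixture_fractions(dir, n_samples)
  )
}

## Bimodal per-feature means; per-sample values drawn from a beta
## distribution with fixed precision, so variance m(1-m)/(prec+1) shrinks
## toward the extremes by construction.
fixture_beta_matrix <- function(dir, n_features, n_samples, n_cells, steps,
                                limits) {
  lo <- stats::rbeta(n_features, 0.4, 4)
  hi <- stats::rbeta(n_features, 4, 0.4)
  pick_hi <- stats::runif(n_features) < 0.5
  means <- ifelse(pick_hi, hi, lo)
  prec <- 150
  betas <- t(vapply(seq_len(n_samples), function(i)
    stats::rbeta(n_features, means * prec, (1 - means) * prec),
    numeric(n_features)))
  colnames(betas) <- default_feature_ids(n_features)
  rownames(betas) <- sprintf("s%02d", seq_len(n_samples))
  ages <- sort(stats::runif(n_samples, 10, 90))
  matrix_path <- file.path(dir, "synthetic_beta_matrix.tsv")
  write_beta_matrix(round(betas, 4), matrix_path, ages = round(ages, 1))

  ## young/old pair: the young sample is the ground state; the old one is
  ## the same populations advanced `steps` Markov steps under site-specific
  ## rates, so estimate_rates() on the old betas has a consistent target.
  young <- ground_state(betas[1, ], colnames(betas),
                        origin = "synthetic-young")
  rates <- estimate_rates(
    pmin(pmax(stats::rbeta(n_features, 0.5, 0.5), 0.02), 0.98),
    limits = limits)
  old_data <- simulate_methylation_dataset(
    young, rates, max_age = steps + 1L, n_sets = 1, n_cells = n_cells,
    seed = stats::runif(1, 1, 2^30))
  old_beta <- old_data$matrix[old_data$ages == steps, ]
  young_path <- file.path(dir, "synthetic_young_sample.tsv")
  old_path <- file.path(dir, "synthetic_old_sample.tsv")
  write_ground_state(young, young_path)
  write_ground_state(ground_state(old_beta, colnames(betas),
                                  origin = "synthetic-old"), old_path)
  c(matrix = matrix_path, young = young_path, old = old_path)
}

fixture_counts <- function(dir, n_genes, n_samples) {
  mu <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 2)
  counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                  mu = rep(mu, n_samples), size = 2),
                   n_genes, n_samples,
                   dimnames = list(default_feature_ids(n_genes),
                                   sprintf("s%02d", seq_len(n_samples))))
  path <- file.path(dir, "synthetic_counts.tsv")
  utils::write.table(data.frame(feature_id = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  c(counts = path)
}

fixture_fractions <- function(dir, n_samples) {
  types <- c("B", "NK", "CD4T", "CD8T", "Mono", "Neutro", "Eosino")
  alpha <- c(2, 2, 6, 4, 3, 20, 1)  # neutrophil-dominated blood
  g <- matrix(stats::rgamma(n_samples * length(types),
                            shape = rep(alpha, each = n_samples)),
              n_samples, length(types))
  f <- g / rowSums(g)
  colnames(f) <- types
  rownames(f) <- sprintf("s%02d", seq_len(n_samples))
  path <- file.path(dir, "synthetic_fractions.tsv")
  utils::write.table(data.frame(sample = rownames(f), round(f, 5),
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fractions = path)
}
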