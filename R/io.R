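# File formats. TSV is the canonical dialect (tab-separated, UTF-8, "."
# decimal); CSV is accepted on read. Datasets serialize one row per
# sample with feature columns plus `age` and `set`; ground states and
# rate tables are small keyed TSVs.

## Read a delimited file, choosing the separator from the extension or by
## sniffing the header line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE) ||
             (!grepl("\t", first) && grepl(",", first))) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a labeled dataset as TSV
#'
#' One row per sample; feature columns first, then `age` and `set`. The
#' simulation mode is stored in a `#mode=` comment line and restored on
#' read.
#'
#' @param data a [labeled_dataset()].
#' @param path output file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns a [labeled_dataset()].
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mode=%s", data$mode), con)
  df <- as.data.frame(data$matrix)
  df$age <- data$ages
  df$set <- data$set_label
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  first <- readLines(path, n = 1L)
  mode <- if (startsWith(first, "#mode=")) sub("^#mode=", "", first)
          else "clamped"
  df <- read_delim_auto(path)
  if (!all(c("age", "set") %in% names(df)))
    stop_arg("dataset file must have `age` and `set` columns")
  feat <- setdiff(names(df), c("age", "set"))
  labeled_dataset(as.matrix(df[feat]), df$age, df$set, mode = mode)
}

#' Write / read a ground state as two-column TSV
#'
#' @param ground a [ground_state()].
#' @param path file path (`feature_id`, `value` columns).
#' @return `write_ground_state` returns `path` invisibly;
#'   `read_ground_state` returns a [ground_state()].
#' @export
write_ground_state <- function(ground, path) {
  stopifnot(inherits(ground, "ground_state"))
  utils::write.table(
    data.frame(feature_id = ground$feature_ids, value = ground$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_state
#' @param origin provenance tag attached on read.
#' @export
read_ground_state <- function(path, origin = basename(path)) {
  df <- read_delim_auto(path)
  ground_state(df$value, df$feature_id, origin = origin)
}

#' Write / read maintenance rates as TSV
#'
#' @param rates a [maintenance_rates()].
#' @param path file path (`feature_id`, `e_m`, `e_d` columns).
#' @param limits limits attached on read (default [rate_limits()]).
#' @return `write_rates` returns `path` invisibly; `read_rates` returns a
#'   [maintenance_rates()].
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "maintenance_rates"))
  utils::write.table(
    data.frame(feature_id = default_feature_ids(length(rates$e_m)),
               e_m = rates$e_m, e_d = rates$e_d),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path, limits = rate_limits()) {
  df <- read_delim_auto(path)
  maintenance_rates(df$e_m, df$e_d, limits = limits,
                    provenance = "estimated")
}

#' Read a beta matrix with optional sample ages
#'
#' Accepts TSV or CSV with features either as rows or as columns. A
#' header column named `feature_id` pins rows as features (sample ids in
#' the remaining column names, and an optional `age` *row* keyed by
#' feature id). Otherwise samples are taken as rows (feature ids in the
#' header, optional `age` column); if neither convention is detectable
#' the longer axis is assumed to be features, with a warning. Values must
#' lie in \[0, 1\]; out-of-range entries raise an error naming feature
#' and sample. Missing values are permitted and propagated.
#'
#' @param path file path.
#' @return List with `betas` (samples x features numeric matrix) and
#'   `ages` (numeric vector or `NULL`).
#' @export
read_beta_matrix <- function(path) {
  df <- read_delim_auto(path)
  ages <- NULL
  if (names(df)[1] == "feature_id") {         # rows are features
    ids <- df$feature_id
    m <- as.matrix(df[-1])
    if ("age" %in% ids) {
      ages <- as.numeric(m[ids == "age", ])
      m <- m[ids != "age", , drop = FALSE]
      ids <- ids[ids != "age"]
    }
    betas <- t(m)
    colnames(betas) <- ids
  } else {                                     # rows are samples
    if (!("age" %in% names(df)) && nrow(df) > ncol(df))
      warning("orientation ambiguous; assuming the longer axis (rows) are samples",
              call. = FALSE)
    if ("age" %in% names(df)) {
      ages <- as.numeric(df$age)
      df <- df[setdiff(names(df), "age")]
    }
    betas <- as.matrix(df)
  }
  if (!is.numeric(betas)) stop_arg("non-numeric cells in beta matrix")
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop_arg("beta values outside [0, 1]: %d offender(s), first at feature %s, sample %s (value %g)",
             nrow(bad), colnames(betas)[b[2]],
             if (!is.null(rownames(betas))) rownames(betas)[b[1]] else b[1],
             betas[b[1], b[2]])
  }
  list(betas = betas, ages = ages)
}

#' Write a beta matrix (samples x features) as TSV
#'
#' @param betas samples x features matrix in \[0, 1\].
#' @param path file path.
#' @param ages optional per-sample ages written as an `age` column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path, ages = NULL) {
  df <- as.data.frame(betas)
  if (!is.null(ages)) df$age <- ages
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
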