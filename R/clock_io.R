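# Clock serialization: TSV coefficient tables with special rows for the
# intercept and the age transform, in the same dialect accepted by
# load_clock_coefficients() for published clocks.

#' Write / read a clock model as a TSV coefficient table
#'
#' The table has `feature_id` and `coefficient` columns; special rows
#' `__intercept__` and `__transform_*__` carry the intercept and the
#' age-transform specification. Plain published coefficient tables
#' (feature + coefficient + optional intercept row) are read by
#' [load_clock_coefficients()]; `read_clock` additionally restores the
#' transform rows written by `write_clock`.
#'
#' @param model a `clock_model`.
#' @param path file path.
#' @return `write_clock` returns `path` invisibly; `read_clock` returns a
#'   `clock_model`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  tr <- model$transform
  special <- data.frame(
    feature_id = c("__intercept__", "__transform_type__",
                   "__transform_scale__", "__transform_shift__",
                   "__transform_k__", "__transform_max_age__",
                   "__transform_adult_age__", "__transform_range_min__",
                   "__transform_range_max__"),
    coefficient = c(model$intercept,
                    match(tr$type, c("identity", "minmax", "multiply",
                                     "loglog", "horvath")),
                    tr$scale, tr$shift, tr$k,
                    if (is.null(tr$max_age)) NA else tr$max_age,
                    tr$adult_age,
                    if (is.null(tr$range_min)) NA else tr$range_min,
                    if (is.null(tr$range_max)) NA else tr$range_max))
  tab <- rbind(
    data.frame(feature_id = model$feature_ids,
               coefficient = unname(model$coefficients)),
    special)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  tab <- read_delim_auto(path)
  special <- grepl("^__transform_", tab$feature_id)
  tr_vals <- stats::setNames(tab$coefficient[special],
                             tab$feature_id[special])
  base <- tab[!special, , drop = FALSE]
  if (!length(tr_vals))
    return(load_clock_coefficients(base))
  type <- c("identity", "minmax", "multiply", "loglog",
            "horvath")[tr_vals[["__transform_type__"]]]
  tr <- age_transform(type,
                      scale = tr_vals[["__transform_scale__"]],
                      shift = tr_vals[["__transform_shift__"]],
                      k = tr_vals[["__transform_k__"]],
                      max_age = if (!is.na(tr_vals[["__transform_max_age__"]]))
                        tr_vals[["__transform_max_age__"]],
                      adult_age = tr_vals[["__transform_adult_age__"]])
  if (!is.na(tr_vals[["__transform_range_min__"]])) {
    tr$range_min <- tr_vals[["__transform_range_min__"]]
    tr$range_max <- tr_vals[["__transform_range_max__"]]
  }
  load_clock_coefficients(base, transform = tr)
}
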