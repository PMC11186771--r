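# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Derive a reproducible child seed from a root seed. Child streams for
## distinct indices are distinct; results stay below 2^31 - 1 so they are
## valid R integer seeds.
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(i)
  as.integer(s %% 2147483647)
}

## Set the RNG if a seed is supplied; otherwise leave the current stream.
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## logit/expit with an epsilon guard: biological beta matrices contain exact
## 0s and 1s, which would map to +/-Inf.
guarded_logit <- function(x, eps = 1e-6) {
  stats::qlogis(pmin(pmax(x, eps), 1 - eps))
}

expit <- function(x) stats::plogis(x)

stop_arg <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("`%s` must be a single finite number", name)
  if (x < min || x > max)
    stop_arg("`%s` must be in [%s, %s]", name, format(min), format(max))
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_arg("`%s` must be an integer", name)
  invisible(x)
}

default_feature_ids <- function(n) {
  sprintf("f%0*d", max(4L, nchar(n)), seq_len(n))
}
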