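# Invertible age transforms applied to the training target before elastic
# net fitting and inverted at prediction time.

#' Age transforms for clock training
#'
#' Four transform families are supported:
#' \describe{
#'   \item{identity}{no transform (default for purely simulated ages).}
#'   \item{minmax}{ages are min-max scaled to \[0, 1\] (bounds fitted on the
#'     training ages and stored in the model), then multiplied by `scale`
#'     and shifted by `shift`; the defaults (400, -120) map arbitrary
#'     simulated time steps onto a human-like year scale.}
#'   \item{multiply}{ages are multiplied by `k` (default 2), the rescaling
#'     used for transcriptomic simulations.}
#'   \item{loglog}{relative-age transform `-log(-log(age / max_age))` with
#'     inverse `exp(-exp(-x))` returning relative age in (0, 1); used for
#'     pan-mammalian-style clocks. Relative ages are clipped to
#'     \[1e-6, 1 - 1e-6\] before the double log.}
#'   \item{horvath}{the piecewise log-linear transform used by published
#'     pan-tissue clocks: `log(age + 1) - log(adult_age + 1)` below
#'     `adult_age`, linear above; needed to apply published coefficient
#'     tables on the year scale.}
#' }
#'
#' @param type one of `"identity"`, `"minmax"`, `"multiply"`, `"loglog"`,
#'   `"horvath"`.
#' @param scale,shift minmax parameters (defaults 400, -120).
#' @param k multiply factor (default 2).
#' @param max_age maximum age for the loglog transform (required for
#'   `"loglog"`).
#' @param adult_age knot of the horvath transform (default 20).
#' @return An object of class `age_transform`.
#' @examples
#' tr <- age_transform("loglog", max_age = 67)
#' inverse_transform_age(tr, transform_age(tr, 33))  # relative age 33/67
#' @export
age_transform <- function(type = c("identity", "minmax", "multiply",
                                   "loglog", "horvath"),
                          scale = 400, shift = -120, k = 2,
                          max_age = NULL, adult_age = 20) {
  type <- match.arg(type)
  if (type == "loglog") {
    if (is.null(max_age)) stop_arg("loglog transform requires `max_age`")
    check_scalar_number(max_age, "max_age")
    if (max_age <= 0) stop_arg("`max_age` must be > 0")
  }
  structure(list(type = type, scale = scale, shift = shift, k = k,
                 max_age = max_age, adult_age = adult_age,
                 range_min = NULL, range_max = NULL),
            class = "age_transform")
}

## Fit data-dependent transform parameters (minmax bounds) on training ages.
fit_transform <- function(tr, ages) {
  if (tr$type == "minmax") {
    tr$range_min <- min(ages)
    tr$range_max <- max(ages)
    if (tr$range_max == tr$range_min)
      stop_arg("minmax transform undefined: all training ages identical")
  }
  if (tr$type == "loglog" && any(ages <= 0 | ages >= tr$max_age))
    stop_arg("loglog transform domain violated: ages must lie strictly between 0 and max_age = %g",
             tr$max_age)
  tr
}

#' Apply an age transform
#' @param tr an [age_transform()] (minmax bounds must have been fitted
#'   during training for `"minmax"`).
#' @param age numeric ages.
#' @return Transformed values.
#' @export
transform_age <- function(tr, age) {
  stopifnot(inherits(tr, "age_transform"))
  switch(tr$type,
    identity = age,
    multiply = tr$k * age,
    minmax = {
      if (is.null(tr$range_min))
        stop_arg("minmax bounds not fitted; train a clock with this transform first")
      (age - tr$range_min) / (tr$range_max - tr$range_min) * tr$scale +
        tr$shift
    },
    loglog = {
      rel <- pmin(pmax(age / tr$max_age, 1e-6), 1 - 1e-6)
      -log(-log(rel))
    },
    horvath = {
      a <- tr$adult_age
      ifelse(age <= a, log(age + 1) - log(a + 1), (age - a) / (a + 1))
    }
  )
}

#' Invert an age transform
#' @param tr an [age_transform()].
#' @param x transformed values (e.g. a linear predictor).
#' @return Ages on the original scale; for `"loglog"` the relative age in
#'   (0, 1).
#' @export
inverse_transform_age <- function(tr, x) {
  stopifnot(inherits(tr, "age_transform"))
  switch(tr$type,
    identity = x,
    multiply = x / tr$k,
    minmax = {
      if (is.null(tr$range_min))
        stop_arg("minmax bounds not fitted")
      (x - tr$shift) / tr$scale * (tr$range_max - tr$range_min) +
        tr$range_min
    },
    loglog = exp(-exp(-x)),
    horvath = {
      a <- tr$adult_age
      ifelse(x <= 0, (1 + a) * exp(x) - 1, (1 + a) * x + a)
    }
  )
}
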