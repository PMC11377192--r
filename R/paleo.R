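#' Generate a synthetic paleo-environmental curve
#'
#' Produces a dense (age, value) series emulating the paleo-variables used by
#' environment-dependent diversification models: a paleotemperature-like
#' series (linear trend or sinusoidal oscillation) or a paleoelevation-like
#' series (staged, logistic mountain uplift that increases monotonically
#' toward the present).
#'
#' @param kind one of `"linear"`, `"sinusoid"`, `"logistic_uplift"`.
#' @param params named list:
#'   * linear: `intercept` (value at age 0), `slope` (per Ma of age);
#'   * sinusoid: `mean`, `amplitude`, `period` (Ma), `phase` (radians);
#'   * logistic_uplift: `height`, `midpoint_ma`, `scale_ma`, and optionally
#'     `pulses`, a list of further `(height, midpoint_ma, scale_ma)` stages
#'     added to the first.
#' @param span_ma age span in Ma (curve covers ages `[0, span_ma]`).
#' @param step_ma sampling step in Ma.
#' @return data.frame with columns `age_ma` (descending from `span_ma` to 0)
#'   and `value`.
#' @export
make_paleo_curve <- function(kind = c("linear", "sinusoid", "logistic_uplift"),
                             params = list(), span_ma, step_ma = 0.1) {
  kind <- match.arg(kind)
  stopifnot(span_ma > 0, step_ma > 0)
  age <- seq(span_ma, 0, by = -step_ma)
  if (age[length(age)] != 0) age <- c(age, 0)
  p <- params
  value <- switch(kind,
    linear = (p$intercept %||% 0) + (p$slope %||% 0) * age,
    sinusoid = (p$mean %||% 0) + (p$amplitude %||% 1) *
      sin(2 * pi * age / (p$period %||% span_ma) + (p$phase %||% 0)),
    logistic_uplift = {
      logis1 <- function(h, mid, sc) h / (1 + exp((age - mid) / sc))
      v <- logis1(p$height %||% 1, p$midpoint_ma %||% (span_ma / 2),
                  p$scale_ma %||% (span_ma / 10))
      for (pl in p$pulses %||% list())
        v <- v + logis1(pl$height, pl$midpoint_ma, pl$scale_ma)
      v
    })
  data.frame(age_ma = age, value = value)
}

#' Smooth a paleo-environment series into an evaluable curve
#'
#' Fits a penalized cubic smoothing spline with the requested effective
#' degrees of freedom to an (age, value) series and returns a curve object
#' evaluable at any age in Myr; outside the data support the curve is
#' extrapolated as a constant (the boundary value). Environment-dependent
#' birth-death fits conventionally use a high df (e.g. 80) so the spline
#' closely tracks the series.
#'
#' @param series data.frame with columns `age_ma` and `value` (or two
#'   unnamed columns in that order); duplicate ages are an error.
#' @param df effective degrees of freedom (>= 2; capped at the number of
#'   points, at which the spline interpolates).
#' @return object of class `paleo_curve` with fields `fun` (vectorized
#'   age -> value), `age_range`, `df`, `series`.
#' @export
smooth_curve <- function(series, df = 80) {
  if (!all(c("age_ma", "value") %in% names(series))) {
    stopifnot(ncol(series) >= 2)
    names(series)[1:2] <- c("age_ma", "value")
  }
  age <- series$age_ma; val <- series$value
  if (length(age) < 4) stop("need at least 4 points")
  if (anyDuplicated(age)) stop("duplicate ages in series")
  if (df < 2) stop("df must be >= 2")
  df_eff <- min(df, length(age))
  if (df_eff >= length(age)) {
    sf <- stats::splinefun(age, val, method = "natural")
  } else {
    sm <- stats::smooth.spline(age, val, df = df_eff)
    # tabulate the fitted spline on a dense grid once; downstream ODE
    # solvers evaluate the curve millions of times
    gx <- seq(min(age), max(age), length.out = max(4L * length(age), 512L))
    sf <- stats::splinefun(gx, stats::predict(sm, gx)$y, method = "natural")
  }
  rng <- range(age)
  fun <- function(x) sf(pmin(pmax(x, rng[1]), rng[2]))
  structure(list(fun = fun, age_range = rng, df = df_eff, series = series),
            class = "paleo_curve")
}

#' Evaluate a paleo curve at ages (Ma)
#' @param curve a `paleo_curve`.
#' @param age_ma numeric ages.
#' @export
eval_curve <- function(curve, age_ma) {
  stopifnot(inherits(curve, "paleo_curve"))
  curve$fun(age_ma)
}

#' @export
print.paleo_curve <- function(x, ...) {
  cat(sprintf("paleo_curve: %d points, ages %.2f-%.2f Ma, df=%g\n",
              nrow(x$series), x$age_range[2], x$age_range[1], x$df))
  invisible(x)
}
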