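#' Univariate distributions for uncertain parameters
#'
#' A `uq_dist` is a light-weight container describing one uncertain
#' parameter: its inverse CDF (the only function the samplers strictly
#' need), CDF, density, support bounds and first two moments. Uniform and
#' normal marginals cover the bundled case studies; arbitrary marginals can
#' be supplied through [dist_custom()].
#'
#' @param lower,upper Support bounds of the uniform distribution.
#' @return A `uq_dist` object.
#' @examples
#' d <- dist_uniform(15, 25)
#' d$quantile(0.5)
#' @export
dist_uniform <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), upper > lower)
  new_uq_dist(
    type = "uniform",
    quantile = function(u) lower + (upper - lower) * u,
    cdf = function(q) pmin(1, pmax(0, (q - lower) / (upper - lower))),
    density = function(q) stats::dunif(q, lower, upper),
    lower = lower, upper = upper,
    mean = (lower + upper) / 2,
    var = (upper - lower)^2 / 12,
    pars = c(lower = lower, upper = upper)
  )
}

#' @rdname dist_uniform
#' @param mean,sd Mean and standard deviation of the normal distribution.
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(sd > 0)
  new_uq_dist(
    type = "normal",
    quantile = function(u) stats::qnorm(u, mean, sd),
    cdf = function(q) stats::pnorm(q, mean, sd),
    density = function(q) stats::dnorm(q, mean, sd),
    lower = -Inf, upper = Inf,
    mean = mean, var = sd^2,
    pars = c(mean = mean, sd = sd)
  )
}

#' Uniform distribution spanning a relative interval around a centre value
#'
#' Builds `Uniform(center - |center| * fraction, center + |center| * fraction)`,
#' the conventional way of expressing "plus or minus x percent" uncertainty
#' around a published parameter value. A `fraction` of zero returns a point
#' mass, i.e. the parameter is treated as fixed. A centre of exactly zero
#' with a positive fraction is an error: the induced interval would have zero
#' width no matter the fraction, which almost always indicates a mistake in
#' the parameter table; supply an explicit interval with [dist_uniform()]
#' instead.
#'
#' @param center Centre (the nominal parameter value).
#' @param fraction Relative half-width, in `[0, 1)`.
#' @return A `uq_dist` object (or a point mass when `fraction == 0`).
#' @examples
#' dist_uniform_pm(120, 0.1) # Uniform(108, 132)
#' @export
dist_uniform_pm <- function(center, fraction) {
  stopifnot(is.numeric(center), is.numeric(fraction), fraction >= 0, fraction < 1)
  if (fraction == 0) {
    return(dist_point(center))
  }
  if (center == 0) {
    stop("`center` is 0 with a positive `fraction`: the interval ",
         "0 * (1 +/- fraction) is degenerate. Supply an explicit interval ",
         "with dist_uniform().", call. = FALSE)
  }
  half <- abs(center) * fraction
  dist_uniform(center - half, center + half)
}

#' @rdname dist_uniform
#' @param value Location of the point mass.
#' @export
dist_point <- function(value) {
  new_uq_dist(
    type = "point",
    quantile = function(u) rep(value, length(u)),
    cdf = function(q) as.numeric(q >= value),
    density = function(q) ifelse(q == value, Inf, 0),
    lower = value, upper = value,
    mean = value, var = 0,
    pars = c(value = value)
  )
}

#' User-supplied marginal defined by its inverse CDF
#'
#' @param quantile Inverse CDF; a function of `u` in `(0, 1)`, vectorised.
#' @param cdf CDF (optional but required by the forward Rosenblatt map).
#' @param density Density (optional; required by the discretized-Stieltjes
#'   orthogonalisation when a polynomial basis must be built on this
#'   marginal).
#' @param lower,upper Support bounds (finite bounds are required for
#'   Stieltjes orthogonalisation; may be `-Inf`/`Inf` otherwise).
#' @param mean,var Moments; estimated numerically from `quantile` when
#'   omitted.
#' @export
dist_custom <- function(quantile, cdf = NULL, density = NULL,
                        lower = -Inf, upper = Inf,
                        mean = NULL, var = NULL) {
  stopifnot(is.function(quantile))
  if (is.null(mean) || is.null(var)) {
    # Gauss-Legendre moments of Q(u) over u in (0,1)
    gl <- gauss_legendre_01(512)
    qv <- quantile(gl$nodes)
    m <- sum(gl$weights * qv)
    v <- sum(gl$weights * (qv - m)^2)
    if (is.null(mean)) mean <- m
    if (is.null(var)) var <- v
  }
  new_uq_dist(
    type = "custom",
    quantile = quantile, cdf = cdf, density = density,
    lower = lower, upper = upper, mean = mean, var = var,
    pars = numeric(0)
  )
}

new_uq_dist <- function(type, quantile, cdf, density, lower, upper, mean, var,
                        pars) {
  structure(
    list(type = type, quantile = quantile, cdf = cdf, density = density,
         lower = lower, upper = upper, mean = mean, var = var, pars = pars),
    class = "uq_dist"
  )
}

#' @export
print.uq_dist <- function(x, ...) {
  ps <- if (length(x$pars)) {
    paste0("(", paste0(names(x$pars), " = ", signif(x$pars, 6), collapse = ", "), ")")
  } else {
    ""
  }
  cat("<uq_dist> ", x$type, ps, "\n", sep = "")
  invisible(x)
}

#' @export
format.uq_dist <- function(x, ...) {
  if (length(x$pars)) {
    paste0(x$type, "(", paste0(signif(x$pars, 6), collapse = ", "), ")")
  } else {
    x$type
  }
}

is_uq_dist <- function(x) inherits(x, "uq_dist")

# Gauss-Legendre rule on (0, 1), weights summing to one.
gauss_legendre_01 <- function(n) {
  r <- gauss_rule_from_recurrence(legendre_recurrence(n, 0, 1), n)
  list(nodes = r$nodes, weights = r$weights)
}
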