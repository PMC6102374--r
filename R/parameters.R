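#' Define the parameters of a model
#'
#' Each model parameter has a name and either a fixed value or a
#' distribution (in which case it is treated as uncertain). Parameters are
#' stored as a tibble with one row per parameter, in declaration order; that
#' order defines the coordinate order of the joint distribution and of every
#' Sobol index reported downstream.
#'
#' A parameter may carry both a distribution and a fixed fallback value
#' (supply a length-2 list `list(value, dist)`); the fallback is used by
#' [screen_single()] when the parameter is held fixed.
#'
#' @param ... Named arguments; each either a single numeric (fixed value), a
#'   [`uq_dist`][dist_uniform] object (uncertain), or `list(value, dist)`
#'   for an uncertain parameter with a fixed fallback value.
#' @return A tibble of class `uq_parameters` with columns `name`, `value`,
#'   `dist` (list-column of `uq_dist` or `NULL`) and `uncertain`.
#' @examples
#' parameters(kappa = dist_uniform(0.025, 0.075), T_env = dist_uniform(15, 25))
#' @export
parameters <- function(...) {
  args <- list(...)
  if (length(args) == 0) stop("no parameters given", call. = FALSE)
  nms <- names(args)
  if (is.null(nms) || any(nms == "")) {
    stop("all parameters must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicated parameter names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  rows <- purrr::map2(args, nms, function(a, nm) {
    if (is_uq_dist(a)) {
      if (a$type == "point") {
        list(value = a$mean, dist = list(NULL), uncertain = FALSE)
      } else {
        list(value = NA_real_, dist = list(a), uncertain = TRUE)
      }
    } else if (is.numeric(a) && length(a) == 1) {
      list(value = as.numeric(a), dist = list(NULL), uncertain = FALSE)
    } else if (is.list(a) && length(a) == 2 && is.numeric(a[[1]]) &&
               is_uq_dist(a[[2]])) {
      list(value = as.numeric(a[[1]]), dist = list(a[[2]]), uncertain = TRUE)
    } else {
      stop("parameter `", nm, "` must be a number, a uq_dist, or ",
           "list(value, dist)", call. = FALSE)
    }
  })
  out <- tibble::tibble(
    name = nms,
    value = unname(purrr::map_dbl(rows, "value")),
    dist = unname(purrr::map(rows, ~ .x$dist[[1]])),
    uncertain = unname(purrr::map_lgl(rows, "uncertain"))
  )
  class(out) <- c("uq_parameters", class(out))
  out
}

#' Attach an explicit (possibly dependent) joint distribution
#'
#' Overrides the product of the declared marginals with a user-supplied
#' joint, typically a dependent one built with [dependent_joint()]. The
#' joint's dimension must equal the number of uncertain parameters.
#'
#' @param params A [parameters()] tibble.
#' @param joint A `uq_joint` object.
#' @export
set_joint <- function(params, joint) {
  stopifnot(inherits(params, "uq_parameters"), inherits(joint, "uq_joint"))
  if (joint$d != sum(params$uncertain)) {
    stop("joint has dimension ", joint$d, " but there are ",
         sum(params$uncertain), " uncertain parameters", call. = FALSE)
  }
  attr(params, "joint") <- joint
  params
}

#' Joint distribution over the uncertain parameters
#'
#' Collects the uncertain parameters of a parameter set (in declaration
#' order) into a joint distribution, recording fixed parameters separately
#' so they can be substituted at evaluation time. If an explicit joint was
#' attached with [set_joint()] it is returned unchanged (with the fixed
#' values carried alongside); otherwise the joint is the product of the
#' declared independent marginals.
#'
#' @param params A [parameters()] tibble.
#' @return A `uq_joint` object with fields `d` (dimension), `names`,
#'   `fixed` (named vector of fixed parameter values) and either
#'   independent `marginals` or a dependent conditional construction.
#' @export
make_joint <- function(params) {
  stopifnot(inherits(params, "uq_parameters"))
  unc <- params$uncertain
  if (!any(unc)) stop("no uncertain parameter in the set", call. = FALSE)
  fixed <- stats::setNames(params$value[!unc], params$name[!unc])
  joint <- attr(params, "joint")
  if (!is.null(joint)) {
    joint$names <- params$name[unc]
    joint$fixed <- fixed
    return(joint)
  }
  structure(
    list(d = sum(unc), names = params$name[unc],
         dependent = FALSE,
         marginals = params$dist[unc],
         fixed = fixed),
    class = "uq_joint"
  )
}

#' Construct a dependent joint distribution coordinate by coordinate
#'
#' The joint is specified constructively, mirroring the sequential
#' conditional factorisation used by the Rosenblatt transformation: the
#' first coordinate is an ordinary marginal, and each later coordinate is a
#' function of the previously drawn coordinates returning the conditional
#' distribution of that coordinate. This keeps both directions of the
#' Rosenblatt map exact.
#'
#' @param marginal A `uq_dist`: the marginal of the first coordinate.
#' @param ... For each further coordinate, a function `function(q)` taking
#'   the vector of previously drawn coordinates and returning a `uq_dist`
#'   (the conditional distribution given those values).
#' @return A dependent `uq_joint`.
#' @examples
#' # kappa_hat given alpha is Uniform(0.025, 0.075) / alpha, so that
#' # alpha * kappa_hat always has the Uniform(0.025, 0.075) distribution.
#' j <- dependent_joint(
#'   dist_uniform(0.5, 1.5),
#'   function(q) dist_uniform(0.025 / q[1], 0.075 / q[1])
#' )
#' @export
dependent_joint <- function(marginal, ...) {
  conds <- list(...)
  stopifnot(is_uq_dist(marginal), length(conds) >= 1)
  ok <- vapply(conds, is.function, logical(1))
  if (!all(ok)) stop("conditional coordinates must be functions", call. = FALSE)
  structure(
    list(d = 1L + length(conds), names = NULL, dependent = TRUE,
         marginal1 = marginal, conditionals = conds, fixed = numeric(0)),
    class = "uq_joint"
  )
}

#' @export
print.uq_joint <- function(x, ...) {
  cat("<uq_joint> d = ", x$d,
      if (isTRUE(x$dependent)) " (dependent)" else " (independent)", "\n",
      sep = "")
  invisible(x)
}

# Conditional distribution of coordinate i given the earlier coordinates.
joint_conditional <- function(joint, i, q_prev) {
  if (!joint$dependent) return(joint$marginals[[i]])
  if (i == 1) joint$marginal1 else joint$conditionals[[i - 1]](q_prev)
}

#' Map points between the unit hypercube and parameter space
#'
#' `rosenblatt_inverse()` maps points `u` from the open unit hypercube to
#' parameter space by applying, coordinate by coordinate, the inverse CDF of
#' each coordinate's (conditional) distribution; `rosenblatt_forward()` is
#' its inverse. For an independent joint this reduces to the marginal
#' inverse CDFs; for a dependent joint the conditional distributions are
#' applied sequentially, which is the classical Rosenblatt construction.
#'
#' Points on the hypercube boundary are rejected (inverse CDFs of unbounded
#' marginals diverge there); the low-discrepancy generators in this package
#' never produce boundary points.
#'
#' @param joint A `uq_joint` from [make_joint()] or [dependent_joint()].
#' @param u Matrix (n x d) or vector of points strictly inside `(0, 1)^d`.
#' @return Matrix (n x d) of parameter points (or of hypercube points for
#'   the forward map).
#' @export
rosenblatt_inverse <- function(joint, u) {
  u <- as_row_matrix(u, joint$d)
  if (any(u <= 0 | u >= 1)) {
    stop("points must lie strictly inside the open unit hypercube",
         call. = FALSE)
  }
  if (!joint$dependent) {
    q <- vapply(seq_len(joint$d),
                function(i) joint$marginals[[i]]$quantile(u[, i]),
                numeric(nrow(u)))
    q <- matrix(q, nrow = nrow(u))
  } else {
    q <- matrix(NA_real_, nrow(u), joint$d)
    for (r in seq_len(nrow(u))) {
      for (i in seq_len(joint$d)) {
        di <- joint_conditional(joint, i, q[r, seq_len(i - 1)])
        q[r, i] <- di$quantile(u[r, i])
      }
    }
  }
  colnames(q) <- joint$names
  q
}

#' @rdname rosenblatt_inverse
#' @param q Matrix (n x d) or vector of parameter points.
#' @export
rosenblatt_forward <- function(joint, q) {
  q <- as_row_matrix(q, joint$d)
  u <- matrix(NA_real_, nrow(q), joint$d)
  for (i in seq_len(joint$d)) {
    if (!joint$dependent) {
      cdf <- joint$marginals[[i]]$cdf
      if (is.null(cdf)) stop("marginal ", i, " has no CDF", call. = FALSE)
      u[, i] <- cdf(q[, i])
    } else {
      for (r in seq_len(nrow(q))) {
        di <- joint_conditional(joint, i, q[r, seq_len(i - 1)])
        if (is.null(di$cdf)) stop("coordinate ", i, " has no CDF", call. = FALSE)
        u[r, i] <- di$cdf(q[r, i])
      }
    }
  }
  u
}

#' Joint probability density
#'
#' For an independent joint this is the product of the marginal densities;
#' for a dependent joint, the product of the sequential conditional
#' densities.
#'
#' @inheritParams rosenblatt_forward
#' @return Numeric vector of densities, one per row of `q`.
#' @export
joint_density <- function(joint, q) {
  q <- as_row_matrix(q, joint$d)
  out <- rep(1, nrow(q))
  for (r in seq_len(nrow(q))) {
    for (i in seq_len(joint$d)) {
      di <- joint_conditional(joint, i, q[r, seq_len(i - 1)])
      if (is.null(di$density)) stop("coordinate ", i, " has no density",
                                    call. = FALSE)
      out[r] <- out[r] * di$density(q[r, i])
    }
  }
  out
}

as_row_matrix <- function(x, d) {
  if (is.matrix(x)) {
    if (ncol(x) != d) stop("expected ", d, " columns, got ", ncol(x),
                           call. = FALSE)
    x
  } else {
    matrix(x, ncol = d, byrow = TRUE)
  }
}

#' Read a parameter set from a JSON configuration file
#'
#' The file maps each parameter name to one of `{"fixed": x}`,
#' `{"uniform": [a, b]}`, `{"uniform_pm": [center, fraction]}` or
#' `{"normal": [mean, sd]}`. Declaration order defines the coordinate
#' order of the joint distribution.
#'
#' @param path Path to the JSON file.
#' @return A [parameters()] tibble.
#' @export
read_parameter_file <- function(path) {
  cfg <- jsonlite_read(path)
  if (!length(names(cfg))) stop("no named parameters in ", path, call. = FALSE)
  args <- lapply(cfg, function(spec) {
    kind <- names(spec)[1]
    v <- unlist(spec[[1]])
    switch(kind,
      fixed = as.numeric(v),
      uniform = dist_uniform(v[1], v[2]),
      uniform_pm = dist_uniform_pm(v[1], v[2]),
      normal = dist_normal(v[1], v[2]),
      stop("unknown distribution kind `", kind, "` in ", path, call. = FALSE)
    )
  })
  do.call(parameters, args)
}

jsonlite_read <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("reading parameter files requires the jsonlite package",
         call. = FALSE)
  }
  jsonlite::read_json(path)
}

# Substitute a matrix of uncertain-coordinate values into full named
# parameter lists (fixed parameters included), one list per row.
node_param_list <- function(joint, nodes) {
  nodes <- as_row_matrix(nodes, joint$d)
  lapply(seq_len(nrow(nodes)), function(r) {
    p <- as.list(c(stats::setNames(nodes[r, ], joint$names), joint$fixed))
    p
  })
}
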