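#' Declare a black-box model
#'
#' Wraps a simulation function in the evaluation contract used throughout
#' the package. The `run` function receives the model parameters as named
#' arguments and returns a list with components `time` (numeric vector or
#' `NULL` for models without a natural axis), `values` (numeric vector) and
#' optionally `info` (a named list passed on to feature functions, e.g.
#' stimulus timing). Returning `NULL`, or values that are all `NA`, marks
#' that evaluation invalid; so does an error raised inside `run`.
#'
#' @param run Function of named parameter arguments returning
#'   `list(time, values, info)`.
#' @param interpolate Set `TRUE` for irregular models (varying number or
#'   placement of output points between evaluations); the ensemble is then
#'   interpolated onto a common grid.
#' @param labels Character vector of axis labels used by the plot methods,
#'   e.g. `c("time (ms)", "voltage (mV)")`.
#' @param postprocess Optional function `(time, values, info)` returning
#'   `list(time, values)`; applied to each evaluation before the
#'   uncertainty calculations but after feature extraction, e.g. to turn
#'   spike trains into regular binary vectors.
#' @param ignore Set `TRUE` to skip uncertainty quantification of the raw
#'   model output and analyse only the features.
#' @param run_batch Optional vectorised evaluator: a function taking a
#'   matrix of parameter points (one row per evaluation, named columns) and
#'   returning `list(time, values)` with `values` a matrix of one row per
#'   evaluation. Used, when present, instead of looping over `run`; rows of
#'   `NA` mark invalid evaluations.
#' @param name Output name used in result containers.
#' @return A `uq_model` object.
#' @export
uq_model <- function(run, interpolate = FALSE, labels = NULL,
                     postprocess = NULL, ignore = FALSE, run_batch = NULL,
                     name = "model") {
  stopifnot(is.function(run))
  structure(
    list(run = run, interpolate = interpolate, labels = labels,
         postprocess = postprocess, ignore = ignore, run_batch = run_batch,
         name = name),
    class = "uq_model"
  )
}

as_uq_model <- function(model) {
  if (inherits(model, "uq_model")) model else uq_model(model)
}

#' Evaluate a model over a set of parameter points
#'
#' Runs the model once per node, capturing failures as invalid evaluations
#' rather than aborting, and returns the raw per-node outputs in node
#' order. Evaluations are independent by contract, so the order of
#' execution never affects the result; with `parallel > 1` the nodes are
#' farmed out to forked workers (unix only) and gathered by node index.
#'
#' @param model A `uq_model` (or plain model function).
#' @param nodes Matrix of parameter points, one row per evaluation, columns
#'   ordered as the uncertain parameters.
#' @param fixed Named vector/list of fixed parameters passed to every
#'   evaluation.
#' @param names Column names for `nodes` when not already set.
#' @param parallel Number of worker processes.
#' @return A `uq_ensemble`: list of per-node raw results (`time`, `values`,
#'   `info`, `valid`, `error`), plus the node matrix.
#' @export
evaluate_ensemble <- function(model, nodes, fixed = NULL, names = NULL,
                              parallel = 1L) {
  model <- as_uq_model(model)
  nodes <- as.matrix(nodes)
  if (!is.null(names)) colnames(nodes) <- names
  if (is.null(colnames(nodes))) {
    stop("nodes must have column names matching the model arguments",
         call. = FALSE)
  }
  if (!is.null(model$run_batch)) {
    return(ensemble_from_batch(model, nodes, fixed))
  }
  eval_one <- function(r) {
    args <- c(as.list(nodes[r, ]), as.list(fixed))
    out <- tryCatch(do.call(model$run, args), error = function(e) e)
    normalize_evaluation(out)
  }
  idx <- seq_len(nrow(nodes))
  raw <- if (parallel > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, eval_one, mc.cores = parallel)
  } else {
    lapply(idx, eval_one)
  }
  valid <- vapply(raw, `[[`, logical(1), "valid")
  if (!any(valid)) {
    first_err <- Filter(Negate(is.null), lapply(raw, `[[`, "error"))[[1]]
    stop("every model evaluation failed; first diagnostic: ", first_err,
         call. = FALSE)
  }
  structure(list(nodes = nodes, raw = raw, batch = NULL),
            class = "uq_ensemble")
}

ensemble_from_batch <- function(model, nodes, fixed) {
  full <- nodes
  if (length(fixed)) {
    fixed <- unlist(fixed)
    full <- cbind(nodes, matrix(rep(fixed, each = nrow(nodes)),
                                nrow(nodes),
                                dimnames = list(NULL, names(fixed))))
  }
  out <- model$run_batch(full)
  stopifnot(is.list(out), is.matrix(out$values),
            nrow(out$values) == nrow(nodes))
  structure(list(nodes = nodes, raw = NULL,
                 batch = list(time = out$time, values = out$values,
                              info = out$info %||% list())),
            class = "uq_ensemble")
}

normalize_evaluation <- function(out) {
  if (inherits(out, "error")) {
    return(list(time = NULL, values = NULL, info = list(), valid = FALSE,
                error = conditionMessage(out)))
  }
  if (is.null(out)) {
    return(list(time = NULL, values = NULL, info = list(), valid = FALSE,
                error = NULL))
  }
  if (!is.list(out) || !("values" %in% names(out))) {
    stop("a model evaluation must return list(time, values, ...)",
         call. = FALSE)
  }
  values <- out$values
  valid <- !is.null(values) &&
    (!is.numeric(values) || !all(is.na(values)))
  list(time = out$time, values = values, info = out$info %||% list(),
       valid = valid, error = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensemble_validity <- function(ensemble) {
  if (!is.null(ensemble$batch)) {
    !apply(ensemble$batch$values, 1, function(r) all(is.na(r)))
  } else {
    vapply(ensemble$raw, `[[`, logical(1), "valid")
  }
}

#' Regularise an ensemble onto a common output grid
#'
#' Stacks the per-node outputs into a matrix with one row per node. Regular
#' outputs (identical length everywhere) pass through unchanged. Irregular
#' outputs require `interpolate = TRUE` and a time axis on every valid
#' evaluation: a common grid is chosen as the time axis of the valid
#' evaluation with the most points, restricted to the span covered by all
#' evaluations (so no evaluation is extrapolated), and every evaluation is
#' interpolated onto it -- piecewise cubic for five or more points, linear
#' below that. Invalid evaluations become rows of `NA`; they are never
#' dropped here, since each analysis method has its own policy for them.
#'
#' @param ensemble A `uq_ensemble`.
#' @param interpolate Allow interpolation of irregular outputs.
#' @param postprocess Optional `(time, values, info)` function applied to
#'   each valid evaluation first.
#' @return List with the common `time` (possibly `NULL`) and the `values`
#'   matrix.
#' @export
regularize <- function(ensemble, interpolate = FALSE, postprocess = NULL) {
  if (!is.null(ensemble$batch)) {
    return(list(time = ensemble$batch$time, values = ensemble$batch$values))
  }
  raw <- ensemble$raw
  valid <- vapply(raw, `[[`, logical(1), "valid")
  evals <- lapply(raw, function(r) {
    if (!r$valid) return(NULL)
    if (!is.null(postprocess)) {
      pp <- postprocess(r$time, r$values, r$info)
      list(time = pp$time, values = as.numeric(pp$values))
    } else {
      list(time = r$time, values = as.numeric(r$values))
    }
  })
  lens <- vapply(evals, function(e) if (is.null(e)) NA_integer_ else length(e$values),
                 integer(1))
  ulen <- unique(lens[!is.na(lens)])
  if (length(ulen) == 1L && !interpolate) {
    time <- evals[[which(valid)[1]]]$time
    values <- matrix(NA_real_, length(raw), ulen)
    for (r in which(valid)) values[r, ] <- evals[[r]]$values
    return(list(time = time, values = values))
  }
  if (!interpolate) {
    bad <- which(!is.na(lens) & lens != ulen[1])[1]
    stop("irregular model output (node ", bad, " has ", lens[bad],
         " points, node ", which(valid)[1], " has ", ulen[1], "); ",
         "construct the model with interpolate = TRUE", call. = FALSE)
  }
  no_time <- which(valid & vapply(evals, function(e) is.null(e) || is.null(e$time),
                                  logical(1)))
  if (length(no_time)) {
    stop("interpolation requested but evaluation at node ", no_time[1],
         " returned no time axis", call. = FALSE)
  }
  ref <- which(valid)[which.max(lens[valid])]
  spans <- vapply(which(valid), function(r) range(evals[[r]]$time), numeric(2))
  lo <- max(spans[1, ])
  hi <- min(spans[2, ])
  grid <- evals[[ref]]$time
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2) {
    stop("evaluations share no common time span to interpolate on",
         call. = FALSE)
  }
  values <- matrix(NA_real_, length(raw), length(grid))
  for (r in which(valid)) {
    e <- evals[[r]]
    values[r, ] <- if (length(e$time) >= 5) {
      stats::spline(e$time, e$values, xout = grid, method = "natural")$y
    } else {
      stats::approx(e$time, e$values, xout = grid)$y
    }
  }
  list(time = grid, values = values)
}

# Evaluate every feature for every node of an ensemble; returns, per
# feature, a list(time, values matrix) aligned with the nodes.
feature_matrices <- function(ensemble, feature_set) {
  raw <- ensemble$raw
  if (is.null(raw)) {
    b <- ensemble$batch
    raw <- lapply(seq_len(nrow(b$values)), function(r) {
      v <- b$values[r, ]
      list(time = b$time, values = v, info = b$info,
           valid = !all(is.na(v)), error = NULL)
    })
  }
  per_node <- lapply(raw, function(r) {
    if (!r$valid) return(NULL)
    prep <- tryCatch(
      if (is.null(feature_set$preprocess)) list(r$time, r$values, r$info)
      else feature_set$preprocess(r$time, r$values, r$info),
      error = function(e) e
    )
    if (inherits(prep, "error")) return(lapply(feature_set$features, function(f) NA_real_))
    lapply(feature_set$features, function(f) {
      out <- tryCatch(do.call(f, prep), error = function(e) NA_real_)
      out
    })
  })
  out <- list()
  for (fn in names(feature_set$features)) {
    vals <- lapply(per_node, function(pn) if (is.null(pn)) NA else pn[[fn]])
    times <- lapply(vals, function(v) if (is.list(v)) v$time else NULL)
    nums <- lapply(vals, function(v) {
      v <- if (is.list(v)) v$values else v
      if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
    })
    lens <- vapply(nums, length, integer(1))
    width <- max(lens)
    ok_len <- lens == width | vapply(nums, function(x) all(is.na(x)), logical(1))
    m <- matrix(NA_real_, length(nums), width)
    for (r in seq_along(nums)) {
      if (ok_len[r] && !all(is.na(nums[[r]]))) m[r, ] <- nums[[r]]
    }
    tms <- Filter(Negate(is.null), times)
    out[[fn]] <- list(time = if (length(tms)) tms[[1]] else NULL, values = m)
  }
  out
}

#' Quantify uncertainty and sensitivity of a model and its features
#'
#' The top-level driver: samples the parameter joint, evaluates the model
#' (and features) at the sampled nodes, and computes, per output, the
#' mean, variance, 5th/95th percentiles and first/total-order Sobol
#' indices with their time averages. With `method = "pc"` (the default) a
#' polynomial chaos expansion is fitted -- by point collocation or
#' pseudo-spectral projection -- and the statistics are read off the
#' expansion; the model and every feature share one node set and one basis
#' and differ only in their coefficients. With `method = "mc"` a Saltelli
#' design of `nr_mc_samples * (d + 2)` evaluations is used: moments and
#' percentiles come from the `A` block and the Sobol indices from
#' Saltelli's estimators. Dependent joints are handled transparently by
#' performing the expansion in the independent base space of the
#' Rosenblatt transformation.
#'
#' Invalid evaluations (failed runs, undefined features) are dropped for
#' point collocation, imputed with the mean for the Saltelli estimators,
#' and a hard error for spectral projection. A warning reports their
#' count; above 50% invalid the analysis aborts, since no statistic is
#' trustworthy then and the parameter distributions should be narrowed.
#'
#' @param parameters A [parameters()] tibble (at least one uncertain
#'   parameter).
#' @param model A `uq_model` or plain model function.
#' @param features Optional: a named list of feature functions
#'   `(time, values, info)`, a `uq_feature_set` (see [spiking_feature_set()]
#'   and [network_feature_set()]), or the strings `"spiking"`/`"network"`.
#' @param method `"pc"` (polynomial chaos) or `"mc"` (quasi-Monte Carlo).
#' @param pc_method `"collocation"` or `"spectral"`.
#' @param polynomial_order Total degree `p` of the expansion (default 4).
#' @param nr_mc_samples Base sample count `N` for `method = "mc"`
#'   (default 10000).
#' @param quadrature_order Quadrature order for spectral projection
#'   (default `polynomial_order + 2`).
#' @param nr_collocation_nodes Number of collocation nodes (default
#'   `2 * (Np + 1)`).
#' @param nr_pc_mc_samples Surrogate samples for percentile estimation.
#' @param seed Seed for the random shift of the Saltelli base sequence;
#'   the collocation path is fully deterministic.
#' @param parallel Worker processes for the model evaluations.
#' @param save_path Optional file path; when given, the result set is
#'   written there with [save_results()].
#' @return A `uq_result` (see [tidy.uq_result()] and [autoplot.uq_result()]).
#' @export
quantify <- function(parameters, model, features = NULL,
                     method = c("pc", "mc"),
                     pc_method = c("collocation", "spectral"),
                     polynomial_order = 4, nr_mc_samples = 10000,
                     quadrature_order = polynomial_order + 2,
                     nr_collocation_nodes = NULL,
                     nr_pc_mc_samples = 10000,
                     seed = NULL, parallel = 1L, save_path = NULL) {
  method <- match.arg(method)
  pc_method <- match.arg(pc_method)
  model <- as_uq_model(model)
  feature_set <- resolve_features(features)
  joint <- make_joint(parameters)
  if (!is.null(seed)) set.seed(seed)

  if (method == "pc") {
    basis <- build_basis(joint, polynomial_order)
    if (pc_method == "collocation") {
      design <- collocation_design(basis, joint, nr_collocation_nodes)
      nodes_q <- design$q
    } else {
      design <- quadrature_design(joint, quadrature_order)
      nodes_q <- design$q
    }
  } else {
    design <- saltelli_design(joint, nr_mc_samples)
    nodes_q <- design$q
  }
  colnames(nodes_q) <- joint$names
  ensemble <- evaluate_ensemble(model, nodes_q, fixed = joint$fixed,
                                parallel = parallel)
  valid <- ensemble_validity(ensemble)
  n_invalid <- sum(!valid)
  if (n_invalid > 0) {
    if (n_invalid > 0.5 * length(valid)) {
      stop(n_invalid, " of ", length(valid), " model evaluations failed ",
           "(more than half); consider redefining the problem with ",
           "narrower parameter distributions", call. = FALSE)
    }
    warning(n_invalid, " of ", length(valid),
            " model evaluations failed and were treated as invalid",
            call. = FALSE)
  }

  outputs <- list()
  if (!model$ignore) {
    reg <- regularize(ensemble, interpolate = model$interpolate,
                      postprocess = model$postprocess)
    outputs[[model$name]] <- reg
  }
  if (!is.null(feature_set)) {
    outputs <- c(outputs, feature_matrices(ensemble, feature_set))
  }
  if (!length(outputs)) {
    stop("nothing to analyse: the model output is ignored and no features ",
         "were given", call. = FALSE)
  }

  results <- purrr::imap(outputs, function(out, nm) {
    analyse_output(out, nm, method, pc_method, design, joint,
                   if (method == "pc") basis else NULL,
                   nr_pc_mc_samples)
  })

  rs <- structure(
    list(outputs = results, parameters = joint$names, method = method,
         pc_method = if (method == "pc") pc_method else NA_character_,
         polynomial_order = if (method == "pc") polynomial_order else NA_real_,
         nr_mc_samples = if (method == "mc") nr_mc_samples else NA_real_,
         n_nodes = nrow(nodes_q), n_invalid = n_invalid,
         seed = seed %||% NA_real_, labels = model$labels),
    class = "uq_result"
  )
  if (!is.null(save_path)) save_results(rs, save_path)
  rs
}

analyse_output <- function(out, name, method, pc_method, design, joint,
                           basis, nr_pc_mc_samples) {
  y <- out$values
  valid <- stats::complete.cases(y)
  res <- list(time = out$time, evaluations = y)
  if (method == "pc") {
    expansion <- if (pc_method == "collocation") {
      fit_collocation(design, y, basis)
    } else {
      fit_spectral(design, y, basis)
    }
    st <- expansion_statistics(expansion)
    sob <- expansion_sobol(expansion)
    pct <- surrogate_percentiles(expansion, joint, n = nr_pc_mc_samples)
    res$mean <- st$mean
    res$variance <- st$variance
  } else {
    N <- design$N
    A <- y[seq_len(N), , drop = FALSE]
    mom <- mc_moments(A)
    pct <- mc_percentiles(A)
    sob <- withCallingHandlers(
      saltelli_sobol(design, y),
      warning = function(w) {
        # imputation count already reported by quantify's invalid warning
        invokeRestart("muffleWarning")
      }
    )
    res$mean <- mom$mean
    res$variance <- mom$variance
  }
  res$percentile_5 <- pct[1, ]
  res$percentile_95 <- pct[2, ]
  res$sobol_first <- sob$first
  res$sobol_total <- sob$total
  res$sobol_first_average <- sob$first_average
  res$sobol_total_average <- sob$total_average
  res$n_invalid <- sum(!valid)
  res
}

#' One-parameter-at-a-time screening
#'
#' Runs a separate single-parameter uncertainty quantification for each
#' uncertain parameter, holding every other parameter at its fixed
#' fallback value. This is a cheap screening: parameters whose lone-
#' parameter variance is negligible can be fixed before the full analysis.
#' Every uncertain parameter must therefore carry a fallback value
#' (`list(value, dist)` in [parameters()]).
#'
#' @inheritParams quantify
#' @param ... Passed on to [quantify()].
#' @return Named list of `uq_result`, one per uncertain parameter.
#' @export
screen_single <- function(parameters, model, ...) {
  stopifnot(inherits(parameters, "uq_parameters"))
  unc <- which(parameters$uncertain)
  if (!length(unc)) stop("no uncertain parameter in the set", call. = FALSE)
  missing_fallback <- unc[is.na(parameters$value[unc])]
  if (length(missing_fallback)) {
    stop("screening holds the other parameters fixed, but ",
         paste(parameters$name[missing_fallback], collapse = ", "),
         " have no fixed fallback value; declare them as list(value, dist)",
         call. = FALSE)
  }
  out <- lapply(unc, function(i) {
    p <- parameters
    for (k in unc) {
      if (k != i) {
        p$dist[k] <- list(NULL)
        p$uncertain[k] <- FALSE
      }
    }
    attr(p, "joint") <- NULL
    quantify(p, model, ...)
  })
  stats::setNames(out, parameters$name[unc])
}
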