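#' @export
print.uq_result <- function(x, ...) {
  cat("<uq_result> method = ", x$method,
      if (x$method == "pc") paste0(" (", x$pc_method, ", order ",
                                   x$polynomial_order, ")") else "",
      ", ", x$n_nodes, " evaluations",
      if (x$n_invalid > 0) paste0(" (", x$n_invalid, " invalid)") else "",
      "\n", sep = "")
  cat("  parameters: ", paste(x$parameters, collapse = ", "), "\n", sep = "")
  cat("  outputs:    ", paste(names(x$outputs), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy an uncertainty-quantification result
#'
#' `tidy()` returns one row per output point with the mean, variance,
#' standard deviation and the 90% prediction-interval bounds; with
#' `type = "sobol"` one row per parameter and output point with the first-
#' and total-order Sobol indices. `glance()` returns a one-row summary of
#' the run.
#'
#' @param x A `uq_result` from [quantify()].
#' @param type `"statistics"` (default) or `"sobol"`.
#' @param outputs Optional subset of output names.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy uq_result
#' @export
tidy.uq_result <- function(x, type = c("statistics", "sobol"),
                           outputs = NULL, ...) {
  type <- match.arg(type)
  nms <- outputs %||% names(x$outputs)
  rows <- purrr::map(nms, function(nm) {
    o <- x$outputs[[nm]]
    tvec <- o$time %||% seq_along(o$mean)
    if (length(tvec) != length(o$mean)) tvec <- seq_along(o$mean)
    if (type == "statistics") {
      tibble::tibble(
        output = nm, time = tvec,
        mean = o$mean, variance = o$variance, sd = sqrt(o$variance),
        percentile_5 = o$percentile_5, percentile_95 = o$percentile_95
      )
    } else {
      S <- o$sobol_first
      ST <- o$sobol_total
      tidyr::expand_grid(output = nm, parameter = x$parameters,
                         time = tvec) |>
        dplyr::mutate(
          sobol_first = as.vector(t(S)),
          sobol_total = as.vector(t(ST))
        )
    }
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.uq_result
#' @method glance uq_result
#' @export
glance.uq_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, pc_method = x$pc_method,
    polynomial_order = x$polynomial_order,
    nr_mc_samples = x$nr_mc_samples,
    n_evaluations = x$n_nodes, n_invalid = x$n_invalid,
    n_outputs = length(x$outputs), seed = x$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an uncertainty-quantification result
#'
#' `autoplot()` draws, per output, the mean with the 90% prediction
#' interval band; `plot_sobol()` the first-order (or total-order) Sobol
#' indices per parameter over the output axis. Scalar outputs are drawn as
#' points with interval bars. These are diagnostic plots, not
#' publication-ready figures.
#'
#' @param object,x A `uq_result`.
#' @param outputs Optional subset of output names.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uq_result
#' @export
autoplot.uq_result <- function(object, outputs = NULL, ...) {
  df <- tidy.uq_result(object, outputs = outputs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$percentile_5, ymax = .data$percentile_95),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~output, scales = "free") +
    ggplot2::labs(
      x = (object$labels %||% c("output point", ""))[1],
      y = (object$labels %||% c("", "value"))[2],
      title = "mean and 90% prediction interval"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.uq_result
#' @param order `"first"` or `"total"`.
#' @export
plot_sobol <- function(x, outputs = NULL, order = c("first", "total"), ...) {
  order <- match.arg(order)
  df <- tidy.uq_result(x, type = "sobol", outputs = outputs)
  col <- paste0("sobol_", order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[col]],
                                   color = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~output, scales = "free_x") +
    ggplot2::labs(x = (x$labels %||% "output point")[1],
                  y = paste0(order, "-order Sobol index")) +
    ggplot2::ylim(0, 1)
}

#' @importFrom rlang .data
NULL

table1_datasets <- c("evaluations", "time", "mean", "variance",
                     "percentile_5", "percentile_95", "sobol_first",
                     "sobol_total", "sobol_first_average",
                     "sobol_total_average")

required_datasets <- setdiff(table1_datasets, "time")

#' Save and load result sets as HDF5
#'
#' Results are persisted hierarchically: one HDF5 group per output, one
#' dataset per stored metric (`evaluations`, `time`, `mean`, `variance`,
#' `percentile_5`, `percentile_95`, `sobol_first`, `sobol_total`,
#' `sobol_first_average`, `sobol_total_average`), plus a `metadata` group
#' with the run settings. HDF5 has no missing-value marker, so any dataset
#' containing missing entries gets a companion 0/1 `<name>_mask` dataset;
#' masked entries are restored as `NA` on load. Loading a file that lacks a
#' required dataset fails naming the first absent one.
#'
#' @param rs A `uq_result`.
#' @param path File path (conventionally `.h5`).
#' @return `load_results()` returns the restored `uq_result`;
#'   `save_results()` returns `path` invisibly.
#' @export
save_results <- function(rs, path) {
  stopifnot(inherits(rs, "uq_result"))
  if (file.exists(path)) unlink(path)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (nm in names(rs$outputs)) {
    o <- rs$outputs[[nm]]
    grp <- paste0("/", nm)
    rhdf5::h5createGroup(path, grp)
    for (ds in table1_datasets) {
      v <- o[[ds]]
      if (is.null(v)) next
      h5_write_masked(v, path, paste0(grp, "/", ds))
    }
  }
  rhdf5::h5createGroup(path, "/metadata")
  meta <- list(
    method = rs$method, pc_method = rs$pc_method,
    polynomial_order = rs$polynomial_order,
    nr_mc_samples = rs$nr_mc_samples, n_nodes = rs$n_nodes,
    n_invalid = rs$n_invalid, seed = rs$seed,
    parameters = rs$parameters, outputs = names(rs$outputs),
    labels = rs$labels %||% character(0)
  )
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.character(v) && length(v) == 0) v <- ""
    rhdf5::h5write(v, path, paste0("/metadata/", nm))
  }
  invisible(path)
}

h5_write_masked <- function(v, path, ds) {
  if (anyNA(v)) {
    mask <- array(as.integer(is.na(v)), dim = dim(v) %||% length(v))
    vv <- v
    vv[is.na(vv)] <- 0
    rhdf5::h5write(vv, path, ds)
    rhdf5::h5write(mask, path, paste0(ds, "_mask"))
  } else {
    rhdf5::h5write(v, path, ds)
  }
}

#' @rdname save_results
#' @export
load_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  idx <- rhdf5::h5ls(path)
  meta_nms <- idx$name[idx$group == "/metadata"]
  meta <- stats::setNames(
    lapply(meta_nms, function(nm) drop_h5(rhdf5::h5read(path, paste0("/metadata/", nm)))),
    meta_nms
  )
  out_nms <- meta$outputs
  outputs <- stats::setNames(lapply(out_nms, function(nm) {
    grp_items <- idx$name[idx$group == paste0("/", nm)]
    o <- list()
    for (ds in table1_datasets) {
      if (!(ds %in% grp_items)) {
        if (ds %in% required_datasets) {
          stop("results file ", path, " lacks dataset `", ds,
               "` for output `", nm, "`", call. = FALSE)
        }
        next
      }
      v <- drop_h5(rhdf5::h5read(path, paste0("/", nm, "/", ds)))
      if (paste0(ds, "_mask") %in% grp_items) {
        mask <- drop_h5(rhdf5::h5read(path, paste0("/", nm, "/", ds, "_mask")))
        v[mask == 1] <- NA
      }
      o[[ds]] <- v
    }
    for (ds in c("sobol_first", "sobol_total")) {
      if (is.matrix(o[[ds]])) rownames(o[[ds]]) <- meta$parameters
    }
    for (ds in c("sobol_first_average", "sobol_total_average")) {
      if (length(o[[ds]]) == length(meta$parameters)) {
        names(o[[ds]]) <- meta$parameters
      }
    }
    o
  }), out_nms)
  structure(
    list(outputs = outputs, parameters = meta$parameters,
         method = meta$method, pc_method = meta$pc_method,
         polynomial_order = meta$polynomial_order,
         nr_mc_samples = meta$nr_mc_samples, n_nodes = meta$n_nodes,
         n_invalid = meta$n_invalid, seed = meta$seed,
         labels = if (identical(meta$labels, "")) NULL else meta$labels),
    class = "uq_result"
  )
}

drop_h5 <- function(v) {
  if (is.array(v) && length(dim(v)) == 1) as.vector(v) else v
}

#' Time-averaged absolute relative error
#'
#' The error metric of the method-comparison experiment: the average over
#' the output grid of `|reference - estimate| / |reference|`. Optionally
#' the initial transient is excluded by dropping all points with
#' `time < exclude_before`. The metric is scale invariant and zero exactly
#' when the estimate equals the reference.
#'
#' @param reference,estimate Numeric vectors on the same grid.
#' @param time Optional grid (needed for `exclude_before`).
#' @param exclude_before Drop grid points earlier than this.
#' @return A scalar.
#' @export
relative_error <- function(reference, estimate, time = NULL,
                           exclude_before = NULL) {
  stopifnot(length(reference) == length(estimate))
  keep <- rep(TRUE, length(reference))
  if (!is.null(exclude_before)) {
    if (is.null(time)) stop("`exclude_before` needs `time`", call. = FALSE)
    keep <- time >= exclude_before
  }
  keep <- keep & !is.na(reference) & !is.na(estimate)
  r <- reference[keep]
  e <- estimate[keep]
  if (!length(r) || all(r == 0)) {
    stop("reference is identically zero on the averaged region",
         call. = FALSE)
  }
  mean(abs(r - e) / abs(r))
}

# Eq-22-style error of the first-order Sobol indices: per parameter the
# time-averaged relative error, then averaged over parameters.
sobol_relative_error <- function(S_ref, S_est, time = NULL,
                                 exclude_before = NULL) {
  stopifnot(all(dim(S_ref) == dim(S_est)))
  errs <- vapply(seq_len(nrow(S_ref)), function(i) {
    relative_error(S_ref[i, ], S_est[i, ], time = time,
                   exclude_before = exclude_before)
  }, numeric(1))
  mean(errs)
}

#' Compare estimator accuracy against a converged reference
#'
#' Re-runs the uncertainty quantification of one model over a grid of
#' budgets -- polynomial orders for the chaos expansion and base sample
#' counts for the Saltelli quasi-Monte Carlo method -- and reports, for
#' each run, the time-averaged absolute relative error of the mean, the
#' variance, and the parameter-averaged first-order Sobol indices with
#' respect to a converged reference. The reference defaults to a
#' point-collocation expansion at `reference_order`; quasi-Monte Carlo
#' errors are averaged over `mc_reruns` independently shifted designs
#' since that estimator is randomised.
#'
#' @inheritParams quantify
#' @param pc_orders Integer vector of polynomial orders to evaluate (may be
#'   empty).
#' @param mc_samples Integer vector of base sample counts `N` (may be
#'   empty); entries below 2 are skipped with a notice.
#' @param reference Optional precomputed `uq_result` to use as reference.
#' @param reference_order Polynomial order of the default reference.
#' @param mc_reruns Number of re-runs averaged for each `mc_samples` entry.
#' @param exclude_before Initial transient excluded from the error metric
#'   (same units as the model time axis).
#' @param output Name of the analysed output (default: the model output).
#' @return A tibble with columns `method`, `budget`, `n_evaluations`,
#'   `error_mean`, `error_variance`, `error_sobol_first`.
#' @export
convergence_experiment <- function(parameters, model, pc_orders = c(2, 3, 4),
                                   mc_samples = integer(0),
                                   reference = NULL, reference_order = 6,
                                   mc_reruns = 5, exclude_before = NULL,
                                   output = NULL, seed = 1, parallel = 1L) {
  model <- as_uq_model(model)
  if (is.null(reference)) {
    reference <- quantify(parameters, model, method = "pc",
                          polynomial_order = reference_order,
                          parallel = parallel)
  }
  out_nm <- output %||% names(reference$outputs)[1]
  ref <- reference$outputs[[out_nm]]
  err_row <- function(rs, method, budget) {
    o <- rs$outputs[[out_nm]]
    tibble::tibble(
      method = method, budget = budget, n_evaluations = rs$n_nodes,
      error_mean = relative_error(ref$mean, o$mean, ref$time, exclude_before),
      error_variance = relative_error(ref$variance, o$variance, ref$time,
                                      exclude_before),
      error_sobol_first = sobol_relative_error(ref$sobol_first,
                                               o$sobol_first, ref$time,
                                               exclude_before)
    )
  }
  rows <- list()
  for (p in pc_orders) {
    rs <- quantify(parameters, model, method = "pc", polynomial_order = p,
                   parallel = parallel)
    rows[[length(rows) + 1]] <- err_row(rs, "pc", p)
  }
  for (k in seq_along(mc_samples)) {
    N <- mc_samples[k]
    if (N < 2) {
      message("skipping mc budget N = ", N, ": below the minimum of 2")
      next
    }
    reruns <- lapply(seq_len(mc_reruns), function(r) {
      rs <- quantify(parameters, model, method = "mc", nr_mc_samples = N,
                     seed = seed + 1000 * k + r, parallel = parallel)
      err_row(rs, "mc", N)
    })
    avg <- dplyr::bind_rows(reruns) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("error_"), mean))
    rows[[length(rows) + 1]] <- tibble::tibble(
      method = "mc", budget = N,
      n_evaluations = reruns[[1]]$n_evaluations
    ) |> dplyr::bind_cols(avg)
  }
  dplyr::bind_rows(rows)
}
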