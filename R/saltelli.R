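#' Saltelli sampling design for Sobol index estimation
#'
#' Builds the structured design behind Saltelli's estimators: two
#' independent blocks `A` and `B` of `N` parameter points each, plus `d`
#' blocks `AB_i` equal to `A` with column `i` replaced by the corresponding
#' column of `B`. The full design has `N * (d + 2)` rows, stacked as
#' `A`, `B`, `AB_1`, ..., `AB_d`. Uncertainty statistics (mean, variance,
#' percentiles) are computed on the `A` block only, since the remaining
#' rows are not mutually independent.
#'
#' The underlying points are a randomly shifted Halton sequence in `2 d`
#' dimensions (columns `1..d` feed `A` and `d+1..2d` feed `B`), mapped to
#' the parameters through the inverse Rosenblatt transformation so that any
#' joint, dependent ones included, is supported. The random shift is drawn
#' from R's RNG: set a seed for a reproducible design, vary it for
#' independent replicates.
#'
#' @param joint A `uq_joint`.
#' @param N Base sample count (at least 2).
#' @return A `uq_saltelli_design`: list with the row matrix `q`
#'   (`N (d + 2)` rows), `N`, `d` and a `block` factor labelling each row.
#' @export
saltelli_design <- function(joint, N) {
  stopifnot(inherits(joint, "uq_joint"), N >= 2)
  d <- joint$d
  base <- halton_nodes(N, 2 * d, shift = TRUE, start = 101L)
  uA <- base[, seq_len(d), drop = FALSE]
  uB <- base[, d + seq_len(d), drop = FALSE]
  blocks <- vector("list", d + 2)
  blocks[[1]] <- uA
  blocks[[2]] <- uB
  for (i in seq_len(d)) {
    ab <- uA
    ab[, i] <- uB[, i]
    blocks[[i + 2]] <- ab
  }
  u <- do.call(rbind, blocks)
  q <- rosenblatt_inverse(joint, u)
  structure(
    list(q = q, u = u, N = N, d = d,
         block = rep(c("A", "B", paste0("AB", seq_len(d))), each = N),
         names = joint$names),
    class = "uq_saltelli_design"
  )
}

#' @export
print.uq_saltelli_design <- function(x, ...) {
  cat("<uq_saltelli_design> N = ", x$N, ", d = ", x$d, ", ",
      nrow(x$q), " rows\n", sep = "")
  invisible(x)
}

#' Monte-Carlo moments of an evaluation block
#'
#' Sample mean and sample variance (with the `n - 1` divisor) per output
#' point, ignoring invalid (`NA`) rows. Intended for the `A` block of a
#' Saltelli design.
#'
#' @param evaluations Numeric matrix, one row per sample.
#' @return List with vectors `mean` and `variance`.
#' @export
mc_moments <- function(evaluations) {
  evaluations <- as.matrix(evaluations)
  valid <- stats::complete.cases(evaluations)
  if (sum(valid) < 2) {
    stop("need at least 2 valid evaluations to estimate moments",
         call. = FALSE)
  }
  y <- evaluations[valid, , drop = FALSE]
  list(mean = colMeans(y),
       variance = apply(y, 2, stats::var))
}

#' Empirical percentiles of an evaluation block
#'
#' @param evaluations Numeric matrix, one row per sample.
#' @param levels Percentile levels in `(0, 1)`.
#' @return Matrix with one row per level (linear interpolation between
#'   order statistics).
#' @export
mc_percentiles <- function(evaluations, levels = c(0.05, 0.95)) {
  evaluations <- as.matrix(evaluations)
  valid <- stats::complete.cases(evaluations)
  if (!any(valid)) stop("no valid evaluations", call. = FALSE)
  y <- evaluations[valid, , drop = FALSE]
  out <- apply(y, 2, stats::quantile, probs = levels, names = FALSE, type = 7)
  matrix(out, nrow = length(levels),
         dimnames = list(paste0("percentile_", levels * 100), NULL))
}

#' Replace invalid evaluations by the mean of the valid ones
#'
#' Saltelli's estimators need a value in every design row. Invalid rows are
#' replaced by the per-output-point mean of the valid rows, the standard
#' workaround; a warning reports how many rows were imputed, since the
#' replacement biases the estimates when many evaluations failed.
#'
#' @param evaluations Numeric matrix with `NA` rows marking failures.
#' @return The matrix with invalid rows imputed.
#' @export
impute_invalid <- function(evaluations) {
  evaluations <- as.matrix(evaluations)
  bad <- !stats::complete.cases(evaluations)
  if (!any(bad)) return(evaluations)
  if (all(bad)) stop("all evaluations are invalid", call. = FALSE)
  warning(sum(bad), " invalid evaluation(s) replaced by the mean of the ",
          sum(!bad), " valid one(s)", call. = FALSE)
  mu <- colMeans(evaluations[!bad, , drop = FALSE])
  evaluations[bad, ] <- matrix(mu, sum(bad), ncol(evaluations), byrow = TRUE)
  evaluations
}

#' Saltelli estimators of the Sobol indices
#'
#' First-order indices use the Saltelli (2010) estimator
#' `S_i = mean(f_B * (f_ABi - f_A)) / V` and total-order indices the Jansen
#' estimator `S_Ti = mean((f_A - f_ABi)^2) / (2 V)`, with `V` the sample
#' variance over the pooled `A` and `B` blocks. Invalid rows must be
#' imputed first (see [impute_invalid()]); [quantify()] does this
#' automatically. Output points with zero pooled variance get `NA` indices.
#'
#' @param design A `uq_saltelli_design`.
#' @param evaluations Numeric matrix aligned with the design rows.
#' @return As [expansion_sobol()]: matrices `first`, `total` and their
#'   averages over output points.
#' @export
saltelli_sobol <- function(design, evaluations) {
  evaluations <- as.matrix(evaluations)
  stopifnot(nrow(evaluations) == nrow(design$q))
  if (anyNA(evaluations)) {
    evaluations <- impute_invalid(evaluations)
  }
  N <- design$N
  d <- design$d
  fA <- evaluations[seq_len(N), , drop = FALSE]
  fB <- evaluations[N + seq_len(N), , drop = FALSE]
  V <- apply(rbind(fA, fB), 2, stats::var)
  nzv <- V > 0
  S <- matrix(NA_real_, d, ncol(evaluations))
  ST <- matrix(NA_real_, d, ncol(evaluations))
  rownames(S) <- rownames(ST) <- design$names
  for (i in seq_len(d)) {
    fABi <- evaluations[(i + 1) * N + seq_len(N), , drop = FALSE]
    S[i, nzv] <- colMeans(fB * (fABi - fA))[nzv] / V[nzv]
    ST[i, nzv] <- (colMeans((fA - fABi)^2) / 2)[nzv] / V[nzv]
  }
  list(first = S, total = ST,
       first_average = rowMeans(S[, nzv, drop = FALSE]),
       total_average = rowMeans(ST[, nzv, drop = FALSE]))
}

#' Block-wise Saltelli estimation for large designs
#'
#' Computes the same first- and total-order Sobol estimates as running
#' [quantify()] with `method = "mc"`, but evaluates and holds only one
#' design block (`A`, `B`, or one `AB_i`) at a time, so reference-quality
#' runs with hundreds of thousands of evaluations stay within a desktop
#' memory budget. Invalid evaluations are imputed with the running valid
#' mean of the block they occur in.
#'
#' @inheritParams quantify
#' @param N Base sample count (the design totals `N * (d + 2)` rows).
#' @return As [saltelli_sobol()], plus the common `time` axis.
#' @export
saltelli_sobol_blockwise <- function(parameters, model, N, seed = NULL,
                                     parallel = 1L) {
  model <- as_uq_model(model)
  joint <- make_joint(parameters)
  if (!is.null(seed)) set.seed(seed)
  d <- joint$d
  base <- halton_nodes(N, 2 * d, shift = TRUE, start = 101L)
  uA <- base[, seq_len(d), drop = FALSE]
  uB <- base[, d + seq_len(d), drop = FALSE]
  eval_block <- function(u) {
    q <- rosenblatt_inverse(joint, u)
    colnames(q) <- joint$names
    ens <- evaluate_ensemble(model, q, fixed = joint$fixed,
                             parallel = parallel)
    reg <- regularize(ens, interpolate = model$interpolate,
                      postprocess = model$postprocess)
    if (anyNA(reg$values)) {
      reg$values <- suppressWarnings(impute_invalid(reg$values))
    }
    reg
  }
  regA <- eval_block(uA)
  fA <- regA$values
  fB <- eval_block(uB)$values
  V <- apply(rbind(fA, fB), 2, stats::var)
  nzv <- V > 0
  S <- matrix(NA_real_, d, ncol(fA), dimnames = list(joint$names, NULL))
  ST <- S
  for (i in seq_len(d)) {
    ui <- uA
    ui[, i] <- uB[, i]
    fABi <- eval_block(ui)$values
    S[i, nzv] <- colMeans(fB * (fABi - fA))[nzv] / V[nzv]
    ST[i, nzv] <- (colMeans((fA - fABi)^2) / 2)[nzv] / V[nzv]
  }
  list(first = S, total = ST,
       first_average = rowMeans(S[, nzv, drop = FALSE]),
       total_average = rowMeans(ST[, nzv, drop = FALSE]),
       time = regA$time)
}
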