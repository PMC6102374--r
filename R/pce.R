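#' Fit a polynomial chaos expansion by point collocation
#'
#' Regresses the model evaluations at the collocation nodes onto the
#' orthonormal basis, one least-squares problem shared across all output
#' points (time samples or feature slots). A Tikhonov (ridge) penalty
#' stabilises the regression; its weight is selected by generalized
#' cross-validation over a small logarithmic grid that includes zero, so
#' noise-free polynomial data of degree at most `p` is reproduced exactly.
#' Rows flagged invalid are dropped before the regression, which point
#' collocation tolerates as long as at least `Np` valid rows remain.
#'
#' @param design Node design from [collocation_design()] (its `x` component
#'   is used), or a node matrix in the basis' evaluation space.
#' @param evaluations Numeric matrix, one row per node, one column per
#'   output point; rows that are entirely `NA` are treated as invalid.
#' @param basis A `uq_basis`.
#' @return A `uq_expansion` with the coefficient matrix (`Np` x number of
#'   output points), the basis, the selected penalty and the number of
#'   valid evaluations.
#' @export
fit_collocation <- function(design, evaluations, basis) {
  x <- if (is.list(design) && !is.null(design$x)) design$x else design
  evaluations <- as.matrix(evaluations)
  x <- as_row_matrix(x, basis$d)
  stopifnot(nrow(x) == nrow(evaluations))
  valid <- stats::complete.cases(evaluations)
  Np <- nrow(basis$indices)
  n_valid <- sum(valid)
  if (n_valid < Np) {
    stop("only ", n_valid, " valid evaluations for ", Np,
         " basis terms; the regression is underdetermined (need at least ",
         Np, ", recommended ", 2 * (Np + 1), ")", call. = FALSE)
  }
  if (n_valid < 2 * (Np + 1) && n_valid < nrow(evaluations)) {
    warning(nrow(evaluations) - n_valid, " invalid evaluation(s) dropped; ",
            n_valid, " valid rows is below the recommended ", 2 * (Np + 1),
            call. = FALSE)
  }
  Phi <- basis_matrix(basis, x[valid, , drop = FALSE])
  y <- evaluations[valid, , drop = FALSE]
  fit <- ridge_gcv(Phi, y)
  new_uq_expansion(basis, fit$coef, lambda = fit$lambda, n_valid = n_valid)
}

# Ridge regression with GCV selection of the penalty, via the
# eigendecomposition of the normal equations (one factorisation serves all
# penalty values and all output columns).
ridge_gcv <- function(Phi, y,
                      lambdas = c(0, 1e-12, 1e-10, 1e-8, 1e-6, 1e-4, 1e-2)) {
  n <- nrow(Phi)
  A <- crossprod(Phi)
  scale <- mean(diag(A))
  eg <- eigen(A, symmetric = TRUE)
  e <- pmax(eg$values, 0)
  B <- crossprod(eg$vectors, crossprod(Phi, y)) # V' Phi' y
  yty <- colSums(y^2)
  tol <- max(e) * 1e-12
  rank_ok <- sum(e > tol) >= ncol(Phi)
  best <- NULL
  for (lam0 in lambdas) {
    lam <- lam0 * scale
    denom <- e + lam
    if (lam == 0 && !rank_ok) next
    inv <- ifelse(denom > tol, 1 / denom, 0)
    trH <- sum(e * inv)
    if (n - trH < 1e-8) next
    fit_quad <- colSums(B^2 * (2 * inv - e * inv^2))
    rss <- pmax(yty - fit_quad, 0)
    gcv <- sum(n * rss / (n - trH)^2)
    # the grid is ascending, so requiring a material improvement keeps the
    # smallest adequate penalty (noise-free data would otherwise drift to
    # large penalties on the cancellation noise floor of the rss identity)
    if (is.null(best) || gcv < best$gcv * (1 - 1e-6)) {
      best <- list(gcv = gcv, lambda = lam0, inv = inv)
    }
  }
  if (is.null(best)) {
    stop("collocation design is rank deficient: ", sum(e > tol),
         " independent directions for ", ncol(Phi), " basis terms",
         call. = FALSE)
  }
  coef <- eg$vectors %*% (B * best$inv)
  list(coef = coef, lambda = best$lambda)
}

#' Fit a polynomial chaos expansion by pseudo-spectral projection
#'
#' Computes the expansion coefficients as discrete projections
#' `c_n = sum_k w_k Y(node_k) phi_n(node_k)` over a Gaussian quadrature
#' rule. Projection offers no way to drop bad rows, so any invalid
#' evaluation is an error; use point collocation for fragile models.
#'
#' @param rule Quadrature rule from [quadrature_design()].
#' @param evaluations Numeric matrix, one row per quadrature node.
#' @param basis A `uq_basis`.
#' @export
fit_spectral <- function(rule, evaluations, basis) {
  evaluations <- as.matrix(evaluations)
  stopifnot(nrow(evaluations) == length(rule$weights))
  if (anyNA(evaluations)) {
    stop("spectral projection cannot handle invalid evaluations; ",
         "use point collocation (pc_method = \"collocation\") instead",
         call. = FALSE)
  }
  Phi <- basis_matrix(basis, rule$x)
  coef <- crossprod(Phi * rule$weights, evaluations)
  new_uq_expansion(basis, coef, lambda = NA_real_,
                   n_valid = nrow(evaluations))
}

new_uq_expansion <- function(basis, coef, lambda, n_valid) {
  structure(
    list(basis = basis, coef = as.matrix(coef), lambda = lambda,
         n_valid = n_valid),
    class = "uq_expansion"
  )
}

#' @export
print.uq_expansion <- function(x, ...) {
  cat("<uq_expansion> ", nrow(x$coef), " terms x ", ncol(x$coef),
      " output points (order ", x$basis$p, ", ", x$n_valid,
      " evaluations)\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted expansion at new points
#'
#' @param expansion A `uq_expansion`.
#' @param x Node matrix in the basis' evaluation space (parameter space for
#'   independent joints, the unit cube for dependent ones).
#' @return Matrix of surrogate outputs, one row per node.
#' @export
evaluate_expansion <- function(expansion, x) {
  basis_matrix(expansion$basis, x) %*% expansion$coef
}

#' Mean and variance from a chaos expansion
#'
#' With an orthonormal basis the mean of the surrogate is the constant-term
#' coefficient and its variance the sum of the squared remaining
#' coefficients, per output point.
#'
#' @param expansion A `uq_expansion`.
#' @return A list with numeric vectors `mean` and `variance`.
#' @export
expansion_statistics <- function(expansion) {
  cf <- expansion$coef
  list(mean = cf[1, ],
       variance = colSums(cf[-1, , drop = FALSE]^2))
}

#' Sobol sensitivity indices from a chaos expansion
#'
#' The orthonormal expansion gives the variance decomposition directly:
#' the first-order index of parameter `i` sums the squared coefficients of
#' the terms involving only coordinate `i`, and the total-order index those
#' of every term involving coordinate `i`, both divided by the total
#' variance. Output points with zero variance have undefined indices and
#' are reported as `NA`; the time-averaged indices are arithmetic means
#' over the remaining points.
#'
#' @param expansion A `uq_expansion`.
#' @return A list with matrices `first` and `total` (parameters x output
#'   points) and vectors `first_average`, `total_average`.
#' @export
expansion_sobol <- function(expansion) {
  cf <- expansion$coef
  idx <- expansion$basis$indices
  d <- ncol(idx)
  total_var <- colSums(cf[-1, , drop = FALSE]^2)
  # a variance at the regression noise floor relative to the output scale
  # counts as zero (e.g. an output pinned by a fixed initial condition)
  nzv <- total_var > 1e-13 * (cf[1, ]^2 + total_var + 1e-300)
  S <- matrix(NA_real_, d, ncol(cf))
  ST <- matrix(NA_real_, d, ncol(cf))
  rownames(S) <- rownames(ST) <- expansion$basis$names
  active <- idx > 0
  n_active <- rowSums(active)
  for (i in seq_len(d)) {
    only_i <- active[, i] & n_active == 1
    any_i <- active[, i]
    S[i, nzv] <- colSums(cf[only_i, nzv, drop = FALSE]^2) / total_var[nzv]
    ST[i, nzv] <- colSums(cf[any_i, nzv, drop = FALSE]^2) / total_var[nzv]
  }
  list(first = S, total = ST,
       first_average = rowMeans(S[, nzv, drop = FALSE]),
       total_average = rowMeans(ST[, nzv, drop = FALSE]))
}

#' Percentiles of the surrogate output
#'
#' Percentiles have no closed form under the expansion, so they are
#' estimated empirically: the surrogate is evaluated at `n` Hammersley
#' points mapped through the joint and the requested percentiles taken per
#' output point (linear interpolation between order statistics).
#'
#' @param expansion A `uq_expansion`.
#' @param joint The `uq_joint` the expansion was fitted under.
#' @param levels Percentile levels in `(0, 1)`.
#' @param n Number of surrogate samples.
#' @return Matrix with one row per level, one column per output point.
#' @export
surrogate_percentiles <- function(expansion, joint, levels = c(0.05, 0.95),
                                  n = 10000) {
  u <- hammersley_nodes(n, joint$d)
  x <- if (expansion$basis$space == "u") u else rosenblatt_inverse(joint, u)
  vals <- evaluate_expansion(expansion, x)
  out <- apply(vals, 2, stats::quantile, probs = levels, names = FALSE,
               type = 7)
  matrix(out, nrow = length(levels),
         dimnames = list(paste0("percentile_", levels * 100), NULL))
}
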