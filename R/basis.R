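#' Orthonormal multivariate polynomial bases
#'
#' Builds the polynomial family used by the chaos expansion: univariate
#' polynomials orthonormal with respect to each marginal, combined into
#' multivariate products truncated at total degree `p`. Uniform marginals
#' yield (shifted) Legendre polynomials and normal marginals Hermite
#' polynomials, both through their classical three-term recurrences; any
#' other marginal with a density and finite support is orthogonalised
#' numerically with the discretized Stieltjes procedure. The basis is
#' normalised internally, so every normalisation factor equals one and the
#' variance of the expansion is a plain sum of squared coefficients.
#'
#' For a dependent joint the basis is built on the independent unit-cube
#' base space of the Rosenblatt transformation (Legendre on `[0, 1]` in each
#' coordinate) and the model is evaluated at the transformed nodes; the
#' expansion then represents the reformulated model, which has the same
#' output distribution as the original.
#'
#' @param joint A `uq_joint`.
#' @param p Total polynomial degree (non-negative integer).
#' @return A `uq_basis` with the multi-index matrix (`Np` rows in graded
#'   lexicographic order, `Np = choose(d + p, p)`), the per-dimension
#'   recurrence coefficients, and the space (`"q"` for parameter space,
#'   `"u"` for the unit-cube base space) in which it is evaluated.
#' @export
build_basis <- function(joint, p) {
  stopifnot(inherits(joint, "uq_joint"), p >= 0)
  d <- joint$d
  if (joint$dependent) {
    space <- "u"
    recur <- replicate(d, legendre_recurrence(p + 1, 0, 1), simplify = FALSE)
  } else {
    space <- "q"
    recur <- lapply(joint$marginals, marginal_recurrence, nmax = p + 1)
  }
  structure(
    list(d = d, p = p, indices = multi_indices(d, p), recur = recur,
         space = space, names = joint$names),
    class = "uq_basis"
  )
}

#' @export
print.uq_basis <- function(x, ...) {
  cat("<uq_basis> d = ", x$d, ", order p = ", x$p, ", Np = ",
      nrow(x$indices), " terms\n", sep = "")
  invisible(x)
}

# Monic three-term recurrence coefficients (alpha_k, beta_k), k = 0..nmax,
# for the probability measure of one marginal; beta_0 = 1 by convention
# since the weight integrates to one.
marginal_recurrence <- function(dist, nmax) {
  switch(dist$type,
    uniform = legendre_recurrence(nmax, dist$lower, dist$upper),
    normal = list(alpha = rep(dist$mean, nmax + 1),
                  beta = c(1, seq_len(nmax) * dist$var)),
    {
      if (is.null(dist$density) || !is.finite(dist$lower) ||
          !is.finite(dist$upper)) {
        stop("cannot build an orthogonal basis for a `", dist$type,
             "` marginal without a density on finite support", call. = FALSE)
      }
      stieltjes_recurrence(dist$density, dist$lower, dist$upper, nmax)
    }
  )
}

# Legendre recurrence mapped to the interval [a, b] with uniform weight.
legendre_recurrence <- function(nmax, a, b) {
  k <- seq_len(nmax)
  h <- (b - a) / 2
  list(alpha = rep((a + b) / 2, nmax + 1),
       beta = c(1, h^2 * k^2 / (4 * k^2 - 1)))
}

# Discretized Stieltjes procedure: discretise the weight with a fine
# Gauss-Legendre rule on [a, b], then run the standard Stieltjes recursion
# for the recurrence coefficients of the induced orthogonal polynomials.
stieltjes_recurrence <- function(density, a, b, nmax, ndisc = 2000) {
  gl <- gauss_rule_from_recurrence(legendre_recurrence(ndisc, a, b), ndisc)
  x <- gl$nodes
  w <- gl$weights * density(x) * (b - a)
  w <- w / sum(w)
  alpha <- numeric(nmax + 1)
  beta <- numeric(nmax + 1)
  beta[1] <- 1
  p_prev <- numeric(length(x))
  p_cur <- rep(1, length(x))
  nrm_cur <- 1
  for (k in 0:nmax) {
    alpha[k + 1] <- sum(w * x * p_cur^2) / nrm_cur
    if (k < nmax) {
      p_next <- (x - alpha[k + 1]) * p_cur -
        (if (k == 0) 0 else beta[k + 1]) * p_prev
      nrm_next <- sum(w * p_next^2)
      beta[k + 2] <- nrm_next / nrm_cur
      p_prev <- p_cur
      p_cur <- p_next
      nrm_cur <- nrm_next
    }
  }
  list(alpha = alpha, beta = beta)
}

# Orthonormal univariate polynomial values P[, k+1] = p_k(x), k = 0..p.
orthonormal_eval <- function(recur, x, p) {
  n <- length(x)
  P <- matrix(0, n, p + 1)
  P[, 1] <- 1
  if (p >= 1) {
    sb <- sqrt(recur$beta)
    P[, 2] <- (x - recur$alpha[1]) * P[, 1] / sb[2]
    if (p >= 2) {
      for (k in 1:(p - 1)) {
        P[, k + 2] <- ((x - recur$alpha[k + 1]) * P[, k + 1] -
                         sb[k + 1] * P[, k]) / sb[k + 2]
      }
    }
  }
  P
}

# Multi-indices of total degree <= p over d dimensions, graded
# lexicographic: ascending total degree, lexicographic within a degree.
multi_indices <- function(d, p) {
  per_degree <- function(g, d) {
    if (d == 1) return(matrix(g, 1, 1))
    do.call(rbind, lapply(0:g, function(first) {
      rest <- per_degree(g - first, d - 1)
      cbind(first, rest, deparse.level = 0)
    }))
  }
  out <- do.call(rbind, lapply(0:p, per_degree, d = d))
  dimnames(out) <- NULL
  out
}

# Design matrix of the multivariate orthonormal basis at a node matrix
# given in the basis' own space.
basis_matrix <- function(basis, nodes) {
  nodes <- as_row_matrix(nodes, basis$d)
  uni <- lapply(seq_len(basis$d), function(i) {
    orthonormal_eval(basis$recur[[i]], nodes[, i], basis$p)
  })
  Np <- nrow(basis$indices)
  Phi <- matrix(1, nrow(nodes), Np)
  for (n in seq_len(Np)) {
    for (i in seq_len(basis$d)) {
      k <- basis$indices[n, i]
      if (k > 0) Phi[, n] <- Phi[, n] * uni[[i]][, k + 1]
    }
  }
  Phi
}

#' Collocation node design
#'
#' Draws the `Ns = 2 (Np + 1)` collocation nodes recommended for
#' point-collocation regression, where `Np = choose(d + p, p)` is the number
#' of expansion terms, by mapping a Hammersley set through the joint's
#' inverse Rosenblatt transformation. The design is deterministic.
#'
#' @param basis A `uq_basis` built for `joint`.
#' @param joint The `uq_joint` the basis was built for.
#' @param n_nodes Number of nodes; defaults to `2 * (Np + 1)`.
#' @return A list with the hypercube nodes `u`, the parameter-space nodes
#'   `q`, and the nodes in the basis' own evaluation space (`x`).
#' @export
collocation_design <- function(basis, joint, n_nodes = NULL) {
  Np <- nrow(basis$indices)
  if (is.null(n_nodes)) n_nodes <- 2L * (Np + 1L)
  u <- hammersley_nodes(n_nodes, joint$d)
  q <- rosenblatt_inverse(joint, u)
  list(u = u, q = q, x = if (basis$space == "u") u else q)
}

#' Quadrature rules for pseudo-spectral projection
#'
#' Builds a Gaussian quadrature rule adapted to the joint: a full tensor
#' rule with `order + 1` nodes per dimension for up to four dimensions, and
#' a Smolyak sparse combination of Gaussian rules above that. Weights sum
#' to one; sparse-rule weights may be negative.
#'
#' @param joint A `uq_joint`.
#' @param order Quadrature order; the recommended default when projecting
#'   onto a degree-`p` basis is `p + 2`.
#' @return A list with parameter-space nodes `q`, base-space nodes `x`,
#'   hypercube nodes `u` (dependent joints only) and `weights`.
#' @export
quadrature_design <- function(joint, order) {
  d <- joint$d
  recur <- if (joint$dependent) {
    replicate(d, legendre_recurrence(order + 2, 0, 1), simplify = FALSE)
  } else {
    lapply(joint$marginals, marginal_recurrence, nmax = order + 2)
  }
  rule <- if (d <= 4) {
    tensor_gauss(recur, order + 1)
  } else {
    smolyak_gauss(recur, order)
  }
  x <- rule$nodes
  if (joint$dependent) {
    q <- rosenblatt_inverse(joint, x)
    list(q = q, x = x, u = x, weights = rule$weights)
  } else {
    list(q = x, x = x, u = NULL, weights = rule$weights)
  }
}

gauss_rule_from_recurrence <- function(recur, n) {
  a <- recur$alpha[seq_len(n)]
  b <- recur$beta[seq_len(n)]
  if (n == 1) return(list(nodes = a, weights = 1))
  J <- diag(a)
  off <- sqrt(b[-1])
  for (i in seq_len(n - 1)) {
    J[i, i + 1] <- off[i]
    J[i + 1, i] <- off[i]
  }
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ord])^2)
}

tensor_gauss <- function(recur, n_per_dim) {
  d <- length(recur)
  rules <- lapply(recur, gauss_rule_from_recurrence, n = n_per_dim)
  grids <- lapply(rules, `[[`, "nodes")
  nodes <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  w <- Reduce(function(acc, r) {
    as.vector(outer(acc, r$weights))
  }, rules[-1], init = rules[[1]]$weights)
  # expand.grid varies the first factor fastest; outer() above matches that
  list(nodes = nodes, weights = w)
}

# Smolyak combination of one-dimensional Gaussian rules: the rule of level
# k uses k nodes. Exactness grows with `order`; duplicate nodes from
# different combination terms are merged.
smolyak_gauss <- function(recur, order) {
  d <- length(recur)
  w_level <- order + d # index-sum cap; reduces to a (order+1)-node rule at d = 1
  keys <- list()
  nodes_acc <- list()
  w_acc <- numeric(0)
  idx <- multi_indices(d, w_level - d) + 1L # k_i >= 1, |k| <= w_level
  sums <- rowSums(idx)
  keep <- sums >= w_level - d + 1
  idx <- idx[keep, , drop = FALSE]
  sums <- sums[keep]
  kmax <- w_level - d + 1 # largest 1D level given every other coordinate >= 1
  rules1d <- lapply(recur, function(rc) {
    lapply(seq_len(kmax), function(k) gauss_rule_from_recurrence(rc, k))
  })
  env <- new.env(hash = TRUE)
  for (r in seq_len(nrow(idx))) {
    k <- idx[r, ]
    coefc <- (-1)^(w_level - sums[r]) * choose(d - 1, w_level - sums[r])
    sub <- lapply(seq_len(d), function(i) rules1d[[i]][[k[i]]])
    tg <- tensor_gauss_rules(sub)
    for (m in seq_len(nrow(tg$nodes))) {
      key <- paste(signif(tg$nodes[m, ], 12), collapse = "|")
      cur <- env[[key]]
      if (is.null(cur)) {
        env[[key]] <- list(node = tg$nodes[m, ], w = coefc * tg$weights[m])
      } else {
        cur$w <- cur$w + coefc * tg$weights[m]
        env[[key]] <- cur
      }
    }
  }
  entries <- as.list(env)
  nodes <- do.call(rbind, lapply(entries, `[[`, "node"))
  weights <- vapply(entries, `[[`, numeric(1), "w")
  keep <- abs(weights) > 1e-14
  list(nodes = nodes[keep, , drop = FALSE], weights = weights[keep])
}

tensor_gauss_rules <- function(rules) {
  grids <- lapply(rules, `[[`, "nodes")
  nodes <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  w <- Reduce(function(acc, r) as.vector(outer(acc, r$weights)),
              rules[-1], init = rules[[1]]$weights)
  list(nodes = nodes, weights = w)
}
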