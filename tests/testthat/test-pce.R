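test_that("a constant model has only the constant coefficient", {
  j <- make_joint(parameters(a = dist_uniform(0, 1), b = dist_uniform(0, 1)))
  b <- build_basis(j, 3)
  des <- collocation_design(b, j)
  y <- matrix(3, nrow(des$q), 1)
  e <- fit_collocation(des, y, b)
  expect_equal(e$coef[1, 1], 3, tolerance = 1e-10)
  expect_lt(max(abs(e$coef[-1, 1])), 1e-8)
  st <- expansion_statistics(e)
  expect_equal(st$variance, 0, tolerance = 1e-12)
})

test_that("polynomials of degree <= p are represented exactly", {
  j <- make_joint(parameters(a = dist_uniform(0, 1), b = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  des <- collocation_design(b, j)
  f <- function(q) q[, 1] + q[, 2]^2
  e <- fit_collocation(des, cbind(f(des$q)), b)
  set.seed(5)
  qtest <- matrix(stats::runif(200), 100, 2)
  expect_equal(drop(evaluate_expansion(e, qtest)), f(qtest),
               tolerance = 1e-6)
  # closed-form moments: E = 1/2 + 1/3, V = 1/12 + (1/5 - 1/9)
  st <- expansion_statistics(e)
  expect_equal(st$mean, 1 / 2 + 1 / 3, tolerance = 1e-8)
  expect_equal(st$variance, 1 / 12 + 1 / 5 - 1 / 9, tolerance = 1e-8)
})

test_that("collocation tolerates dropped invalid rows", {
  j <- make_joint(parameters(a = dist_uniform(0, 1), b = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  des <- collocation_design(b, j)
  y <- matrix(3, nrow(des$q), 1)
  y[seq(1, nrow(y), by = 10), ] <- NA # ~10% invalid
  expect_warning(e <- fit_collocation(des, y, b), "invalid")
  expect_equal(e$coef[1, 1], 3, tolerance = 1e-10)
  expect_lt(max(abs(e$coef[-1, 1])), 1e-8)
  y2 <- y
  y2[-(1:3), ] <- NA
  expect_error(fit_collocation(des, y2, b), "underdetermined")
})

test_that("linear-in-parameters statistics match closed forms", {
  j <- make_joint(parameters(q = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  des <- collocation_design(b, j)
  e <- fit_collocation(des, cbind(des$q[, 1]), b)
  st <- expansion_statistics(e)
  expect_equal(st$mean, 0.5, tolerance = 1e-10)
  expect_equal(st$variance, 1 / 12, tolerance = 1e-10)
  sob <- expansion_sobol(e)
  expect_equal(unname(sob$first[1, 1]), 1, tolerance = 1e-10)
  expect_equal(unname(sob$total[1, 1]), 1, tolerance = 1e-10)
})

test_that("sobol indices from the expansion match variance decompositions", {
  j <- make_joint(linear_params())
  b <- build_basis(j, 4)
  des <- collocation_design(b, j)
  e <- fit_collocation(des, cbind(des$q[, 1] + 2 * des$q[, 2]), b)
  sob <- expansion_sobol(e)
  expect_equal(unname(sob$first[, 1]), c(0.2, 0.8), tolerance = 1e-8)
  expect_equal(sob$first, sob$total, tolerance = 1e-8)

  ji <- make_joint(interaction_params())
  bi <- build_basis(ji, 4)
  di <- collocation_design(bi, ji)
  ei <- fit_collocation(di, cbind(di$q[, 1] * di$q[, 2]), bi)
  si <- expansion_sobol(ei)
  expect_equal(unname(si$first[, 1]), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(si$total[, 1]), c(1, 1), tolerance = 1e-8)
})

test_that("zero-variance output points get flagged missing indices", {
  j <- make_joint(parameters(q = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  des <- collocation_design(b, j)
  y <- cbind(rep(7, nrow(des$q)), des$q[, 1]) # constant and varying point
  e <- fit_collocation(des, y, b)
  sob <- expansion_sobol(e)
  expect_true(is.na(sob$first[1, 1]))
  expect_equal(unname(sob$first[1, 2]), 1, tolerance = 1e-10)
  expect_equal(unname(sob$first_average), 1) # averaged over nonzero-variance points
})

test_that("spectral projection reproduces analytic coefficients", {
  j <- make_joint(parameters(q = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  rule <- quadrature_design(j, 4)
  e <- fit_spectral(rule, cbind(rule$q[, 1]^2), b)
  # independent oracle: c_n = integral of q^2 * phi_n(q) dq via quadrature
  grid <- seq(0.5, 2e5 - 0.5) / 2e5 # midpoint rule on (0, 1)
  phi <- uqsa:::basis_matrix(b, matrix(grid))
  cn <- colMeans(phi * grid^2)
  expect_equal(drop(e$coef), cn, tolerance = 1e-6)
  st <- expansion_statistics(e)
  expect_equal(st$mean, 1 / 3, tolerance = 1e-10)
  expect_equal(st$variance, 4 / 45, tolerance = 1e-10)
})

test_that("spectral projection refuses invalid evaluations", {
  j <- make_joint(parameters(q = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  rule <- quadrature_design(j, 4)
  y <- cbind(rule$q[, 1])
  y[2] <- NA
  expect_error(fit_spectral(rule, y, b), "collocation")
})

test_that("surrogate percentiles recover uniform quantiles and stay ordered", {
  j <- make_joint(parameters(q = dist_uniform(0, 1)))
  b <- build_basis(j, 2)
  des <- collocation_design(b, j)
  e <- fit_collocation(des, cbind(des$q[, 1]), b)
  pct <- surrogate_percentiles(e, j)
  expect_equal(unname(pct[, 1]), c(0.05, 0.95), tolerance = 0.01)
  # constant model: both percentiles equal the constant
  ec <- fit_collocation(des, matrix(2.5, nrow(des$q), 1), b)
  pc <- surrogate_percentiles(ec, j)
  expect_equal(unname(pc[, 1]), c(2.5, 2.5), tolerance = 1e-8)
  expect_true(all(pct[1, ] <= pct[2, ]))
})

test_that("sobol index sums satisfy their theoretical bounds", {
  # a model with interactions of all orders across three parameters
  ps <- parameters(a = dist_uniform(0, 1), b = dist_uniform(0, 1),
                   c = dist_uniform(0, 1))
  j <- make_joint(ps)
  b4 <- build_basis(j, 4)
  des <- collocation_design(b4, j)
  q <- des$q
  y <- cbind(q[, 1] + q[, 2] * q[, 3], exp(q[, 1] * q[, 2] * q[, 3]))
  e <- fit_collocation(des, y, b4)
  sob <- expansion_sobol(e)
  expect_true(all(colSums(sob$first) <= 1 + 1e-6))
  expect_true(all(colSums(sob$total) >= 1 - 1e-6))
  expect_true(all(sob$first <= sob$total + 1e-12))
})
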