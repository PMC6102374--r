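test_that("failing evaluations are masked invalid, not fatal", {
  m <- uq_model(function(q1, q2) {
    if (q1 > 0.8) stop("diverged")
    list(time = NULL, values = q1 + q2)
  })
  nodes <- cbind(q1 = c(0.1, 0.9, 0.5), q2 = c(0, 0, 0))
  ens <- evaluate_ensemble(m, nodes)
  expect_equal(uqsa:::ensemble_validity(ens), c(TRUE, FALSE, TRUE))
  m_fail <- uq_model(function(q1, q2) stop("boom"))
  expect_error(evaluate_ensemble(m_fail, nodes), "boom")
})

test_that("a NULL return marks the evaluation invalid (missing marker)", {
  m <- uq_model(function(q1) {
    if (q1 > 0.5) return(NULL)
    list(time = NULL, values = q1)
  })
  ens <- evaluate_ensemble(m, cbind(q1 = c(0.2, 0.7)))
  expect_equal(uqsa:::ensemble_validity(ens), c(TRUE, FALSE))
})

test_that("regular ensembles pass through regularize unchanged", {
  m <- uq_model(function(a) list(time = 0:4, values = rep(a, 5)))
  ens <- evaluate_ensemble(m, cbind(a = c(1, 2)))
  reg <- regularize(ens)
  expect_equal(reg$time, 0:4)
  expect_equal(reg$values, rbind(rep(1, 5), rep(2, 5)))
})

test_that("irregular output needs interpolate and preserves smooth signals", {
  m <- uq_model(function(n) {
    tt <- seq(0, 1, length.out = round(n))
    list(time = tt, values = 2 * tt + 1)
  }, interpolate = TRUE)
  ens <- evaluate_ensemble(m, cbind(n = c(100, 101)))
  reg <- regularize(ens, interpolate = TRUE)
  expect_equal(length(reg$time), 101)
  expect_equal(reg$values[1, ], 2 * reg$time + 1, tolerance = 1e-6)
  expect_error(regularize(ens, interpolate = FALSE), "interpolate = TRUE")

  m_no_time <- uq_model(function(n) list(time = NULL, values = seq_len(round(n))),
                        interpolate = TRUE)
  ens2 <- evaluate_ensemble(m_no_time, cbind(n = c(3, 4)))
  expect_error(regularize(ens2, interpolate = TRUE), "no time axis")
})

test_that("statistics are invariant to the node evaluation order", {
  ps <- linear_params()
  rs <- quantify(ps, linear_model())
  # same design, rows evaluated through the scalar path in permuted order
  j <- make_joint(ps)
  b <- build_basis(j, 4)
  des <- collocation_design(b, j)
  perm <- rev(seq_len(nrow(des$q)))
  y_perm <- cbind(des$q[perm, 1] + 2 * des$q[perm, 2])
  e <- fit_collocation(list(x = des$x[perm, ]), y_perm, b)
  expect_equal(expansion_statistics(e)$mean,
               rs$outputs$linear$mean, tolerance = 1e-10)
  expect_equal(expansion_statistics(e)$variance,
               rs$outputs$linear$variance, tolerance = 1e-10)
})

test_that("invalid evaluations are counted and reported", {
  m <- uq_model(function(q1, q2) {
    if (q1 > 0.9) return(NULL)
    list(time = NULL, values = q1 + q2)
  })
  w <- capture_warnings(rs <- quantify(linear_params(), m,
                                       polynomial_order = 2))
  expect_true(any(grepl("[0-9]+ of [0-9]+ model evaluations failed", w)))
  expect_gt(rs$n_invalid, 0)
  expect_equal(rs$outputs$model$n_invalid, rs$n_invalid)

  m_half <- uq_model(function(q1, q2) {
    if (q1 > 0.4) return(NULL)
    list(time = NULL, values = q1)
  })
  expect_error(suppressWarnings(quantify(linear_params(), m_half)),
               "redefining the problem")
})

test_that("an identity feature reproduces the model's own statistics", {
  rs <- quantify(linear_params(), linear_model(),
                 features = list(identity_feature = function(time, values, info) values))
  expect_equal(rs$outputs$identity_feature$mean, rs$outputs$linear$mean,
               tolerance = 1e-9)
  expect_equal(rs$outputs$identity_feature$sobol_first,
               rs$outputs$linear$sobol_first, tolerance = 1e-9)
})

test_that("quantify is reproducible under a fixed seed", {
  rs1 <- quantify(linear_params(), linear_model(), method = "mc",
                  nr_mc_samples = 256, seed = 5)
  rs2 <- quantify(linear_params(), linear_model(), method = "mc",
                  nr_mc_samples = 256, seed = 5)
  expect_identical(rs1$outputs$linear$mean, rs2$outputs$linear$mean)
  expect_identical(rs1$outputs$linear$sobol_first,
                   rs2$outputs$linear$sobol_first)
})

test_that("pc and mc agree on the coffee cup within Monte-Carlo error", {
  rs_pc <- coffee_case()
  rs_mc <- quantify(coffee_parameters(), coffee_model(), method = "mc",
                    nr_mc_samples = 2^12, seed = 17)
  expect_lt(max(abs(rs_pc$outputs$coffee_cup$mean -
                      rs_mc$outputs$coffee_cup$mean)), 0.1)
})

test_that("unknown method tokens are rejected", {
  expect_error(quantify(linear_params(), linear_model(), method = "bogus"))
  expect_error(quantify(linear_params(), linear_model(), pc_method = "x"))
})

test_that("screening runs one single-parameter analysis per parameter", {
  ps <- parameters(
    kappa = list(0.05, dist_uniform(0.025, 0.075)),
    T_env = list(20, dist_uniform(15, 25))
  )
  single <- screen_single(ps, coffee_model(), polynomial_order = 3)
  expect_named(single, c("kappa", "T_env"))
  expect_equal(single$kappa$parameters, "kappa")
  # three uncertain parameters exercise repeated fixing of the others
  ps3 <- parameters(kappa = list(0.05, dist_uniform(0.025, 0.075)),
                    T_env = list(20, dist_uniform(15, 25)),
                    T0_scale = list(1, dist_uniform(0.9, 1.1)))
  m3 <- uq_model(function(kappa, T_env, T0_scale) {
    coffee_cup(kappa, T_env, T0 = 95 * T0_scale, n_points = 30)
  })
  s3 <- screen_single(ps3, m3, polynomial_order = 2)
  expect_named(s3, c("kappa", "T_env", "T0_scale"))
  expect_true(all(vapply(s3, function(r) r$n_nodes, numeric(1)) == 8))
  o_full <- coffee_case()$outputs$coffee_cup
  v_sum <- single$kappa$outputs$coffee_cup$variance +
    single$T_env$outputs$coffee_cup$variance
  # near-additive model: single-parameter variances nearly decompose the total
  idx <- o_full$variance > 1
  expect_lt(max(abs(v_sum[idx] - o_full$variance[idx]) / o_full$variance[idx]),
            0.15)
  # kappa-only variance peaks early, like its full-analysis sobol index
  vk <- single$kappa$outputs$coffee_cup$variance
  tt <- single$kappa$outputs$coffee_cup$time
  expect_lt(tt[which.max(vk)], 100)
  expect_error(screen_single(coffee_parameters(), coffee_model()),
               "fallback")
})

test_that("parallel and serial evaluation give identical ensembles", {
  skip_on_os("windows")
  m <- uq_model(function(q1, q2) list(time = NULL, values = q1 * q2))
  nodes <- cbind(q1 = runif(8), q2 = runif(8))
  e1 <- evaluate_ensemble(m, nodes, parallel = 1)
  e4 <- evaluate_ensemble(m, nodes, parallel = 2)
  expect_equal(lapply(e1$raw, `[[`, "values"),
               lapply(e4$raw, `[[`, "values"))
})
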