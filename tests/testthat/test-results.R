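test_that("results round-trip losslessly through HDF5", {
  rs <- coffee_case()
  path <- withr::local_tempfile(fileext = ".h5")
  save_results(rs, path)
  back <- load_results(path)
  o1 <- rs$outputs$coffee_cup
  o2 <- back$outputs$coffee_cup
  for (ds in c("evaluations", "time", "mean", "variance", "percentile_5",
               "percentile_95", "sobol_first", "sobol_total",
               "sobol_first_average", "sobol_total_average")) {
    expect_identical(unname(as.vector(o1[[ds]])), unname(as.vector(o2[[ds]])),
                     label = ds)
  }
  expect_equal(back$parameters, rs$parameters)
  expect_equal(back$method, rs$method)
  expect_equal(dim(o2$sobol_first), dim(o1$sobol_first))
  expect_equal(rownames(o2$sobol_first), c("kappa", "T_env"))
})

test_that("loading a file without a required dataset names it", {
  rs <- coffee_case()
  path <- withr::local_tempfile(fileext = ".h5")
  save_results(rs, path)
  rhdf5::h5delete(path, "/coffee_cup/sobol_first")
  expect_error(load_results(path), "sobol_first")
  expect_error(load_results(tempfile()), "no such file")
})

test_that("missing feature values survive persistence as flagged missing", {
  m <- uq_model(function(q1, q2) list(time = NULL, values = q1 + q2))
  feat <- list(sometimes = function(time, values, info) {
    if (values > 1.2) NA_real_ else values
  })
  rs <- suppressWarnings(
    quantify(linear_params(), m, features = feat, polynomial_order = 2)
  )
  path <- withr::local_tempfile(fileext = ".h5")
  save_results(rs, path)
  back <- load_results(path)
  ev1 <- rs$outputs$sometimes$evaluations
  expect_true(anyNA(ev1))
  expect_identical(unname(back$outputs$sometimes$evaluations), unname(ev1))
})

test_that("the relative error metric matches hand-computed cases", {
  x <- c(1, 2, 3)
  expect_equal(relative_error(x, x), 0)
  expect_equal(relative_error(rep(2, 10), rep(3, 10)), 0.5)
  tt <- seq(1, 2, length.out = 200)
  expect_equal(relative_error(tt, tt + 0.1), 0.1 * mean(1 / tt))
  expect_equal(0.1 * mean(1 / tt), 0.0693, tolerance = 1e-3)
  expect_error(relative_error(rep(0, 3), x), "identically zero")
})

test_that("the error metric is scale invariant and supports transient cuts", {
  set.seed(6)
  ref <- stats::runif(50, 1, 2)
  est <- ref + stats::rnorm(50, 0, 0.05)
  expect_equal(relative_error(ref, est), relative_error(-7 * ref, -7 * est))
  tt <- seq(0, 15, length.out = 50)
  e_cut <- relative_error(ref, est, time = tt, exclude_before = 5)
  keep <- tt >= 5
  expect_equal(e_cut, mean(abs(ref[keep] - est[keep]) / ref[keep]))
})

test_that("a convergence experiment against itself reports zero error", {
  ref <- coffee_case()
  tab <- convergence_experiment(coffee_parameters(), coffee_model(),
                                pc_orders = 4, reference = ref)
  expect_equal(tab$error_mean, 0, tolerance = 1e-12)
  expect_equal(tab$error_variance, 0, tolerance = 1e-12)
  expect_equal(tab$error_sobol_first, 0, tolerance = 1e-12)
})

test_that("expansion errors shrink with order and beat matched-budget sampling", {
  ps <- hh_parameters(uncertain = c("gbar_Na", "gbar_K", "gbar_L"))
  tab <- convergence_experiment(ps, hh_model(), pc_orders = c(1, 2, 4),
                                mc_samples = 14, mc_reruns = 2,
                                reference_order = 6, seed = 3)
  pc <- tab[tab$method == "pc", ]
  expect_true(all(diff(pc$error_mean) < 0))
  # matched budgets: order 4 uses 72 nodes, N = 14 uses 70 evaluations
  mc <- tab[tab$method == "mc", ]
  expect_lt(pc$error_mean[pc$budget == 4], mc$error_mean)
  expect_message(
    convergence_experiment(ps, hh_model(), pc_orders = integer(0),
                           mc_samples = 1, reference = coffee_case(),
                           output = "coffee_cup"),
    "below the minimum"
  )
})

test_that("tidy, glance and the plot builders expose the result set", {
  rs <- coffee_case()
  td <- tidy(rs)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 150)
  expect_true(all(td$percentile_5 <= td$percentile_95))
  ts <- tidy(rs, type = "sobol")
  expect_equal(nrow(ts), 300)
  expect_true(all(ts$sobol_first <= ts$sobol_total + 1e-9, na.rm = TRUE))
  g <- glance(rs)
  expect_equal(g$n_evaluations, 32)
  p <- ggplot2::autoplot(rs)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_sobol(rs), "ggplot")
})
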