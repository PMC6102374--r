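test_that("coffee cup matches its closed-form solution", {
  out <- coffee_cup(0.05, 20)
  expect_equal(out$values[1], 95)
  analytic <- 20 + 75 * exp(-0.05 * out$time)
  expect_lt(max(abs(out$values - analytic)), 1e-4)
  set.seed(14)
  for (r in 1:100) {
    k <- stats::runif(1, 0.025, 0.075)
    te <- stats::runif(1, 15, 25)
    o <- coffee_cup(k, te, n_points = 20)
    expect_lt(max(abs(o$values - (te + (95 - te) * exp(-k * o$time)))), 1e-4)
  }
  # strong cooling drives the cup to the environment temperature
  fast <- coffee_cup(5, 20)
  expect_lt(max(abs(fast$values[-1] - 20)), 2)
})

test_that("the dependent parameterisation is a pure reparameterisation", {
  a <- coffee_cup_dependent(1, 0.05, 20)
  b <- coffee_cup(0.05, 20)
  expect_identical(a$values, b$values)
  c1 <- coffee_cup_dependent(2, 0.025, 18)
  c2 <- coffee_cup_dependent(1, 0.05, 18)
  expect_equal(c1$values, c2$values, tolerance = 1e-10)
})

test_that("hodgkin-huxley starts at V0 and fires under the standard stimulus", {
  full <- hodgkin_huxley(window = c(0, 15))
  expect_equal(full$values[1], -10) # initial voltage
  win <- hodgkin_huxley()
  expect_true(all(win$time >= 5 & win$time <= 15))
  sp <- find_spikes(win$time, win$values, threshold = 30)
  expect_gte(length(sp), 1) # at least one action potential in the window

  # resting-convention check: from the steady state at 0 mV with no
  # stimulus the membrane stays at rest (the default V_0 = -10 mV start
  # instead fires an anode-break rebound spike, so rest is set explicitly)
  rest <- hodgkin_huxley(V_0 = 0, n_0 = 0.3177, m_0 = 0.0529, h_0 = 0.5961,
                         stimulus = 0, t_end = 50, window = c(0, 50))
  sp0 <- find_spikes(rest$time, rest$values, threshold = 30)
  expect_length(sp0, 0)
  expect_lt(abs(rest$values[length(rest$values)]), 1) # stays near 0 mV
})

test_that("halving the integration step barely changes the trace", {
  a <- hodgkin_huxley(dt = 0.01, record_every = 10L)
  b <- hodgkin_huxley(dt = 0.005, record_every = 20L)
  expect_equal(a$time, b$time)
  expect_lt(max(abs(a$values - b$values)), 0.5)
})

test_that("hh parameter sets carry the published values and +/-10% intervals", {
  ps <- hh_parameters()
  expect_equal(nrow(ps), 11)
  expect_true(all(ps$uncertain))
  d_gna <- ps$dist[[which(ps$name == "gbar_Na")]]
  expect_equal(c(d_gna$lower, d_gna$upper), c(108, 132))
  d_v0 <- ps$dist[[which(ps$name == "V_0")]]
  expect_equal(c(d_v0$lower, d_v0$upper), c(-11, -9))
  ps3 <- hh_parameters(uncertain = c("gbar_Na", "gbar_K", "gbar_L"))
  expect_equal(sum(ps3$uncertain), 3)
  expect_equal(make_joint(ps3)$fixed[["E_Na"]], 112)
})

test_that("the batch and scalar hh evaluators agree", {
  ps <- hh_parameters(uncertain = c("gbar_Na", "gbar_K"))
  j <- make_joint(ps)
  nodes <- sample_joint(j, 3)
  colnames(nodes) <- j$names
  m <- hh_model()
  batch <- m$run_batch(cbind(nodes, matrix(rep(j$fixed, each = 3), 3,
                                           dimnames = list(NULL, names(j$fixed)))))
  for (r in 1:3) {
    one <- do.call(m$run, c(as.list(nodes[r, ]), as.list(j$fixed)))
    expect_equal(batch$values[r, ], one$values, tolerance = 1e-12)
  }
})

test_that("network simulations are reproducible and validate the delay", {
  a <- brunel_lif(2.0, 6, 2, t_sim = 300, seed = 7)
  b <- brunel_lif(2.0, 6, 2, t_sim = 300, seed = 7)
  expect_identical(a$values, b$values)
  expect_equal(a$info$simulation_end, 300)
  expect_error(brunel_lif(2, 6, 0.05), "delay")
})

test_that("network activity grows with the external drive", {
  counts <- vapply(c(1.5, 2.5, 3.5), function(eta) {
    out <- brunel_lif(eta, 6.5, 2, t_sim = 300, seed = 11)
    sum(vapply(out$values, length, integer(1)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("brunel parameter ranges follow the two network states", {
  sr <- brunel_parameters("SR")
  ai <- brunel_parameters("AI")
  g_sr <- sr$dist[[which(sr$name == "g")]]
  g_ai <- ai$dist[[which(ai$name == "g")]]
  expect_equal(c(g_sr$lower, g_sr$upper), c(1, 3))
  expect_equal(c(g_ai$lower, g_ai$upper), c(5, 8))
  eta <- ai$dist[[which(ai$name == "eta")]]
  expect_equal(c(eta$lower, eta$upper), c(1.5, 3.5))
})
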