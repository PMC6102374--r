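# Small algebraic test models and closed-form oracles shared across tests.

# Y = Q1 + 2 Q2 on Uniform(0,1)^2: mean 3/2, variance 5/12, S = (1/5, 4/5).
linear_params <- function() {
  parameters(q1 = dist_uniform(0, 1), q2 = dist_uniform(0, 1))
}
linear_model <- function() {
  uq_model(
    run = function(q1, q2) list(time = NULL, values = q1 + 2 * q2),
    run_batch = function(nodes) {
      list(time = NULL,
           values = cbind(nodes[, "q1"] + 2 * nodes[, "q2"]))
    },
    name = "linear"
  )
}

# Y = Q1 * Q2 on Uniform(-1,1)^2: pure interaction, S_i = 0, S_Ti = 1.
interaction_params <- function() {
  parameters(q1 = dist_uniform(-1, 1), q2 = dist_uniform(-1, 1))
}
interaction_model <- function() {
  uq_model(
    run = function(q1, q2) list(time = NULL, values = q1 * q2),
    run_batch = function(nodes) {
      list(time = NULL, values = cbind(nodes[, "q1"] * nodes[, "q2"]))
    },
    name = "interaction"
  )
}

# Closed-form mean/variance of the cooling coffee cup under
# kappa ~ U(a, b), T_env ~ U(c, d), T0 fixed:
#   E[T](t)  = E[T_env] (1 - g(t)) + T0 g(t),  g(t) = E[e^-kappa t]
#   V[T](t)  = Var(T_env) (1 - g)^2-free decomposition computed exactly below
coffee_closed_form <- function(tt, a = 0.025, b = 0.075, c = 15, d = 25,
                               T0 = 95) {
  g1 <- ifelse(tt == 0, 1, (exp(-a * tt) - exp(-b * tt)) / (tt * (b - a)))
  g2 <- ifelse(tt == 0, 1, (exp(-2 * a * tt) - exp(-2 * b * tt)) / (2 * tt * (b - a)))
  mE <- (c + d) / 2
  vE <- (d - c)^2 / 12
  mean_T <- mE + (T0 - mE) * g1
  # T = T_env (1 - e) + T0 e with e = exp(-kappa t) independent of T_env
  # E[T^2] = E[T_env^2] E[(1-e)^2] + 2 T0 E[T_env] E[e(1-e)] + T0^2 E[e^2]
  ET2 <- (vE + mE^2) * (1 - 2 * g1 + g2) + 2 * T0 * mE * (g1 - g2) + T0^2 * g2
  list(mean = mean_T, variance = ET2 - mean_T^2)
}

# Synthetic voltage trace: Gaussian bumps of given peak times/heights on a
# flat baseline.
bump_trace <- function(peaks, heights = 40, baseline = -65, sd = 1,
                       t_end = max(peaks) + 20, dt = 0.05) {
  time <- seq(0, t_end, by = dt)
  V <- rep(baseline, length(time))
  heights <- rep_len(heights, length(peaks))
  for (i in seq_along(peaks)) {
    V <- V + (heights[i] - baseline) * exp(-(time - peaks[i])^2 / (2 * sd^2))
  }
  list(time = time, values = V)
}

# Session-level cache so expensive case-study runs are computed once and
# shared between test files.
.uq_test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .uq_test_cache)) {
    assign(key, force(expr), envir = .uq_test_cache)
  }
  get(key, envir = .uq_test_cache)
}

hh_case_p4 <- function() {
  cached("hh_p4", quantify(hh_parameters(), hh_model()))
}
hh_case_p5 <- function() {
  cached("hh_p5", quantify(hh_parameters(), hh_model(), polynomial_order = 5))
}
coffee_case <- function(p = 4) {
  cached(paste0("coffee_p", p),
         quantify(coffee_parameters(), coffee_model(), polynomial_order = p))
}
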