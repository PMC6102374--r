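#' Cooling coffee cup model
#'
#' Newton's law of cooling, `dT/dt = -kappa (T - T_env)` with fixed initial
#' temperature `T0 = 95` degrees C, integrated over 200 minutes with an
#' adaptive solver at tight tolerances and reported on a uniform 150-point
#' grid. `coffee_cup_dependent()` is the reparameterised variant
#' `dT/dt = -alpha * kappa_hat (T - T_env)`, whose trajectory is identical
#' to `coffee_cup()` with `kappa = alpha * kappa_hat`.
#'
#' @param kappa Cooling constant (1/min).
#' @param T_env Environment temperature (degrees C).
#' @param T0 Initial temperature (degrees C).
#' @param t_end End time (min).
#' @param n_points Grid size.
#' @return `list(time, values, info)` following the model contract.
#' @export
coffee_cup <- function(kappa, T_env, T0 = 95, t_end = 200, n_points = 150) {
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(
    y = c(T = T0), times = times,
    func = function(t, y, p) list(-kappa * (y - T_env)),
    parms = NULL, rtol = 1e-10, atol = 1e-10
  )
  list(time = times, values = as.numeric(sol[, "T"]), info = list())
}

#' @rdname coffee_cup
#' @param alpha,kappa_hat Factors of the reparameterised cooling constant
#'   `kappa = alpha * kappa_hat`; `alpha` is dimensionless and must be
#'   nonzero.
#' @export
coffee_cup_dependent <- function(alpha, kappa_hat, T_env, T0 = 95,
                                 t_end = 200, n_points = 150) {
  coffee_cup(alpha * kappa_hat, T_env, T0 = T0, t_end = t_end,
             n_points = n_points)
}

#' @rdname coffee_cup
#' @export
coffee_model <- function() {
  uq_model(coffee_cup, labels = c("time (min)", "temperature (C)"),
           name = "coffee_cup")
}

#' @rdname coffee_cup
#' @export
coffee_dependent_model <- function() {
  uq_model(coffee_cup_dependent,
           labels = c("time (min)", "temperature (C)"),
           name = "coffee_cup_dependent")
}

#' Case-study parameter sets
#'
#' `coffee_parameters()` declares the two uncertain parameters of the
#' cooling coffee cup, `kappa ~ Uniform(0.025, 0.075)` and
#' `T_env ~ Uniform(15, 25)`. `coffee_dependent_parameters()` declares the
#' reparameterised, statistically dependent version: `alpha` gets an
#' (arbitrary, zero-free) uniform distribution and `kappa_hat | alpha` is
#' `Uniform(0.025, 0.075) / alpha`, so the product `alpha * kappa_hat`
#' always follows the original `kappa` distribution and the analysis
#' outcome cannot depend on the distribution chosen for `alpha`.
#'
#' @return A [parameters()] tibble (with an attached dependent joint for
#'   the dependent variant).
#' @export
coffee_parameters <- function() {
  parameters(
    kappa = dist_uniform(0.025, 0.075),
    T_env = dist_uniform(15, 25)
  )
}

#' @rdname coffee_parameters
#' @param alpha_range Support of the uniform distribution assigned to
#'   `alpha`; must not include zero.
#' @export
coffee_dependent_parameters <- function(alpha_range = c(0.5, 1.5)) {
  if (alpha_range[1] <= 0 && alpha_range[2] >= 0) {
    stop("the distribution of alpha must not include zero", call. = FALSE)
  }
  ps <- parameters(
    alpha = dist_uniform(alpha_range[1], alpha_range[2]),
    kappa_hat = dist_uniform(0.025 / max(abs(alpha_range)),
                             0.075 / min(abs(alpha_range))),
    T_env = dist_uniform(15, 25)
  )
  joint <- dependent_joint(
    dist_uniform(alpha_range[1], alpha_range[2]),
    function(q) dist_uniform(0.025 / q[1], 0.075 / q[1]),
    function(q) dist_uniform(15, 25)
  )
  set_joint(ps, joint)
}

hh_param_order <- c("V_0", "C_m", "gbar_Na", "gbar_K", "gbar_L",
                    "E_Na", "E_K", "E_L", "n_0", "m_0", "h_0")

hh_defaults <- c(V_0 = -10, C_m = 1, gbar_Na = 120, gbar_K = 36,
                 gbar_L = 0.3, E_Na = 112, E_K = -12, E_L = 10.613,
                 n_0 = 0.0011, m_0 = 0.0003, h_0 = 0.9998)

#' Hodgkin-Huxley membrane model
#'
#' The original four-variable action-potential model in its historical
#' convention (resting potential at 0 mV, depolarisation positive), with
#' the classical rate functions and the parameter set `V_0 = -10` mV,
#' `C_m = 1` uF/cm^2, `gbar_Na = 120`, `gbar_K = 36`, `gbar_L = 0.3`
#' mS/cm^2, `E_Na = 112`, `E_K = -12`, `E_L = 10.613` mV and gating
#' initials `n_0 = 0.0011`, `m_0 = 0.0003`, `h_0 = 0.9998`. A continuous
#' external stimulus (default 140 uA/cm^2) is applied from `t = 0`; the
#' membrane is integrated with fixed-step RK4 (dt = 0.01 ms, compiled) and
#' reported on the analysis window (default 5-15 ms, sampled every 0.05 ms)
#' so the initial transient is excluded from the uncertainty analysis.
#'
#' @param V_0,C_m,gbar_Na,gbar_K,gbar_L,E_Na,E_K,E_L,n_0,m_0,h_0 Model
#'   parameters (see above for units).
#' @param stimulus Injected current (uA/cm^2) from `t = 0`.
#' @param t_end Simulation end (ms).
#' @param window Reported time window (ms).
#' @param dt Integration step (ms).
#' @param record_every Report every this many steps.
#' @return `list(time, values, info)`; `info` carries the stimulus timing.
#' @export
hodgkin_huxley <- function(V_0 = -10, C_m = 1, gbar_Na = 120, gbar_K = 36,
                           gbar_L = 0.3, E_Na = 112, E_K = -12,
                           E_L = 10.613, n_0 = 0.0011, m_0 = 0.0003,
                           h_0 = 0.9998, stimulus = 140, t_end = 15,
                           window = c(5, 15), dt = 0.01, record_every = 5L) {
  q <- matrix(c(V_0, C_m, gbar_Na, gbar_K, gbar_L, E_Na, E_K, E_L,
                n_0, m_0, h_0), 1, 11)
  out <- .hh_run_batch(q, stimulus, t_end, dt, record_every)
  keep <- out$time >= window[1] & out$time <= window[2]
  list(time = out$time[keep], values = out$values[1, keep],
       info = list(stimulus_start = 0, stimulus_end = t_end))
}

#' @rdname hodgkin_huxley
#' @export
hh_model <- function(stimulus = 140, t_end = 15, window = c(5, 15),
                     dt = 0.01, record_every = 5L) {
  run <- function(...) {
    hodgkin_huxley(..., stimulus = stimulus, t_end = t_end, window = window,
                   dt = dt, record_every = record_every)
  }
  run_batch <- function(nodes) {
    q <- matrix(NA_real_, nrow(nodes), 11)
    for (j in seq_along(hh_param_order)) {
      nm <- hh_param_order[j]
      q[, j] <- if (nm %in% colnames(nodes)) nodes[, nm] else hh_defaults[[nm]]
    }
    out <- .hh_run_batch(q, stimulus, t_end, dt, record_every)
    keep <- out$time >= window[1] & out$time <= window[2]
    list(time = out$time[keep], values = out$values[, keep, drop = FALSE],
         info = list(stimulus_start = 0, stimulus_end = t_end))
  }
  uq_model(run, run_batch = run_batch,
           labels = c("time (ms)", "membrane potential (mV)"),
           name = "hodgkin_huxley")
}

#' @rdname hodgkin_huxley
#' @param uncertain Names of the parameters to treat as uncertain (default
#'   all eleven).
#' @param fraction Relative half-width of the uniform uncertainty interval
#'   around each nominal value (default 10 percent).
#' @export
hh_parameters <- function(uncertain = hh_param_order, fraction = 0.1) {
  stopifnot(all(uncertain %in% hh_param_order))
  args <- lapply(hh_param_order, function(nm) {
    v <- hh_defaults[[nm]]
    if (nm %in% uncertain) list(v, dist_uniform_pm(v, fraction)) else v
  })
  do.call(parameters, stats::setNames(args, hh_param_order))
}

#' Recurrent network of integrate-and-fire neurons
#'
#' A sparsely connected excitatory-inhibitory network: 10000 excitatory
#' and 2500 inhibitory leaky integrate-and-fire neurons with current-based
#' delta synapses, each receiving 1000 randomly chosen excitatory and 250
#' inhibitory connections (connection probability 0.1) plus external
#' Poisson drive of rate `eta` times the threshold rate. The excitatory
#' synaptic weight is `J = 0.1` mV, inhibitory weights are `-g * J`, and
#' spikes are delivered after a delay of `delay` ms. Membrane constants
#' follow the canonical parameterisation of this network model: time
#' constant 20 ms, threshold 20 mV, reset 10 mV, refractory period 2 ms;
#' the integration step is 0.1 ms. The network is simulated for 1000 ms
#' and the spike times of the first 20 excitatory neurons are recorded
#' after a 100 ms warm-up.
#'
#' Depending on `g` and `eta` the network settles into qualitatively
#' different states; with `eta` in `[1.5, 3.5]` and delays of a few ms,
#' `g` in `[1, 3]` gives the synchronous-regular (SR) state and `g` in
#' `[5, 8]` the asynchronous-irregular (AI) state.
#'
#' @param eta External input rate relative to the threshold rate.
#' @param g Relative strength of inhibitory synapses.
#' @param delay Synaptic delay (ms).
#' @param J Excitatory synaptic weight (mV).
#' @param t_sim Simulated time (ms).
#' @param t_record Recording start (ms).
#' @param n_record Number of recorded excitatory units.
#' @param seed Seed of the network's internal random number generator
#'   (connectivity and Poisson drive); identical seeds give identical
#'   spike trains.
#' @param dt Integration step (ms).
#' @return `list(time = NULL, values = <list of spike-time vectors>,
#'   info = list(simulation_end))`.
#' @export
brunel_lif <- function(eta, g, delay, J = 0.1, t_sim = 1000, t_record = 100,
                       n_record = 20, seed = 1, dt = 0.1) {
  out <- .brunel_run(eta, g, delay, J, t_sim, t_record, as.integer(n_record),
                     as.integer(seed), dt)
  list(time = NULL, values = out$spiketrains,
       info = list(simulation_end = out$simulation_end))
}

#' @rdname brunel_lif
#' @param ignore Skip uncertainty quantification of the raw (binned) spike
#'   trains and analyse only features; recommended, and the default.
#' @param bin_dt Bin width (ms) of the binary post-processing used when the
#'   raw output is analysed.
#' @export
brunel_model <- function(J = 0.1, t_sim = 1000, t_record = 100,
                         n_record = 20, seed = 1, dt = 0.1,
                         ignore = TRUE, bin_dt = 1) {
  run <- function(eta, g, delay) {
    brunel_lif(eta, g, delay, J = J, t_sim = t_sim, t_record = t_record,
               n_record = n_record, seed = seed, dt = dt)
  }
  uq_model(
    run, ignore = ignore,
    postprocess = function(time, values, info) {
      pp <- binary_spike_postprocess(values, dt = bin_dt,
                                     end = info$simulation_end)
      list(time = pp$time, values = as.numeric(pp$values))
    },
    labels = c("time (ms)", "spike probability"),
    name = "brunel"
  )
}

#' @rdname brunel_lif
#' @param state `"SR"` (synchronous regular) or `"AI"` (asynchronous
#'   irregular); selects the uniform parameter ranges of the corresponding
#'   network state.
#' @export
brunel_parameters <- function(state = c("SR", "AI")) {
  state <- match.arg(state)
  g_range <- if (state == "SR") c(1, 3) else c(5, 8)
  parameters(
    eta = dist_uniform(1.5, 3.5),
    g = dist_uniform(g_range[1], g_range[2]),
    delay = dist_uniform(1.5, 3)
  )
}
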