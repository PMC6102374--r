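test_that("spike detection finds contiguous super-threshold excursions", {
  flat <- bump_trace(numeric(0), t_end = 100)
  expect_length(find_spikes(flat$time, flat$values), 0)

  one <- bump_trace(50)
  sp <- find_spikes(one$time, one$values)
  expect_length(sp, 1)
  expect_equal(sp$spikes[[1]]$peak_time, 50, tolerance = 0.05)

  two <- bump_trace(c(80, 30))
  sp2 <- find_spikes(two$time, two$values)
  expect_length(sp2, 2)
  expect_equal(vapply(sp2$spikes, `[[`, numeric(1), "peak_time"), c(30, 80),
               tolerance = 0.05)
  expect_error(find_spikes(c(1, 1, 2), c(0, 0, 0)), "increasing")
})

test_that("count, rate and latency features follow their definitions", {
  tr <- bump_trace(c(1100, 1200, 1300), t_end = 2000)
  sp <- find_spikes(tr$time, tr$values)
  f <- spiking_features(sp, list(stimulus_start = 1000, stimulus_end = 1900))
  expect_equal(f$nr_spikes, 3)
  expect_equal(f$spike_rate, 3 / 900)
  expect_equal(f$time_before_first_spike, 100, tolerance = 0.05)
  expect_equal(f$spike_rate * 900, f$nr_spikes)
  expect_error(spiking_features(sp, list(stimulus_start = 1000)),
               "stimulus_end")
})

test_that("a perfectly periodic train has zero accommodation", {
  tr <- bump_trace(seq(100, 400, by = 50), t_end = 500)
  sp <- find_spikes(tr$time, tr$values)
  f <- spiking_features(sp, list(stimulus_start = 0, stimulus_end = 500))
  expect_equal(f$accommodation_index, 0, tolerance = 1e-10)
})

test_that("features undefined at the observed spike count return NA", {
  tr <- bump_trace(100, t_end = 300)
  sp <- find_spikes(tr$time, tr$values)
  f <- spiking_features(sp, list(stimulus_start = 0, stimulus_end = 300))
  expect_true(is.na(f$average_AHP_depth)) # needs >= 2 spikes
  expect_true(is.na(f$accommodation_index)) # needs >= 2 intervals
  expect_false(is.na(f$average_AP_overshoot))
})

test_that("AP width matches the half-height chord of a triangular spike", {
  # triangular spike with slope 50 mV/ms peaking at 40 mV; the onset is the
  # threshold crossing at -30 mV, so the measurement level is
  # (-30 + 40) / 2 = 5 mV and the chord width is 2 (40 - 5) / 50 = 1.4 ms
  time <- seq(0, 24, by = 0.01)
  V <- pmax(-60, 40 - 50 * abs(time - 12))
  sp <- find_spikes(time, V, threshold = -30)
  f <- spiking_features(sp, list(stimulus_start = 0, stimulus_end = 24))
  expect_equal(f$average_AP_width, 2 * (40 - 5) / 50, tolerance = 0.02)
  expect_equal(f$average_AP_overshoot, 40, tolerance = 0.5)
})

test_that("binary post-processing reproduces the worked example", {
  out <- binary_spike_postprocess(c(0, 2, 3.5), dt = 0.5, end = 4)
  expect_equal(out$time, seq(0, 4, by = 0.5))
  expect_equal(out$values[1, ], c(1, 0, 0, 0, 1, 0, 0, 1, 0))
})

test_that("binary post-processing invariants hold", {
  expect_equal(binary_spike_postprocess(numeric(0), 0.5, 4)$values[1, ],
               rep(0, 9))
  two_in_one <- binary_spike_postprocess(c(1.0, 1.1), dt = 0.5, end = 2)
  expect_equal(sum(two_in_one$values), 1)
  set.seed(8)
  for (r in 1:20) {
    dt <- stats::runif(1, 0.1, 2)
    end <- stats::runif(1, 5, 50)
    s <- sort(stats::runif(sample(0:20, 1), 0, end))
    out <- binary_spike_postprocess(s, dt, end)
    expect_length(out$time, floor(end / dt) + 1)
    expect_lte(sum(out$values), length(s))
  }
  expect_error(binary_spike_postprocess(c(1, 5), dt = 0.5, end = 4),
               "outside")
})

test_that("identical regular trains give zero fanofactor and unit correlation", {
  trains <- replicate(4, seq(10, 990, by = 20), simplify = FALSE)
  nf <- network_features(trains, end = 1000)
  expect_equal(nf$fanofactor, 0)
  expect_true(all(abs(nf$corrcoef - 1) < 1e-12))
  expect_equal(nf$average_isi, 20)
  expect_equal(nf$average_cv, 0)
  expect_equal(nf$average_local_variation, 0)
})

test_that("poisson trains have the interval statistics of a poisson process", {
  set.seed(21)
  rate <- 0.05 # spikes per ms -> mean isi 20 ms
  trains <- replicate(10, cumsum(stats::rexp(4000, rate)), simplify = FALSE)
  trains <- lapply(trains, function(s) s[s < 50000])
  nf <- network_features(trains, end = 50000)
  expect_equal(nf$average_isi, 1 / rate, tolerance = 0.05 * (1 / rate))
  expect_equal(nf$average_cv, 1, tolerance = 0.05)
  expect_equal(nf$average_local_variation, 1, tolerance = 0.1)
})

test_that("spike-train distances behave like metrics", {
  a <- c(10, 30, 50)
  expect_equal(victor_purpura_dist(a, a), 0)
  expect_equal(van_rossum_dist(a, a), 0)
  b <- c(a, 70)
  # moving is prohibitively expensive in the high-cost limit: the extra
  # spike is simply deleted, cost 1
  expect_equal(victor_purpura_dist(a, b, q = 1e9), 1)
  expect_equal(victor_purpura_dist(numeric(0), b), 4)
  expect_gt(van_rossum_dist(a, b), 0)
  expect_equal(van_rossum_dist(a, b), van_rossum_dist(b, a))
})

test_that("pairwise feature matrices are symmetric with unit diagonal", {
  set.seed(33)
  trains <- replicate(5, sort(stats::runif(30, 0, 1000)), simplify = FALSE)
  nf <- network_features(trains, end = 1000)
  for (m in list(nf$corrcoef, nf$covariance, nf$victor_purpura_dist,
                 nf$van_rossum_dist)) {
    expect_equal(m, t(m))
  }
  expect_equal(diag(nf$corrcoef), rep(1, 5))
  expect_true(all(nf$victor_purpura_dist >= 0))
  expect_true(all(diag(nf$victor_purpura_dist) == 0))
})

test_that("network features drive a full uncertainty analysis", {
  # toy network: regular trains whose common period is the uncertain rate
  m <- uq_model(function(period) {
    trains <- lapply(0:3, function(u) seq(10 + u, 990, by = period))
    list(time = NULL, values = trains, info = list(simulation_end = 1000))
  }, ignore = TRUE)
  ps <- parameters(period = dist_uniform(20, 40))
  rs <- quantify(ps, m, features = network_feature_set(
    features = c("average_isi", "average_cv", "fanofactor", "corrcoef")
  ), polynomial_order = 3)
  o <- rs$outputs$average_isi
  expect_equal(o$mean, 30, tolerance = 0.1) # E[period]
  expect_equal(unname(rs$outputs$average_cv$mean), 0, tolerance = 1e-6)
  expect_equal(unname(rs$outputs$fanofactor$mean), 0, tolerance = 0.02)
  expect_equal(length(rs$outputs$corrcoef$mean), 16) # 4 x 4 flattened
})

test_that("spike trains round-trip through the plain-text format", {
  trains <- list(c(0.5, 2, 3.75), numeric(0), c(10))
  path <- withr::local_tempfile(fileext = ".txt")
  write_spike_trains(trains, path)
  back <- read_spike_trains(path)
  expect_equal(back, trains)
})
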