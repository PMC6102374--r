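#' Locate action potentials in a voltage trace
#'
#' A spike is one contiguous excursion of the membrane potential above the
#' detection threshold. For each excursion the peak sample is found and a
#' window of configurable extent around the peak is cut out, so downstream
#' shape features (width, afterhyperpolarisation) have the full waveform to
#' work with. Windows are clipped at the trace ends and spikes are returned
#' in order of their peak times.
#'
#' @param time,V Equal-length numeric vectors; `time` must be strictly
#'   increasing.
#' @param threshold Detection threshold in the units of `V`. The default
#'   -30 mV suits traces with a physiological resting potential near
#'   -65 mV; models stated in the historical 0 mV-resting convention
#'   should pass a positive threshold instead.
#' @param extent_before,extent_after Window extent around the peak, in the
#'   units of `time`.
#' @return A `uq_spikes` object: list of spikes (each with `time`, `V`,
#'   `peak_time`, `peak_V`, `onset_time`, `onset_V`) plus the trace span.
#' @export
find_spikes <- function(time, V, threshold = -30,
                        extent_before = 5, extent_after = 5) {
  stopifnot(length(time) == length(V))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  above <- V > threshold
  if (!any(above)) {
    return(structure(list(spikes = list(), span = range(time)),
                     class = "uq_spikes"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  spikes <- lapply(runs, function(k) {
    i0 <- starts[k]
    i1 <- ends[k]
    seg <- i0:i1
    pk <- seg[which.max(V[seg])]
    w0 <- max(1, which(time >= time[pk] - extent_before)[1])
    w1 <- max(which(time <= time[pk] + extent_after))
    win <- w0:w1
    list(time = time[win], V = V[win],
         peak_time = time[pk], peak_V = V[pk],
         onset_time = time[i0], onset_V = V[i0])
  })
  spikes <- spikes[order(vapply(spikes, `[[`, numeric(1), "peak_time"))]
  structure(list(spikes = spikes, span = range(time)), class = "uq_spikes")
}

#' @export
print.uq_spikes <- function(x, ...) {
  cat("<uq_spikes> ", length(x$spikes), " spike(s) on [",
      x$span[1], ", ", x$span[2], "]\n", sep = "")
  invisible(x)
}

#' @export
length.uq_spikes <- function(x) length(x$spikes)

spike_peak_times <- function(spikes) {
  vapply(spikes$spikes, `[[`, numeric(1), "peak_time")
}

#' Features of a spiking single-neuron response
#'
#' Computes the classical stimulus-response features of a detected spike
#' set: spike count and rate over the stimulus period, latency to the
#' first spike, accommodation of the interspike intervals, and the
#' average peak height, afterhyperpolarisation depth and half-height
#' width of the action potentials. Features that are undefined for the
#' observed spike count (for example the afterhyperpolarisation depth with
#' fewer than two spikes) are returned as `NA`, which the uncertainty
#' pipeline treats as an invalid evaluation to be discarded.
#'
#' The accommodation index averages
#' `(ISI_i - ISI_(i-1)) / (ISI_i + ISI_(i-1))` over consecutive interval
#' pairs, after discarding the first `k` intervals; `k` defaults to 1 when
#' five or more intervals are available and 0 otherwise. The spike width
#' is measured at the voltage midway between a spike's onset and peak,
#' with linear interpolation across the crossing samples.
#'
#' @param spikes A `uq_spikes` from [find_spikes()].
#' @param info Named list with `stimulus_start` and `stimulus_end`
#'   (same time units as the trace).
#' @param accommodation_k Number of initial interspike intervals to
#'   discard; `NULL` for the adaptive default.
#' @return Named list of scalar features: `nr_spikes`, `spike_rate`,
#'   `time_before_first_spike`, `accommodation_index`,
#'   `average_AP_overshoot`, `average_AHP_depth`, `average_AP_width`.
#' @export
spiking_features <- function(spikes, info, accommodation_k = NULL) {
  for (key in c("stimulus_start", "stimulus_end")) {
    if (is.null(info[[key]])) {
      stop("spiking features need info$", key, call. = FALSE)
    }
  }
  t_on <- info$stimulus_start
  t_off <- info$stimulus_end
  peaks <- spike_peak_times(spikes)
  in_stim <- peaks >= t_on & peaks <= t_off
  nr <- sum(in_stim)
  duration <- t_off - t_on
  first <- if (any(in_stim)) min(peaks[in_stim]) else NA_real_
  isi <- diff(peaks)
  acc <- NA_real_
  if (length(isi) >= 2) {
    k <- accommodation_k %||% (if (length(isi) < 5) 0L else 1L)
    isi_k <- if (k > 0) isi[-seq_len(min(k, length(isi) - 2))] else isi
    if (length(isi_k) >= 2) {
      ratio <- diff(isi_k) / (isi_k[-1] + isi_k[-length(isi_k)])
      acc <- mean(ratio)
    }
  }
  n_sp <- length(spikes$spikes)
  overshoot <- if (n_sp >= 1) {
    mean(vapply(spikes$spikes, `[[`, numeric(1), "peak_V"))
  } else NA_real_
  ahp <- NA_real_
  if (n_sp >= 2) {
    depths <- vapply(seq_len(n_sp - 1), function(i) {
      a <- spikes$spikes[[i]]$peak_time
      b <- spikes$spikes[[i + 1]]$peak_time
      # global minimum between consecutive peaks, read from the windows
      seg <- unlist(lapply(spikes$spikes[c(i, i + 1)], function(s) {
        s$V[s$time >= a & s$time <= b]
      }))
      if (length(seg)) min(seg) else NA_real_
    }, numeric(1))
    ahp <- mean(depths, na.rm = FALSE)
  }
  width <- if (n_sp >= 1) {
    mean(vapply(spikes$spikes, spike_halfwidth, numeric(1)))
  } else NA_real_
  list(
    nr_spikes = as.numeric(nr),
    spike_rate = nr / duration,
    time_before_first_spike = first - t_on,
    accommodation_index = acc,
    average_AP_overshoot = overshoot,
    average_AHP_depth = ahp,
    average_AP_width = width
  )
}

# Width of one spike at the level midway between onset and peak voltage.
spike_halfwidth <- function(spike) {
  level <- (spike$onset_V + spike$peak_V) / 2
  t <- spike$time
  v <- spike$V
  pk <- which.max(v)
  up <- crossing_time(t, v, level, seq_len(pk), rising = TRUE)
  down <- crossing_time(t, v, level, pk:length(v), rising = FALSE)
  if (is.na(up) || is.na(down)) return(NA_real_)
  down - up
}

crossing_time <- function(t, v, level, idx, rising) {
  tt <- t[idx]
  vv <- v[idx]
  cross <- if (rising) {
    which(vv[-length(vv)] < level & vv[-1] >= level)
  } else {
    which(vv[-length(vv)] >= level & vv[-1] < level)
  }
  if (!length(cross)) return(NA_real_)
  i <- if (rising) cross[length(cross)] else cross[1]
  frac <- (level - vv[i]) / (vv[i + 1] - vv[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Convert spike trains to regular binary sequences
#'
#' Maps each spike train onto the regular grid `0, dt, ..., end`: a bin is
#' 1 when at least one spike falls in it and 0 otherwise. A spike at time
#' `s` lands in bin `round(s / dt)`, with ties at bin edges rounded up, so
#' for example the train `[0, 2, 3.5]` at a 0.5 ms resolution over 4 ms
#' becomes `[1, 0, 0, 0, 1, 0, 0, 1, 0]`.
#'
#' @param trains List of numeric vectors of spike times (ms), one per
#'   recorded unit, or a single numeric vector.
#' @param dt Grid resolution (ms), positive.
#' @param end Simulation end time (ms); no spike may exceed it.
#' @return List with the grid `time` and the 0/1 `values` matrix (one row
#'   per unit).
#' @export
binary_spike_postprocess <- function(trains, dt, end) {
  stopifnot(dt > 0, end > 0)
  if (is.numeric(trains)) trains <- list(trains)
  grid <- seq(0, end, by = dt)
  nb <- length(grid)
  values <- matrix(0, length(trains), nb)
  for (u in seq_along(trains)) {
    s <- trains[[u]]
    if (length(s) == 0) next
    if (any(s > end + 1e-12) || any(s < 0)) {
      stop("spike time outside [0, end] in train ", u, call. = FALSE)
    }
    bins <- floor(s / dt + 0.5) + 1 # round half up
    bins[bins > nb] <- nb
    values[u, unique(bins)] <- 1
  }
  list(time = grid, values = values)
}

#' Features of a set of network spike trains
#'
#' Summarises the activity of recorded units in a spiking network:
#' per-unit firing rates and interspike-interval statistics, their
#' averages over units, count variability across units (Fano factor),
#' pairwise spike-train distances and the correlation/covariance of the
#' binned trains. Per-unit features are returned as vectors over units and
#' pairwise features as symmetric matrices; features requiring more
#' interspike intervals than a train provides are `NA` for that unit.
#'
#' Definitions: `cv` is the standard deviation over mean of a unit's
#' intervals; `local_variation` is
#' `3 / (n - 1) * sum(((I_i - I_(i+1)) / (I_i + I_(i+1)))^2)` over a
#' unit's `n` intervals; `fanofactor` is the variance over the mean of the
#' per-unit spike counts; `average_isi` averages the per-unit mean
#' interval over units. The Victor-Purpura distance uses a spike-moving
#' cost `q` per unit time (default `1 / 5` per ms) and the van Rossum
#' distance an exponential kernel with time constant `tau` (default
#' 10 ms). The instantaneous rate is the population rate in a sliding
#' window (default 10 ms) on the binned grid, in spikes per second per
#' unit.
#'
#' @param trains List of spike-time vectors (ms), one per recorded unit.
#' @param end Simulation end time (ms).
#' @param bin_dt Bin width (ms) for the binned correlation, covariance and
#'   interval histogram; defaults to 1 ms.
#' @param vp_q Victor-Purpura shift cost (1/ms).
#' @param vr_tau Van Rossum kernel time constant (ms).
#' @param rate_window Instantaneous-rate window (ms).
#' @param isi_bins Number of histogram bins for `binned_isi`.
#' @return Named list of the thirteen features.
#' @export
network_features <- function(trains, end, bin_dt = 1, vp_q = 1 / 5,
                             vr_tau = 10, rate_window = 10, isi_bins = 10) {
  stopifnot(length(trains) >= 1)
  n_units <- length(trains)
  counts <- vapply(trains, length, integer(1))
  isis <- lapply(trains, function(s) if (length(s) >= 2) diff(sort(s)) else numeric(0))

  firing_rate <- counts / end * 1000 # spikes/s
  mean_isi <- vapply(isis, function(i) if (length(i)) mean(i) else NA_real_,
                     numeric(1))
  cv <- vapply(isis, function(i) {
    if (length(i) >= 2) stats::sd(i) / mean(i) else NA_real_
  }, numeric(1))
  lv <- vapply(isis, function(i) {
    n <- length(i)
    if (n >= 2) {
      3 / (n - 1) * sum(((i[-n] - i[-1]) / (i[-n] + i[-1]))^2)
    } else NA_real_
  }, numeric(1))

  binned <- binary_spike_postprocess(trains, dt = bin_dt, end = end)
  bmat <- binned$values
  if (n_units >= 2) {
    cc <- suppressWarnings(stats::cor(t(bmat)))
    cv_mat <- stats::cov(t(bmat))
    vp <- matrix(0, n_units, n_units)
    vr <- matrix(0, n_units, n_units)
    for (a in seq_len(n_units - 1)) {
      for (b in (a + 1):n_units) {
        vp[a, b] <- vp[b, a] <- victor_purpura_dist(trains[[a]], trains[[b]], vp_q)
        vr[a, b] <- vr[b, a] <- van_rossum_dist(trains[[a]], trains[[b]], vr_tau)
      }
    }
  } else {
    cc <- matrix(1, 1, 1)
    cv_mat <- matrix(stats::var(bmat[1, ]), 1, 1)
    vp <- vr <- matrix(0, 1, 1)
  }

  all_isi <- unlist(isis)
  hist_breaks <- seq(0, max(c(all_isi, bin_dt)), length.out = isi_bins + 1)
  binned_isi <- if (length(all_isi)) {
    graphics::hist(all_isi, breaks = hist_breaks, plot = FALSE)$counts
  } else {
    rep(0, isi_bins)
  }

  # population rate in a centred sliding window on the binned grid; the
  # window is clipped at the trace ends so no edge bins are lost
  w_half <- max(1L, round(rate_window / bin_dt)) %/% 2L
  pop <- colSums(matrix(bmat, nrow = n_units))
  cs <- cumsum(c(0, pop))
  nb <- length(pop)
  lo <- pmax(seq_len(nb) - w_half, 1L)
  hi <- pmin(seq_len(nb) + w_half, nb)
  inst <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1) / n_units / bin_dt * 1000

  list(
    average_firing_rate = firing_rate,
    instantaneous_rate = list(time = binned$time, values = inst),
    average_isi = mean(mean_isi, na.rm = TRUE),
    cv = cv,
    average_cv = mean(cv, na.rm = TRUE),
    local_variation = lv,
    average_local_variation = mean(lv, na.rm = TRUE),
    fanofactor = stats::var(counts) / mean(counts),
    victor_purpura_dist = vp,
    van_rossum_dist = vr,
    binned_isi = binned_isi,
    corrcoef = cc,
    covariance = cv_mat
  )
}

#' Spike-train dissimilarity metrics
#'
#' `victor_purpura_dist()` is the minimal cost of editing one train into
#' the other, where inserting or deleting a spike costs 1 and moving a
#' spike by `dt` costs `q * |dt|` (computed by dynamic programming).
#' `van_rossum_dist()` convolves each train with a one-sided exponential
#' kernel of time constant `tau` and returns the L2 distance of the
#' filtered traces, evaluated in closed form.
#'
#' @param a,b Numeric vectors of spike times.
#' @param q Cost per unit time of moving a spike (1/ms).
#' @export
victor_purpura_dist <- function(a, b, q = 1 / 5) {
  a <- sort(a)
  b <- sort(b)
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) return(na + nb)
  G <- matrix(0, na + 1, nb + 1)
  G[, 1] <- 0:na
  G[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      G[i + 1, j + 1] <- min(G[i, j + 1] + 1,
                             G[i + 1, j] + 1,
                             G[i, j] + q * abs(a[i] - b[j]))
    }
  }
  G[na + 1, nb + 1]
}

#' @rdname victor_purpura_dist
#' @param tau Exponential kernel time constant (ms).
#' @export
van_rossum_dist <- function(a, b, tau = 10) {
  cross_sum <- function(x, y) {
    if (!length(x) || !length(y)) return(0)
    sum(exp(-abs(outer(x, y, "-")) / tau))
  }
  d2 <- (cross_sum(a, a) + cross_sum(b, b) - 2 * cross_sum(a, b)) / 2
  sqrt(max(d2, 0))
}

#' Built-in feature sets
#'
#' `spiking_feature_set()` bundles the seven single-neuron features of
#' [spiking_features()] behind a shared preprocessing step that locates the
#' spikes once per evaluation; the model's `info` must carry
#' `stimulus_start` and `stimulus_end`. `network_feature_set()` bundles the
#' scalar network features (matrix-valued ones are flattened) for models
#' whose `values` is a list of spike trains and whose `info` carries
#' `simulation_end`. Either object, or the strings `"spiking"` /
#' `"network"`, can be passed to [quantify()]'s `features` argument.
#'
#' @param threshold,extent_before,extent_after Passed to [find_spikes()].
#' @param features Subset of feature names to keep (default all).
#' @return A `uq_feature_set`.
#' @export
spiking_feature_set <- function(threshold = -30, extent_before = 5,
                                extent_after = 5, features = NULL) {
  nms <- c("nr_spikes", "spike_rate", "time_before_first_spike",
           "accommodation_index", "average_AP_overshoot",
           "average_AHP_depth", "average_AP_width")
  if (!is.null(features)) nms <- intersect(nms, features)
  fs <- lapply(nms, function(nm) {
    force(nm)
    function(spikes, info) spiking_features(spikes, info)[[nm]]
  })
  structure(
    list(
      preprocess = function(time, values, info) {
        list(find_spikes(time, values, threshold = threshold,
                         extent_before = extent_before,
                         extent_after = extent_after),
             info)
      },
      features = stats::setNames(fs, nms)
    ),
    class = "uq_feature_set"
  )
}

#' @rdname spiking_feature_set
#' @param bin_dt,vp_q,vr_tau,rate_window,isi_bins Passed to
#'   [network_features()].
#' @export
network_feature_set <- function(bin_dt = 1, vp_q = 1 / 5, vr_tau = 10,
                                rate_window = 10, isi_bins = 10,
                                features = NULL) {
  nms <- c("average_firing_rate", "instantaneous_rate", "average_isi", "cv",
           "average_cv", "local_variation", "average_local_variation",
           "fanofactor", "victor_purpura_dist", "van_rossum_dist",
           "binned_isi", "corrcoef", "covariance")
  if (!is.null(features)) nms <- intersect(nms, features)
  fs <- lapply(nms, function(nm) {
    force(nm)
    function(nf, info) {
      v <- nf[[nm]]
      if (is.matrix(v)) as.numeric(v) else v
    }
  })
  structure(
    list(
      preprocess = function(time, values, info) {
        if (is.null(info$simulation_end)) {
          stop("network features need info$simulation_end", call. = FALSE)
        }
        list(network_features(values, end = info$simulation_end,
                              bin_dt = bin_dt, vp_q = vp_q, vr_tau = vr_tau,
                              rate_window = rate_window,
                              isi_bins = isi_bins),
             info)
      },
      features = stats::setNames(fs, nms)
    ),
    class = "uq_feature_set"
  )
}

resolve_features <- function(features) {
  if (is.null(features)) return(NULL)
  if (inherits(features, "uq_feature_set")) return(features)
  if (is.character(features) && length(features) == 1) {
    return(switch(features,
                  spiking = spiking_feature_set(),
                  network = network_feature_set(),
                  none = NULL,
                  stop("unknown feature set `", features, "`", call. = FALSE)))
  }
  if (is.list(features) && all(vapply(features, is.function, logical(1)))) {
    if (is.null(names(features)) || any(names(features) == "")) {
      stop("feature functions must be named", call. = FALSE)
    }
    return(structure(list(preprocess = NULL, features = features),
                     class = "uq_feature_set"))
  }
  stop("`features` must be NULL, a named list of functions, a ",
       "uq_feature_set, or one of \"spiking\"/\"network\"", call. = FALSE)
}

#' Read and write spike trains as plain text
#'
#' One recorded unit per line, spike times in milliseconds separated by
#' whitespace; empty lines denote silent units.
#'
#' @param trains List of numeric spike-time vectors.
#' @param path File path.
#' @export
write_spike_trains <- function(trains, path) {
  lines <- vapply(trains, function(s) paste(format(s, trim = TRUE), collapse = " "),
                  character(1))
  writeLines(lines, path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    if (!nzchar(trimws(l))) numeric(0) else as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
}
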