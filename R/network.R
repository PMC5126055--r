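#' Basal ganglia network configuration
#'
#' Collects every tunable constant of the spiking circuit: lattice shape,
#' per-nucleus Izhikevich parameters, synaptic gains and time constants for
#' each projection (signs are fixed by anatomy and hard-wired in the
#' integrator: GPe->STN and striatal MSN projections are GABAergic
#' inhibitory, STN projections glutamatergic excitatory), the
#' dopamine scaling of lateral connectivity within STN and GPe, the striatal
#' rate map, and the thalamic race model.  There is no cortex->STN
#' hyper-direct projection and no GPe->GPi projection in this circuit.
#'
#' Dopamine modulates the lateral coupling as
#' `g_lat_eff = g_lat * max(0, 1 - da_coupling * DA)`, so low dopamine
#' (parkinsonian state) strengthens lateral coupling within STN and GPe and
#' promotes synchronous bursting.
#'
#' All defaults are package calibration constants (chosen so that the
#' healthy network is asynchronous and tonic while the low-dopamine network
#' shows ~4 Hz synchronous bursting); they can be overridden individually or
#' loaded from a YAML file via [read_bg_config()].
#'
#' @param rows,cols lattice shape of every nucleus (default 50 x 50).
#' @param dt integration step (ms), explicit Euler.
#' @param trial_ms maximum simulated time of one IGT trial (ms).
#' @param stn,gpe,gpi [izh_params()] per nucleus.  The in-network STN bias
#'   (34 pA) exceeds the isolated-neuron default of [nucleus_params()]: it
#'   stands in for background excitatory drive (cortical/brainstem) omitted
#'   from the reduced circuit, and balances the tonic component of
#'   pallido-subthalamic inhibition so healthy STN stays tonically active.
#' @param tau_exc,tau_inh excitatory and pallidal inhibitory synaptic time
#'   constants (ms); the slow pallidal inhibition (GABA-B-like) sets the
#'   period of the parkinsonian burst rhythm.
#' @param tau_str striatal MSN (GABAergic) synaptic time constant (ms).
#' @param g_gpe_stn,g_stn_gpe,g_d2_gpe,g_d1_gpi,g_stn_gpi projection gain
#'   magnitudes (pA per unit synaptic activation).
#' @param g_lat_stn,g_lat_gpe lateral (4-neighbour) coupling gains within
#'   STN (excitatory) and GPe (inhibitory) before dopamine scaling.
#' @param da_coupling coefficient `k` of the dopamine scaling of lateral
#'   and pallido-subthalamic coupling.
#' @param gpe_stn_floor dopamine-independent fraction of the GPe->STN
#'   efficacy: the projection scales as
#'   `g_gpe_stn * (floor + (1 - floor) * max(0, 1 - k DA))`, so healthy
#'   dopamine weakens but does not abolish pallido-subthalamic inhibition.
#' @param da_healthy,da_pd tonic dopamine level in healthy and parkinsonian
#'   conditions (dimensionless, 0-1).
#' @param rate_min,rate_max striatal firing-rate bounds (Hz); cortico-striatal
#'   weights map affinely onto `[rate_min, rate_max]` over
#'   `[w_floor, w_max]`, clipped to the physiological band.
#' @param w_max cortico-striatal weight clip (upper anchor of the rate map).
#' @param w_floor lower anchor of the rate map: weights at or below this
#'   value all drive the striatum at `rate_min`, so decks whose values have
#'   collapsed become indistinguishable at the 2 Hz floor.
#' @param outcome_scale factor converting deck points to the learning scale
#'   used in the TD step (default 0.01: 100 points = 1).
#' @param race_drive,race_gain,race_leak,race_noise,race_threshold,tau_rate
#'   thalamic race model: each deck's leaky accumulator integrates
#'   `drive - race_gain * GPi_quadrant_rate` with Gaussian noise and wins at
#'   `race_threshold`; `tau_rate` (ms) smooths the GPi rate estimate.
#' @param race_onset settle time (ms) before the accumulators start, so the
#'   decision reads steady-state pallidal output rather than the startup
#'   transient.
#' @return an object of class `bg_config`.
#' @export
bg_network_config <- function(rows = 50, cols = 50, dt = 0.1, trial_ms = 300,
                              stn = izh_params(0.005, 0.265, -65, 2,
                                               bias = 34),
                              gpe = nucleus_params("GPe"),
                              gpi = nucleus_params("GPi"),
                              tau_exc = 5, tau_inh = 140, tau_str = 10,
                              g_gpe_stn = 88, g_stn_gpe = 40,
                              g_d2_gpe = 2, g_d1_gpi = 30, g_stn_gpi = 10,
                              g_lat_stn = 15.75, g_lat_gpe = 7.875,
                              da_coupling = 1, gpe_stn_floor = 0.1,
                              da_healthy = 1, da_pd = 0.1,
                              rate_min = 2, rate_max = 40, w_max = 2,
                              w_floor = 0.1,
                              outcome_scale = 0.01,
                              race_drive = 0.0475, race_gain = 5e-4,
                              race_leak = 0.01, race_noise = 0.05,
                              race_threshold = 1, tau_rate = 2,
                              race_onset = 150) {
  stopifnot(rows >= 2, cols >= 2, dt > 0, trial_ms > 0,
            inherits(stn, "izh_params"), inherits(gpe, "izh_params"),
            inherits(gpi, "izh_params"),
            tau_exc > 0, tau_inh > 0, tau_str > 0, rate_min >= 0, rate_max > rate_min,
            w_max > 0, race_threshold > 0, tau_rate > 0, race_onset >= 0)
  gains <- c(g_gpe_stn = g_gpe_stn, g_stn_gpe = g_stn_gpe,
             g_d2_gpe = g_d2_gpe, g_d1_gpi = g_d1_gpi,
             g_stn_gpi = g_stn_gpi, g_lat_stn = g_lat_stn,
             g_lat_gpe = g_lat_gpe)
  if (any(gains < 0)) stop("gains are magnitudes; signs are fixed by anatomy")
  structure(list(rows = rows, cols = cols, dt = dt, trial_ms = trial_ms,
                 stn = stn, gpe = gpe, gpi = gpi,
                 tau_exc = tau_exc, tau_inh = tau_inh, tau_str = tau_str,
                 g_gpe_stn = g_gpe_stn, g_stn_gpe = g_stn_gpe,
                 g_d2_gpe = g_d2_gpe, g_d1_gpi = g_d1_gpi,
                 g_stn_gpi = g_stn_gpi,
                 g_lat_stn = g_lat_stn, g_lat_gpe = g_lat_gpe,
                 da_coupling = da_coupling, gpe_stn_floor = gpe_stn_floor,
                 da_healthy = da_healthy,
                 da_pd = da_pd,
                 rate_min = rate_min, rate_max = rate_max, w_max = w_max,
                 w_floor = w_floor,
                 outcome_scale = outcome_scale,
                 race_drive = race_drive, race_gain = race_gain,
                 race_leak = race_leak, race_noise = race_noise,
                 race_threshold = race_threshold, tau_rate = tau_rate,
                 race_onset = race_onset),
            class = "bg_config")
}

#' Tonic dopamine level of a condition
#'
#' Healthy control has full dopamine; all parkinsonian conditions share the
#' depleted level (medication is modelled at the cortico-striatal learning
#' stage, not as restored tonic dopamine).
#'
#' @param condition condition label (see [dopamine_params()]).
#' @param config a [bg_network_config()].
#' @return scalar dopamine level.
#' @export
dopamine_level <- function(condition, config = bg_network_config()) {
  if (condition == "HC") config$da_healthy else config$da_pd
}

#' Deck quadrant map of the lattice
#'
#' Partitions a `rows x cols` lattice into the four rectangular quadrants
#' carrying the signals of decks A-D, applied uniformly to every nucleus:
#' deck A occupies the low-row/low-column quadrant (containing lattice point
#' (13, 13) at default size) and deck D the high-row/high-column quadrant
#' (containing (38, 38)); B and C take the remaining two.
#'
#' @param rows,cols lattice shape.
#' @return a `rows x cols` character matrix of deck labels; the quadrants
#'   are disjoint and cover the lattice.
#' @export
quadrant_map <- function(rows = 50, cols = 50) {
  hi <- floor(rows / 2)
  hj <- floor(cols / 2)
  i <- matrix(seq_len(rows), rows, cols)
  j <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  m <- matrix("D", rows, cols)
  m[i <= hi & j <= hj] <- "A"
  m[i <= hi & j > hj] <- "B"
  m[i > hi & j <= hj] <- "C"
  m
}

# 0-based quadrant index vector (column-major) for the C++ engine
quadrant_index <- function(rows, cols) {
  match(as.vector(quadrant_map(rows, cols)), c("A", "B", "C", "D")) - 1L
}

#' Striatal Poisson rates from cortico-striatal weights
#'
#' Maps each deck's `w_D1` and `w_D2` affinely onto firing rates for the D1
#' (drive to GPi) and D2 (drive to GPe) striatal populations of the
#' corresponding quadrant: an affine map anchored at
#' `(w_floor, rate_min)` and `(w_max, rate_max)`, clipped to the
#' physiological band `[rate_min, rate_max]` (2-40 Hz by default).
#'
#' @param weights a `cs_weights` object.
#' @param config a [bg_network_config()].
#' @return list with numeric 4-vectors `d1` and `d2` (Hz, named by deck).
#' @export
striatal_rates <- function(weights, config = bg_network_config()) {
  stopifnot(inherits(weights, "cs_weights"))
  if (any(!is.finite(weights$d1)) || any(!is.finite(weights$d2)))
    stop("weights must be finite")
  aff <- function(w) {
    r <- config$rate_min + (config$rate_max - config$rate_min) *
      (w - config$w_floor) / (config$w_max - config$w_floor)
    pmin(pmax(r, config$rate_min), config$rate_max)
  }
  list(d1 = aff(weights$d1), d2 = aff(weights$d2))
}

#' Generate Poisson spike trains
#'
#' Spikes are Bernoulli(`rate * dt`) per time bin per neuron (drawn as a
#' binomial count per neuron placed uniformly over bins, which has the same
#' joint law).  Seeded through the R session RNG.
#'
#' @param rate firing rate (Hz); scalar applied to all neurons or one per
#'   neuron.
#' @param duration_ms train duration (ms).
#' @param dt bin width (ms); `rate * dt` must stay below 1.
#' @param n_neurons number of independent trains.
#' @param seed optional integer; if given, [set.seed()] is called first.
#' @return data frame with columns `neuron` and `time_ms` (bin start times).
#' @export
generate_poisson_spikes <- function(rate, duration_ms, dt = 0.1,
                                    n_neurons = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- rep_len(rate, n_neurons)
  p <- rate * dt / 1000
  if (any(p >= 1)) stop("rate * dt >= 1: dt too coarse for this rate")
  steps <- floor(duration_ms / dt)
  counts <- rbinom(n_neurons, steps, p)
  neuron <- rep(seq_len(n_neurons), counts)
  bins <- unlist(lapply(seq_len(n_neurons), function(i) {
    if (counts[i] == 0) integer(0) else sort(sample.int(steps, counts[i]))
  }))
  data.frame(neuron = neuron, time_ms = (bins - 1) * dt)
}

#' Race-model selection from accumulator traces
#'
#' The first accumulator to cross the threshold wins; if several cross on
#' the same step the winner is drawn uniformly from the tied set; if none
#' crosses, the accumulator with the largest final value wins and the
#' decision is flagged as a timeout.
#'
#' @param traces numeric matrix, time steps x accumulators.
#' @param threshold decision threshold.
#' @return list with `index` (winning accumulator), `step` (crossing step
#'   or `NA`), and `timeout` flag.
#' @export
race_select <- function(traces, threshold = 1) {
  traces <- as.matrix(traces)
  if (ncol(traces) < 1) stop("need at least one accumulator")
  crossed <- traces >= threshold
  any_cross <- which(rowSums(crossed) > 0)
  if (length(any_cross) == 0) {
    final <- traces[nrow(traces), ]
    win <- which(final == max(final))
    if (length(win) > 1) win <- sample(win, 1)
    return(list(index = win, step = NA_integer_, timeout = TRUE))
  }
  step <- any_cross[1]
  tied <- which(crossed[step, ])
  win <- if (length(tied) > 1) sample(tied, 1) else tied
  list(index = win, step = step, timeout = FALSE)
}

# Assemble the argument list for the C++ engine.
engine_cfg <- function(config, rates, electrode, condition, seed,
                       n_steps, race, record = character(0),
                       record_acc = FALSE, stn_v0 = NULL, stn_u0 = NULL) {
  da <- dopamine_level(condition, config)
  lat_scale <- max(0, 1 - config$da_coupling * da)
  gs_scale <- config$gpe_stn_floor + (1 - config$gpe_stn_floor) * lat_scale
  prof <- if (is.null(electrode)) {
    matrix(0, config$rows, config$cols)
  } else {
    dbs_profile(electrode, config$rows, config$cols)
  }
  par_vec <- function(p) c(a = p$a, b = p$b, c = p$c, d = p$d,
                           v_peak = p$v_peak, bias = p$bias)
  list(rows = config$rows, cols = config$cols, dt = config$dt,
       n_steps = as.integer(n_steps), seed = as.double(seed),
       stn_params = par_vec(config$stn), gpe_params = par_vec(config$gpe),
       gpi_params = par_vec(config$gpi),
       g_gpe_stn = config$g_gpe_stn * gs_scale,
       g_stn_gpe = config$g_stn_gpe,
       g_d2_gpe = config$g_d2_gpe, g_d1_gpi = config$g_d1_gpi,
       g_stn_gpi = config$g_stn_gpi,
       g_lat_stn = config$g_lat_stn * lat_scale,
       g_lat_gpe = config$g_lat_gpe * lat_scale,
       tau_exc = config$tau_exc, tau_inh = config$tau_inh,
       tau_str = config$tau_str,
       rate_d1 = unname(rates$d1), rate_d2 = unname(rates$d2),
       quadrant = quadrant_index(config$rows, config$cols),
       dbs_profile = as.vector(prof),
       dbs_period = if (is.null(electrode)) 1 else electrode$period,
       dbs_phase_width = if (is.null(electrode)) 0 else electrode$phase_width,
       race = race,
       race_drive = config$race_drive, race_gain = config$race_gain,
       race_leak = config$race_leak, race_noise = config$race_noise,
       race_threshold = config$race_threshold, tau_rate = config$tau_rate,
       race_onset = config$race_onset,
       record_stn = "STN" %in% record, record_gpe = "GPe" %in% record,
       record_gpi = "GPi" %in% record, record_acc = record_acc,
       stn_v0 = stn_v0, stn_u0 = stn_u0)
}

new_seed <- function() sample.int(.Machine$integer.max, 1)

#' Simulate one IGT trial of network time
#'
#' Runs the full selection loop for up to `trial_ms` of simulated time:
#' cortico-striatal weights set the D1/D2 striatal Poisson rates per deck
#' quadrant, D1 inhibits GPi and D2 inhibits GPe, the STN-GPe loop evolves
#' (with DBS current injected into STN when an electrode is given), and the
#' per-quadrant GPi rate inhibits the corresponding thalamic accumulator.
#' The first accumulator to reach threshold selects its deck; if none
#' crosses within the trial the largest accumulator wins (timeout).
#'
#' @param config a [bg_network_config()].
#' @param weights a `cs_weights` object (see [init_weights()]).
#' @param electrode an [electrode_config()] or `NULL` for stimulation off.
#' @param condition condition label, sets the tonic dopamine level (see
#'   [dopamine_level()]).
#' @param seed integer seed for the trial's stochastic dynamics; defaults to
#'   a draw from the session RNG.
#' @param record character vector of nuclei whose spike rasters to keep
#'   (e.g. `c("STN", "GPi")`); empty by default for speed.
#' @return list with `deck` (label), `decision_time` (ms), `timeout`,
#'   `accumulators`, `gpi_quadrant_rates` and `stn_quadrant_rates` (Hz,
#'   named by deck), plus recorded rasters under `spikes`.
#' @export
simulate_trial <- function(config, weights, electrode = NULL,
                           condition = "HC", seed = new_seed(),
                           record = character(0)) {
  stopifnot(inherits(config, "bg_config"), inherits(weights, "cs_weights"))
  rates <- striatal_rates(weights, config)
  n_steps <- ceiling(config$trial_ms / config$dt)
  cfg <- engine_cfg(config, rates, electrode, condition, seed, n_steps,
                    race = TRUE, record = record)
  res <- .bg_engine(cfg)
  decks <- c("A", "B", "C", "D")
  spikes <- list()
  if ("STN" %in% record) spikes$STN <- res$stn_spikes
  if ("GPe" %in% record) spikes$GPe <- res$gpe_spikes
  if ("GPi" %in% record) spikes$GPi <- res$gpi_spikes
  list(deck = decks[res$selected],
       decision_time = res$decision_time,
       timeout = res$timeout,
       accumulators = stats::setNames(res$acc, decks),
       gpi_quadrant_rates = stats::setNames(res$gpi_quadrant_rates, decks),
       stn_quadrant_rates = stats::setNames(res$stn_quadrant_rates, decks),
       spikes = spikes)
}

#' Open-loop network simulation for population activity
#'
#' Runs the circuit for a fixed duration without the decision race, to
#' study population dynamics (bursting, synchrony, spectra) under a given
#' condition and stimulation setting.  Striatal drive comes from the given
#' weights (default: all weights 0.5, symmetric across decks).
#'
#' @param config a [bg_network_config()].
#' @param duration_ms simulated time (ms).
#' @param condition condition label (sets tonic dopamine).
#' @param electrode an [electrode_config()] or `NULL`.
#' @param weights optional `cs_weights`; default symmetric.
#' @param seed integer seed.
#' @param record nuclei to record (default `"STN"`).
#' @return object of class `bg_sim`: list with `spikes` (per nucleus data
#'   frames with `neuron`, `time_ms`), `duration_ms`, `dt`, `n_neurons`,
#'   `rows`, `cols`, `condition`, `electrode`, `spike_counts`,
#'   `gpi_quadrant_rates`, `stn_quadrant_rates`.
#' @export
simulate_network <- function(config = bg_network_config(), duration_ms = 2000,
                             condition = "PD_OFF", electrode = NULL,
                             weights = NULL, seed = new_seed(),
                             record = "STN") {
  stopifnot(inherits(config, "bg_config"), duration_ms > 0)
  if (is.null(weights)) {
    decks <- c("A", "B", "C", "D")
    weights <- structure(list(d1 = stats::setNames(rep(0.5, 4), decks),
                              d2 = stats::setNames(rep(0.5, 4), decks)),
                         class = "cs_weights")
  }
  rates <- striatal_rates(weights, config)
  n_steps <- ceiling(duration_ms / config$dt)
  cfg <- engine_cfg(config, rates, electrode, condition, seed, n_steps,
                    race = FALSE, record = record)
  res <- .bg_engine(cfg)
  decks <- c("A", "B", "C", "D")
  spikes <- list()
  if ("STN" %in% record) spikes$STN <- res$stn_spikes
  if ("GPe" %in% record) spikes$GPe <- res$gpe_spikes
  if ("GPi" %in% record) spikes$GPi <- res$gpi_spikes
  structure(list(spikes = spikes, duration_ms = n_steps * config$dt,
                 dt = config$dt, n_neurons = config$rows * config$cols,
                 rows = config$rows, cols = config$cols,
                 condition = condition, electrode = electrode,
                 spike_counts = res$spike_counts,
                 gpi_quadrant_rates = stats::setNames(res$gpi_quadrant_rates, decks),
                 stn_quadrant_rates = stats::setNames(res$stn_quadrant_rates, decks)),
            class = "bg_sim")
}
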