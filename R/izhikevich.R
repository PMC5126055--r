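#' Izhikevich neuron parameters
#'
#' Parameter set for the two-variable Izhikevich model
#' \deqn{dv/dt = 0.04 v^2 + 5 v + 140 - u + I}
#' \deqn{du/dt = a (b v - u)}
#' with the reset rule: when \eqn{v \ge v_{peak}} the neuron spikes,
#' \eqn{v \leftarrow c} and \eqn{u \leftarrow u + d}.
#'
#' @param a recovery timescale (1/ms); must be positive.
#' @param b recovery sensitivity (dimensionless).
#' @param c post-spike reset potential (mV); must lie below `v_peak`.
#' @param d post-spike recovery increment; must be positive.
#' @param v_peak spike cutoff (mV), fixed at +30 by the model contract.
#' @param bias tonic bias current (pA) giving the nucleus its intrinsic
#'   firing rate.
#' @return an object of class `izh_params`.
#' @export
izh_params <- function(a, b, c, d, v_peak = 30, bias = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (a <= 0 || d <= 0) stop("'a' and 'd' must be positive")
  if (c >= v_peak) stop("reset potential 'c' must lie below v_peak")
  if (v_peak != 30) stop("v_peak is fixed at +30 mV in this model")
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak, bias = bias),
            class = "izh_params")
}

#' Default Izhikevich parameters per nucleus
#'
#' Calibrated so that in isolation (bias current only) STN neurons fire
#' tonically at roughly 5-15 Hz and show post-inhibitory rebound (slow
#' recovery, high `b`), while GPe and GPi fire tonically at higher pallidal
#' rates.  Values are package calibration constants, recorded in the default
#' configuration.
#'
#' @param nucleus one of `"STN"`, `"GPe"`, `"GPi"`.
#' @return an `izh_params` object.
#' @export
nucleus_params <- function(nucleus = c("STN", "GPe", "GPi")) {
  nucleus <- match.arg(nucleus)
  switch(nucleus,
    STN = izh_params(a = 0.005, b = 0.265, c = -65, d = 2,  bias = 3),
    GPe = izh_params(a = 0.1,   b = 0.2,   c = -65, d = 2,  bias = 4.2),
    GPi = izh_params(a = 0.1,   b = 0.2,   c = -65, d = 2,  bias = 6))
}

#' Create a lattice of Izhikevich neurons
#'
#' Each basal-ganglia nucleus is modelled as a 2D array of neurons
#' (default 50 x 50).  State is held as `rows x cols` matrices of the
#' membrane potential `v` (mV) and recovery variable `u`.
#'
#' @param nucleus nucleus label (`"STN"`, `"GPe"` or `"GPi"`).
#' @param rows,cols lattice dimensions.
#' @param params an [izh_params()] object; defaults to the nucleus default.
#' @param v0,u0 optional initial state (scalar or `rows x cols` matrix);
#'   default is the reset potential `c` with `u = b * v`.
#' @return an object of class `neuron_grid`.
#' @export
neuron_grid <- function(nucleus = c("STN", "GPe", "GPi"), rows = 50, cols = 50,
                        params = nucleus_params(nucleus), v0 = NULL, u0 = NULL) {
  nucleus <- match.arg(nucleus)
  stopifnot(rows >= 1, cols >= 1)
  if (is.null(v0)) v0 <- params$c
  if (is.null(u0)) u0 <- params$b * v0
  v <- matrix(v0, rows, cols)
  u <- matrix(u0, rows, cols)
  structure(list(nucleus = nucleus, rows = rows, cols = cols,
                 v = v, u = u, params = params),
            class = "neuron_grid")
}

#' One forward-Euler step of an Izhikevich lattice
#'
#' Advances every neuron by `dt` using a simultaneous explicit Euler update
#' of `v` and `u`, then applies the spike/reset rule: neurons with
#' \eqn{v \ge v_{peak}} are flagged as spiking, reset to `c`, and their
#' recovery variable incremented by `d`.
#'
#' @param grid a [neuron_grid()].
#' @param I_ext external current map (pA; scalar or `rows x cols` matrix),
#'   e.g. a DBS current.
#' @param I_syn synaptic current map (pA; scalar or matrix).
#' @param dt time step (ms), must be positive.
#' @return a list with elements `grid` (updated state) and `spiked`
#'   (logical `rows x cols` matrix marking exactly the neurons that crossed
#'   `v_peak` on this step).
#' @export
izhikevich_step <- function(grid, I_ext = 0, I_syn = 0, dt = 0.1) {
  stopifnot(inherits(grid, "neuron_grid"), dt > 0)
  p <- grid$params
  I <- expand_map(I_ext, grid) + expand_map(I_syn, grid)
  v <- grid$v
  u <- grid$u
  vn <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
  un <- u + dt * (p$a * (p$b * v - u))
  if (any(!is.finite(un)) || any(is.na(vn))) {
    stop(sprintf(
      "non-finite state in %s lattice after step (dt = %g ms); the explicit Euler scheme is unstable here, reduce dt",
      grid$nucleus, dt))
  }
  r <- izh_reset(vn, un, p)
  if (any(!is.finite(r$v)) || any(!is.finite(r$u))) {
    stop(sprintf(
      "non-finite state in %s lattice after step (dt = %g ms); the explicit Euler scheme is unstable here, reduce dt",
      grid$nucleus, dt))
  }
  grid$v <- r$v
  grid$u <- r$u
  list(grid = grid, spiked = r$spiked)
}

#' Spike/reset rule of the Izhikevich model
#'
#' Applies the threshold rule to a state: wherever \eqn{v \ge v_{peak}},
#' set \eqn{v = c} and \eqn{u = u + d}.  Idempotent because the reset
#' potential lies strictly below `v_peak`.
#'
#' @param v,u state matrices (or vectors).
#' @param params an [izh_params()] object.
#' @return list with `v`, `u` and logical `spiked`.
#' @export
izh_reset <- function(v, u, params) {
  spiked <- v >= params$v_peak
  v[spiked] <- params$c
  u[spiked] <- u[spiked] + params$d
  list(v = v, u = u, spiked = spiked)
}

#' Subthreshold fixed point of the Izhikevich equations
#'
#' Solves \eqn{0.04 v^2 + (5 - b) v + 140 + I = 0} for the stable (more
#' hyperpolarised) root and returns `u = b v`.  Returns `NULL` when no real
#' fixed point exists (the neuron fires tonically at that current).
#'
#' @param params an [izh_params()] object.
#' @param I constant input current (pA).
#' @return list with `v` and `u`, or `NULL`.
#' @export
izh_fixed_point <- function(params, I = 0) {
  b <- params$b
  disc <- (5 - b)^2 - 4 * 0.04 * (140 + I)
  if (disc < 0) return(NULL)
  v <- (-(5 - b) - sqrt(disc)) / (2 * 0.04)
  list(v = v, u = b * v)
}

# Broadcast a scalar current to the lattice shape; validate matrix inputs.
expand_map <- function(x, grid) {
  if (length(x) == 1) return(matrix(x, grid$rows, grid$cols))
  if (!is.matrix(x) || nrow(x) != grid$rows || ncol(x) != grid$cols)
    stop("current map does not conform to the lattice shape")
  x
}

#' Export a spike raster as a two-column CSV
#'
#' @param spikes data frame with columns `neuron` and `time_ms` (as returned
#'   in the `spikes` element of [simulate_network()] results).
#' @param file path of the CSV file to write.
#' @return the file path, invisibly.
#' @export
write_raster_csv <- function(spikes, file) {
  stopifnot(all(c("neuron", "time_ms") %in% names(spikes)))
  write.csv(spikes[, c("neuron", "time_ms")], file, row.names = FALSE)
  invisible(file)
}
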