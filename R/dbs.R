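#' DBS electrode configuration
#'
#' Describes a deep-brain-stimulation electrode acting on the STN lattice:
#' the injected current falls off as a Gaussian around the electrode centre,
#' \deqn{I_{ij} = A_{DBS} \exp(-((i - i_c)^2 + (j - j_c)^2) / \sigma^2),}
#' and is pulsed as a charge-balanced biphasic rectangular train at a
#' clinical frequency.
#'
#' The three named electrode positions used in position experiments are
#' `1 = (13, 13)` (deck-A quadrant), `2 = (25, 25)` (module centre) and
#' `3 = (38, 38)` (deck-D quadrant); pass them via `position`.
#'
#' @param center electrode centre `(i_c, j_c)` in 1-based lattice
#'   coordinates.
#' @param amplitude pulse amplitude `A_DBS` (pA), non-negative.
#' @param sigma current-spread parameter (lattice units), positive.  The
#'   default 35 makes the e^-1 radius cover a 50 x 50 module
#'   (whole-module stimulation).
#' @param frequency pulse frequency (Hz), default 130 (clinical high
#'   frequency).
#' @param phase_width duration of each phase (ms); default 0.4 ms,
#'   calibrated so that the printed pA amplitude axis (70-300 pA) spans the
#'   desynchronisation/entrainment operating range of the lattice neurons.
#' @param position optional named position 1, 2 or 3 overriding `center`.
#' @return an object of class `electrode_config`.
#' @export
electrode_config <- function(center = c(25, 25), amplitude = 130, sigma = 35,
                             frequency = 130, phase_width = 0.4,
                             position = NULL) {
  if (!is.null(position)) {
    stopifnot(position %in% 1:3)
    center <- list(c(13, 13), c(25, 25), c(38, 38))[[position]]
  }
  stopifnot(length(center) == 2, amplitude >= 0, sigma > 0, frequency > 0,
            phase_width > 0)
  period <- 1000 / frequency
  if (2 * phase_width > period)
    stop("biphasic pulse (2 * phase_width) does not fit in the period")
  structure(list(center = as.numeric(center), amplitude = amplitude,
                 sigma = sigma, frequency = frequency,
                 phase_width = phase_width, period = period),
            class = "electrode_config")
}

#' Gaussian spatial profile of the DBS current
#'
#' Evaluates the current-spread map over the lattice:
#' `amplitude * exp(-((i - i_c)^2 + (j - j_c)^2) / sigma^2)`.  Note the
#' denominator is `sigma^2`, not `2 sigma^2`.
#'
#' @param electrode an [electrode_config()].
#' @param rows,cols lattice shape.
#' @return a `rows x cols` matrix of peak currents (pA); maximum
#'   `amplitude` at the centre, radially symmetric, monotonically decaying
#'   with distance.
#' @export
dbs_profile <- function(electrode, rows = 50, cols = 50) {
  stopifnot(inherits(electrode, "electrode_config"))
  ic <- electrode$center[1]
  jc <- electrode$center[2]
  i <- matrix(seq_len(rows), rows, cols)
  j <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  electrode$amplitude * exp(-((i - ic)^2 + (j - jc)^2) / electrode$sigma^2)
}

#' Biphasic pulse polarity at time t
#'
#' The pulse train has period `1000 / frequency` ms; polarity is +1 during
#' the first `phase_width` ms of each period, -1 during the second, and 0 in
#' the remaining inter-pulse gap.  Equal phase widths make the waveform
#' charge-balanced.
#'
#' @param t time (ms), scalar or vector, non-negative.
#' @param electrode an [electrode_config()].
#' @return polarity factor(s) in `{+1, -1, 0}`.
#' @export
dbs_waveform <- function(t, electrode) {
  stopifnot(inherits(electrode, "electrode_config"), all(t >= 0))
  m <- t %% electrode$period
  ifelse(m < electrode$phase_width, 1,
         ifelse(m < 2 * electrode$phase_width, -1, 0))
}

#' Instantaneous DBS current map
#'
#' Spatial profile times pulse polarity; this is the current added to the
#' external input of STN neurons (and only STN) at time `t`.
#'
#' @param t time (ms, scalar).
#' @param electrode an [electrode_config()], or `NULL` for stimulation off.
#' @param rows,cols lattice shape.
#' @return a `rows x cols` current matrix (pA).
#' @export
dbs_current <- function(t, electrode, rows = 50, cols = 50) {
  if (is.null(electrode)) return(matrix(0, rows, cols))
  dbs_waveform(t, electrode) * dbs_profile(electrode, rows, cols)
}
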