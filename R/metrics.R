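#' Population synchrony index
#'
#' Kuramoto-style phase order parameter computed from spike times: each
#' neuron's phase advances linearly from 0 to 2*pi between consecutive
#' spikes, and the index is the time average of
#' \eqn{|N^{-1} \sum_j e^{i\phi_j(t)}|} over the window where every included
#' neuron has a defined phase.  Bounded in `[0, 1]`: 1 for perfectly
#' coincident spiking, near 0 for incoherent populations (at most about
#' `1/sqrt(N)` for independent phases).
#'
#' Neurons with fewer than two spikes have no phase and are excluded (a
#' message reports how many); if all are excluded the index is undefined and
#' an error is raised.
#'
#' @param sim a `bg_sim` object, or a data frame of spikes with columns
#'   `neuron` and `time_ms`.
#' @param nucleus which recorded raster to use when `sim` is a `bg_sim`
#'   (default `"STN"`).
#' @param grid_ms evaluation grid spacing (ms).
#' @return scalar synchrony index.
#' @export
synchrony_index <- function(sim, nucleus = "STN", grid_ms = 1) {
  spikes <- raster_from(sim, nucleus)
  byn <- split(spikes$time_ms, spikes$neuron)
  byn <- lapply(byn, sort)
  nsp <- lengths(byn)
  excluded <- sum(nsp < 2)
  byn <- byn[nsp >= 2]
  if (length(byn) < 2)
    stop("synchrony index undefined: fewer than two neurons with >= 2 spikes")
  if (excluded > 0)
    message(excluded, " neuron(s) with < 2 spikes excluded from synchrony index")
  t0 <- max(vapply(byn, function(s) s[1], numeric(1)))
  t1 <- min(vapply(byn, function(s) s[length(s)], numeric(1)))
  if (t1 <= t0)
    stop("synchrony index undefined: no common window with defined phases")
  grid <- seq(t0, t1, by = grid_ms)
  re <- numeric(length(grid))
  im <- numeric(length(grid))
  for (s in byn) {
    k <- findInterval(grid, s, rightmost.closed = TRUE)
    k[k < 1] <- 1
    k[k >= length(s)] <- length(s) - 1
    phase <- 2 * pi * (grid - s[k]) / (s[k + 1] - s[k])
    re <- re + cos(phase)
    im <- im + sin(phase)
  }
  n <- length(byn)
  mean(sqrt(re^2 + im^2)) / n
}

#' Spectral peak of the population mean field
#'
#' Bins the population spike raster into a mean-field rate signal, removes
#' the mean, and returns the discrete-Fourier-spectrum argmax within a
#' frequency band (default 2-8 Hz, the tremor band).  A peak is flagged as
#' `prominent` when its power exceeds 10 times the median spectral power
#' (white-noise-like signals fail this).
#'
#' @param sim a `bg_sim`, a spike data frame, or a plain numeric vector
#'   already containing a mean-field signal sampled at `1000 / bin_ms` Hz.
#' @param band numeric length-2 frequency band (Hz) searched for the peak.
#' @param nucleus raster to use for `bg_sim` input.
#' @param bin_ms width of the rate bins (ms).
#' @return list with `frequency` (Hz), `power`, and logical `prominent`.
#' @export
spectral_peak <- function(sim, band = c(2, 8), nucleus = "STN", bin_ms = 1) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  fs <- 1000 / bin_ms
  if (is.numeric(sim) && is.null(dim(sim))) {
    x <- sim
  } else {
    spikes <- raster_from(sim, nucleus)
    dur <- if (inherits(sim, "bg_sim")) sim$duration_ms else max(spikes$time_ms)
    breaks <- seq(0, dur + bin_ms, by = bin_ms)
    x <- as.numeric(table(cut(spikes$time_ms, breaks)))
  }
  n <- length(x)
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency ", fs / 2, " Hz")
  if (band[1] < 1000 / (n * bin_ms) * 2)
    warning("signal shorter than two periods of the lowest band frequency")
  x <- x - mean(x)
  pw <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq(2, floor(n / 2))
  pw <- pw[half]
  freqs <- freqs[half]
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("no Fourier frequency falls inside the band")
  k <- which(in_band)[which.max(pw[in_band])]
  list(frequency = freqs[k], power = pw[k],
       prominent = pw[k] > 10 * median(pw))
}

#' Mean firing rate per deck quadrant
#'
#' @param sim a `bg_sim` or spike data frame.
#' @param rows,cols lattice shape (taken from a `bg_sim` automatically).
#' @param duration_ms recording duration (ms); from `bg_sim` automatically.
#' @param nucleus raster to use for `bg_sim` input.
#' @return named numeric vector, spikes/neuron/second for quadrants A-D.
#' @export
quadrant_rates <- function(sim, rows = NULL, cols = NULL, duration_ms = NULL,
                           nucleus = "STN") {
  if (inherits(sim, "bg_sim")) {
    rows <- sim$rows; cols <- sim$cols; duration_ms <- sim$duration_ms
  }
  stopifnot(!is.null(rows), !is.null(cols), !is.null(duration_ms))
  spikes <- raster_from(sim, nucleus)
  qv <- c("A", "B", "C", "D")[quadrant_index(rows, cols) + 1L]
  nq <- table(factor(qv, levels = c("A", "B", "C", "D")))
  cnt <- table(factor(qv[spikes$neuron], levels = c("A", "B", "C", "D")))
  stats::setNames(as.numeric(cnt) / (as.numeric(nq) * duration_ms / 1000),
                  c("A", "B", "C", "D"))
}

raster_from <- function(sim, nucleus) {
  if (inherits(sim, "bg_sim")) {
    if (!nucleus %in% names(sim$spikes))
      stop("nucleus ", nucleus, " was not recorded in this simulation")
    sim$spikes[[nucleus]]
  } else {
    stopifnot(all(c("neuron", "time_ms") %in% names(sim)))
    sim
  }
}

#' Write metrics in tidy long format
#'
#' @param metrics data frame (run, condition, metric, value).
#' @param file output CSV path.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(metrics, file) {
  write.csv(metrics, file, row.names = FALSE)
  invisible(file)
}
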