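# Shared fixtures: small lattices keep network tests fast; the calibrated
# gains are the package defaults so dynamics stay in the tested regime.

small_config <- function(rows = 24, cols = 24, ...) {
  bg_network_config(rows = rows, cols = cols, ...)
}

make_weights <- function(d1 = rep(0.5, 4), d2 = rep(0.5, 4)) {
  decks <- c("A", "B", "C", "D")
  structure(list(d1 = stats::setNames(d1, decks),
                 d2 = stats::setNames(d2, decks)),
            class = "cs_weights")
}

# deterministic periodic raster: n neurons, common period, per-neuron offset
staggered_raster <- function(n, period = 100, duration = 2000,
                             offsets = (seq_len(n) - 1) * period / n) {
  do.call(rbind, lapply(seq_len(n), function(j) {
    times <- seq(offsets[j], duration, by = period)
    data.frame(neuron = j, time_ms = times)
  }))
}

# cache for expensive full-scale experiment tables shared across
# acceptance-tier tests
.acc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) {
    assign(key, force(expr), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}
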