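test_that("quadrants partition the lattice and carry the stated anchors", {
  qm <- quadrant_map(50, 50)
  expect_identical(dim(qm), c(50L, 50L))
  expect_identical(sort(unique(as.vector(qm))), c("A", "B", "C", "D"))
  expect_true(all(table(qm) == 625L))  # four equal quadrants
  expect_identical(qm[13, 13], "A")
  expect_identical(qm[38, 38], "D")
  expect_identical(qm[25, 25], "A")
  expect_identical(qm[13, 38], "B")
  expect_identical(qm[38, 13], "C")
})

test_that("the anatomy of the wiring is fixed: no negative gains accepted", {
  expect_error(bg_network_config(g_gpe_stn = -5), "anatomy")
  expect_error(bg_network_config(g_lat_stn = -1), "anatomy")
})

test_that("striatal rates are an affine map of weights clipped to 2-40 Hz", {
  cfg <- bg_network_config()
  mid <- (cfg$w_floor + cfg$w_max) / 2
  r <- striatal_rates(make_weights(d1 = c(-1, cfg$w_floor, mid, 10),
                                   d2 = c(0, 1, 2, 3)), cfg)
  expect_identical(unname(r$d1[1]), 2)              # below the floor anchor
  expect_identical(unname(r$d1[2]), 2)              # at the floor anchor
  expect_equal(unname(r$d1[3]), (2 + 40) / 2)       # midpoint of the map
  expect_identical(unname(r$d1[4]), 40)             # above the upper anchor
  expect_identical(unname(r$d1[4]), cfg$rate_max)
  expect_true(all(r$d2 >= 2 & r$d2 <= 40))
  w <- make_weights(); w$d1[1] <- NaN
  expect_error(striatal_rates(w, cfg), "finite")
})

test_that("Poisson spike generation is seeded, bounded and empty at rate 0", {
  expect_identical(nrow(generate_poisson_spikes(0, 1000, n_neurons = 5,
                                                seed = 1)), 0L)
  a <- generate_poisson_spikes(20, 500, n_neurons = 10, seed = 4)
  b <- generate_poisson_spikes(20, 500, n_neurons = 10, seed = 4)
  expect_identical(a, b)
  expect_error(generate_poisson_spikes(600, 100, dt = 2), "dt too coarse")
})

test_that("Poisson counts have the right mean and unit Fano factor", {
  sp <- generate_poisson_spikes(40, 10000, dt = 0.1, n_neurons = 1000,
                                seed = 11)
  counts <- tabulate(sp$neuron, nbins = 1000)
  expect_equal(mean(counts), 400, tolerance = 0.02)
  fano <- var(counts) / mean(counts)
  expect_gt(fano, 0.85)
  expect_lt(fano, 1.15)
})

test_that("race selection follows first crossing, ties and timeout rules", {
  # single accumulator always wins
  tr <- matrix(seq(0, 2, length.out = 50), ncol = 1)
  expect_identical(race_select(tr)$index, 1L)
  # deterministic ordering: largest drive crosses first
  tr <- sapply(c(0.05, 0.02, 0.02, 0.02), function(d) cumsum(rep(d, 100)))
  r <- race_select(tr, threshold = 1)
  expect_identical(unname(r$index), 1L)
  expect_false(r$timeout)
  # no crossing: argmax fallback flagged as timeout
  tr <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.1, 0.2), nrow = 2,
               byrow = TRUE)
  r <- race_select(tr, threshold = 1)
  expect_true(r$timeout)
  # two equal leaders crossing together are split about evenly
  tr <- cbind(cumsum(rep(0.05, 40)), cumsum(rep(0.05, 40)),
              cumsum(rep(0.01, 40)), cumsum(rep(0.01, 40)))
  set.seed(9)
  wins <- replicate(400, race_select(tr, threshold = 1)$index)
  expect_true(all(wins %in% 1:2))
  p1 <- mean(wins == 1)
  expect_gt(p1, 0.5 - 3 * sqrt(0.25 / 400))
  expect_lt(p1, 0.5 + 3 * sqrt(0.25 / 400))
})

test_that("a trial is deterministic under its seed", {
  cfg <- small_config()
  w <- make_weights()
  a <- simulate_trial(cfg, w, condition = "HC", seed = 123, record = "STN")
  b <- simulate_trial(cfg, w, condition = "HC", seed = 123, record = "STN")
  expect_identical(a$deck, b$deck)
  expect_identical(a$decision_time, b$decision_time)
  expect_identical(a$spikes$STN, b$spikes$STN)
  expect_identical(a$gpi_quadrant_rates, b$gpi_quadrant_rates)
})

test_that("exactly one deck is selected and symmetric weights give uniform choice", {
  cfg <- small_config()
  w <- make_weights()
  decks <- vapply(1:80, function(s)
    simulate_trial(cfg, w, condition = "HC", seed = 1000 + s)$deck,
    character(1))
  expect_true(all(decks %in% c("A", "B", "C", "D")))
  tab <- table(factor(decks, levels = c("A", "B", "C", "D")))
  # chi-square goodness of fit against uniform
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("a strongly weighted deck wins the majority of trials", {
  cfg <- small_config()
  w <- make_weights(d1 = c(0.2, 0.2, 2.5, 0.2))
  decks <- vapply(1:40, function(s)
    simulate_trial(cfg, w, condition = "HC", seed = 2000 + s)$deck,
    character(1))
  expect_gt(mean(decks == "C"), 0.5)
})

test_that("zero-amplitude stimulation is bit-identical to stimulation off", {
  cfg <- small_config()
  w <- make_weights()
  el0 <- electrode_config(center = c(12, 12), amplitude = 0, sigma = 10)
  off <- simulate_trial(cfg, w, electrode = NULL, condition = "PD_OFF",
                        seed = 55, record = "STN")
  on0 <- simulate_trial(cfg, w, electrode = el0, condition = "PD_OFF",
                        seed = 55, record = "STN")
  expect_identical(off$deck, on0$deck)
  expect_identical(off$decision_time, on0$decision_time)
  expect_identical(off$spikes$STN, on0$spikes$STN)
})

test_that("low dopamine produces synchronous bursting, absent without GPe->STN", {
  seeds <- 1:4
  R <- function(cfg, cond) vapply(seeds, function(s) {
    sim <- simulate_network(cfg, 1500, cond, seed = s)
    tryCatch(suppressMessages(synchrony_index(sim)),
             error = function(e) 0)
  }, numeric(1))
  cfg <- small_config(30, 30)
  r_pd <- R(cfg, "PD_OFF")
  r_hc <- R(cfg, "HC")
  expect_gt(mean(r_pd), mean(r_hc) + 0.15)
  # the parkinsonian rhythm is a prominent tremor-band oscillation ...
  pd <- simulate_network(cfg, 2000, "PD_OFF", seed = 1)
  pk_pd <- spectral_peak(pd, band = c(2, 8))
  expect_true(pk_pd$prominent)
  # ... and the pallido-subthalamic projection is what keeps it a balanced
  # low-rate bursting regime: severing it removes the only inhibition onto
  # STN and the module degenerates into runaway firing at >10x the rate
  cfg_cut <- small_config(30, 30, g_gpe_stn = 0)
  cut <- simulate_network(cfg_cut, 2000, "PD_OFF", seed = 1)
  rate <- function(sim) nrow(sim$spikes$STN) / (900 * sim$duration_ms / 1000)
  expect_gt(rate(cut), 10 * rate(pd))
})

test_that("network configuration round-trips through YAML", {
  cfg <- bg_network_config(rows = 12, cols = 12, g_lat_stn = 9,
                           race_noise = 0.07)
  f <- tempfile(fileext = ".yaml")
  write_bg_config(cfg, f)
  cfg2 <- read_bg_config(f)
  expect_equal(cfg2, cfg)
  y <- yaml::read_yaml(f); y$not_a_key <- 1; yaml::write_yaml(y, f)
  expect_error(read_bg_config(f), "unknown configuration")
  unlink(f)
})

test_that("the bundled default configuration matches the package defaults", {
  f <- system.file("extdata", "default_config.yaml", package = "bgstim")
  expect_equal(read_bg_config(f), bg_network_config())
})
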