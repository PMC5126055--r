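test_that("parameter validation enforces the model contract", {
  expect_error(izh_params(a = -0.1, b = 0.2, c = -65, d = 2), "positive")
  expect_error(izh_params(a = 0.1, b = 0.2, c = -65, d = 0), "positive")
  expect_error(izh_params(a = 0.1, b = 0.2, c = 40, d = 2), "below v_peak")
  expect_error(izh_params(a = 0.1, b = 0.2, c = -65, d = 2, v_peak = 25),
               "fixed at \\+30")
  p <- izh_params(a = 0.02, b = 0.2, c = -65, d = 8)
  expect_s3_class(p, "izh_params")
  expect_identical(p$v_peak, 30)
})

test_that("a single Euler step matches a hand-computed scalar oracle", {
  p <- izh_params(a = 0.02, b = 0.2, c = -65, d = 8)
  g <- neuron_grid("STN", 1, 1, params = p, v0 = -65, u0 = 0.2 * -65)
  r <- izhikevich_step(g, I_ext = 10, dt = 0.1)
  # independent scalar computation of the same update
  v <- -65; u <- 0.2 * -65; I <- 10; dt <- 0.1
  v_exp <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
  u_exp <- u + dt * (p$a * (p$b * v - u))
  expect_identical(r$grid$v[1, 1], v_exp)
  expect_identical(r$grid$u[1, 1], u_exp)
  expect_false(r$spiked[1, 1])
})

test_that("crossing v_peak flags a spike and applies the reset rule", {
  p <- nucleus_params("GPe")
  # start just below threshold with a large current so the update crosses
  g <- neuron_grid("GPe", 1, 1, params = p, v0 = 29, u0 = 0)
  u_after <- 0 + 0.1 * (p$a * (p$b * 29 - 0))
  r <- izhikevich_step(g, I_ext = 200, dt = 0.1)
  expect_true(r$spiked[1, 1])
  expect_identical(r$grid$v[1, 1], p$c)
  expect_identical(r$grid$u[1, 1], u_after + p$d)
})

test_that("the subthreshold fixed point is invariant under the Euler step", {
  p <- izh_params(a = 0.02, b = 0.2, c = -65, d = 8)
  fp <- izh_fixed_point(p, I = 0)
  expect_false(is.null(fp))
  g <- neuron_grid("STN", 2, 2, params = p, v0 = fp$v, u0 = fp$u)
  r <- izhikevich_step(g, I_ext = 0, dt = 0.1)
  expect_equal(max(abs(r$grid$v - fp$v)), 0, tolerance = 1e-10)
  expect_equal(max(abs(r$grid$u - fp$u)), 0, tolerance = 1e-10)
  # no fixed point once the current exceeds the knee
  expect_null(izh_fixed_point(p, I = 20))
})

test_that("vectorised lattice update is bit-identical to a scalar loop", {
  p <- nucleus_params("STN")
  set.seed(7)
  v0 <- matrix(runif(9, -80, 29), 3, 3)
  u0 <- matrix(runif(9, -20, 5), 3, 3)
  I <- matrix(runif(9, -5, 40), 3, 3)
  g <- neuron_grid("STN", 3, 3, params = p, v0 = v0, u0 = u0)
  r <- izhikevich_step(g, I_ext = I, dt = 0.1)
  # scalar-loop oracle
  vs <- v0; us <- u0; sp <- matrix(FALSE, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    vv <- v0[i, j] + 0.1 * (0.04 * v0[i, j] * v0[i, j] + 5 * v0[i, j] +
                              140 - u0[i, j] + I[i, j])
    uu <- u0[i, j] + 0.1 * (p$a * (p$b * v0[i, j] - u0[i, j]))
    if (vv >= p$v_peak) { sp[i, j] <- TRUE; vv <- p$c; uu <- uu + p$d }
    vs[i, j] <- vv; us[i, j] <- uu
  }
  expect_identical(r$grid$v, vs)
  expect_identical(r$grid$u, us)
  expect_identical(unname(r$spiked), sp)
})

test_that("the reset rule is idempotent", {
  p <- nucleus_params("GPi")
  v <- c(35, 10, -70); u <- c(0, 1, 2)
  once <- izh_reset(v, u, p)
  twice <- izh_reset(once$v, once$u, p)
  expect_identical(once$v, twice$v)
  expect_identical(once$u, twice$u)
  expect_false(any(twice$spiked))
})

test_that("after any step all membrane potentials lie at or below v_peak", {
  p <- nucleus_params("STN")
  set.seed(11)
  g <- neuron_grid("STN", 5, 5, params = p,
                   v0 = matrix(runif(25, -80, 29.9), 5, 5),
                   u0 = matrix(0, 5, 5))
  for (k in 1:50) {
    r <- izhikevich_step(g, I_ext = 30, dt = 0.1)
    g <- r$grid
    expect_true(all(g$v <= p$v_peak))
  }
})

test_that("the compiled engine reproduces the R lattice step exactly", {
  cfg <- small_config(rows = 3, cols = 3)
  p <- cfg$stn
  set.seed(3)
  v0 <- runif(9, -70, -50)
  u0 <- p$b * v0
  rates <- list(d1 = rep(0, 4), d2 = rep(0, 4))  # silence the striatum
  ecfg <- bgstim:::engine_cfg(cfg, rates, electrode = NULL, condition = "HC",
                              seed = 1, n_steps = 1, race = FALSE,
                              stn_v0 = v0, stn_u0 = u0)
  res <- bgstim:::.bg_engine(ecfg)
  g <- neuron_grid("STN", 3, 3, params = p,
                   v0 = matrix(v0, 3, 3), u0 = matrix(u0, 3, 3))
  r <- izhikevich_step(g, I_ext = p$bias, dt = cfg$dt)
  expect_identical(res$stn_v, as.vector(r$grid$v))
  expect_identical(res$stn_u, as.vector(r$grid$u))
})

test_that("non-conforming current maps and unstable states are rejected", {
  g <- neuron_grid("STN", 4, 4)
  expect_error(izhikevich_step(g, I_ext = matrix(0, 2, 2)), "lattice shape")
  g$v[] <- 1e200  # v^2 overflows; recovery update yields Inf - Inf = NaN
  g$u[] <- Inf
  expect_error(izhikevich_step(g, dt = 0.1), "reduce dt")
})

test_that("spike rasters round-trip through the two-column CSV export", {
  sp <- data.frame(neuron = c(1L, 2L, 2L), time_ms = c(0.5, 1.2, 7.7))
  f <- tempfile(fileext = ".csv")
  write_raster_csv(sp, f)
  back <- read.csv(f)
  expect_equal(back, sp)
  unlink(f)
})
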