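test_that("free BMP-2 degradation halves the field in 0.42 days", {
  p <- bmp_params()
  expect_equal(log(2) / p$lambda_free, 0.42)
  # RK4 integration of dg/dt = -degradation_rate(g) over one half-life
  g <- 1
  nstep <- 420L
  h <- 0.42 / nstep
  f <- function(g) -degradation_rate(g, p)
  for (i in seq_len(nstep)) {
    k1 <- f(g); k2 <- f(g + h / 2 * k1)
    k3 <- f(g + h / 2 * k2); k4 <- f(g + h * k3)
    g <- g + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(g, 0.5, tolerance = 1e-9)
})

test_that("encapsulated pool in intact gel halves in 3.25 days", {
  out <- gel_pool_step(g_gel = 1, a = 1, dt = 3.25)
  expect_equal(out$g_gel, 0.5)
  expect_equal(out$released, 0)  # a = 1: no release channel
  expect_equal(out$destroyed, 0.5)
})

test_that("gel pool step conserves mass between channels", {
  g0 <- c(10, 5, 0, 2)
  a <- c(1, 0.5, 0.2, 0)
  out <- gel_pool_step(g0, a, dt = 1)
  expect_equal(out$g_gel + out$released + out$destroyed, g0)
  expect_true(all(out$released >= 0 & out$destroyed >= 0))
  # release accelerates as the gel degrades
  r1 <- gel_pool_step(1, 0.9, 1)$released
  r2 <- gel_pool_step(1, 0.1, 1)$released
  expect_gt(r2, r1)
})

test_that("background consumption at g = Kma equals Vmax / 2", {
  p <- bmp_params()
  cs <- 5e5; cb <- 2e5
  vmax <- (cs + cb) * p$v_max_per_cell
  expect_equal(background_consumption_rate(p$Kma, cs, cb, p), vmax / 2)
  expect_equal(background_consumption_rate(0, cs, cb, p), 0)
  # saturates at Vmax
  expect_lt(background_consumption_rate(1e6, cs, cb, p), vmax)
})

test_that("production falls with ambient concentration", {
  p <- bmp_params()
  gg <- c(0, 0.01, 0.1, 1, 10)
  rates <- production_rate(gg, 1e6, 0, p)
  expect_true(all(diff(rates) < 0))
  expect_equal(production_rate(1, 2e5, 3e5, p),
               p$alpha_prod * 5e5 / (p$gamma + p$gamma0))
})

test_that("homeostatic concentration of populated tissue lies in band", {
  p <- bmp_params()
  band <- physiological_range()
  th <- rule_thresholds()
  gstar <- homeostatic_g(th$c_source, p)
  expect_gte(gstar, band$band_low)
  expect_lte(gstar, band$band_high)
  # it is a true balance point
  expect_equal(production_rate(gstar, th$c_source, 0, p),
               degradation_rate(gstar, p) +
                 background_consumption_rate(gstar, th$c_source, 0, p),
               tolerance = 1e-6)
  expect_equal(homeostatic_g(0, p), 0)
  # more cells support a higher equilibrium
  expect_gt(homeostatic_g(2e6, p), gstar)
})

test_that("differentiation sink drains to exactly g_min and no further", {
  gm <- bmp_params()$g_min
  g <- c(10, gm, gm / 2, 0)
  ev <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(differentiation_sink(g, ev, gm), c(gm, gm, gm / 2, 0))
})

test_that("step_bmp2 keeps the field non-negative and decays without cells", {
  grid <- sim_grid(4, 2, 0.5)
  nc <- grid$nc
  g0 <- rep(1, nc)
  st <- bmp_state(g0)
  zero <- numeric(nc)
  out <- st
  for (d in 1:5)
    out <- step_bmp2(out, zero, zero, zero, rep(FALSE, nc), 1, grid)
  expect_true(all(out$g >= 0))
  # no cells: pure half-life decay, 5 days is ~11.9 half-lives
  expect_equal(max(out$g), exp(-bmp_params()$lambda_free * 5),
               tolerance = 1e-6)
})

test_that("bmp state and diffusivity validate inputs", {
  expect_error(bmp_state(c(-1, 0)), ">= 0")
  expect_error(bmp_state(c(1, 2), c(1, 2, 3)), "length")
  p <- bmp_params()
  expect_equal(bmp_diffusivity(1, p), p$D_gel)
  expect_equal(bmp_diffusivity(0, p), p$D_vivo)
  expect_error(bmp_params(t_half_free = 4), "faster")
})
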