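test_that("proliferation follows the exact logistic closed form", {
  th <- rule_thresholds()
  g <- 0.05           # physiological: fold = 1
  c0 <- 1e5
  dt <- 2.5
  K <- th$c_max
  r <- th$r_prolif
  expected <- K * c0 / (c0 + (K - c0) * exp(-r * dt))
  expect_equal(proliferate(c0, g, dt, th), expected)
  # step-size invariance of the exact update
  two <- proliferate(proliferate(c0, g, 1.25, th), g, 1.25, th)
  expect_equal(two, expected)
  # never exceeds carrying density; zero stays zero
  expect_lte(proliferate(K, g, 10, th), K)
  expect_equal(proliferate(0, g, 1, th), 0)
})

test_that("space competition shrinks the effective carrying capacity", {
  th <- rule_thresholds()
  g <- 0.05
  free <- proliferate(1e5, g, 1, th, c_other = 0)
  crowd <- proliferate(1e5, g, 1, th, c_other = 0.9 * th$c_max)
  expect_gt(free, crowd)
  # saturates at the reduced capacity
  lim <- proliferate(1e5, g, 500, th, c_other = 0.9 * th$c_max)
  expect_equal(lim, 0.1 * th$c_max, tolerance = 1e-6)
  # overcrowded volumes relax downward (Keff <= 0)
  over <- proliferate(2e5, g, 1, th, c_other = th$c_max)
  expect_lt(over, 2e5)
  expect_gte(over, 0)
})

test_that("proliferation and differentiation are gated by g_min", {
  th <- rule_thresholds()
  g_low <- 0.5 * physiological_range()$g_min
  expect_equal(proliferate(1e5, g_low, 1, th), 1e5)
  cells <- cell_fields(1)
  cells$cs <- 1e5
  out <- differentiate(cells, psi = 0.005, g = g_low, dt = 1, th)
  expect_equal(out$cells$cs, 1e5)
  expect_equal(out$cells$cb, 0)
  expect_false(any(out$event_mask))
})

test_that("stimulus bands select the differentiation fate", {
  th <- rule_thresholds()
  g <- 1
  psi <- c(0.005, 0.03, 0.2)    # bone / cartilage / fibrous bands
  cells <- cell_fields(3)
  cells$cs <- rep(1e5, 3)
  out <- differentiate(cells, psi, rep(g, 3), 1, th)
  frac <- 1 - exp(-th$r_diff)
  expect_equal(out$cells$cb, c(1e5 * frac, 0, 0))
  expect_equal(out$cells$cc, c(0, 1e5 * frac, 0))
  expect_equal(out$cells$cf, c(0, 0, 1e5 * frac))
  expect_equal(out$cells$cs, rep(1e5 * (1 - frac), 3))
  # event mask only for chondro/osteogenic fates
  expect_equal(out$event_mask, c(TRUE, TRUE, FALSE))
  # trace conversions below c_event_min do not trigger the sink
  tiny <- cell_fields(1); tiny$cs <- 10
  expect_false(any(differentiate(tiny, 0.005, g, 1, th)$event_mask))
})

test_that("cell mass is conserved through differentiation", {
  th <- rule_thresholds()
  cells <- cell_fields(4)
  cells$cs <- c(1e5, 5e4, 2e5, 0)
  before <- sum(cells$cs)
  out <- differentiate(cells, c(0.005, 0.03, 0.2, 0.005), rep(1, 4), 1, th)
  after <- with(out$cells, sum(cs + cb + cc + ch + cf))
  expect_equal(after, before)
})

test_that("maturation converts cartilage to bone via the calcified stage", {
  th <- rule_thresholds()
  nc <- 1
  cells <- cell_fields(nc)
  cells$cc <- 5e5
  comp <- new_composition(nc)
  comp[1, "cartilage"] <- 0.6
  comp[1, "granulation"] <- 0.4
  g <- 30   # hypertrophy strongly promoted
  for (d in 1:60) {
    out <- mature_and_produce(cells, comp, 0.03, g, 1, th)
    cells <- out$cells; comp <- out$composition
  }
  expect_lt(comp[1, "cartilage"], 0.05)
  expect_gt(comp[1, "woven"], 0.5)
  expect_gt(cells$cb, 0)
  expect_true(all(comp >= 0) && all(rowSums(comp) <= 1 + 1e-9))
})

test_that("bone matrix production fills displaceable space only", {
  th <- rule_thresholds()
  cells <- cell_fields(2)
  cells$cb <- c(1e6, 1e6)
  comp <- new_composition(2)
  comp[1, "granulation"] <- 1      # displaceable
  comp[2, "cortical"] <- 1         # nothing displaceable
  g <- 200                          # maximal production fold
  for (d in 1:100) {
    out <- mature_and_produce(cells, comp, 0.005, g, 1, th)
    cells <- out$cells; comp <- out$composition
  }
  expect_gt(comp[1, "woven"], 0.9)
  expect_equal(unname(comp[2, "woven"]), 0)
  expect_true(all(rowSums(comp) <= 1 + 1e-9))
  # immutable mask protects cortical elements entirely
  comp3 <- new_composition(1); comp3[1, "granulation"] <- 1
  cells3 <- cell_fields(1); cells3$cb <- 1e6
  out3 <- mature_and_produce(cells3, comp3, 0.005, g, 1, th,
                             immutable = TRUE)
  expect_equal(unname(out3$composition[1, "woven"]), 0)
})

test_that("higher BMP-2 accelerates bone matrix production", {
  th <- rule_thresholds()
  step_woven <- function(g) {
    # cb low enough that production stays below the displaceable-space cap
    cells <- cell_fields(1); cells$cb <- 1e4
    comp <- new_composition(1); comp[1, "granulation"] <- 1
    unname(mature_and_produce(cells, comp, 0.005, g, 1,
                              th)$composition[1, "woven"])
  }
  expect_equal(step_woven(10) / step_woven(0.05), 2.3, tolerance = 1e-8)
  expect_equal(step_woven(200) / step_woven(0.05), 5.5, tolerance = 1e-8)
})
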