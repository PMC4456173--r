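test_that("Q4 element passes the patch test (linear field exact)", {
  grid <- sim_grid(2.5, 1.5, 0.5)   # 5 x 3 elements
  nd <- bmpheal:::grid_nodes(grid)
  # prescribed linear displacement field
  ux_exact <- 1e-3 * (0.2 + 0.5 * nd$x - 0.3 * nd$y)
  uy_exact <- 1e-3 * (-0.1 + 0.4 * nd$x + 0.7 * nd$y)
  tol <- 1e-9
  bnd <- which(nd$x < tol | nd$x > grid$Lx - tol |
                 nd$y < tol | nd$y > grid$Ly - tol)
  dofs <- c(2L * bnd - 1L, 2L * bnd)
  vals <- c(ux_exact[bnd], uy_exact[bnd])
  sol <- bmpheal:::fe_solve(grid, E = 10, nu = 0.3,
                            dirichlet_dofs = dofs, dirichlet_vals = vals)
  expect_equal(sol$ux, ux_exact, tolerance = 1e-10)
  expect_equal(sol$uy, uy_exact, tolerance = 1e-10)
  # constant strain recovered everywhere
  st <- compute_stimulus(grid, sol)
  expect_equal(st$exx, rep(5e-4, grid$nc), tolerance = 1e-10)
  expect_equal(st$eyy, rep(7e-4, grid$nc), tolerance = 1e-10)
  expect_equal(st$exy, rep(0.5 * (4e-4 - 3e-4), grid$nc), tolerance = 1e-10)
})

test_that("fixated uniform bar matches the series-spring oracle", {
  # uniform bar, axis symmetry at y = 0, fixator spring on the platen:
  # platen displacement = -F / (k_fix + E' A / L), E' = E / (1 - nu^2)
  # (plane strain with free lateral surface = plane-stress-like axial
  # stiffness through the standard modulus substitution)
  E <- 500; nu <- 0.3
  grid <- sim_grid(10, 2, 0.25)
  props <- list(E = rep(E, grid$nc), nu = rep(nu, grid$nc))
  ld <- load_case(axial_load = 14.4, fixator_stiffness = 277)
  sol <- solve_displacements(grid, props, ld)
  EA_over_L <- E / (1 - nu^2) * grid$Ly / grid$Lx
  expect_equal(sol$master_disp, -14.4 / (277 + EA_over_L), tolerance = 1e-8)
  # without the fixator the bar takes the whole load
  sol0 <- solve_displacements(grid, props, load_case(14.4, 1e-9))
  expect_equal(sol0$master_disp, -14.4 / EA_over_L, tolerance = 1e-6)
})

test_that("displacements scale linearly with the load", {
  grid <- sim_grid(4, 2, 0.5)
  set.seed(3)
  props <- list(E = runif(grid$nc, 10, 1000), nu = runif(grid$nc, 0.05, 0.4))
  s1 <- solve_displacements(grid, props, load_case(14.4, 277))
  s2 <- solve_displacements(grid, props, load_case(28.8, 277))
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-9)
})

test_that("homogenization reproduces pure-tissue endpoints exactly", {
  props <- tissue_properties()
  for (m in material_names()) {
    comp <- new_composition(1)
    comp[1, m] <- 1
    hp <- homogenize_properties(comp)
    expect_equal(hp$E, props[m, "E"])
    expect_equal(hp$nu, props[m, "nu"])
  }
  # the woven-bone calibration endpoint of the property table
  comp <- new_composition(1); comp[1, "woven"] <- 1
  expect_equal(homogenize_properties(comp)$E, 982.48)
})

test_that("homogenized modulus is bounded by its constituents", {
  set.seed(11)
  comp <- matrix(runif(5 * 8), 5, 8,
                 dimnames = list(NULL, material_names()))
  comp <- comp / rowSums(comp) * runif(5, 0.3, 1)
  hp <- homogenize_properties(comp)
  props <- tissue_properties()
  expect_true(all(hp$E >= min(props$E) & hp$E <= max(props$E)))
  expect_true(all(hp$nu >= min(props$nu) & hp$nu <= max(props$nu)))
  # solids-renormalized: scaling all fractions down leaves E unchanged
  expect_equal(homogenize_properties(comp)$E,
               homogenize_properties(comp * 0.5)$E)
  expect_error(homogenize_properties(new_composition(2)), "empty")
})

test_that("stimulus psi is a deviatoric invariant", {
  expect_equal(strain_invariant_psi(0, 0, 0), 0)
  # pure shear: sqrt(J2) equals the tensorial shear strain
  gam <- 3e-3
  expect_equal(strain_invariant_psi(0, 0, gam), gam)
  # invariant under in-plane rotation of the strain tensor
  exx <- 2e-3; eyy <- -1e-3; exy <- 5e-4
  p0 <- strain_invariant_psi(exx, eyy, exy)
  for (th in c(0.3, 1.1, 2.4)) {
    c2 <- cos(th); s2 <- sin(th)
    exx_r <- exx * c2^2 + eyy * s2^2 + 2 * exy * s2 * c2
    eyy_r <- exx * s2^2 + eyy * c2^2 - 2 * exy * s2 * c2
    exy_r <- (eyy - exx) * s2 * c2 + exy * (c2^2 - s2^2)
    expect_equal(strain_invariant_psi(exx_r, eyy_r, exy_r), p0)
  }
  # first order in strain; J2 form is its square
  expect_equal(strain_invariant_psi(2 * exx, 2 * eyy, 2 * exy), 2 * p0)
  expect_equal(strain_invariant_psi(exx, eyy, exy, form = "J2"), p0^2)
})

test_that("softer callus strains more under the same load", {
  grid <- sim_grid(10, 2, 0.25)
  make <- function(E_gap) {
    E <- rep(20e3, grid$nc)
    E[abs(grid$xc - 5) < 2] <- E_gap
    list(E = E, nu = rep(0.3, grid$nc))
  }
  ld <- load_case()
  psi_soft <- compute_stimulus(grid, solve_displacements(grid, make(1), ld))$psi
  psi_stiff <- compute_stimulus(grid, solve_displacements(grid, make(100), ld))$psi
  gap <- abs(grid$xc - 5) < 2
  expect_gt(median(psi_soft[gap]), median(psi_stiff[gap]))
})
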