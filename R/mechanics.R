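#' Homogenized element properties from tissue composition
#'
#' Material constants per element are fraction-weighted arithmetic means of
#' the constituent tissue properties, with fractions renormalized over the
#' solid constituents (rule of mixtures). The homogenized Young's modulus
#' is therefore always bounded by the min/max constituent modulus.
#'
#' @param composition composition matrix (see [new_composition()]).
#' @param props per-material property table, default [tissue_properties()].
#' @return data.frame with per-element `E` (MPa), `nu`, `k` (mm2).
#' @export
homogenize_properties <- function(composition, props = tissue_properties()) {
  check_composition(composition)
  if (!identical(colnames(composition), rownames(props)))
    stop("composition columns must match the property table materials")
  solid <- rowSums(composition)
  if (any(solid <= 0))
    stop("cannot homogenize an empty composition (no solid constituents)")
  data.frame(E = as.numeric(composition %*% props$E) / solid,
             nu = as.numeric(composition %*% props$nu) / solid,
             k = as.numeric(composition %*% props$k) / solid)
}

# Homogenization with a soft floor for (near-)void elements, used by the
# mechanical assembly: an element with almost no solid content must not
# make the stiffness matrix singular, so it gets a compliant filler.
mech_properties <- function(composition, props = tissue_properties(),
                            E_void = 5e-3, nu_void = 0.05, s_min = 0.01) {
  solid <- rowSums(composition)
  E <- rep(E_void, nrow(composition))
  nu <- rep(nu_void, nrow(composition))
  ok <- solid >= s_min
  if (any(ok)) {
    E[ok] <- as.numeric(composition[ok, , drop = FALSE] %*% props$E) / solid[ok]
    nu[ok] <- as.numeric(composition[ok, , drop = FALSE] %*% props$nu) / solid[ok]
  }
  list(E = E, nu = nu)
}

# Geometry-only parts of the Q4 plane-strain element stiffness for an
# hx-by-hy rectangle: Ke = lambda * Klam + mu * Kmu (Lame split of the
# plane-strain constitutive matrix), integrated with 2x2 Gauss quadrature.
q4_reference_stiffness <- function(hx, hy) {
  gp <- 1 / sqrt(3)
  pts <- expand.grid(xi = c(-gp, gp), eta = c(-gp, gp))
  Clam <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)
  Cmu <- diag(c(2, 2, 1))
  Klam <- matrix(0, 8, 8)
  Kmu <- matrix(0, 8, 8)
  detJ <- hx * hy / 4
  for (q in seq_len(nrow(pts))) {
    xi <- pts$xi[q]; eta <- pts$eta[q]
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dNdx <- dNdxi * 2 / hx
    dNdy <- dNdeta * 2 / hy
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    Klam <- Klam + t(B) %*% Clam %*% B * detJ
    Kmu <- Kmu + t(B) %*% Cmu %*% B * detJ
  }
  list(Klam = Klam, Kmu = Kmu)
}

# Element -> global DOF incidence for the node mesh of a sim_grid.
# Node (i, j) has id i + (j-1)(nx+1); element nodes are numbered CCW.
q4_edof <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  ei <- rep(seq_len(nx), times = ny)
  ej <- rep(seq_len(ny), each = nx)
  n1 <- ei + (ej - 1L) * (nx + 1L)
  n2 <- n1 + 1L
  n3 <- n2 + (nx + 1L)
  n4 <- n1 + (nx + 1L)
  nodes <- cbind(n1, n2, n3, n4)
  edof <- matrix(0L, nrow = grid$nc, ncol = 8L)
  edof[, c(1, 3, 5, 7)] <- 2L * nodes - 1L
  edof[, c(2, 4, 6, 8)] <- 2L * nodes
  edof
}

# Node coordinates of the FE mesh (length (nx+1)*(ny+1) each).
grid_nodes <- function(grid) {
  x <- seq(0, grid$Lx, length.out = grid$nx + 1L)
  y <- seq(0, grid$Ly, length.out = grid$ny + 1L)
  list(x = rep(x, times = grid$ny + 1L), y = rep(y, each = grid$nx + 1L),
       nn = (grid$nx + 1L) * (grid$ny + 1L))
}

# General linear solve: assemble, apply Dirichlet values, optionally tie a
# set of x-DOFs to one master DOF (rigid platen) with a grounded spring of
# stiffness k_master and an applied force f_master on the master.
fe_solve <- function(grid, E, nu, dirichlet_dofs = integer(),
                     dirichlet_vals = numeric(), platen_nodes = NULL,
                     k_master = 0, f_master = 0, point_forces = NULL) {
  nc <- grid$nc
  E <- rep_len(E, nc); nu <- rep_len(nu, nc)
  if (any(E <= 0) || any(nu < 0) || any(nu >= 0.5))
    stop("element properties must satisfy E > 0, 0 <= nu < 0.5")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  ref <- q4_reference_stiffness(grid$hx, grid$hy)
  edof <- q4_edof(grid)
  nd <- grid_nodes(grid)
  ndof <- 2L * nd$nn
  ridx <- rep(1:8, times = 8)
  cidx <- rep(1:8, each = 8)
  ii <- as.vector(t(edof[, ridx]))
  jj <- as.vector(t(edof[, cidx]))
  vlam <- as.vector(ref$Klam)
  vmu <- as.vector(ref$Kmu)
  xx <- as.vector(t(outer(lam, vlam) + outer(mu, vmu)))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))

  # reduced-DOF map: 0 = fixed, shared positive id = tied to the platen
  dmap <- integer(ndof)
  free <- rep(TRUE, ndof)
  free[dirichlet_dofs] <- FALSE
  master_id <- NA_integer_
  platen_dofs <- integer()
  if (!is.null(platen_nodes) && length(platen_nodes)) {
    platen_dofs <- setdiff(2L * platen_nodes - 1L, dirichlet_dofs)
  }
  is_platen <- rep(FALSE, ndof)
  is_platen[platen_dofs] <- TRUE
  ordinary <- which(free & !is_platen)
  dmap[ordinary] <- seq_along(ordinary)
  nred <- length(ordinary)
  if (length(platen_dofs)) {
    master_id <- nred + 1L
    dmap[platen_dofs] <- master_id
    nred <- nred + 1L
  }
  Tm <- Matrix::sparseMatrix(i = which(dmap > 0), j = dmap[dmap > 0], x = 1,
                             dims = c(ndof, nred))
  ud <- numeric(ndof)
  ud[dirichlet_dofs] <- dirichlet_vals
  Ffull <- numeric(ndof)
  if (!is.null(point_forces))
    Ffull[point_forces$dof] <- Ffull[point_forces$dof] + point_forces$value
  Kred <- Matrix::t(Tm) %*% K %*% Tm
  Fred <- as.numeric(Matrix::t(Tm) %*% (Ffull - K %*% ud))
  if (!is.na(master_id)) {
    Kred[master_id, master_id] <- Kred[master_id, master_id] + k_master
    Fred[master_id] <- Fred[master_id] + f_master
  }
  ured <- tryCatch(as.numeric(Matrix::solve(Kred, Fred)),
                   error = function(e) stop("singular mechanical system: ",
                                            conditionMessage(e)))
  u <- as.numeric(Tm %*% ured) + ud
  list(u = u, ux = u[seq(1, ndof, 2)], uy = u[seq(2, ndof, 2)],
       master_disp = if (is.na(master_id)) NA_real_ else ured[master_id])
}

#' Quasi-static plane-strain displacement solve of the fixated construct
#'
#' Linear elastic solve of the loaded half-section under the daily gait
#' load: the distal face (x = 0) is fixed axially, the cylinder axis
#' (y = 0) is a symmetry plane, the proximal face (x = Lx) is tied to a
#' rigid end plate that carries the applied axial load, and the external
#' fixator acts as an axial spring between the end plates (the distal
#' plate being fixed, a grounded spring of the fixator stiffness on the
#' platen DOF).
#'
#' @param grid a [sim_grid()].
#' @param element_props list/data.frame with per-element `E` (MPa) and `nu`.
#' @param load a [load_case()].
#' @return list with nodal displacement vectors `ux`, `uy` (mm), the raw
#'   DOF vector `u` and the platen axial displacement `master_disp`.
#' @export
solve_displacements <- function(grid, element_props, load = load_case()) {
  nd <- grid_nodes(grid)
  tol <- 1e-9
  distal <- which(nd$x < tol)
  axis <- which(nd$y < tol)
  proximal <- which(nd$x > grid$Lx - tol)
  dir_dofs <- c(2L * distal - 1L, 2L * axis)
  fe_solve(grid, element_props$E, element_props$nu,
           dirichlet_dofs = dir_dofs,
           dirichlet_vals = numeric(length(dir_dofs)),
           platen_nodes = proximal,
           k_master = load$fixator_stiffness,
           f_master = -load$axial_load)
}

#' Axial load case of the fixated rat femur
#'
#' @param axial_load peak axial gait load, N (applied in compression).
#' @param fixator_stiffness axial stiffness of the external fixator, N/mm.
#' @return list of class `load_case`.
#' @export
load_case <- function(axial_load = 14.4, fixator_stiffness = 277) {
  stopifnot(axial_load >= 0, fixator_stiffness >= 0)
  structure(list(axial_load = axial_load,
                 fixator_stiffness = fixator_stiffness),
            class = "load_case")
}

#' Element strains and the distortional mechanical stimulus
#'
#' Evaluates the small-strain tensor at each element centroid and the
#' scalar stimulus psi driving tissue differentiation: the second invariant
#' J2 of the deviatoric strain tensor (with the plane-strain out-of-plane
#' strain of zero included in the deviator), reported by default as
#' `sqrt(J2)` so the stimulus is first order in strain. psi is zero for
#' purely volumetric strain states and invariant under rotations.
#'
#' @param grid a [sim_grid()].
#' @param displacements result of [solve_displacements()] (or any list
#'   with a DOF vector `u`).
#' @param form `"sqrtJ2"` (default) or `"J2"`.
#' @return list with per-element `exx`, `eyy`, `exy` and `psi`.
#' @export
compute_stimulus <- function(grid, displacements, form = c("sqrtJ2", "J2")) {
  form <- match.arg(form)
  u <- displacements$u
  edof <- q4_edof(grid)
  ux <- matrix(u[edof[, c(1, 3, 5, 7)]], ncol = 4)
  uy <- matrix(u[edof[, c(2, 4, 6, 8)]], ncol = 4)
  sx <- c(-1, 1, 1, -1) / (2 * grid$hx)
  sy <- c(-1, -1, 1, 1) / (2 * grid$hy)
  exx <- as.numeric(ux %*% sx)
  eyy <- as.numeric(uy %*% sy)
  exy <- 0.5 * (as.numeric(ux %*% sy) + as.numeric(uy %*% sx))
  psi <- strain_invariant_psi(exx, eyy, exy, form)
  list(exx = exx, eyy = eyy, exy = exy, psi = psi)
}

#' @rdname compute_stimulus
#' @param exx,eyy,exy in-plane small-strain components (plane strain,
#'   `ezz = 0`); `exy` is the tensorial shear strain.
#' @export
strain_invariant_psi <- function(exx, eyy, exy, form = c("sqrtJ2", "J2")) {
  form <- match.arg(form)
  tr <- exx + eyy  # ezz = 0
  dxx <- exx - tr / 3
  dyy <- eyy - tr / 3
  dzz <- -tr / 3
  J2 <- 0.5 * (dxx^2 + dyy^2 + dzz^2 + 2 * exy^2)
  if (form == "sqrtJ2") sqrt(J2) else J2
}
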