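#' Cells blocked from MSC migration
#'
#' MSCs cannot migrate through a control volume whose dominant content is
#' mineralized tissue (woven bone, cortical bone or calcified cartilage):
#' a cell is blocked when the mineralized fraction exceeds the threshold.
#' All fluxes through faces touching a blocked cell are zero.
#'
#' @param composition composition matrix (see [new_composition()]).
#' @param threshold mineralized-fraction threshold in `(0, 1]`.
#' @return logical vector, `TRUE` where migration is blocked.
#' @export
migration_mask <- function(composition,
                           threshold = motility_params()$mineral_block_threshold) {
  mineral_fraction(composition) > threshold
}

#' Advance MSC migration by one macro step
#'
#' Conservative finite-volume update of the Keller--Segel type flux
#' `-D(a) grad c + c chi_eff grad g` with zero-flux outer boundaries.
#' The chemotactic sensitivity is gel-gated and BMP-2 modulated:
#' `chi_eff = chi0 (1 - a) * chemotaxis_fold(g, MSC)` (the mechanical
#' baseline times the chemical fold), its face drift speed saturating at
#' `v_chemo_max`. Chemotaxis is integrated explicitly with donor-cell
#' upwinding under a positivity-preserving CFL sub-cycle; random motility
#' is integrated implicitly. Faces touching a mineral-blocked or
#' medium-free cell carry no flux, so mass is conserved exactly and the
#' field stays non-negative by construction of the scheme.
#'
#' @param cs MSC concentration field, cells/cm3.
#' @param a normalized alginate field.
#' @param g free BMP-2 field, ng/cm3.
#' @param composition composition matrix (for the mineral block rule).
#' @param dt macro step, day.
#' @param grid a [sim_grid()].
#' @param params a [motility_params()].
#' @param curves modulation curve set.
#' @param open logical mask of cells containing a migratable medium
#'   (solid tissue or gel); closed (void) cells are impenetrable.
#' @return updated MSC field.
#' @export
transport_step <- function(cs, a, g, composition, dt, grid,
                           params = motility_params(),
                           curves = default_modulation_curves(),
                           open = NULL) {
  stopifnot(dt > 0, length(cs) == grid$nc)
  if (any(cs < 0)) stop("cell concentrations must be >= 0")
  blocked <- migration_mask(composition, params$mineral_block_threshold)
  if (!is.null(open)) blocked <- blocked | !open
  mob <- cell_mobility(a, params)
  chi_eff <- mob$chi * chemotaxis_fold(g, "MSC", curves)
  f <- grid_faces(grid)
  vcap <- params$v_chemo_max
  vx <- 0.5 * (chi_eff[f$xk1] + chi_eff[f$xk2]) *
    (g[f$xk2] - g[f$xk1]) / grid$hx
  vy <- 0.5 * (chi_eff[f$yk1] + chi_eff[f$yk2]) *
    (g[f$yk2] - g[f$yk1]) / grid$hy
  vx <- pmin(pmax(vx, -vcap), vcap)
  vy <- pmin(pmax(vy, -vcap), vcap)
  vx[blocked[f$xk1] | blocked[f$xk2]] <- 0
  vy[blocked[f$yk1] | blocked[f$yk2]] <- 0
  vmax <- max(abs(vx), abs(vy), 0)
  if (vmax > 0) {
    dt_cfl <- 0.9 / (2 * vmax / grid$hx + 2 * vmax / grid$hy)
    nsub <- max(1L, ceiling(dt / dt_cfl))
    h <- dt / nsub
    for (s in seq_len(nsub)) {
      fx <- ifelse(vx > 0, vx * cs[f$xk1], vx * cs[f$xk2])
      fy <- ifelse(vy > 0, vy * cs[f$yk1], vy * cs[f$yk2])
      delta <- numeric(grid$nc)
      delta[f$xk1] <- delta[f$xk1] - fx / grid$hx
      delta[f$xk2] <- delta[f$xk2] + fx / grid$hx
      delta[f$yk1] <- delta[f$yk1] - fy / grid$hy
      delta[f$yk2] <- delta[f$yk2] + fy / grid$hy
      cs <- cs + h * delta
    }
  }
  cs <- diffuse_implicit(grid, cs, mob$D, dt, open = !blocked)
  cs[cs < 0 & cs > -1e-9 * max(cs, 1)] <- 0  # linear-solver round-off only
  if (any(!is.finite(cs)) || any(cs < 0))
    stop("cell transport produced a negative or non-finite concentration")
  cs
}
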