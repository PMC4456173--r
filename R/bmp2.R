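#' BMP-2 field state
#'
#' Two pools are tracked on the grid: the free concentration `g` moving in
#' the tissue fluid and the encapsulated concentration `g_gel` bound inside
#' the alginate carrier (both ng/cm3). Encapsulated BMP-2 degrades with its
#' in-gel half-life and is gradually handed over to the free pool as the
#' gel degrades; only the free pool diffuses, is consumed and signals.
#'
#' @param g free BMP-2 field, ng/cm3, >= 0.
#' @param g_gel encapsulated BMP-2 field, ng/cm3, >= 0.
#' @return object of class `bmp_state`.
#' @export
bmp_state <- function(g, g_gel = numeric(length(g)) ) {
  if (any(g < 0) || any(g_gel < 0)) stop("BMP-2 concentrations must be >= 0")
  if (length(g) != length(g_gel)) stop("g and g_gel must match in length")
  structure(list(g = as.numeric(g), g_gel = as.numeric(g_gel)),
            class = "bmp_state")
}

#' Background BMP-2 consumption rate (receptor endocytosis)
#'
#' Michaelis--Menten uptake of free BMP-2 by MSCs and bone cells, the main
#' consumers: rate `Vmax g / (Kma + g)` with `Vmax = (cs + cb) *
#' v_max_per_cell`, saturating at `Vmax` for large g.
#'
#' @param g free BMP-2, ng/cm3.
#' @param cs,cb MSC and bone-cell concentrations, cells/cm3.
#' @param params a [bmp_params()].
#' @return consumption rate, ng cm-3 day-1.
#' @export
background_consumption_rate <- function(g, cs, cb, params = bmp_params()) {
  if (any(g < 0) || any(cs < 0) || any(cb < 0))
    stop("concentrations must be >= 0")
  vmax <- (cs + cb) * params$v_max_per_cell
  vmax * g / (params$Kma + g)
}

#' BMP-2 production rate by cells
#'
#' Cells secrete BMP-2 faster when ambient levels are sub-physiological:
#' rate `alpha_prod (cs + cb) / (gamma g + gamma0)`, strictly decreasing in
#' g. Together with the background consumption this maintains the
#' homeostatic physiological band when cells are present.
#'
#' @inheritParams background_consumption_rate
#' @return production rate, ng cm-3 day-1.
#' @export
production_rate <- function(g, cs, cb, params = bmp_params()) {
  if (any(g < 0) || any(cs < 0) || any(cb < 0))
    stop("concentrations must be >= 0")
  params$alpha_prod * (cs + cb) / (params$gamma * g + params$gamma0)
}

#' Homeostatic free BMP-2 concentration for a resident cell population
#'
#' Solves production = degradation + background consumption for a uniform
#' population of `c_total` cells (no diffusion, no gel): the concentration
#' at which healthy, fully populated tissue self-maintains. With the
#' default constants and cells at carrying density this lies inside the
#' physiological band.
#'
#' @param c_total resident cell concentration, cells/cm3.
#' @param params a [bmp_params()].
#' @return equilibrium concentration, ng/cm3 (0 when `c_total` is 0).
#' @export
homeostatic_g <- function(c_total, params = bmp_params()) {
  stopifnot(length(c_total) == 1L, c_total >= 0)
  if (c_total == 0) return(0)
  bal <- function(g) production_rate(g, c_total, 0, params) -
    degradation_rate(g, params) -
    background_consumption_rate(g, c_total, 0, params)
  stats::uniroot(bal, c(1e-8, 1e4), tol = 1e-12)$root
}

#' First-order in vivo degradation rate of free BMP-2
#'
#' Exponential decay with the in vivo half-life: `dg/dt = -lambda g`,
#' `lambda = ln 2 / t_half_free`.
#'
#' @inheritParams background_consumption_rate
#' @return degradation rate, ng cm-3 day-1 (loss, reported positive).
#' @export
degradation_rate <- function(g, params = bmp_params()) {
  params$lambda_free * g
}

#' Consumption of BMP-2 by differentiation events
#'
#' Wherever an MSC differentiation event towards the chondrogenic or
#' osteogenic fate occurred in a control volume during the step, all free
#' BMP-2 above the minimal physiological level is consumed, leaving
#' exactly `g_min`. Fibroblastic events do not consume BMP-2. The sink
#' never drives g below `g_min`.
#'
#' @param g free BMP-2 field, ng/cm3.
#' @param event_mask logical field, `TRUE` where a chondro/osteogenic
#'   differentiation event occurred.
#' @param g_min minimal physiological concentration, ng/cm3.
#' @return updated g field.
#' @export
differentiation_sink <- function(g, event_mask,
                                 g_min = bmp_params()$g_min) {
  stopifnot(length(g) == length(event_mask))
  ifelse(event_mask & g > g_min, g_min, g)
}

#' Advance the encapsulated BMP-2 pool by one step
#'
#' The in-gel pool decays with total rate `lambda_gel + lambda_rel(a)`
#' where `lambda_rel(a) = lambda_rel0 (1 - a)`: the `lambda_gel` share is
#' destroyed by in-gel half-life degradation, the `lambda_rel` share is
#' released into the free pool. With `a` held over the step the update is
#' the exact exponential, split between the two channels in proportion to
#' their rates, so destroyed + released equals the pool decrease exactly.
#'
#' @param g_gel encapsulated BMP-2 field, ng/cm3.
#' @param a normalized alginate field in `[0, 1]`.
#' @param dt time step, day, > 0.
#' @param params a [bmp_params()].
#' @param gel_params an [alginate_params()].
#' @return list with `g_gel` (updated field), `released` and `destroyed`
#'   (ng/cm3 transferred over the step).
#' @export
gel_pool_step <- function(g_gel, a, dt, params = bmp_params(),
                          gel_params = alginate_params()) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(a < 0) || any(a > 1)) stop("a must lie in [0, 1]")
  lam_rel <- gel_params$lambda_rel0 * (1 - a)
  lam_tot <- params$lambda_gel + lam_rel
  g_new <- g_gel * exp(-lam_tot * dt)
  loss <- g_gel - g_new
  released <- ifelse(lam_tot > 0, loss * lam_rel / lam_tot, 0)
  list(g_gel = g_new, released = released, destroyed = loss - released)
}

#' Effective BMP-2 diffusivity inside partially degraded gel
#'
#' Linear blend of the intact-gel and gel-free endpoint diffusivities:
#' `D(a) = a D_gel + (1 - a) D_vivo`.
#'
#' @inheritParams gel_pool_step
#' @return diffusivity field, mm2/day.
#' @export
bmp_diffusivity <- function(a, params = bmp_params()) {
  a * params$D_gel + (1 - a) * params$D_vivo
}

#' Advance the BMP-2 balance by one macro step
#'
#' Operator-split update of the free and encapsulated pools: (1) exact
#' in-gel decay and release; (2) differentiation-event sink to `g_min`;
#' (3) sub-cycled reactions -- Michaelis--Menten background consumption,
#' half-life degradation and cell production, integrated with an
#' exponential update of the g-proportional losses so the field can never
#' go negative; (4) implicit diffusion with gel-blended diffusivity and
#' zero-flux outer boundaries.
#'
#' @param state a [bmp_state()].
#' @param a normalized alginate field.
#' @param cs,cb MSC and bone-cell fields, cells/cm3.
#' @param event_mask logical differentiation-event field.
#' @param dt macro step, day.
#' @param grid a [sim_grid()].
#' @param params a [bmp_params()].
#' @param gel_params an [alginate_params()].
#' @param open logical mask of cells containing a medium (tissue or gel);
#'   closed cells exchange no BMP-2.
#' @param dt_react reaction sub-cycle step, day.
#' @return updated [bmp_state()] with attribute `released_total` (ng).
#' @export
step_bmp2 <- function(state, a, cs, cb, event_mask, dt, grid,
                      params = bmp_params(), gel_params = alginate_params(),
                      open = NULL, dt_react = 0.05) {
  stopifnot(inherits(state, "bmp_state"), dt > 0)
  if (is.null(open)) open <- rep(TRUE, grid$nc)
  gp <- gel_pool_step(state$g_gel, a, dt, params, gel_params)
  g <- state$g + gp$released
  g <- differentiation_sink(g, event_mask, params$g_min)
  nsub <- max(1L, ceiling(dt / dt_react))
  h <- dt / nsub
  cells <- cs + cb
  for (s in seq_len(nsub)) {
    lam_eff <- params$lambda_free +
      cells * params$v_max_per_cell / (params$Kma + g)
    prod <- production_rate(g, cs, cb, params)
    g <- g * exp(-lam_eff * h) + prod * h
  }
  g <- diffuse_implicit(grid, g, bmp_diffusivity(a, params) * open, dt, open)
  g[g < 0 & g > -1e-12] <- 0  # round-off from the linear solver only
  if (any(!is.finite(g)) || any(g < 0))
    stop("BMP-2 step produced a negative or non-finite concentration")
  out <- bmp_state(g, gp$g_gel)
  attr(out, "released_total") <- sum(gp$released) * grid$area
  out
}
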