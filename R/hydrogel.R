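#' Advance the alginate field by one step
#'
#' The normalized alginate amount decays pointwise with rate
#' `lambda_deg_bulk + c * lambda_deg_cell`: slow bulk hydrolysis plus
#' cell-driven destabilisation of the ionic cross-links proportional to the
#' local total cell concentration. The update is the exact exponential for
#' the cell field held over the step, so `a` stays in `[0, 1]` and is
#' monotone non-increasing unconditionally.
#'
#' @param a normalized alginate field in `[0, 1]`.
#' @param c_total total cell concentration field, cells/cm3, >= 0.
#' @param dt time step, day, > 0.
#' @param params an [alginate_params()].
#' @return updated alginate field.
#' @export
alginate_step <- function(a, c_total, dt, params = alginate_params()) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(a < 0) || any(a > 1)) stop("a must lie in [0, 1]")
  if (any(c_total < 0)) stop("cell concentrations must be >= 0")
  a * exp(-(params$lambda_deg_bulk + c_total * params$lambda_deg_cell) * dt)
}

#' Cell motility inside (partially degraded) hydrogel
#'
#' Random motility and chemotactic sensitivity scale linearly with the
#' free (non-gel) volume: `D = D0 (1 - a)` and `chi = chi0 (1 - a)`. A weak
#' random-migration floor `eps_D_frac * D0` is retained even in intact gel
#' (dense gels impede but do not perfectly freeze cells); chemotaxis is
#' fully blocked at `a = 1`.
#'
#' @param a normalized alginate amount in `[0, 1]` (scalar or field).
#' @param params a [motility_params()].
#' @return list with fields `D` (mm2/day) and `chi`
#'   (mm2 day-1 (ng/cm3)-1), same length as `a`.
#' @export
cell_mobility <- function(a, params = motility_params()) {
  if (any(a < 0) || any(a > 1)) stop("a must lie in [0, 1]")
  eps <- params$eps_D_frac * params$D0
  list(D = params$D0 * (1 - a) + eps * a,
       chi = params$chi0 * (1 - a))
}
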