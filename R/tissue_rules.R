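#' Cell population fields
#'
#' Concentrations (cells/cm3) of the five populations tracked per control
#' volume: migrating MSCs `cs`, and the stationary differentiated
#' populations -- bone cells `cb`, chondrocytes `cc`,
#' hypertrophic/calcifying chondrocytes `ch` and fibroblasts `cf`.
#' Differentiated cells act as in-place matrix producers; only MSCs move.
#'
#' @param nc number of cells, or a [sim_grid()].
#' @return list of class `cell_fields` with zero-initialised fields.
#' @export
cell_fields <- function(nc) {
  if (inherits(nc, "sim_grid")) nc <- nc$nc
  z <- numeric(nc)
  structure(list(cs = z, cb = z, cc = z, ch = z, cf = z),
            class = "cell_fields")
}

total_cells <- function(cells) {
  cells$cs + cells$cb + cells$cc + cells$ch + cells$cf
}

#' MSC proliferation under BMP-2 modulation
#'
#' Logistic growth towards the carrying density at the baseline rate
#' multiplied by the dose-dependent proliferation fold (the
#' mechano-chemical coupling: chemically modulated rate = mechanical
#' baseline x fold). Proliferation, like all cellular activity, requires
#' at least the minimal physiological BMP-2 concentration. The update is
#' the exact logistic solution for rates held over the step, so the field
#' stays in `[0, c_max]`.
#'
#' @param cs MSC field, cells/cm3.
#' @param g free BMP-2 field, ng/cm3.
#' @param dt time step, day.
#' @param thresholds a [rule_thresholds()].
#' @param curves modulation curve set.
#' @param active optional logical mask of cells where proliferation can
#'   occur at all (e.g. a medium is present); combined with the BMP-2 gate.
#' @param c_other concentration of non-proliferating occupants
#'   (differentiated cells) competing for the same space; the logistic
#'   carrying density available to MSCs is `c_max - c_other`.
#' @return updated MSC field.
#' @export
proliferate <- function(cs, g, dt, thresholds = rule_thresholds(),
                        curves = default_modulation_curves(),
                        active = NULL, c_other = 0) {
  stopifnot(dt > 0)
  if (is.null(active)) active <- rep(TRUE, length(cs))
  act <- active & differentiation_allowed(g)
  r <- thresholds$r_prolif * proliferation_fold(g, curves)
  K <- thresholds$c_max
  Keff <- K - c_other
  # exact solution of dc/dt = (r/K) c (Keff - c); also valid for Keff <= 0
  # (overcrowded volumes relax downward); the Keff -> 0 limit is the
  # pure quadratic decay c0 / (1 + r c0 t / K)
  eg <- exp(-r * Keff * dt / K)
  cs_new <- ifelse(abs(Keff) > K * 1e-12,
                   Keff * cs / (cs + (Keff - cs) * eg),
                   cs / (1 + r * cs * dt / K))
  cs_new[cs == 0] <- 0
  ifelse(act, cs_new, cs)
}

#' Mechanoregulated, BMP-2-gated MSC differentiation
#'
#' Where the BMP-2 gate is open (`g >= g_min`) and the mechanical stimulus
#' exceeds the dormancy floor, MSCs commit at the baseline rate `r_diff`
#' to the fate selected by the stimulus band: bone cells for
#' `psi <= psi_bone_max`, chondrocytes up to `psi_cartilage_max`, and
#' fibroblasts above. Chondro/osteogenic commitments above the minimal
#' event density set the BMP-2 event mask (the subsequent event sink
#' drains free BMP-2 to `g_min`); fibroblastic commitments never do.
#'
#' @param cells a [cell_fields()].
#' @param psi mechanical stimulus field (dimensionless).
#' @param g free BMP-2 field, ng/cm3.
#' @inheritParams proliferate
#' @return list with `cells` (updated), `event_mask` (logical field) and
#'   `record`, a data.frame of per-cell fate flags and converted amounts.
#' @export
differentiate <- function(cells, psi, g, dt, thresholds = rule_thresholds(),
                          curves = default_modulation_curves(),
                          active = NULL) {
  stopifnot(inherits(cells, "cell_fields"), dt > 0)
  if (is.null(active)) active <- rep(TRUE, length(cells$cs))
  gate <- active & differentiation_allowed(g) &
    psi > thresholds$psi_resorb_min
  osteo <- gate & psi <= thresholds$psi_bone_max
  chondro <- gate & psi > thresholds$psi_bone_max &
    psi <= thresholds$psi_cartilage_max
  fibro <- gate & psi > thresholds$psi_cartilage_max
  frac <- 1 - exp(-thresholds$r_diff * dt)
  dcs <- ifelse(gate, cells$cs * frac, 0)
  cells$cs <- cells$cs - dcs
  cells$cb <- cells$cb + dcs * osteo
  cells$cc <- cells$cc + dcs * chondro
  cells$cf <- cells$cf + dcs * fibro
  event_mask <- (osteo | chondro) & dcs >= thresholds$c_event_min
  list(cells = cells, event_mask = event_mask,
       record = data.frame(osteo = osteo, chondro = chondro, fibro = fibro,
                           converted = dcs))
}

#' Chondrocyte maturation and extracellular matrix production
#'
#' Three coupled processes update the tissue composition: (1) chondrocytes
#' hypertrophy at `r_mature * hypertrophy_fold(g)` and their cartilage
#' matrix calcifies in proportion to the hypertrophic share of the local
#' chondral population; (2) calcified cartilage is replaced by woven bone
#' (endochondral ossification) at `r_endochondral`, the resident
#' hypertrophic chondrocytes being replaced by bone cells at the same
#' rate; (3) matrix is produced in place -- woven bone linearly in the
#' bone-cell concentration times `bone_production_fold(g)`, cartilage
#' linearly in chondrocytes, fibrous tissue linearly in fibroblasts (the
#' fibroblastic pathway is BMP-2 independent, all others require
#' `g >= g_min`). Newly produced matrix fills void space first, then
#' displaces debris, then granulation tissue; production is capped by the
#' displaceable space so fractions stay valid.
#'
#' @param cells a [cell_fields()].
#' @param composition composition matrix.
#' @param psi mechanical stimulus field (unused by the default rules but
#'   part of the rule surface for stimulus-windowed variants).
#' @param g free BMP-2 field, ng/cm3.
#' @param dt time step, day.
#' @param thresholds a [rule_thresholds()].
#' @param curves modulation curve set.
#' @param immutable logical mask of elements whose composition never
#'   changes (cortical bone regions).
#' @return list with updated `composition` and `cells`.
#' @export
mature_and_produce <- function(cells, composition, psi, g, dt,
                               thresholds = rule_thresholds(),
                               curves = default_modulation_curves(),
                               immutable = NULL) {
  stopifnot(inherits(cells, "cell_fields"), dt > 0)
  nc <- nrow(composition)
  if (is.null(immutable)) immutable <- rep(FALSE, nc)
  act <- differentiation_allowed(g) & !immutable
  th <- thresholds

  # (1) hypertrophy and calcification
  hfold <- hypertrophy_fold(g, curves)
  mfrac <- ifelse(act, 1 - exp(-th$r_mature * hfold * dt), 0)
  dcc <- cells$cc * mfrac
  chondral <- cells$cc + cells$ch
  w_h <- ifelse(chondral > 0, cells$ch / chondral, 0)
  dcalc <- composition[, "cartilage"] * mfrac * w_h
  cells$cc <- cells$cc - dcc
  cells$ch <- cells$ch + dcc
  composition[, "cartilage"] <- composition[, "cartilage"] - dcalc
  composition[, "calcified_cartilage"] <-
    composition[, "calcified_cartilage"] + dcalc

  # (2) endochondral replacement by woven bone
  efrac <- ifelse(act, 1 - exp(-th$r_endochondral * dt), 0)
  dendo <- composition[, "calcified_cartilage"] * efrac
  composition[, "calcified_cartilage"] <-
    composition[, "calcified_cartilage"] - dendo
  composition[, "woven"] <- composition[, "woven"] + dendo
  dch <- cells$ch * efrac
  cells$ch <- cells$ch - dch
  cells$cb <- cells$cb + dch

  # (3) matrix production into displaceable space
  bfold <- bone_production_fold(g, curves)
  d_woven <- ifelse(act, th$r_bone_matrix * cells$cb * bfold * dt, 0)
  d_cart <- ifelse(act, th$r_cart_matrix * cells$cc * dt, 0)
  d_fib <- ifelse(immutable, 0, th$r_fib_matrix * cells$cf * dt)
  total <- d_woven + d_cart + d_fib
  void <- pmax(0, 1 - rowSums(composition))
  cap <- void + composition[, "debris"] + composition[, "granulation"]
  scale <- ifelse(total > cap & total > 0, cap / total, 1)
  d_woven <- d_woven * scale
  d_cart <- d_cart * scale
  d_fib <- d_fib * scale
  total <- total * scale
  use_void <- pmin(void, total)
  rem <- total - use_void
  use_debris <- pmin(composition[, "debris"], rem)
  use_gran <- pmin(composition[, "granulation"], rem - use_debris)
  composition[, "debris"] <- composition[, "debris"] - use_debris
  composition[, "granulation"] <- composition[, "granulation"] - use_gran
  composition[, "woven"] <- composition[, "woven"] + d_woven
  composition[, "cartilage"] <- composition[, "cartilage"] + d_cart
  composition[, "fibrous"] <- composition[, "fibrous"] + d_fib
  # numerical guard: keep fractions valid against round-off
  composition[composition < 0] <- 0
  over <- rowSums(composition)
  bad <- over > 1
  if (any(bad))
    composition[bad, ] <- composition[bad, ] / over[bad]
  list(composition = composition, cells = cells)
}
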