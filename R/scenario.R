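#' Define a healing scenario
#'
#' A scenario bundles the idealized rat-femur geometry (2D longitudinal
#' half-section of a cylinder with unit thickness), the treatment (gap
#' size, hydrogel, BMP-2 dose), the fixation and load, the time horizon
#' and every model parameter set. Geometry defaults beyond the gap size
#' are reconstructions of the idealized section: 20 mm modeled length,
#' 2 mm outer radius, 0.7 mm cortical wall, 0.2 mm periosteal/endosteal
#' progenitor strips, and (small-gap case only) a 1 mm periosteal callus
#' band over a 10 mm callus extent.
#'
#' @param gap_mm fracture gap / defect length, mm (2 = regular fracture,
#'   8 = critical-size defect).
#' @param gel_present is the defect filled with alginate hydrogel?
#' @param bmp2_dose_ug BMP-2 dose loaded in the gel, micrograms (requires
#'   `gel_present`).
#' @param horizon_days simulated time, day (42 for the 2 mm validation,
#'   84 for defect scenarios).
#' @param h target mesh edge length, mm.
#' @param length_mm,outer_radius_mm,cortex_mm,strip_mm,callus_band_mm,callus_length_mm
#'   geometry dimensions, mm.
#' @param with_callus include the outer periosteal callus band (default:
#'   only for gaps <= 4 mm).
#' @param load a [load_case()].
#' @param thresholds a [rule_thresholds()].
#' @param motility a [motility_params()].
#' @param bmp a [bmp_params()].
#' @param gel an [alginate_params()].
#' @param curves modulation curve set.
#' @param psi_form `"sqrtJ2"` or `"J2"` stimulus definition.
#' @param seed integer seed recorded with the run (the model itself is
#'   deterministic).
#' @return list of class `healing_scenario`.
#' @export
scenario <- function(gap_mm = 8, gel_present = TRUE, bmp2_dose_ug = 5,
                     horizon_days = if (gap_mm <= 4) 42 else 84,
                     h = 0.25, length_mm = 20, outer_radius_mm = 2,
                     cortex_mm = 0.7, strip_mm = 0.2, callus_band_mm = 1,
                     callus_length_mm = 10,
                     with_callus = gap_mm <= 4,
                     load = load_case(), thresholds = rule_thresholds(),
                     motility = motility_params(), bmp = bmp_params(),
                     gel = alginate_params(),
                     curves = default_modulation_curves(),
                     psi_form = c("sqrtJ2", "J2"), seed = 1L) {
  psi_form <- match.arg(psi_form)
  if (bmp2_dose_ug > 0 && !gel_present)
    stop("a BMP-2 dose requires the hydrogel carrier (gel_present = TRUE)")
  if (horizon_days <= 0) stop("horizon must be positive")
  if (gap_mm <= 0 || gap_mm >= length_mm - 2)
    stop("gap must be positive and leave cortical fragments on both sides")
  if (cortex_mm >= outer_radius_mm) stop("cortex thicker than the radius")
  structure(list(gap_mm = gap_mm, gel_present = gel_present,
                 bmp2_dose_ug = bmp2_dose_ug, horizon_days = horizon_days,
                 h = h, length_mm = length_mm,
                 outer_radius_mm = outer_radius_mm, cortex_mm = cortex_mm,
                 strip_mm = strip_mm, callus_band_mm = callus_band_mm,
                 callus_length_mm = callus_length_mm,
                 with_callus = with_callus, load = load,
                 thresholds = thresholds, motility = motility, bmp = bmp,
                 gel = gel, curves = curves, psi_form = psi_form,
                 seed = as.integer(seed)),
            class = "healing_scenario")
}

#' @export
print.healing_scenario <- function(x, ...) {
  cat(sprintf(paste0("<healing_scenario> %g mm gap, %s, %g ug BMP-2, ",
                     "%g days, h = %g mm\n"),
              x$gap_mm, if (x$gel_present) "alginate gel" else "no gel",
              x$bmp2_dose_ug, x$horizon_days, x$h))
  invisible(x)
}

#' Build the mesh, region masks and initial fields of a scenario
#'
#' The half-section spans `[0, length] x [0, Ly]` with the symmetry axis
#' at y = 0. Regions: medullary canal (marrow, modeled as debris tissue)
#' below the endosteal radius, cortical walls outside the gap, the gap
#' band itself (void if untreated, alginate if a gel is implanted, or
#' granulation tissue for the regular small fracture), and for the
#' small-gap case an outer callus band of granulation tissue. Endosteal
#' and periosteal strips adjacent to the intact cortex hold MSCs at the
#' source density; over the gap the periosteum is resected (large defect)
#' or intact (small fracture). Free BMP-2 starts at `g_min` in living
#' tissue and zero in void/gel; the encapsulated pool starts uniform over
#' the gel at dose / gel volume.
#'
#' @param sc a [scenario()].
#' @return list of class `healing_state` with the grid, masks,
#'   composition, cell/BMP/alginate fields and the scenario.
#' @export
build_scenario <- function(sc) {
  stopifnot(inherits(sc, "healing_scenario"))
  r_out <- sc$outer_radius_mm
  r_endo <- r_out - sc$cortex_mm
  peri_h <- sc$strip_mm
  Ly <- r_out + peri_h + if (sc$with_callus) sc$callus_band_mm else 0
  grid <- sim_grid(sc$length_mm, Ly, sc$h)
  x <- grid$xc; y <- grid$yc
  xm <- sc$length_mm / 2
  in_gap <- abs(x - xm) < sc$gap_mm / 2
  in_callus_x <- abs(x - xm) < sc$callus_length_mm / 2
  marrow <- y < r_endo & !in_gap
  cortex <- y >= r_endo & y < r_out & !in_gap
  peri_layer <- y >= r_out & y < r_out + peri_h & !in_gap
  defect <- in_gap & y < r_out + peri_h   # gap band incl. periosteal level
  callus <- if (sc$with_callus)
    y >= r_out + peri_h & in_callus_x else rep(FALSE, grid$nc)

  comp <- new_composition(grid$nc)
  comp[marrow, "debris"] <- 1
  comp[cortex, "cortical"] <- 1
  comp[peri_layer, "granulation"] <- 1
  comp[callus, "granulation"] <- 1
  a <- numeric(grid$nc)
  g_gel <- numeric(grid$nc)
  if (sc$gap_mm <= 4 && !sc$gel_present) {
    comp[defect, "granulation"] <- 1           # fracture hematoma
  } else if (sc$gel_present) {
    a[defect] <- 1
    comp[defect, "alginate"] <- 1
    if (sc$bmp2_dose_ug > 0) {
      vol_cm3 <- sum(defect) * grid$area * 1 / 1000  # unit thickness, mm3->cm3
      g_gel[defect] <- sc$bmp2_dose_ug * 1000 / vol_cm3
    }
  }                                            # else: defect left void

  solid <- solid_fraction(comp)
  open <- solid > 0.05
  # host tissue starts at the homeostatic BMP-2 level its resident cells
  # maintain, not at the bare physiological minimum
  g0 <- max(homeostatic_g(sc$thresholds$c_source, sc$bmp), sc$bmp$g_min)
  g <- ifelse(open & a == 0, g0, 0)

  endo_strip <- y >= r_endo - sc$strip_mm & y < r_endo & !in_gap
  peri_strip <- peri_layer
  if (sc$gap_mm <= 4) {
    # intact periosteum continues over the small gap at the callus base
    peri_strip <- peri_strip | (in_gap & y >= r_out & y < r_out + peri_h)
  }
  sources <- endo_strip | peri_strip
  cells <- cell_fields(grid)
  cells$cs[sources] <- sc$thresholds$c_source
  # host tissue is living and at cellular homeostasis: marrow stroma holds
  # progenitors and cortical bone holds resident bone cells, both of which
  # sustain the physiological BMP-2 balance of intact tissue
  cells$cs[marrow] <- pmax(cells$cs[marrow], sc$thresholds$c_source)
  cells$cb[cortex] <- sc$thresholds$c_source

  structure(list(grid = grid, scenario = sc, composition = comp,
                 cells = cells, bmp = bmp_state(g, g_gel), a = a,
                 masks = list(marrow = marrow, cortex = cortex,
                              defect = defect, gap = in_gap & y < r_out,
                              callus = callus, sources = sources,
                              gel = defect & sc$gel_present)),
            class = "healing_state")
}
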