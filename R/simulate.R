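#' Run a bone-healing simulation
#'
#' Daily macro time loop coupling all model components. Each day:
#' (1) homogenize element properties from the tissue composition, solve
#' the plane-strain mechanical problem under the gait load with the
#' fixator spring, and extract the distortional stimulus psi;
#' (2) MSC migration (gel-gated diffusion--chemotaxis with the mineral
#' block rule); (3) cell-fate rules -- differentiation by stimulus band
#' under the BMP-2 gate, logistic proliferation, hypertrophy and matrix
#' production; (4) BMP-2 balance step with the day's differentiation-event
#' mask (release from the gel, event sink, consumption/degradation/
#' production, diffusion); (5) alginate degradation; (6) summary record.
#' Progenitor source strips are replenished to the source density after
#' each transport step. The model is deterministic for a given scenario.
#'
#' @param sc a [scenario()] or a built [build_scenario()] state.
#' @param snapshot_days integer vector of days at which to keep full field
#'   snapshots (day 0 and the final day are always kept).
#' @param verbose print a progress line every 14 simulated days.
#' @return object of class `healing_sim`: list with `summary` (per-day
#'   data.frame), `final` (fields at the horizon), `snapshots`, `scenario`
#'   and the grid.
#' @export
simulate_healing <- function(sc, snapshot_days = integer(), verbose = FALSE) {
  state <- if (inherits(sc, "healing_state")) sc else build_scenario(sc)
  scn <- state$scenario
  grid <- state$grid
  th <- scn$thresholds
  comp <- state$composition
  cells <- state$cells
  bmp <- state$bmp
  a <- state$a
  masks <- state$masks
  gel0 <- masks$gel
  ndays <- as.integer(round(scn$horizon_days))

  rows <- vector("list", ndays + 1L)
  snaps <- list()
  psi <- numeric(grid$nc)
  record_row <- function(day, psi) {
    gap <- masks$gap
    # tissue = solid medium in the gap that is not majority gel; the
    # physiological-band comparison is defined on tissue, where cells live
    tis <- gap & solid_fraction(comp) > 0.05 & a < 0.5
    data.frame(
      day = day,
      bone_pct_defect = 100 * mean(bone_fraction(comp)[gap]),
      cartilage_pct_defect = 100 * mean((comp[, "cartilage"] +
        comp[, "calcified_cartilage"])[gap]),
      mean_g_defect = mean(bmp$g[gap]),
      mean_g_tissue_defect = if (any(tis)) mean(bmp$g[tis]) else NA_real_,
      max_g = max(bmp$g),
      mean_a_defect = if (any(gel0)) mean(a[gel0]) else 0,
      total_msc = field_total(grid, cells$cs),
      total_bone_cells = field_total(grid, cells$cb),
      total_chondrocytes = field_total(grid, cells$cc + cells$ch),
      total_fibroblasts = field_total(grid, cells$cf),
      psi_median_defect = stats::median(psi[gap]),
      psi_max = max(psi))
  }

  open_mask <- function() solid_fraction(comp) > 0.05
  take_snapshot <- function(day) {
    snaps[[as.character(day)]] <<- list(day = day, composition = comp,
                                        cells = cells, g = bmp$g,
                                        g_gel = bmp$g_gel, a = a, psi = psi)
  }

  rows[[1L]] <- record_row(0, psi)
  take_snapshot(0L)
  for (day in seq_len(ndays)) {
    open <- open_mask()
    # (1) mechanics
    mp <- mech_properties(comp)
    disp <- solve_displacements(grid, mp, scn$load)
    mech <- compute_stimulus(grid, disp, scn$psi_form)
    psi <- mech$psi
    # (2) MSC migration + sources
    cells$cs <- transport_step(cells$cs, a, bmp$g, comp, 1, grid,
                               scn$motility, scn$curves, open)
    cells$cs[masks$sources] <- pmax(cells$cs[masks$sources], th$c_source)
    # (3) cell fate and matrix rules; the periosteal/endosteal strips are
    # progenitor niches: they supply MSCs but commitment happens only in
    # the wound tissue they feed
    dd <- differentiate(cells, psi, bmp$g, 1, th, scn$curves,
                        open & !masks$sources)
    cells <- dd$cells
    cells$cs <- proliferate(cells$cs, bmp$g, 1, th, scn$curves, open,
                            c_other = total_cells(cells) - cells$cs)
    mm <- mature_and_produce(cells, comp, psi, bmp$g, 1, th, scn$curves,
                             immutable = masks$cortex)
    cells <- mm$cells
    comp <- mm$composition
    # (4) BMP-2 balance
    bmp <- step_bmp2(bmp, a, cells$cs, cells$cb, dd$event_mask, 1, grid,
                     scn$bmp, scn$gel, open)
    # (5) alginate degradation; gel fraction shrinks with a.
    # Cell-driven cross-link destabilisation is part of active tissue
    # invasion, so it carries the same BMP-2 activity gate as the other
    # cellular rules: quiescent cells that merely seeped in do not remodel.
    c_active <- total_cells(cells) * differentiation_allowed(bmp$g)
    a_new <- alginate_step(a, c_active, 1, scn$gel)
    # invading tissue replaces the degraded gel volume: freed space is
    # granulation (wound) tissue, not a cavity
    comp[gel0, "granulation"] <- comp[gel0, "granulation"] +
      (a - a_new)[gel0]
    comp[gel0, "alginate"] <- a_new[gel0]
    a <- a_new
    rows[[day + 1L]] <- record_row(day, psi)
    if (day %in% snapshot_days || day == ndays) take_snapshot(day)
    if (verbose && day %% 14 == 0)
      message(sprintf("day %3d: bone %5.1f%%, mean g %8.3g, mean a %.2f",
                      day, rows[[day + 1L]]$bone_pct_defect,
                      rows[[day + 1L]]$mean_g_defect,
                      rows[[day + 1L]]$mean_a_defect))
  }
  summary_df <- do.call(rbind, rows)
  structure(list(summary = summary_df,
                 final = list(composition = comp, cells = cells, g = bmp$g,
                              g_gel = bmp$g_gel, a = a, psi = psi),
                 snapshots = snaps, grid = grid, scenario = scn,
                 masks = masks),
            class = "healing_sim")
}

#' Week at which defect bone fill first crosses a threshold
#' @param sim a `healing_sim`.
#' @param pct threshold in percent of the defect area.
#' @return first crossing time in weeks (linear interpolation between
#'   days), or `NA` if never crossed.
#' @export
week_of_crossing <- function(sim, pct = 10) {
  s <- sim$summary
  i <- which(s$bone_pct_defect >= pct)
  if (!length(i)) return(NA_real_)
  i <- i[1L]
  if (i == 1L) return(s$day[1L] / 7)
  d0 <- s$day[i - 1L]; d1 <- s$day[i]
  b0 <- s$bone_pct_defect[i - 1L]; b1 <- s$bone_pct_defect[i]
  (d0 + (pct - b0) / (b1 - b0) * (d1 - d0)) / 7
}

#' @export
print.healing_sim <- function(x, ...) {
  s <- x$summary
  n <- nrow(s)
  cat(sprintf("<healing_sim> %g mm gap, %s, %g ug BMP-2, %d days\n",
              x$scenario$gap_mm,
              if (x$scenario$gel_present) "alginate gel" else "no gel",
              x$scenario$bmp2_dose_ug, s$day[n]))
  cat(sprintf("  defect bone fill: %.1f%% (day %d)\n",
              s$bone_pct_defect[n], s$day[n]))
  wk <- week_of_crossing(x, 10)
  cat(sprintf("  10%% bone crossing: %s\n",
              if (is.na(wk)) "never" else sprintf("week %.1f", wk)))
  if (x$scenario$gel_present)
    cat(sprintf("  alginate remaining: %.1f%%\n", 100 * s$mean_a_defect[n]))
  invisible(x)
}

#' @export
summary.healing_sim <- function(object, ...) {
  s <- object$summary
  n <- nrow(s)
  out <- list(
    final_bone_pct = s$bone_pct_defect[n],
    final_cartilage_pct = s$cartilage_pct_defect[n],
    final_alginate_pct = 100 * s$mean_a_defect[n],
    week_cross_10pct = week_of_crossing(object, 10),
    peak_mean_g = max(s$mean_g_defect),
    final_mean_g = s$mean_g_defect[n],
    days = s$day[n])
  class(out) <- "summary.healing_sim"
  out
}

#' @export
print.summary.healing_sim <- function(x, ...) {
  cat(sprintf("final defect bone fill : %.1f %%\n", x$final_bone_pct))
  cat(sprintf("final cartilage        : %.1f %%\n", x$final_cartilage_pct))
  cat(sprintf("alginate remaining     : %.1f %%\n", x$final_alginate_pct))
  cat(sprintf("10%% bone crossing      : %s\n",
              if (is.na(x$week_cross_10pct)) "never"
              else sprintf("week %.1f", x$week_cross_10pct)))
  cat(sprintf("peak mean BMP-2 (defect): %.3g ng/cm3\n", x$peak_mean_g))
  cat(sprintf("final mean BMP-2 (defect): %.3g ng/cm3\n", x$final_mean_g))
  invisible(x)
}

#' @export
plot.healing_sim <- function(x, which = c("timeseries", "map"), ...) {
  which <- match.arg(which)
  s <- x$summary
  if (which == "timeseries") {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(s$day / 7, s$bone_pct_defect, type = "l", lwd = 2,
                   xlab = "weeks", ylab = "defect bone fill (%)",
                   main = "new bone in defect", ylim = c(0, 100))
    if (x$scenario$gel_present)
      graphics::lines(s$day / 7, 100 * s$mean_a_defect, lty = 2)
    graphics::plot(s$day / 7, pmax(s$mean_g_defect, 1e-4), type = "l",
                   log = "y", lwd = 2, xlab = "weeks",
                   ylab = "mean free BMP-2 (ng/cm3)", main = "BMP-2")
    graphics::abline(h = c(0.008, 0.5), lty = 3)
  } else {
    bf <- matrix(bone_fraction(x$final$composition), x$grid$nx, x$grid$ny)
    graphics::image(seq(0, x$grid$Lx, length.out = x$grid$nx),
                    seq(0, x$grid$Ly, length.out = x$grid$ny), bf,
                    xlab = "x (mm)", ylab = "y (mm)",
                    main = "final bone fraction", useRaster = TRUE)
  }
  invisible(x)
}
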