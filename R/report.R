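#' Write run outputs to disk
#'
#' Writes the per-day summary as CSV, a JSON digest (final bone and
#' alginate percentages, week of the 10% bone crossing, peak BMP-2) and a
#' legacy-ASCII VTK structured-points series of the stored field
#' snapshots (bone fraction, free/encapsulated BMP-2, alginate, MSC
#' density, stimulus), one file per snapshot day.
#'
#' @param sim a `healing_sim` from [simulate_healing()].
#' @param dir output directory (created if needed).
#' @param basename file stem for all outputs.
#' @return invisibly, the vector of written paths.
#' @export
report <- function(sim, dir, basename = "run") {
  stopifnot(inherits(sim, "healing_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  csv <- file.path(dir, paste0(basename, "_summary.csv"))
  utils::write.csv(sim$summary, csv, row.names = FALSE)
  paths <- c(paths, csv)
  sm <- summary(sim)
  js <- file.path(dir, paste0(basename, "_summary.json"))
  jsonlite::write_json(
    list(final_bone_pct = sm$final_bone_pct,
         final_alginate_pct = sm$final_alginate_pct,
         week_cross_10pct = sm$week_cross_10pct,
         peak_mean_g = sm$peak_mean_g,
         final_mean_g = sm$final_mean_g,
         scenario = list(gap_mm = sim$scenario$gap_mm,
                         gel_present = sim$scenario$gel_present,
                         bmp2_dose_ug = sim$scenario$bmp2_dose_ug,
                         horizon_days = sim$scenario$horizon_days,
                         seed = sim$scenario$seed)),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, js)
  for (snap in sim$snapshots) {
    vtk <- file.path(dir, sprintf("%s_day%03d.vtk", basename, snap$day))
    write_vtk_snapshot(sim$grid, snap, vtk)
    paths <- c(paths, vtk)
  }
  invisible(paths)
}

#' Write one field snapshot as a legacy ASCII VTK file
#'
#' Cell-centred fields are written as STRUCTURED_POINTS point data at the
#' cell centres (spacing = cell size), which any VTK viewer renders
#' directly.
#'
#' @param grid a [sim_grid()].
#' @param snap a snapshot list from a `healing_sim`.
#' @param path output file path.
#' @export
write_vtk_snapshot <- function(grid, snap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("bone healing fields, day %d", snap$day),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               sprintf("ORIGIN %g %g 0", grid$hx / 2, grid$hy / 2),
               sprintf("SPACING %g %g 1", grid$hx, grid$hy),
               sprintf("POINT_DATA %d", grid$nc)), con)
  wf <- function(name, v) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default",
                 paste(formatC(v, format = "g", digits = 6))), con)
  }
  wf("bone_fraction", bone_fraction(snap$composition))
  wf("cartilage_fraction", snap$composition[, "cartilage"] +
       snap$composition[, "calcified_cartilage"])
  wf("bmp2_free", snap$g)
  wf("bmp2_gel", snap$g_gel)
  wf("alginate", snap$a)
  wf("msc_density", snap$cells$cs)
  wf("stimulus_psi", snap$psi)
  invisible(path)
}
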