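#' Per-element tissue composition
#'
#' Volume fractions of the eight solid materials per control volume (see
#' [tissue_properties()]); the remainder to 1 is fluid/void. Cortical bone
#' fractions are set by the geometry and never change during a run.
#'
#' @param nc number of cells.
#' @return `nc x 8` numeric matrix with columns [material_names()],
#'   initialised to zero (all void).
#' @export
new_composition <- function(nc) {
  matrix(0, nrow = nc, ncol = length(material_names()),
         dimnames = list(NULL, material_names()))
}

#' @rdname new_composition
#' @param composition a composition matrix.
#' @return `solid_fraction`: per-cell sum of solid fractions in `[0, 1]`.
#' @export
solid_fraction <- function(composition) {
  pmin(rowSums(composition), 1)
}

#' @rdname new_composition
#' @return `mineral_fraction`: per-cell mineralized fraction (woven +
#'   cortical bone + calcified cartilage).
#' @export
mineral_fraction <- function(composition) {
  composition[, "woven"] + composition[, "cortical"] +
    composition[, "calcified_cartilage"]
}

#' @rdname new_composition
#' @return `bone_fraction`: per-cell bone fraction (woven + cortical).
#' @export
bone_fraction <- function(composition) {
  composition[, "woven"] + composition[, "cortical"]
}

check_composition <- function(composition, tol = 1e-9) {
  if (any(composition < -tol) || any(composition > 1 + tol))
    stop("composition fractions must lie in [0, 1]")
  if (any(rowSums(composition) > 1 + 1e-6))
    stop("composition fractions must sum to <= 1")
  invisible(TRUE)
}
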