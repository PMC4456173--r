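#' BMP-2 kinetic parameters
#'
#' Constants of the BMP-2 balance law: Michaelis--Menten background
#' consumption by MSCs and bone cells, first-order in vivo half-life decay,
#' cell production that is inversely related to the ambient concentration,
#' Fickian diffusion, and the in-gel pool kinetics.
#'
#' @param g_min lower physiological bound, ng/cm3.
#' @param t_half_free in vivo BMP-2 half-life, day.
#' @param t_half_gel half-life of BMP-2 encapsulated in the hydrogel, day.
#' @param Kma Michaelis constant of background consumption, ng/cm3.
#' @param v_max_per_cell maximal consumption rate per cell,
#'   ng cm-3 day-1 cell-1 (cells as concentrations, cells/cm3).
#' @param alpha_prod production scale, ng ml-1 cell-1 day-1.
#' @param gamma production inhibition slope, (ng/ml)-1.
#' @param gamma0 production inhibition offset, dimensionless.
#' @param D_gel BMP-2 diffusivity inside intact alginate, mm2/day.
#' @param D_vivo BMP-2 diffusivity in vivo (gel absent), mm2/day.
#' @return list of class `bmp_params`; includes derived first-order rates
#'   `lambda_free = ln2/t_half_free` and `lambda_gel = ln2/t_half_gel`
#'   (day-1).
#' @export
bmp_params <- function(g_min = 0.008, t_half_free = 0.42, t_half_gel = 3.25,
                       Kma = 11.01, v_max_per_cell = 1.43e-7,
                       alpha_prod = 2e-9, gamma = 15, gamma0 = 0.01,
                       D_gel = 0.2, D_vivo = 8.64) {
  p <- list(g_min = g_min, t_half_free = t_half_free, t_half_gel = t_half_gel,
            Kma = Kma, v_max_per_cell = v_max_per_cell,
            alpha_prod = alpha_prod, gamma = gamma, gamma0 = gamma0,
            D_gel = D_gel, D_vivo = D_vivo)
  if (any(unlist(p) <= 0)) stop("all BMP-2 kinetic parameters must be > 0")
  if (t_half_free >= t_half_gel)
    stop("free BMP-2 must degrade faster than encapsulated BMP-2")
  if (D_gel >= D_vivo) stop("diffusion must be slower inside the gel")
  p$lambda_free <- log(2) / t_half_free
  p$lambda_gel <- log(2) / t_half_gel
  class(p) <- "bmp_params"
  p
}

#' Alginate hydrogel parameters
#'
#' Degradation and release constants of the alginate carrier plus its
#' (fixed) poroelastic constants. Bulk hydrolysis is slow (the gel is
#' nearly intact after 12 weeks when acellular); invading cells destabilise
#' the ionic cross-links and dominate degradation at realistic densities.
#' BMP-2 release accelerates as degradation exposes gel surface:
#' `lambda_rel(a) = lambda_rel0 (1 - a)`.
#'
#' @param lambda_deg_bulk bulk hydrolysis rate, day-1.
#' @param lambda_deg_cell cell-driven degradation rate, day-1 cell-1
#'   (cells as cells/cm3).
#' @param lambda_rel0 release rate scale, day-1.
#' @param E_hg,nu_hg,k_hg Young's modulus (MPa), Poisson ratio and
#'   permeability (mm2) of the gel.
#' @return list of class `alginate_params`.
#' @export
alginate_params <- function(lambda_deg_bulk = 5e-4, lambda_deg_cell = 6.5e-6,
                            lambda_rel0 = 0.027,
                            E_hg = 0.05, nu_hg = 0.048, k_hg = 7e-12) {
  p <- list(lambda_deg_bulk = lambda_deg_bulk,
            lambda_deg_cell = lambda_deg_cell, lambda_rel0 = lambda_rel0,
            E_hg = E_hg, nu_hg = nu_hg, k_hg = k_hg)
  if (any(unlist(p) <= 0)) stop("all alginate parameters must be > 0")
  class(p) <- "alginate_params"
  p
}

#' Poroelastic tissue properties
#'
#' Per-material Young's modulus E (MPa), Poisson ratio nu and permeability
#' k (mm2) for the eight materials of the model. The baseline mechanical
#' solve is drained linear elasticity evaluated once per day of loading, so
#' k is carried and reported but not used by the solver.
#'
#' @return data.frame with row names `debris`, `granulation`, `cartilage`,
#'   `calcified_cartilage`, `fibrous`, `woven`, `cortical`, `alginate` and
#'   columns `E`, `nu`, `k`.
#' @export
tissue_properties <- function() {
  data.frame(
    E  = c(1.85, 7.79, 27.05, 57.05, 80.07, 982.48, 20e3, 0.05),
    nu = c(0.048, 0.048, 0.103, 0.108, 0.127, 0.295, 0.3, 0.048),
    k  = c(7e-12, 1e-14, 5e-15, 5e-15, 1e-14, 1e-17, 1e-17, 7e-12),
    row.names = c("debris", "granulation", "cartilage",
                  "calcified_cartilage", "fibrous", "woven", "cortical",
                  "alginate"))
}

#' Names of the solid material fractions tracked per element
#' @return character vector matching the rows of [tissue_properties()].
#' @export
material_names <- function() rownames(tissue_properties())

#' MSC motility parameters
#'
#' Free random motility `D0` and chemotactic sensitivity `chi0` are not
#' constrained by the source data (only their linear scaling with gel
#' content is); defaults are of the order used in prior bone-healing
#' transport models and are the principal calibration knobs of the cell
#' invasion speed. A weak random-migration floor `eps_D_frac * D0` remains
#' inside intact gel, and drift speed saturates at `v_chemo_max`
#' (receptor-saturation cap; it also realises the design contract that
#' peak chemotactic drift is of order 2 mm/day at the largest dose).
#'
#' @param D0 free random motility, mm2/day.
#' @param chi0 free chemotactic sensitivity, mm2 day-1 (ng/cm3)-1.
#' @param eps_D_frac weak-migration floor as a fraction of D0 (0 disables).
#' @param v_chemo_max drift-speed cap, mm/day.
#' @param mineral_block_threshold mineralized volume fraction above which a
#'   control volume blocks MSC migration.
#' @return list of class `motility_params`.
#' @export
motility_params <- function(D0 = 0.022, chi0 = 0.02, eps_D_frac = 0.01,
                            v_chemo_max = 2, mineral_block_threshold = 0.5) {
  stopifnot(D0 > 0, chi0 > 0, eps_D_frac >= 0, v_chemo_max > 0,
            mineral_block_threshold > 0, mineral_block_threshold <= 1)
  structure(list(D0 = D0, chi0 = chi0, eps_D_frac = eps_D_frac,
                 v_chemo_max = v_chemo_max,
                 mineral_block_threshold = mineral_block_threshold),
            class = "motility_params")
}

#' Mechanoregulation thresholds and baseline cellular rates
#'
#' Stimulus bands of the tissue-differentiation algorithm and the baseline
#' (physiological BMP-2) rates that the modulation folds multiply. The
#' stimulus psi is the square root of the second invariant of the
#' deviatoric strain tensor, so thresholds are strain-like and
#' dimensionless. These constants are calibration values inherited from the
#' mechanoregulation literature rather than measured quantities; the
#' shipped defaults are frozen to a single calibration under which a 2 mm
#' gap unites while an untreated 8 mm defect does not (see the methods
#' vignette) and are fully configurable.
#'
#' @param psi_resorb_min stimulus at or below which tissue is mechanically
#'   dormant (no differentiation). The default 0 disables the floor:
#'   arbitrarily low strains remain osteogenic, so a defect that has
#'   stiffened (strain-shielded itself) can still complete ossification;
#'   bone resorption/remodeling is outside the model.
#' @param psi_bone_max upper stimulus bound of the osteogenic band.
#' @param psi_cartilage_max upper bound of the chondrogenic band; above it
#'   MSCs become fibroblasts.
#' @param r_prolif baseline logistic MSC proliferation rate, day-1.
#' @param r_diff baseline MSC differentiation rate, day-1.
#' @param r_mature baseline chondrocyte hypertrophy/calcification rate, day-1.
#' @param r_endochondral calcified cartilage to woven bone replacement
#'   rate, day-1.
#' @param r_bone_matrix woven bone matrix production, fraction day-1 cell-1.
#' @param r_cart_matrix cartilage matrix production, fraction day-1 cell-1.
#' @param r_fib_matrix fibrous matrix production, fraction day-1 cell-1.
#' @param c_max MSC carrying density, cells/cm3.
#' @param c_source progenitor source density held at the periosteal and
#'   endosteal strips, cells/cm3.
#' @param c_event_min smallest converting cell density that counts as a
#'   differentiation event for the BMP-2 event sink, cells/cm3 (a trace
#'   of migrating cells should not drain a control volume of BMP-2).
#' @return list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(psi_resorb_min = 0, psi_bone_max = 0.01,
                            psi_cartilage_max = 0.06,
                            r_prolif = 0.6, r_diff = 0.3, r_mature = 0.15,
                            r_endochondral = 0.15,
                            r_bone_matrix = 2.4e-7, r_cart_matrix = 6e-8,
                            r_fib_matrix = 2e-8,
                            c_max = 1.2e6, c_source = 1.2e6,
                            c_event_min = 1e3) {
  stopifnot(psi_resorb_min >= 0, psi_resorb_min < psi_bone_max,
            psi_bone_max < psi_cartilage_max)
  rates <- c(r_prolif, r_diff, r_mature, r_endochondral, r_bone_matrix,
             r_cart_matrix, r_fib_matrix)
  if (any(rates < 0)) stop("rates must be >= 0")
  structure(list(psi_resorb_min = psi_resorb_min, psi_bone_max = psi_bone_max,
                 psi_cartilage_max = psi_cartilage_max,
                 r_prolif = r_prolif, r_diff = r_diff, r_mature = r_mature,
                 r_endochondral = r_endochondral,
                 r_bone_matrix = r_bone_matrix, r_cart_matrix = r_cart_matrix,
                 r_fib_matrix = r_fib_matrix, c_max = c_max,
                 c_source = c_source, c_event_min = c_event_min),
            class = "rule_thresholds")
}
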