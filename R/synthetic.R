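# Seeded synthetic-data generators emulating the study's assay formats:
# fast-exchange titrations, incremental-injection ITC thermograms, and
# pseudo-first-order isomerisation progress curves, all with additive
# Gaussian noise. Generator parameters are embedded in the object metadata
# (and written as file comments) so recovery tests never hard-code them.

# evaluate expr under a temporary RNG state; same seed, same draws
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default assay designs
#'
#' Grids used by the synthetic generators: a titration of 100 uM observed
#' species with ligand from 0 to 8 equivalents (extendable to 40 equivalents
#' for weak binders via `max_equiv`), an incremental ITC run of 20 x 2 uL
#' injections into a 200 uL cell, and a coupled-assay enzyme series over the
#' 5 to 40 nM range with 50 uM cis substrate.
#'
#' @param p_total observed species total, uM.
#' @param max_equiv largest ligand-to-protein ratio in the titration.
#' @return Named list of design parameters.
#' @export
titration_design <- function(p_total = 100, max_equiv = 8) {
  stopifnot(p_total > 0, max_equiv > 0)
  equiv <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8)
  if (max_equiv > 8)
    equiv <- c(equiv, seq(12, max_equiv, by = 4))
  list(p_total = p_total, l_totals = p_total * equiv[equiv <= max_equiv])
}

#' @rdname titration_design
#' @param cell_vol_uL,cell_uM,syringe_uM,n_inj,inj_vol_uL ITC geometry.
#' @export
itc_design <- function(cell_vol_uL = 200, cell_uM = 50, syringe_uM = 500,
                       n_inj = 20, inj_vol_uL = 2) {
  stopifnot(cell_vol_uL > 0, n_inj >= 1, inj_vol_uL > 0)
  list(cell_vol_uL = cell_vol_uL, cell_uM = cell_uM,
       syringe_uM = syringe_uM, inj_vol_uL = rep(inj_vol_uL, n_inj))
}

#' @rdname titration_design
#' @param enzyme_uM enzyme concentration grid, uM.
#' @param s_cis0_uM initial cis-substrate concentration, uM.
#' @param times sampling times, s.
#' @export
ppiase_design <- function(enzyme_uM = c(0.005, 0.01, 0.02, 0.04),
                          s_cis0_uM = 50, times = seq(0, 150, by = 1)) {
  stopifnot(length(enzyme_uM) >= 1, s_cis0_uM > 0, all(diff(times) > 0))
  list(enzyme_uM = enzyme_uM, s_cis0_uM = s_cis0_uM, times = times)
}

#' Generate a synthetic fast-exchange titration
#'
#' Forward model [predict_shift()] plus additive Gaussian noise. The default
#' limiting shifts span 0.2 ppm, a typical amplitude for a well-perturbed
#' amide resonance followed to saturation.
#'
#' @param kd dissociation constant, uM.
#' @param delta_free,delta_bound limiting shifts, ppm.
#' @param design a [titration_design()].
#' @param sigma noise standard deviation, ppm.
#' @param seed integer seed; identical seeds give bit-identical series.
#' @return A [titration_series()] whose `meta` records all generator
#'   parameters.
#' @export
gen_titration <- function(kd, delta_free = 8.30, delta_bound = 8.10,
                          design = titration_design(), sigma = 0.005,
                          seed = NULL) {
  stopifnot(kd > 0, sigma >= 0)
  clean <- predict_shift(design$p_total, design$l_totals, kd,
                         delta_free, delta_bound)
  obs <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sigma))
  titration_series(design$p_total, design$l_totals, obs,
                   delta_free = delta_free,
                   meta = list(kd_uM = kd, delta_free_ppm = delta_free,
                               delta_bound_ppm = delta_bound,
                               sigma_ppm = sigma, seed = seed))
}

#' Generate a synthetic ITC thermogram
#'
#' Forward model [itc_heats()] plus additive Gaussian noise scaled to the
#' largest injection heat.
#'
#' @param kd dissociation constant, uM.
#' @param n stoichiometry.
#' @param dH binding enthalpy, kcal/mol.
#' @param design an [itc_design()].
#' @param sigma_rel noise standard deviation as a fraction of the largest
#'   absolute heat.
#' @param seed integer seed.
#' @return An [itc_thermogram()] with generator parameters in `meta`.
#' @export
gen_itc <- function(kd, n = 1, dH = -5, design = itc_design(),
                    sigma_rel = 0.02, seed = NULL) {
  stopifnot(kd > 0, sigma_rel >= 0)
  clean <- itc_heats(n, kd, dH, design$cell_vol_uL, design$cell_uM,
                     design$syringe_uM, design$inj_vol_uL)
  sigma <- sigma_rel * max(abs(clean))
  obs <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sigma))
  itc_thermogram(design$cell_vol_uL, design$cell_uM, design$syringe_uM,
                 design$inj_vol_uL, obs,
                 meta = list(kd_uM = kd, n = n, dH_kcal_mol = dH,
                             sigma_ucal = sigma, seed = seed))
}

#' Generate synthetic coupled-assay progress curves
#'
#' One pseudo-first-order curve per enzyme concentration,
#' `signal = 1 - exp(-k_obs t)` with `k_obs` from [ppiase_kobs()], plus
#' additive Gaussian noise scaled to the unit curve amplitude.
#'
#' @param turnover turnover number, s^-1.
#' @param k0 uncatalysed isomerisation rate, s^-1.
#' @param design a [ppiase_design()].
#' @param sigma_rel noise standard deviation as a fraction of the curve
#'   amplitude.
#' @param seed integer seed.
#' @return List of [progress_curve()] objects with generator parameters in
#'   each `meta`.
#' @export
gen_ppiase <- function(turnover, k0 = 0.02, design = ppiase_design(),
                       sigma_rel = 0.01, seed = NULL) {
  stopifnot(turnover >= 0, k0 >= 0, sigma_rel >= 0)
  with_seed(seed, lapply(design$enzyme_uM, function(E) {
    k <- ppiase_kobs(k0, turnover, E, design$s_cis0_uM)
    clean <- 1 - exp(-k * design$times)
    obs <- clean + stats::rnorm(length(clean), 0, sigma_rel)
    progress_curve(E, design$s_cis0_uM, design$times, obs,
                   meta = list(turnover_s1 = turnover, k0_s1 = k0,
                               sigma = sigma_rel, seed = seed))
  }))
}
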