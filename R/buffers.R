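# Hofmeister ionic-replacement arithmetic used to design the isotonic
# fractionation buffers: the replacing concentration of a monovalent
# cation is Cr = 18 / Ri, with Ri the relative (solvated) ionic radius in
# picometres and the empirical constant 18 carrying units mol*pm/L.

#' Relative ionic radii of the Hofmeister monovalent cations
#'
#' Relative (solvation-shell) radii in picometres for the three cations
#' used in the fractionation buffers: Li 90, Na 116, K 152.
#'
#' @return Named numeric vector of radii in pm.
#' @examples
#' ionicRadii()
#' @export
ionicRadii <- function() c(Li = 90, Na = 116, K = 152)

#' Replacing cation concentration from the relative ionic radius
#'
#' Computes the concentration of a cation that replaces sodium in
#' isotonic saline while preserving the ionic ratio around proteins:
#' `Cr = 18 / Ri` (mol/L), where `Ri` is the relative ionic radius in pm
#' and 18 is an empirical constant with units mol*pm/L.
#'
#' @param radius_pm positive scalar, relative ionic radius in picometres.
#' @return Molarity in mol/L.
#' @examples
#' replacingConcentration(90)   # 0.200 mol/L (200 mM LiCl)
#' replacingConcentration(152)  # ~0.118 mol/L
#' @export
replacingConcentration <- function(radius_pm) {
  if (!is.numeric(radius_pm) || length(radius_pm) != 1L || radius_pm <= 0)
    stop("radius_pm must be a single positive number")
  18 / radius_pm
}

#' Practical recipe concentration for a replacing salt
#'
#' Evaluates [replacingConcentration()] for a named ion (or an explicit
#' radius) and rounds to the nearest 10 mM to give a weighable recipe
#' value. The rounding rule reproduces the 120 mM KCl and 200 mM LiCl
#' recipes; for Na it yields 160 mM (18/116 = 155.2 mM rounded up),
#' deliberately not forced to the 154 mM of standard saline, which is an
#' external reference solution rather than an output of the equation.
#'
#' @param ion one of `"Li"`, `"Na"`, `"K"`; ignored if `radius_pm` given.
#' @param radius_pm optional explicit relative radius in pm.
#' @return List with `ion`, `radius_pm`, `exact_molarity` (mol/L) and
#'   `recipe_mM` (integer mM, nearest 10).
#' @examples
#' recipeConcentration("K")$recipe_mM   # 120
#' recipeConcentration("Li")$recipe_mM  # 200
#' @export
recipeConcentration <- function(ion = c("Li", "Na", "K"), radius_pm = NULL) {
  if (is.null(radius_pm)) {
    ion <- match.arg(ion)
    radius_pm <- ionicRadii()[[ion]]
  } else {
    ion <- if (length(ion) == 1L) ion else NA_character_
  }
  m <- replacingConcentration(radius_pm)
  list(
    ion = ion,
    radius_pm = radius_pm,
    exact_molarity = m,
    recipe_mM = as.integer(round(m * 1000 / 10) * 10)
  )
}

#' Ideal osmolarity of a fully dissociating solute
#'
#' `concentration_mM * dissociated_species`, assuming complete ideal
#' dissociation (no osmotic coefficient). For a 1:1 salt such as NaCl,
#' 154 mM gives 308 mOsm/L, the isotonic reference.
#'
#' @param concentration_mM non-negative solute concentration in mM.
#' @param dissociated_species positive integer count of species produced
#'   per formula unit (2 for a 1:1 salt, 1 for a non-dissociating solute).
#' @return Osmolarity in mOsm/L.
#' @examples
#' osmolarity(154, 2)  # 308
#' @export
osmolarity <- function(concentration_mM, dissociated_species = 2L) {
  if (!is.numeric(concentration_mM) || any(concentration_mM < 0))
    stop("concentration_mM must be non-negative")
  if (!is.numeric(dissociated_species) || length(dissociated_species) != 1L ||
      dissociated_species < 1)
    stop("dissociated_species must be a positive integer")
  concentration_mM * dissociated_species
}

#' Convert percent weight/volume to millimolarity
#'
#' `percent_wv` g per 100 mL equals `percent_wv * 10` g/L; dividing by
#' the molar mass gives mol/L, reported in mM. 0.90% w/v NaCl
#' (58.44 g/mol) gives 154 mM.
#'
#' @param percent_wv non-negative, grams of solute per 100 mL.
#' @param molar_mass_g_per_mol positive molar mass, g/mol.
#' @return Concentration in mM.
#' @examples
#' percentWvToMolarity(0.90, 58.44)  # ~154 mM
#' @export
percentWvToMolarity <- function(percent_wv, molar_mass_g_per_mol) {
  if (!is.numeric(percent_wv) || any(percent_wv < 0))
    stop("percent_wv must be non-negative")
  if (!is.numeric(molar_mass_g_per_mol) || length(molar_mass_g_per_mol) != 1L ||
      molar_mass_g_per_mol <= 0)
    stop("molar_mass_g_per_mol must be a single positive number")
  percent_wv * 10 / molar_mass_g_per_mol * 1000
}

#' Convert millimolarity to percent weight/volume
#'
#' Inverse of [percentWvToMolarity()].
#'
#' @param concentration_mM non-negative concentration in mM.
#' @param molar_mass_g_per_mol positive molar mass, g/mol.
#' @return Percent w/v (g per 100 mL).
#' @export
molarityToPercentWv <- function(concentration_mM, molar_mass_g_per_mol) {
  if (!is.numeric(concentration_mM) || any(concentration_mM < 0))
    stop("concentration_mM must be non-negative")
  if (!is.numeric(molar_mass_g_per_mol) || length(molar_mass_g_per_mol) != 1L ||
      molar_mass_g_per_mol <= 0)
    stop("molar_mass_g_per_mol must be a single positive number")
  concentration_mM / 1000 * molar_mass_g_per_mol / 10
}
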