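# Chemical bookkeeping for the staining solutions: molar masses and
# mass concentrations, used to sanity-check agent formulations such as
# Gadobutrol (C18H31GdN4O9, 1.0 mmol/mL aqueous) and elemental iodine in
# ethanol. Attenuation coefficients are never derived from composition;
# these helpers exist for consistency checks only.

# IUPAC standard atomic weights (2021 abridged, conventional values where an
# interval is published), g/mol.
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971,
  Br = 79.904, Kr = 83.798, Rb = 85.468, Sr = 87.62, Y = 88.906,
  Zr = 91.224, Nb = 92.906, Mo = 95.95, Ru = 101.07, Rh = 102.91,
  Pd = 106.42, Ag = 107.87, Cd = 112.41, In = 114.82, Sn = 118.71,
  Sb = 121.76, Te = 127.60, I = 126.904, Xe = 131.29, Cs = 132.91,
  Ba = 137.33, La = 138.91, Ce = 140.12, Pr = 140.91, Nd = 144.24,
  Sm = 150.36, Eu = 151.96, Gd = 157.25, Tb = 158.93, Dy = 162.50,
  Ho = 164.93, Er = 167.26, Tm = 168.93, Yb = 173.05, Lu = 174.97,
  Hf = 178.49, Ta = 180.95, W = 183.84, Re = 186.21, Os = 190.23,
  Ir = 192.22, Pt = 195.08, Au = 196.97, Hg = 200.59, Tl = 204.38,
  Pb = 207.2, Bi = 208.98, Th = 232.04, U = 238.03
)

#' Parse a chemical formula
#'
#' Turns a Hill-style formula string such as `"C18H31GdN4O9"` or `"I2"` into
#' a named integer vector of element counts. Element symbols must be from the
#' standard periodic table and counts must be positive integers (an omitted
#' count means 1).
#'
#' @param formula A formula string, or an already-parsed named numeric vector
#'   of element counts (returned unchanged after validation).
#' @return Named integer vector of per-element atom counts.
#' @examples
#' chemical_formula("H2O")
#' chemical_formula("C18H31GdN4O9")  # Gadobutrol
#' @export
chemical_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
      stop("'formula' must be a single non-empty formula string", call. = FALSE)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(formula)) {
      stop("cannot parse chemical formula: '", formula, "'", call. = FALSE)
    }
    syms <- sub("[0-9]*$", "", tokens)
    nums <- sub("^[A-Z][a-z]?", "", tokens)
    counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
    names(counts) <- syms
    # collapse repeated symbols (e.g. "CH3COOH")
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[order(names(counts))]
  }
  bad <- setdiff(names(counts), names(.atomic_weights))
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("element counts must be positive integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Molar mass of a compound
#'
#' Sum of count times standard atomic weight over the formula's elements.
#'
#' @inheritParams chemical_formula
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("I2")            # elemental iodine, 253.81 g/mol
#' molar_mass("C18H31GdN4O9")  # Gadobutrol, ~604.7 g/mol
#' @export
molar_mass <- function(formula) {
  counts <- chemical_formula(formula)
  sum(counts * .atomic_weights[names(counts)])
}

#' Mass concentration of a solution from its molarity
#'
#' Converts a molar concentration to a mass concentration using the
#' compound's molar mass; mmol/mL times g/mol gives mg/mL. For Gadobutrol at
#' 1.0 mmol/mL this reproduces the nominal 604.72 mg/mL formulation of the
#' clinical gadolinium agent.
#'
#' @inheritParams chemical_formula
#' @param molarity_mmol_ml Molar concentration in mmol/mL; must be >= 0.
#' @return Mass concentration in mg/mL.
#' @examples
#' mass_concentration("C18H31GdN4O9", 1.0)
#' @export
mass_concentration <- function(formula, molarity_mmol_ml) {
  if (!is.numeric(molarity_mmol_ml) || length(molarity_mmol_ml) != 1L ||
      is.na(molarity_mmol_ml) || molarity_mmol_ml < 0) {
    stop("'molarity_mmol_ml' must be a single non-negative number",
         call. = FALSE)
  }
  molarity_mmol_ml * molar_mass(formula)
}
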