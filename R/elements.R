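#' @useDynLib crysformer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Static element tables: IUPAC standard atomic weights (u) and single-bond
# covalent radii (Angstrom, Cordero et al. compilation). Kept internal so the
# density label needs no runtime dependency.
.element_mass <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224, Nb = 92.906, Mo = 95.95,
  Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87, Cd = 112.41,
  In = 114.82, Sn = 118.71, Sb = 121.76, Te = 127.60, I = 126.90, Xe = 131.29,
  Cs = 132.91, Ba = 137.33, La = 138.91, W = 183.84, Re = 186.21, Os = 190.23,
  Ir = 192.22, Pt = 195.08, Au = 196.97, Hg = 200.59, Tl = 204.38,
  Pb = 207.2, Bi = 208.98
)

.element_covrad <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Sc = 1.70,
  Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20,
  Br = 1.20, Kr = 1.16, Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75,
  Nb = 1.64, Mo = 1.54, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45,
  Cd = 1.44, In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39,
  Xe = 1.40, Cs = 2.44, Ba = 2.15, La = 2.07, W = 1.62, Re = 1.51,
  Os = 1.44, Ir = 1.41, Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45,
  Pb = 1.46, Bi = 1.48
)

#' Standard atomic mass of an element
#'
#' @param symbol character vector of element symbols.
#' @return numeric vector of atomic masses in unified atomic mass units.
#' @export
atomic_mass <- function(symbol) {
  m <- .element_mass[symbol]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Covalent radius of an element
#'
#' @param symbol character vector of element symbols.
#' @return numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(symbol) {
  r <- .element_covrad[symbol]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(r)]), collapse = ", "))
  }
  unname(r)
}
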