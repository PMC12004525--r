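#' Element constants used across the package
#'
#' Per-element physical constants backing descriptor weights, molecular
#' weights, the toy conformer energy, and the dipole-like synthetic property:
#' atomic number, standard atomic mass (Da), van der Waals volume (A^3),
#' Sanderson electronegativity, static polarizability (A^3), Pauling
#' electronegativity (source of the mean-centred pseudo-charges), van der
#' Waals radius (A) and a 12-6 Lennard-Jones well depth (kcal/mol), plus the
#' standard valence used for implicit-hydrogen completion.
#'
#' Values are the tabulated constants found in standard descriptor handbooks
#' and general-purpose force fields; they are deliberately frozen here so the
#' package has no runtime dependency for them.
#'
#' @format A data.frame with one row per supported element.
#' @export
element_constants <- data.frame(
  element       = c("H",   "C",    "N",    "O",    "S",    "F",    "Cl"),
  z             = c(1L,    6L,     7L,     8L,     16L,    9L,     17L),
  mass          = c(1.008, 12.011, 14.007, 15.999, 32.06,  18.998, 35.45),
  vdw_volume    = c(6.709, 22.449, 15.599, 11.494, 24.429, 9.203,  23.228),
  sanderson_en  = c(2.592, 2.746,  3.194,  3.654,  2.957,  4.000,  3.475),
  polarizability= c(0.667, 1.760,  1.100,  0.802,  2.900,  0.557,  2.180),
  pauling_en    = c(2.20,  2.55,   3.04,   3.44,   2.58,   3.98,   3.16),
  vdw_radius    = c(1.20,  1.70,   1.55,   1.52,   1.80,   1.47,   1.75),
  lj_epsilon    = c(0.020, 0.070,  0.070,  0.060,  0.250,  0.060,  0.230),
  valence       = c(1L,    4L,     3L,     2L,     2L,     1L,     1L),
  stringsAsFactors = FALSE
)
rownames(element_constants) <- element_constants$element

# kcal/(mol K); the Boltzmann/gas constant on the energy scale used internally
.kB_KCAL <- 0.0019872041

# conversion factors to kcal/mol
.ENERGY_FACTORS <- c(
  "kcal/mol" = 1,
  "kJ/mol"   = 1 / 4.184,
  "eV"       = 23.060548,
  "hartree"  = 627.509474
)

.element_lookup <- function(elements, column) {
  unknown <- setdiff(unique(elements), element_constants$element)
  if (length(unknown) > 0L) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  element_constants[elements, column]
}
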