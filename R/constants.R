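# Nuclear data and reference compositions used throughout the package.
# Coherent neutron scattering lengths in fm (1 fm = 1e-5 Angstrom).

.b_coh <- c(
  H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803,
  S = 2.847, P = 5.13,
  X = 10.0   # generic point scatterer for idealized models
)

# Displaced (excluded) solvent volumes per heavy-atom group, Angstrom^3
# (Fraser-MacRae-Suzuki style fixed table).
.v_excl <- c(
  H = 5.15, D = 5.15, C = 16.44, N = 2.49, O = 9.13,
  S = 19.86, P = 5.73, X = 0.0
)

# van der Waals radii, Angstrom; X (dummy scatterer) treated as a point.
.r_vdw <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52,
  S = 1.80, P = 1.80, X = 0.0
)

# Volume of one water molecule, Angstrom^3 (fixes the solvent SLD scale).
.v_water <- 30.0

# SLD unit conversion: b [fm] / V [A^3] -> 1e-5 A / A^3 = 1e-5 A^-2
.fm_per_A <- 1e-5

# Reference monomer formulas per biomolecular class. Element counts are per
# "average" monomer; h_labile is the subset of H bound to N/O/S that exchanges
# with solvent; volume is the displaced monomer volume in A^3 (consistent with
# the class partial specific volume and monomer mass).
.class_formulas <- list(
  protein = list(        # average amino-acid residue
    counts = c(C = 4.90, N = 1.35, O = 1.49, S = 0.03),
    h_total = 7.70, h_labile = 1.60, mass = 110.0, volume = 133.0
  ),
  nucleic_acid = list(   # average ribonucleotide (Na salt)
    counts = c(C = 9.50, N = 3.75, O = 7.00, P = 1.00),
    h_total = 11.0, h_labile = 2.20, mass = 330.0, volume = 301.0
  ),
  lipid = list(          # POPC-like phospholipid
    counts = c(C = 42.0, N = 1.0, O = 8.0, P = 1.0),
    h_total = 82.0, h_labile = 0.0, mass = 760.0, volume = 1262.0
  ),
  carbohydrate = list(   # anhydroglucose unit
    counts = c(C = 6.0, O = 5.0),
    h_total = 10.0, h_labile = 3.0, mass = 162.0, volume = 164.0
  ),
  other_organic = list(  # small-metabolite average, glucose-like
    counts = c(C = 6.0, O = 5.0),
    h_total = 10.0, h_labile = 3.0, mass = 162.0, volume = 164.0
  ),
  inorganic = list(      # KCl-like salt pair, no hydrogen
    counts = c(S = 2.0), # b ~ 5.7 fm per "monomer"
    h_total = 0.0, h_labile = 0.0, mass = 74.0, volume = 45.0
  )
)

# Labile (exchangeable) hydrogens per residue, attached to heavy atoms:
# backbone amide N-H (1, except PRO 0) plus side-chain N/O/S hydrogens.
.sidechain_labile <- c(
  ALA = 0, ARG = 5, ASN = 2, ASP = 0, CYS = 1, GLN = 2, GLU = 0, GLY = 0,
  HIS = 1, ILE = 0, LEU = 0, LYS = 3, MET = 0, PHE = 0, PRO = 0, SER = 1,
  THR = 1, TRP = 1, TYR = 1, VAL = 0
)

#' Coherent neutron scattering length of an element
#'
#' Tabulated bound coherent scattering lengths used by the Debye engine and
#' the scattering-length-density arithmetic.
#'
#' @param element Character vector of element symbols (H, D, C, N, O, S, P, or
#'   `"X"` for a generic unit point scatterer).
#' @return Scattering lengths in fm.
#' @export
#' @examples
#' scattering_length(c("H", "D", "C"))
scattering_length <- function(element) {
  b <- .b_coh[toupper(element)]
  if (anyNA(b)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(b)]), collapse = ", "))
  }
  unname(b)
}
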