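# Monoisotopic constants. Single embedded source; every mass in the package
# derives from these values (atomic masses of the lightest stable isotope,
# CODATA/IUPAC, >= 6 decimals).

.ELEMENT_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885271,
  F  = 18.99840320,
  Br = 78.9183376,
  I  = 126.904473,
  Se = 79.9165218,
  Fe = 55.9349421,
  Mg = 23.98504170,
  Ca = 39.96259098,
  Zn = 63.9291422
)

# Residue (= amino acid minus water) elemental compositions, the 20 standard
# one-letter codes. Residue masses are computed from .ELEMENT_MASS so the
# atomic table is the only source of truth.
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

PROTON_MASS     <- 1.00727646688
ISOTOPE_SPACING <- 1.003355      # average C13-C12 peptide isotope spacing, Da
OXYGEN_MASS     <- 15.9949146221
WATER_MASS      <- 2 * 1.0078250319 + 15.9949146221
NH3_MASS        <- 14.0030740052 + 3 * 1.0078250319

# filled at load time from .RESIDUE_FORMULA (see zzz.R)
.xlscreen_env <- new.env(parent = emptyenv())

.residue_masses <- function() {
  if (is.null(.xlscreen_env$residue_mass)) {
    .xlscreen_env$residue_mass <- vapply(
      .RESIDUE_FORMULA,
      function(f) monoisotopic_mass(parse_formula(f)),
      numeric(1)
    )
  }
  .xlscreen_env$residue_mass
}
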