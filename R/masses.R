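## Monoisotopic masses. Everything is derived at load time from elemental
## compositions so that residue, modification and glycan masses stay mutually
## consistent; unit tests pin them against an independently coded elemental
## oracle.

# Monoisotopic element masses in Da.
ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503224,
  N = 14.00307400443,
  O = 15.99491461957,
  S = 31.9720711744
)

# Mass of a named elemental composition, e.g. c(C = 2, H = 3, N = 1, O = 1).
formula_mass <- function(formula) {
  unknown <- setdiff(names(formula), names(ELEMENT_MASS))
  if (length(unknown) > 0) {
    abort_egfofuc(paste0("unknown element(s): ", paste(unknown, collapse = ", ")),
                  "unknown_residue_error")
  }
  sum(ELEMENT_MASS[names(formula)] * formula)
}

# Residue (i.e. dehydrated amino acid) elemental compositions.
RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

RESIDUE_MASS <- vapply(RESIDUE_FORMULA, formula_mass, numeric(1))

PROTON_MASS <- 1.00727646688
WATER_MASS <- formula_mass(c(H = 2, O = 1))

# Carbamidomethylation of cysteine (iodoacetamide alkylation), +C2H3NO.
CARBAMIDOMETHYL_MASS <- formula_mass(c(C = 2, H = 3, N = 1, O = 1))

# Glycan residue (anhydro) compositions: deoxyhexose (fucose),
# N-acetylhexosamine (GlcNAc), hexose, N-acetylneuraminic acid.
GLYCAN_FORMULA <- list(
  dHex   = c(C = 6, H = 10, O = 4),
  HexNAc = c(C = 8, H = 13, N = 1, O = 5),
  Hex    = c(C = 6, H = 10, O = 5),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8)
)

GLYCAN_MASS <- vapply(GLYCAN_FORMULA, formula_mass, numeric(1))

#' Monoisotopic residue masses
#'
#' Monoisotopic masses (Da) of the 20 standard amino-acid residues
#' (dehydrated), derived from elemental compositions.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
#' @examples
#' residue_masses()[["G"]] # 57.02146
residue_masses <- function() RESIDUE_MASS

#' Monoisotopic glycan residue masses
#'
#' Monoisotopic delta masses (Da) of the glycan residues used in O-fucosylglycan
#' extension series: dHex (fucose), HexNAc, Hex and NeuAc.
#'
#' @return Named numeric vector of glycan residue masses in Da.
#' @export
#' @examples
#' glycan_masses()[["dHex"]] # 146.0579
glycan_masses <- function() GLYCAN_MASS
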