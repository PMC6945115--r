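#' Bondi van der Waals radii
#'
#' Van der Waals radii (Angstrom) for the elements that occur in protein,
#' water and monatomic-ion models, after Bondi (1964). Used as the default
#' atom radii for pore radius profiling.
#'
#' @return Named numeric vector, element symbol -> radius in Angstrom.
#' @export
#' @examples
#' bondi_radii()[["C"]]
bondi_radii <- function() {
  c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, `NA` = 2.27, K = 2.75,
    MG = 1.73, CA = 2.31, ZN = 1.39
  )
}

# Wimley-White interface scale, kcal/mol (free energy of transfer from water
# to the POPC interface, whole residues). Positive = prefers water
# (hydrophilic), negative = prefers the interface (hydrophobic).
.ww_interface_raw <- c(
  ALA = 0.17, ARG = 0.81, ASN = 0.42, ASP = 1.23, CYS = -0.24,
  GLN = 0.58, GLU = 2.02, GLY = 0.01, HIS = 0.17, ILE = -0.31,
  LEU = -0.56, LYS = 0.99, MET = -0.23, PHE = -1.13, PRO = 0.45,
  SER = 0.13, THR = 0.14, TRP = -1.85, TYR = -0.94, VAL = 0.07
)

#' Wimley-White hydrophobicity scale rescaled to [-1, 1]
#'
#' The Wimley-White interface scale (water-to-POPC-interface transfer free
#' energies of the 20 standard residues) linearly rescaled so that the most
#' hydrophobic residue (Trp) maps to +1 and the most hydrophilic (Glu) maps
#' to -1, matching the convention -1 = very hydrophilic, +1 = very
#' hydrophobic.
#'
#' @param raw If `TRUE` return the raw interface free energies in kcal/mol
#'   instead of the rescaled values.
#' @return Named numeric vector over three-letter residue codes.
#' @export
#' @examples
#' ww_scale()[["TRP"]]  # +1, most hydrophobic
#' ww_scale()[["GLU"]]  # -1, most hydrophilic
ww_scale <- function(raw = FALSE) {
  g <- .ww_interface_raw
  if (raw) {
    return(g)
  }
  lo <- min(g) # most hydrophobic
  hi <- max(g) # most hydrophilic
  # linear map: hi -> -1, lo -> +1
  h <- (hi + lo - 2 * g) / (hi - lo)
  round(h / max(abs(h)), 12) # exact +/-1 at endpoints despite fp rounding
}

#' Chloride reference radii
#'
#' Literature values for the radius of a dehydrated chloride ion (Pauling
#' ionic radius, 1.81 Angstrom) and an effective hydrated chloride radius
#' (about 3.3 Angstrom). These are external literature constants, not
#' quantities computed by this package; they are offered as reference lines
#' for pore radius profiles and are freely configurable.
#'
#' @return Named numeric vector with elements `dehydrated` and `hydrated`
#'   (Angstrom).
#' @export
chloride_reference_radii <- function() {
  c(dehydrated = 1.81, hydrated = 3.3)
}

# element inference from a PDB/GRO atom name when no element column is
# available; strips digits and primes, keeps leading one/two letters
.infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN") & nchar(nm) == 2, two, one)
}

# vdW lookup with graceful fallback to carbon for unknown elements
.vdw_for <- function(elements, table = bondi_radii()) {
  r <- unname(table[toupper(elements)])
  r[is.na(r)] <- table[["C"]]
  r
}
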