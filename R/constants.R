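# Physical constants and elemental data used throughout the package.
# Centralised so every module shares one set of masses.

#' Physical constants for HDX-MS mass arithmetic
#'
#' Mass constants shared by the forward model, the fitters and the
#' synthetic-data generator.
#'
#' \describe{
#'   \item{\code{mass_dh}}{Mass difference between deuterium and hydrogen,
#'     1.00628 Da, added per incorporated deuteron.}
#'   \item{\code{mass_proton}}{Proton mass, 1.00728 Da, used for m/z to
#'     neutral-mass conversion.}
#'   \item{\code{index_spacing}}{Nominal spacing (Da) used to map a neutral
#'     mass onto the integer isotopologue/deuteron index grid. Chosen midway
#'     between the C-13 neutron spacing (1.00336 Da) and the deuteron spacing
#'     (1.00628 Da) so rounding is unambiguous for peptide-sized envelopes.}
#' }
#'
#' @format A named list of numeric scalars.
#' @keywords internal
hdx_constants <- list(
  mass_dh       = 1.00628,
  mass_proton   = 1.00728,
  index_spacing = (1.0033548 + 1.00628) / 2
)

# Isotope masses (Da) and abundances per element; first row is the lightest
# (monoisotopic) isotope, `dn` is the neutron surplus relative to it.
.element_isotopes <- list(
  C = data.frame(dn = c(0L, 1L),
                 mass = c(12.0000000, 13.0033548),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(dn = c(0L, 1L),
                 mass = c(1.00782503, 2.01410178),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(dn = c(0L, 1L),
                 mass = c(14.00307401, 15.00010890),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(dn = c(0L, 1L, 2L),
                 mass = c(15.99491462, 16.99913176, 17.99915961),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(dn = c(0L, 1L, 2L, 4L),
                 mass = c(31.97207117, 32.97145891, 33.96786701, 35.96708076),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Elemental composition of amino-acid residues (peptide-bond residues, i.e.
# free amino acid minus one water). Columns C, H, N, O, S.
.residue_formulas <- matrix(
  c( # C   H   N  O  S
     3,  5,  1, 1, 0,  # A
     6, 12,  4, 1, 0,  # R
     4,  6,  2, 2, 0,  # N
     4,  5,  1, 3, 0,  # D
     3,  5,  1, 1, 1,  # C
     5,  8,  2, 2, 0,  # Q
     5,  7,  1, 3, 0,  # E
     2,  3,  1, 1, 0,  # G
     6,  7,  3, 1, 0,  # H
     6, 11,  1, 1, 0,  # I
     6, 11,  1, 1, 0,  # L
     6, 12,  2, 1, 0,  # K
     5,  9,  1, 1, 1,  # M
     9,  9,  1, 1, 0,  # F
     5,  7,  1, 1, 0,  # P
     3,  5,  1, 2, 0,  # S
     4,  7,  1, 2, 0,  # T
    11, 10,  2, 1, 0,  # W
     9,  9,  1, 2, 0,  # Y
     5,  9,  1, 1, 0), # V
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("C", "H", "N", "O", "S")))

# Elemental composition (C, H, N, O, S) of a peptide from its sequence:
# sum of residue formulas plus one water.
.peptide_formula <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, rownames(.residue_formulas))
  if (length(bad) > 0) {
    stop("unknown_residue: sequence contains non-standard residue(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  counts <- colSums(.residue_formulas[aa, , drop = FALSE])
  counts["H"] <- counts["H"] + 2  # one water
  counts["O"] <- counts["O"] + 1
  counts
}
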