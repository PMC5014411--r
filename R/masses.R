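# Monoisotopic residue masses (Da), canonical 20 amino acids.
# Cysteine is handled dynamically: fixed carbamidomethylation (+57.02146 Da)
# reflects iodoacetamide alkylation during sample preparation.
AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.00728
WATER_MASS  <- 18.01056
CARBAMIDOMETHYL <- 57.02146

residue_masses <- function(peptide, carbamidomethyl = TRUE) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(AA_MONO))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- AA_MONO[res]
  if (carbamidomethyl) m[res == "C"] <- m[res == "C"] + CARBAMIDOMETHYL
  unname(m)
}

#' Monoisotopic neutral peptide mass
#'
#' @param peptide amino-acid string (canonical residues).
#' @param carbamidomethyl logical; apply fixed carbamidomethylation
#'   (+57.02146 Da) to every cysteine. Default `TRUE`, matching alkylated
#'   sample preparation.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(peptide, carbamidomethyl = TRUE) {
  sum(residue_masses(peptide, carbamidomethyl)) + WATER_MASS
}

#' Singly charged b- and y-ion ladders
#'
#' Computes the standard collision-induced-dissociation fragment series for a
#' peptide: b(i) is the N-terminal fragment of i residues plus a proton, y(i)
#' the C-terminal fragment of i residues plus water and a proton. These obey
#' y(i) + b(n-i) = neutral precursor mass + 2 protons.
#'
#' @inheritParams peptide_mass
#' @return list with numeric vectors `b` and `y`, each of length
#'   `nchar(peptide) - 1` (the full-length ions are omitted, as conventional).
#' @export
fragment_ions <- function(peptide, carbamidomethyl = TRUE) {
  m <- residue_masses(peptide, carbamidomethyl)
  n <- length(m)
  if (n < 2) return(list(b = numeric(0), y = numeric(0)))
  b <- cumsum(m)[-n] + PROTON_MASS
  y <- cumsum(rev(m))[-n] + WATER_MASS + PROTON_MASS
  list(b = b, y = y)
}

# Ions present in the `alt` ladder but absent (within tol) from the `det`
# ladder: the masses that can only arise from the alternative allele.
diagnostic_ions <- function(alt_peptide, det_peptide, tol,
                            carbamidomethyl = TRUE) {
  alt <- unlist(fragment_ions(alt_peptide, carbamidomethyl))
  det <- unlist(fragment_ions(det_peptide, carbamidomethyl))
  if (!length(alt)) return(numeric(0))
  if (!length(det)) return(unname(alt))
  keep <- vapply(alt, function(mz) all(abs(det - mz) > tol), logical(1))
  unname(alt[keep])
}
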