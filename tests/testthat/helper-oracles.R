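# Independent oracles. These deliberately avoid the package's internals:
# masses are rebuilt from elemental compositions, digestion from a direct
# transcription of the cleavage rule, counting from a per-individual scan.

# --- elemental fragment/peptide mass oracle ---------------------------------

.atom <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)

# residue formulas as atom counts C,H,N,O,S
.residue_formula <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oracle_residue_mass <- function(res, carbamidomethyl = TRUE) {
  f <- .residue_formula[[res]]
  m <- sum(f * .atom[c("C", "H", "N", "O", "S")])
  if (carbamidomethyl && res == "C")
    m <- m + sum(c(2, 3, 1, 1, 0) * .atom[c("C", "H", "N", "O", "S")])
  m
}

oracle_peptide_mass <- function(pep, carbamidomethyl = TRUE) {
  res <- strsplit(pep, "")[[1]]
  sum(vapply(res, oracle_residue_mass, numeric(1), carbamidomethyl)) +
    2 * .atom[["H"]] + .atom[["O"]]
}

oracle_fragment_ions <- function(pep, carbamidomethyl = TRUE) {
  res <- strsplit(pep, "")[[1]]
  m <- vapply(res, oracle_residue_mass, numeric(1), carbamidomethyl)
  n <- length(m)
  proton <- 1.00727646677
  water <- 2 * .atom[["H"]] + .atom[["O"]]
  # y_i = mass of the i C-terminal residues + water + proton
  list(b = cumsum(m)[-n] + proton,
       y = cumsum(rev(m))[-n] + water + proton)
}

# --- digestion oracle -------------------------------------------------------

# Enumerate cleavage positions by rule (after K/R unless next is P), then
# union every run of <= max_missed + 1 adjacent fragments.
oracle_digest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  sites <- integer(0)
  for (i in seq_len(max(0, n - 1)))
    if (res[i] %in% c("K", "R") && res[i + 1] != "P")
      sites <- c(sites, i)
  bounds <- c(0L, sites, n)
  out <- list()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(i + max_missed, length(bounds) - 1)) {
      out[[length(out) + 1L]] <- c(bounds[i] + 1L, bounds[j + 1L],
                                   j - i)
    }
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end", "missed_cleavages")
  df$peptide <- substring(sequence, df$start, df$end)
  df[order(df$start, df$end - df$start), c("peptide", "start", "end",
                                           "missed_cleavages")]
}

# --- carrier-counting oracle ------------------------------------------------

# combination: data.frame(rs_id, allele). Exhaustive per-individual scan
# (pivoted to individual x locus lookup tables for speed; the decision per
# individual is still taken one individual at a time, straight from the
# definition).
oracle_count <- function(panel, combination) {
  g <- panel$genotypes
  inds <- unique(g$individual_id)
  loci <- unique(combination$rs_id)
  key <- paste(g$individual_id, g$rs_id)
  x <- 0L; n <- 0L
  for (ind in inds) {
    idx <- match(paste(ind, loci), key)
    if (anyNA(idx)) next
    a1 <- g$a1[idx]; a2 <- g$a2[idx]
    if (anyNA(a1) || anyNA(a2)) next
    n <- n + 1L
    ok <- TRUE
    for (k in seq_len(nrow(combination))) {
      j <- match(combination$rs_id[k], loci)
      if (!(a1[j] == combination$allele[k] ||
            a2[j] == combination$allele[k])) ok <- FALSE
    }
    if (ok) x <- x + 1L
  }
  c(x = x, n = n)
}

# --- misc -------------------------------------------------------------------

random_aa_sequence <- function(len,
                               alphabet = strsplit(
                                 "ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

expect_same_peptide_set <- function(a, b) {
  key <- function(d) sort(paste(d$peptide, d$start, d$end,
                                d$missed_cleavages))
  expect_identical(key(a), key(b))
}
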