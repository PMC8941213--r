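# Amino-acid constants used across the simulator and the aligners.

# canonical 20-residue alphabet
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# monoisotopic residue masses (Da)
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_H2O <- 18.0105646
MASS_PROTON <- 1.00727646

#' Monoisotopic precursor m/z of a peptide
#'
#' @param peptide Character vector of uppercase peptide sequences over the
#'   20-residue alphabet.
#' @param charge Precursor charge state (default 2, the most common tryptic
#'   peptide charge).
#' @return Numeric vector of m/z values in Thomson.
#' @export
#' @examples
#' peptide_mz("PEPTIDEK")
peptide_mz <- function(peptide, charge = 2L) {
  stopifnot(is.character(peptide), charge >= 1L)
  # ASCII-indexed mass table for speed on large peptide sets
  tab <- numeric(128)
  tab[utf8ToInt(paste(names(AA_MONO_MASS), collapse = ""))] <- AA_MONO_MASS
  vapply(peptide, function(p) {
    m <- tab[utf8ToInt(p)]
    if (any(m == 0) || any(is.na(m))) {
      abort(paste0("invalid amino acid(s) in peptide: ", p))
    }
    (sum(m) + MASS_H2O + charge * MASS_PROTON) / charge
  }, numeric(1), USE.NAMES = FALSE)
}

# validate that a string is a plain uppercase amino-acid sequence
assert_aa_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(paste0(what, " must be a single non-empty string"))
  }
  aa <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0(what, " contains non-amino-acid characters: ",
                 paste(unique(bad), collapse = ", ")))
  }
  invisible(x)
}

# seeded RNG scope: runs code with a derived seed, restores the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_peptide <- function(n, min_length = 8L, max_length = 20L) {
  len <- sample(seq.int(min_length, max_length), n, replace = TRUE)
  vapply(len, function(l) paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""),
         character(1))
}
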