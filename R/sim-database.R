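#' Generate a protein database with near-duplicate families
#'
#' Builds `n_families` families of `family_size` sequences each. The first
#' member of a family is a random founder over the 20-residue alphabet;
#' the remaining members are point-mutated copies. All mutants of a family
#' draw their substitutions from the same per-family site set of size
#' `round((1 - within_family_identity) * founder_length)`, so *every*
#' within-family pair (not just founder vs mutant) differs at no more than
#' that many positions and within-family identity is guaranteed to stay at
#' or above the configured value. Cross-family identity is unconstrained
#' (random founders are essentially unrelated).
#'
#' @param config A [sim_config()].
#' @return An object of class `protein_db`: a list with `proteins`, a
#'   tibble of `accession`, `family_id`, `sequence` (the ground-truth
#'   family membership), and `config`.
#' @export
#' @examples
#' db <- generate_protein_database(sim_config(seed = 7, n_families = 3,
#'                                            family_size = 2))
#' db$proteins
generate_protein_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$founder_length
  n_mut <- round((1 - config$within_family_identity) * L)
  if (config$within_family_identity < 1 && n_mut == 0) {
    abort(paste0(
      "within_family_identity ", config$within_family_identity,
      " cannot be realised at founder length ", L,
      ": the implied mutation count rounds to 0"
    ))
  }
  with_seed(config$seed, {
    fams <- purrr::map(seq_len(config$n_families), function(f) {
      founder <- sample(AA_ALPHABET, L, replace = TRUE)
      sites <- if (n_mut > 0) sample.int(L, n_mut) else integer(0)
      members <- purrr::map_chr(seq_len(config$family_size), function(m) {
        s <- founder
        if (m > 1 && n_mut > 0) {
          # substitute every mutable site with a residue different from the
          # founder's, so founder identity is exactly the configured value
          s[sites] <- vapply(founder[sites], function(orig) {
            sample(setdiff(AA_ALPHABET, orig), 1)
          }, character(1))
        }
        paste(s, collapse = "")
      })
      tibble(
        accession = sprintf("F%03d_P%02d", f, seq_len(config$family_size)),
        family_id = sprintf("F%03d", f),
        sequence = members
      )
    })
    structure(
      list(proteins = bind_rows(fams), config = config),
      class = "protein_db"
    )
  })
}

#' Within-family identity self-check of a synthetic database
#'
#' Computes all within-family pairwise global identities and reports the
#' minimum per family, so a generated database can be verified against the
#' clustering threshold it is meant to exercise.
#'
#' @param db A `protein_db` from [generate_protein_database()].
#' @return Tibble with `family_id`, `n_pairs`, `min_identity`.
#' @export
database_self_check <- function(db) {
  stopifnot(inherits(db, "protein_db"))
  db$proteins |>
    group_by(.data$family_id) |>
    summarise(
      n_pairs = choose(n(), 2),
      min_identity = {
        s <- .data$sequence
        if (length(s) < 2) 1 else {
          pr <- utils::combn(length(s), 2)
          min(global_identity(s[pr[1, ]], s[pr[2, ]]))
        }
      },
      .groups = "drop"
    )
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is proline,
#' and returns all peptides carrying 0 to `missed_cleavages_max` missed
#' cleavage sites. Peptides shorter than `min_length` or longer than
#' `max_length` residues are excluded (the usual bottom-up detectability
#' window).
#'
#' @param sequence Single uppercase amino-acid string.
#' @param missed_cleavages_max Maximum number of internal missed cleavage
#'   sites (default 0).
#' @param min_length,max_length Detectability window in residues
#'   (defaults 6 and 50).
#' @return Tibble with `peptide` (unique) and `n_missed` (the smallest
#'   missed-cleavage count producing that peptide).
#' @export
#' @examples
#' digest_protein("MKWVTFISLLLLFSSAYSR", missed_cleavages_max = 1)
digest_protein <- function(sequence, missed_cleavages_max = 0L,
                           min_length = 6L, max_length = 50L) {
  assert_aa_sequence(sequence)
  stopifnot(missed_cleavages_max >= 0)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  # cleavage after K/R unless followed by P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1] != "P"]
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nfrag <- length(starts)
  peps <- character(0); miss <- integer(0)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + missed_cleavages_max)) {
      len <- ends[j] - starts[i] + 1L
      if (len >= min_length && len <= max_length) {
        peps <- c(peps, substr(sequence, starts[i], ends[j]))
        miss <- c(miss, j - i)
      }
    }
  }
  if (length(peps) == 0) {
    return(tibble(peptide = character(0), n_missed = integer(0)))
  }
  # unique peptides, keeping the smallest missed-cleavage count
  ord <- order(peps, miss)
  keep <- !duplicated(peps[ord])
  tibble(peptide = peps[ord][keep], n_missed = miss[ord][keep])
}
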