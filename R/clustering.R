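#' Global alignment identity between two sequences
#'
#' Identity is the number of identical aligned positions in a global
#' (Needleman-Wunsch) alignment with match +1, mismatch -1 and linear gap
#' -1, divided by the length of the *shorter* sequence — the convention
#' CD-HIT uses, so a perfect substring match of a longer sequence scores 1.
#' Symmetric and in [0, 1]. Vectorised over pairs.
#'
#' @param seq_a,seq_b Character vectors of equal length (recycled if one
#'   has length 1) of non-empty uppercase sequences.
#' @return Numeric vector of identities in [0, 1].
#' @export
#' @examples
#' global_identity("PEPTIDE", "PEPSIDE")  # 6/7
global_identity <- function(seq_a, seq_b) {
  if (length(seq_a) == 1) seq_a <- rep(seq_a, length(seq_b))
  if (length(seq_b) == 1) seq_b <- rep(seq_b, length(seq_a))
  if (any(!nzchar(seq_a)) || any(!nzchar(seq_b))) {
    abort("sequences must be non-empty")
  }
  aln <- .nw_align_cpp(seq_a, seq_b)
  aln$identities / pmin(nchar(seq_a), nchar(seq_b))
}

#' Greedy sequence clustering at an identity threshold
#'
#' Stands in for CD-HIT: sequences are sorted by decreasing length (ties
#' broken by accession) and each is assigned to the first existing cluster
#' whose *representative* reaches at least `threshold` global identity;
#' otherwise it founds a new cluster with itself as representative. The
#' result partitions the input and is fully deterministic.
#'
#' @param proteins Tibble/data frame with columns `accession` and
#'   `sequence` (e.g. the `proteins` element of a `protein_db`, or
#'   [read_fasta()] output).
#' @param threshold Identity threshold in (0, 1]; default 0.95, the
#'   protein-grouping cutoff of the pipeline.
#' @return A tibble of class `protein_groups` with one row per member:
#'   `group_id`, `representative`, `accession`, `identity` (identity of
#'   the member to its representative; 1 for the representative itself).
#'   The threshold is stored in the `threshold` attribute.
#' @export
greedy_cluster <- function(proteins, threshold = 0.95) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  if (nrow(proteins) < 1) abort("need at least one sequence")
  if (threshold <= 0 || threshold > 1) abort("threshold must lie in (0, 1]")
  if (anyDuplicated(proteins$accession)) abort("duplicate accessions")

  ord <- order(-nchar(proteins$sequence), proteins$accession)
  acc <- proteins$accession[ord]
  seqs <- proteins$sequence[ord]
  n <- length(seqs)

  rep_idx <- integer(0)            # indices (into ord'ed vectors) of reps
  assign_group <- integer(n)
  assign_ident <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(rep_idx) > 0) {
      ids <- global_identity(rep(seqs[i], length(rep_idx)), seqs[rep_idx])
      hit <- which(ids >= threshold)
      if (length(hit) > 0) {
        g <- hit[1]                # first-fit, in cluster creation order
        assign_group[i] <- g
        assign_ident[i] <- ids[g]
        placed <- TRUE
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign_group[i] <- length(rep_idx)
      assign_ident[i] <- 1
    }
  }

  out <- tibble(
    group_id = sprintf("PG%05d", assign_group),
    representative = acc[rep_idx][assign_group],
    accession = acc,
    identity = assign_ident
  ) |>
    arrange(.data$group_id, dplyr::desc(.data$identity), .data$accession)
  attr(out, "threshold") <- threshold
  class(out) <- c("protein_groups", class(out))
  out
}
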