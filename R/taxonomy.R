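# The seven canonical ranks, most specific last
TAXON_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species")

# validate a taxonomy table and return fast lookup environments
tax_index <- function(tree) {
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(tree)))
  roots <- tree$taxid[tree$taxid == tree$parent | is.na(tree$parent)]
  if (length(roots) != 1) abort("tree must have exactly one root")
  parent <- setNames(tree$parent, tree$taxid)
  rank <- setNames(tree$rank, tree$taxid)
  name <- setNames(tree$name, tree$taxid)
  list(parent = parent, rank = rank, name = name, root = roots)
}

# lineage from a taxid up to (and including) the root
tax_lineage <- function(taxid, idx) {
  path <- integer(0)
  cur <- taxid
  for (i in seq_len(length(idx$parent) + 1)) {
    path <- c(path, cur)
    if (cur == idx$root) return(path)
    nxt <- idx$parent[[as.character(cur)]]
    if (is.null(nxt) || is.na(nxt)) abort(paste0("broken lineage at taxid ", cur))
    cur <- nxt
  }
  abort("cycle detected in taxonomy tree")
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is ancestral to (or equal to) every input taxid.
#' Idempotent and order-invariant over its input set.
#'
#' @param taxids Non-empty vector of taxids present in the tree.
#' @param tree Taxonomy tibble (`taxid`, `parent`, `rank`, `name`) with a
#'   single root whose parent is itself.
#' @return A single taxid.
#' @export
lca <- function(taxids, tree) {
  if (length(taxids) == 0) abort("empty taxid set")
  idx <- if (is.list(tree) && !is.data.frame(tree)) tree else tax_index(tree)
  unknown <- setdiff(taxids, names(idx$parent))
  if (length(unknown) > 0) {
    abort(paste0("unknown taxid(s): ", paste(unknown, collapse = ", ")))
  }
  taxids <- unique(taxids)
  lin1 <- tax_lineage(taxids[1], idx)
  if (length(taxids) == 1) return(lin1[1])
  common <- lin1
  for (t in taxids[-1]) {
    common <- common[common %in% tax_lineage(t, idx)]
  }
  common[1]
}

# resolve a taxid to its ancestor at (or, for missing intermediate ranks,
# the nearest named ancestor above) the requested rank; NA when the taxid
# itself is coarser than the requested rank
ancestor_at_rank <- function(taxid, rank, idx) {
  want <- match(rank, TAXON_RANKS)
  if (is.na(want)) abort(paste0("invalid rank: ", rank))
  own <- match(idx$rank[[as.character(taxid)]], TAXON_RANKS)
  if (is.na(own) || own < want) return(NA_integer_)  # coarser than requested
  lin <- tax_lineage(taxid, idx)
  pos <- match(idx$rank[as.character(lin)], TAXON_RANKS)
  at <- which(!is.na(pos) & pos == want)
  if (length(at) > 0) return(lin[at[1]])
  above <- which(!is.na(pos) & pos < want)
  if (length(above) > 0) return(lin[above[1]])
  NA_integer_
}

#' Intensity-weighted peptide taxonomy profile
#'
#' Computes each peptide's lowest common ancestor over its possible source
#' taxa; if the LCA sits at or below the requested rank, the peptide's
#' intensity accrues to its ancestor at that rank, otherwise to the
#' "Unassigned" category (the fate of broadly shared peptides). Shares are
#' normalized per sample.
#'
#' @param peptide_taxa Tibble `peptide`, `taxid`: every taxon a peptide
#'   could originate from.
#' @param intensities Tibble `sample`, `peptide`, `intensity` (e.g. PSM
#'   rows; intensities are summed per sample-peptide first).
#' @param tree Taxonomy tibble.
#' @param rank One of superkingdom, phylum, class, order, family, genus,
#'   species.
#' @return Tibble `sample`, `taxon`, `taxid`, `share` with
#'   `basis = "peptide-intensity"`; shares sum to 1 per sample.
#' @export
peptide_taxon_profile <- function(peptide_taxa, intensities, tree, rank) {
  if (!rank %in% TAXON_RANKS) abort(paste0("invalid rank: ", rank))
  stopifnot(all(c("peptide", "taxid") %in% names(peptide_taxa)),
            all(c("sample", "peptide", "intensity") %in% names(intensities)))
  if (any(intensities$intensity < 0)) abort("intensities must be non-negative")
  idx <- tax_index(tree)
  pep_lca <- peptide_taxa |>
    group_by(.data$peptide) |>
    summarise(lca_taxid = lca(.data$taxid, idx), .groups = "drop") |>
    mutate(
      taxid = vapply(.data$lca_taxid, ancestor_at_rank, integer(1),
                     rank = rank, idx = idx),
      taxon = ifelse(is.na(.data$taxid), "Unassigned",
                     idx$name[as.character(.data$taxid)])
    )
  intensities |>
    group_by(.data$sample, .data$peptide) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    inner_join(pep_lca |> select("peptide", "taxid", "taxon"), by = "peptide") |>
    group_by(.data$sample, .data$taxon, .data$taxid) |>
    summarise(mass = sum(.data$intensity), .groups = "drop") |>
    group_by(.data$sample) |>
    mutate(share = .data$mass / sum(.data$mass)) |>
    ungroup() |>
    mutate(basis = "peptide-intensity") |>
    select("sample", "taxon", "taxid", "share", "basis") |>
    arrange(.data$sample, dplyr::desc(.data$share))
}

#' Read-count taxonomy profile from an amplicon count table
#'
#' Rolls each counted taxon up to the requested rank via the tree;
#' counts on taxa coarser than the rank go to "Unassigned". Shares are
#' normalized per sample.
#'
#' @param counts Tibble `taxid`, `sample`, `count` (non-negative integers).
#' @param tree Taxonomy tibble.
#' @param rank Requested rank.
#' @return Tibble `sample`, `taxon`, `taxid`, `share` with
#'   `basis = "read-count"`.
#' @export
amplicon_profile <- function(counts, tree, rank) {
  if (!rank %in% TAXON_RANKS) abort(paste0("invalid rank: ", rank))
  stopifnot(all(c("taxid", "sample", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("counts must be non-negative")
  idx <- tax_index(tree)
  unknown <- setdiff(unique(counts$taxid), names(idx$parent))
  if (length(unknown) > 0) {
    abort(paste0("taxon absent from tree: ", paste(unknown, collapse = ", ")))
  }
  rolled <- counts |>
    distinct(.data$taxid) |>
    mutate(
      rolled_taxid = vapply(.data$taxid, ancestor_at_rank, integer(1),
                            rank = rank, idx = idx),
      taxon = ifelse(is.na(.data$rolled_taxid), "Unassigned",
                     idx$name[as.character(.data$rolled_taxid)])
    )
  counts |>
    inner_join(rolled, by = "taxid") |>
    group_by(.data$sample, .data$taxon, taxid = .data$rolled_taxid) |>
    summarise(mass = sum(.data$count), .groups = "drop") |>
    group_by(.data$sample) |>
    mutate(share = .data$mass / sum(.data$mass)) |>
    ungroup() |>
    mutate(basis = "read-count") |>
    select("sample", "taxon", "taxid", "share", "basis") |>
    arrange(.data$sample, dplyr::desc(.data$share))
}

#' Ratio between two taxa in a profile
#'
#' Averages each taxon's share over samples, then reports
#' numerator / denominator together with the conventional "1:x" label
#' (x = denominator over numerator, rounded to the nearest integer).
#'
#' @param profile A profile tibble from [peptide_taxon_profile()] or
#'   [amplicon_profile()].
#' @param numerator_taxon,denominator_taxon Taxon names.
#' @return List with `numerator_share`, `denominator_share`, `ratio` and
#'   `label`.
#' @export
#' @examples
#' prof <- tibble::tibble(sample = "S1",
#'                        taxon = c("Bacteroidetes", "Firmicutes"),
#'                        share = c(0.042, 0.227))
#' taxon_ratio(prof, "Bacteroidetes", "Firmicutes")$label  # "1:5"
taxon_ratio <- function(profile, numerator_taxon, denominator_taxon) {
  stopifnot(all(c("sample", "taxon", "share") %in% names(profile)) ||
              all(c("taxon", "share") %in% names(profile)))
  avg <- profile |>
    group_by(.data$taxon) |>
    summarise(share = mean(.data$share), .groups = "drop")
  num <- avg$share[avg$taxon == numerator_taxon]
  den <- avg$share[avg$taxon == denominator_taxon]
  if (length(num) == 0 || length(den) == 0) {
    abort("both taxa must be present in the profile")
  }
  if (den == 0) abort("denominator share is zero")
  list(
    numerator_share = num,
    denominator_share = den,
    ratio = num / den,
    label = paste0("1:", round(den / num))
  )
}
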