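#' Count-based (unweighted) GO relative abundance
#'
#' Per sample and namespace, every protein group observed in that sample
#' contributes one full count to *each* of its GO terms (no fractional
#' splitting), and one count to the "None" category if it carries no
#' annotation in that namespace. Shares are counts over the per-sample
#' total including None. Terms whose share never reaches
#' `other_max_share` in any sample are collapsed into "Other".
#'
#' @param qm A `quant_matrix`; a group counts as observed in a sample when
#'   its value there is non-missing. Use the matrix *before*
#'   missing-value filtering — relative abundance is computed on all
#'   quantifiable groups.
#' @param annotations Tibble `group_id`, `go_id`, `namespace`, `name`.
#' @param other_max_share Collapse threshold (default 0.01); set to 0 to
#'   disable the "Other" category.
#' @return Tibble `sample`, `namespace`, `go_id`, `name`, `share`, `mode`;
#'   shares sum to 1 within each sample-namespace stratum.
#' @export
unweighted_go_abundance <- function(qm, annotations, other_max_share = 0.01) {
  obs <- qm_long_observed(qm) |>
    distinct(.data$sample, .data$group_id) |>
    mutate(weight = 1)
  go_abundance_impl(obs, annotations, "unweighted", other_max_share)
}

#' Intensity-weighted GO relative abundance
#'
#' As [unweighted_go_abundance()], but each observed group contributes the
#' *mean* intensity of its observed (unshared) constituent peptides in
#' that sample — a proxy for protein copy number that controls for
#' protein length, since longer proteins yield more peptides but not
#' higher per-peptide intensity.
#'
#' @param psms PSM tibble (`sample`, `peptide`, `intensity`), optionally
#'   MBR-augmented.
#' @param map Peptide-to-group map from [build_peptide_group_map()];
#'   shared peptides are excluded.
#' @param annotations Tibble `group_id`, `go_id`, `namespace`, `name`.
#' @param other_max_share Collapse threshold (default 0.01).
#' @return Tibble as in [unweighted_go_abundance()] with
#'   `mode = "weighted"`.
#' @export
weighted_go_abundance <- function(psms, map, annotations,
                                  other_max_share = 0.01) {
  obs <- psms |>
    inner_join(map, by = "peptide") |>
    filter(!.data$shared, .data$intensity > 0) |>
    group_by(.data$sample, .data$group_id) |>
    summarise(weight = mean(.data$intensity), .groups = "drop")
  go_abundance_impl(obs, annotations, "weighted", other_max_share)
}

# shared accumulation: obs = (sample, group_id, weight)
go_abundance_impl <- function(obs, annotations, mode, other_max_share) {
  stopifnot(all(c("group_id", "go_id", "namespace") %in% names(annotations)))
  namespaces <- sort(unique(annotations$namespace))
  out <- purrr::map(namespaces, function(ns) {
    ann <- annotations |> filter(.data$namespace == ns)
    annotated <- obs |>
      inner_join(ann |> select("group_id", "go_id", "name") |> distinct(),
                 by = "group_id", relationship = "many-to-many")
    none <- obs |>
      anti_join(ann |> distinct(.data$group_id), by = "group_id") |>
      mutate(go_id = "None", name = "None")
    long <- bind_rows(annotated, none) |>
      group_by(.data$sample, .data$go_id, .data$name) |>
      summarise(mass = sum(.data$weight), .groups = "drop") |>
      group_by(.data$sample) |>
      mutate(share = .data$mass / sum(.data$mass)) |>
      ungroup() |>
      mutate(namespace = ns)
    # collapse terms that never reach the threshold in any sample
    if (other_max_share > 0) {
      minor <- long |>
        filter(.data$go_id != "None") |>
        group_by(.data$go_id) |>
        summarise(minor = max(.data$share) < other_max_share, .groups = "drop") |>
        filter(.data$minor) |>
        pull(.data$go_id)
      long <- long |>
        mutate(
          go_id = ifelse(.data$go_id %in% minor, "Other", .data$go_id),
          name = ifelse(.data$go_id == "Other", "Other", .data$name)
        ) |>
        group_by(.data$sample, .data$namespace, .data$go_id, .data$name) |>
        summarise(share = sum(.data$share), .groups = "drop")
    }
    long |> select("sample", "namespace", "go_id", "name", "share")
  })
  bind_rows(out) |>
    mutate(mode = mode) |>
    arrange(.data$namespace, .data$sample, dplyr::desc(.data$share))
}

# long view of observed cells of a quant matrix
qm_long_observed <- function(qm) {
  qm |>
    as_tibble() |>
    tidyr::pivot_longer(-"group_id", names_to = "sample",
                        values_to = "value") |>
    filter(!is.na(.data$value))
}

#' Weighted-to-unweighted fold expansion of GO terms
#'
#' For each term, the per-sample ratio weighted share / unweighted share,
#' averaged over samples. Ratios above 1 mean the term expands when
#' weighting by intensity (few but abundant proteins); below 1 it
#' contracts (many but lowly abundant proteins). Samples where the
#' unweighted share is zero are excluded from the mean and counted.
#'
#' @param weighted,unweighted GO abundance tables from
#'   [weighted_go_abundance()] / [unweighted_go_abundance()].
#' @param go_id Optional term filter (errors if absent from both tables).
#' @return Tibble `go_id`, `namespace`, `fold_expansion`,
#'   `n_samples_used`, `n_samples_excluded`.
#' @export
fold_expansion <- function(weighted, unweighted, go_id = NULL) {
  joined <- inner_join(
    weighted |> select("sample", "namespace", "go_id", w_share = "share"),
    unweighted |> select("sample", "namespace", "go_id", u_share = "share"),
    by = c("sample", "namespace", "go_id")
  ) |>
    filter(!.data$go_id %in% c("None", "Other"))
  if (!is.null(go_id)) {
    sel <- go_id
    joined <- joined |> filter(.data$go_id %in% sel)
    if (nrow(joined) == 0) abort(paste0("term not present in both tables: ", sel))
  }
  joined |>
    group_by(.data$go_id, .data$namespace) |>
    summarise(
      fold_expansion = mean((.data$w_share / .data$u_share)[.data$u_share > 0]),
      n_samples_used = sum(.data$u_share > 0),
      n_samples_excluded = sum(.data$u_share == 0),
      .groups = "drop"
    )
}

#' Hypergeometric GO term enrichment
#'
#' One-sided over-representation test of each GO term among significant
#' protein groups against the universe (non-significant plus significant
#' groups), from the 2x2 table significant/not x annotated/not. The
#' odds ratio uses the Haldane correction (add 0.5 to every cell) when any
#' cell is zero. Terms annotating fewer than `min_annotated` universe
#' groups are skipped.
#'
#' @param significant_groups Character vector of significant group ids.
#' @param universe_groups Character vector of the universe (the union with
#'   `significant_groups` is taken).
#' @param annotations Tibble `group_id`, `go_id`, `namespace`, `name`.
#' @param min_annotated Minimum annotated universe groups per term
#'   (default 2).
#' @return Tibble `go_id`, `namespace`, `name`, `n_significant_annotated`,
#'   `n_universe_annotated`, `n_significant`, `n_universe`, `odds_ratio`,
#'   `p_value`, sorted by p-value.
#' @export
go_enrichment <- function(significant_groups, universe_groups, annotations,
                          min_annotated = 2L) {
  if (length(significant_groups) == 0) abort("empty significant set")
  universe <- union(universe_groups, significant_groups)
  sig <- unique(significant_groups)
  N <- length(universe); n_sig <- length(sig)
  ann <- annotations |>
    filter(.data$group_id %in% universe) |>
    distinct(.data$group_id, .data$go_id, .data$namespace, .data$name)
  terms <- ann |>
    group_by(.data$go_id, .data$namespace, .data$name) |>
    summarise(
      n_universe_annotated = n_distinct(.data$group_id),
      n_significant_annotated = n_distinct(.data$group_id[.data$group_id %in% sig]),
      .groups = "drop"
    ) |>
    filter(.data$n_universe_annotated >= min_annotated)
  terms |>
    mutate(
      n_significant = n_sig, n_universe = N,
      p_value = phyper(.data$n_significant_annotated - 1,
                       .data$n_universe_annotated,
                       N - .data$n_universe_annotated,
                       n_sig, lower.tail = FALSE),
      odds_ratio = purrr::map2_dbl(
        .data$n_significant_annotated, .data$n_universe_annotated,
        function(k, K) {
          a <- k; b <- n_sig - k; cc <- K - k; d <- N - K - (n_sig - k)
          if (min(a, b, cc, d) == 0) {
            a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
          }
          (a * d) / (b * cc)
        }
      )
    ) |>
    arrange(.data$p_value) |>
    select("go_id", "namespace", "name", "n_significant_annotated",
           "n_universe_annotated", "n_significant", "n_universe",
           "odds_ratio", "p_value")
}
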