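#' Map peptides to protein groups and flag shared peptides
#'
#' A peptide is assigned to the unique protein group containing *all* of
#' its parent accessions. If its accessions span more than one group the
#' peptide is flagged shared (and carries no group assignment): shared
#' peptides are excluded from group quantification downstream.
#'
#' @param psms PSM tibble with columns `peptide` and `proteins`
#'   (`;`-joined accessions).
#' @param groups Group membership table with columns `group_id` and
#'   `accession` (e.g. a `protein_groups` from [greedy_cluster()], or a
#'   ground-truth membership table renamed accordingly).
#' @return Tibble `peptide`, `group_id` (`NA` when shared), `shared`.
#' @export
build_peptide_group_map <- function(psms, groups) {
  stopifnot(all(c("peptide", "proteins") %in% names(psms)),
            all(c("group_id", "accession") %in% names(groups)))
  lookup <- setNames(groups$group_id, groups$accession)
  peps <- distinct(psms, .data$peptide, .data$proteins)
  acc_list <- strsplit(peps$proteins, ";", fixed = TRUE)
  unknown <- setdiff(unique(unlist(acc_list)), names(lookup))
  if (length(unknown) > 0) {
    abort(paste0("accession(s) not in any group: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  gps <- lapply(acc_list, function(a) unique(unname(lookup[a])))
  n_gp <- lengths(gps)
  tibble(
    peptide = peps$peptide,
    group_id = ifelse(n_gp == 1, vapply(gps, `[`, character(1), 1),
                      NA_character_),
    shared = n_gp > 1
  ) |>
    distinct(.data$peptide, .keep_all = TRUE)
}

#' Aggregate peptide intensities into a group-by-sample matrix
#'
#' Intensity from shared peptides (accessions spanning more than one group)
#' contributes nothing. A group's value in a sample is the sum of its
#' unshared peptide intensities there; groups with no observed peptide in a
#' sample are missing (`NA`). Zero or negative intensities are treated as
#' non-detections.
#'
#' @param psms PSM tibble (`sample`, `peptide`, `intensity`, ...),
#'   optionally augmented by [match_between_runs()].
#' @param map Peptide-to-group map from [build_peptide_group_map()].
#' @param samples Sample sheet tibble (`sample`, `cohort`); fixes the
#'   column order and carries cohort labels.
#' @return A raw-scale `quant_matrix`.
#' @export
aggregate_intensities <- function(psms, map, samples) {
  stopifnot(all(c("sample", "peptide", "intensity") %in% names(psms)),
            all(c("sample", "cohort") %in% names(samples)))
  long <- psms |>
    inner_join(map, by = "peptide") |>
    filter(!.data$shared, .data$intensity > 0) |>
    group_by(.data$group_id, .data$sample) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop")
  wide <- long |>
    tidyr::pivot_wider(names_from = "sample", values_from = "intensity")
  for (s in setdiff(samples$sample, names(wide))) wide[[s]] <- NA_real_
  new_quant_matrix(wide |> arrange(.data$group_id), samples, "raw")
}

#' Simplified match-between-runs
#'
#' Transfers peptide identifications onto identification-free MS1 features:
#' for each peptide identified in at least one donor run and absent from an
#' acceptor run, an acceptor feature is assigned that peptide when its m/z
#' lies within `ppm_tol` parts-per-million and its retention time within
#' `rt_window_min` minutes of the donor *medians*. Candidate pairs are
#' resolved greedily by closest ppm error (each feature used once, each
#' peptide transferred once per acceptor run), and an existing
#' identification is never overwritten. Transferred rows are flagged
#' `mbr = TRUE`.
#'
#' @param psms Identified PSM tibble (`sample`, `scan`, `peptide`,
#'   `proteins`, `mz`, `rt_min`, `intensity`).
#' @param features Identification-free feature tibble (`sample`, `scan`,
#'   `mz`, `rt_min`, `intensity`).
#' @param ppm_tol Precursor tolerance in ppm (default 10).
#' @param rt_window_min Retention-time window in minutes (default 15).
#' @return `psms` with transferred rows appended and an `mbr` flag column.
#' @export
match_between_runs <- function(psms, features, ppm_tol = 10,
                               rt_window_min = 15) {
  stopifnot(all(c("sample", "peptide", "mz", "rt_min", "intensity") %in%
                  names(psms)))
  if (n_distinct(psms$sample) < 2) abort("match-between-runs needs >= 2 runs")
  psms <- psms |> mutate(mbr = FALSE)
  if (is.null(features) || nrow(features) == 0) return(psms)

  donor <- psms |>
    group_by(.data$peptide) |>
    summarise(
      donor_mz = median(.data$mz),
      donor_rt = median(.data$rt_min),
      proteins = first(.data$proteins),
      samples_seen = list(unique(.data$sample)),
      .groups = "drop"
    )

  transferred <- purrr::map(unique(features$sample), function(s) {
    feats <- features |> filter(.data$sample == s)
    cand_peps <- donor |>
      filter(!purrr::map_lgl(.data$samples_seen, ~ s %in% .x))
    if (nrow(cand_peps) == 0 || nrow(feats) == 0) return(NULL)
    # all (feature, peptide) pairs inside both tolerances
    pairs <- tidyr::expand_grid(
      feats |> select(feat_scan = "scan", feat_mz = "mz",
                      feat_rt = "rt_min", feat_intensity = "intensity"),
      cand_peps |> select("peptide", "donor_mz", "donor_rt", "proteins")
    ) |>
      mutate(
        ppm = abs(.data$feat_mz - .data$donor_mz) / .data$donor_mz * 1e6,
        drt = abs(.data$feat_rt - .data$donor_rt)
      ) |>
      filter(.data$ppm <= ppm_tol, .data$drt <= rt_window_min) |>
      arrange(.data$ppm)
    if (nrow(pairs) == 0) return(NULL)
    used_feat <- character(0); used_pep <- character(0); keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      fs <- as.character(pairs$feat_scan[i]); pp <- pairs$peptide[i]
      if (!(fs %in% used_feat) && !(pp %in% used_pep)) {
        keep[i] <- TRUE
        used_feat <- c(used_feat, fs); used_pep <- c(used_pep, pp)
      }
    }
    pairs[keep, ] |>
      mutate(sample = s) |>
      select("sample", scan = "feat_scan", "peptide", "proteins",
             mz = "feat_mz", rt_min = "feat_rt",
             intensity = "feat_intensity") |>
      mutate(mbr = TRUE)
  })
  bind_rows(psms, bind_rows(transferred))
}

#' Remove protein groups with too many missing values
#'
#' Implements the three literal removal rules of the pipeline: a group is
#' removed if (1) both cohorts contain only null values, (2) one cohort
#' contains only null values and the other fewer than `min_nonnull`
#' non-null values, or (3) both cohorts contain fewer than `min_nonnull`
#' non-null values each. The `"shortcut"` method keeps a group iff
#' `max(n_healthy, n_uc) >= min_nonnull`, which is provably equivalent and
#' kept as a cross-check.
#'
#' @param qm A `quant_matrix`.
#' @param min_nonnull Minimum non-null count (default 4).
#' @param method `"rules"` (the literal three rules) or `"shortcut"`.
#' @return The filtered `quant_matrix`.
#' @export
filter_missing <- function(qm, min_nonnull = 4L,
                           method = c("rules", "shortcut")) {
  method <- match.arg(method)
  samples <- qm_samples(qm)
  if (any(table(factor(samples$cohort, levels = unique(samples$cohort))) == 0) ||
      n_distinct(samples$cohort) < 2) {
    abort("both cohorts need at least one sample")
  }
  m <- qm_values(qm)
  cohorts <- unique(samples$cohort)
  n1 <- rowSums(!is.na(m[, samples$sample[samples$cohort == cohorts[1]],
                         drop = FALSE]))
  n2 <- rowSums(!is.na(m[, samples$sample[samples$cohort == cohorts[2]],
                         drop = FALSE]))
  keep <- if (method == "rules") {
    rule1 <- n1 == 0 & n2 == 0
    rule2 <- (n1 == 0 & n2 < min_nonnull) | (n2 == 0 & n1 < min_nonnull)
    rule3 <- n1 < min_nonnull & n2 < min_nonnull
    !(rule1 | rule2 | rule3)
  } else {
    pmax(n1, n2) >= min_nonnull
  }
  replace_qm_values(qm, m[keep, , drop = FALSE])
}

# generalized log2: glog2(0.75) = 0; glog2(x) -> log2(x) for large x
glog2 <- function(x) log2(x + sqrt(x^2 + 1)) - 1

#' Calibrated generalized-log normalization
#'
#' A deterministic variance-stabilizing transform: per sample, values are
#' affine-calibrated and passed through the generalized log
#' `glog2(x) = log2(x + sqrt(x^2 + 1)) - 1`, with the per-sample offset and
#' scale chosen so the transformed non-missing values have median 0 and
#' median absolute deviation 1, each target solved by monotone
#' root-finding. The transform is strictly increasing within each sample,
#' and two samples differing only by a multiplicative constant normalize
#' to identical columns. A matrix already on the normalized-log scale is
#' returned unchanged.
#'
#' @param qm A raw-scale `quant_matrix`.
#' @return A `quant_matrix` on the `normalized-log` scale.
#' @export
normalize_glog <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm_scale(qm) == "normalized-log") return(qm)
  m <- qm_values(qm)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    obs <- v[!is.na(v)]
    if (length(obs) < 3) {
      abort(sprintf("sample '%s' has fewer than 3 non-missing values",
                    colnames(m)[j]))
    }
    med <- median(obs)
    spread <- median(abs(obs - med))
    if (spread == 0) {
      abort(sprintf("sample '%s' is constant and cannot be calibrated",
                    colnames(m)[j]))
    }
    # inner solve: offset a pinning the transformed median at 0 (glog2 is
    # monotone, so the transformed median is decreasing in a); the closed
    # form a = med - 0.75 b (glog2(0.75) = 0) seeds the bracket and is
    # exact for odd counts
    solve_a <- function(b) {
      g <- function(a) median(glog2((obs - a) / b))
      ctr <- med - 0.75 * b; w <- 10 * (spread + b)
      lo <- ctr - w; hi <- ctr + w
      while (g(lo) < 0) lo <- lo - w
      while (g(hi) > 0) hi <- hi + w
      uniroot(g, c(lo, hi), tol = 1e-12)$root
    }
    # outer solve: scale b for transformed MAD 1 (decreasing in b)
    f <- function(b) {
      a <- solve_a(b)
      t <- glog2((obs - a) / b)
      median(abs(t - median(t))) - 1
    }
    lo <- spread * 1e-8; hi <- spread * 1e8
    while (f(hi) > 0 && hi < spread * 1e30) hi <- hi * 100
    while (f(lo) < 0 && lo > spread * 1e-30) lo <- lo / 100
    b <- uniroot(f, c(lo, hi), tol = 1e-12)$root
    m[, j] <- glog2((v - solve_a(b)) / b)
  }
  replace_qm_values(qm, m, scale = "normalized-log")
}
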