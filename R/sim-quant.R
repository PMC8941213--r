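#' Simulate a two-cohort label-free quantification experiment
#'
#' Digests every database protein, then draws a log2 MS1 intensity for each
#' detectable peptide in each sample as
#' family baseline + cohort effect + peptide offset + measurement noise.
#' Baselines are Normal(`intensity_log_mean`, `intensity_log_sd`) per
#' family; `n_diff_groups` families receive a cohort effect of
#' `log2_effect_size` with randomised sign (applied to the UC cohort).
#' Missingness is left-censored: the dropout probability is a logistic
#' function of the log2 intensity, so low-abundance measurements vanish
#' preferentially. A dropped-out peptide may still leave an
#' identification-free MS1 feature (probability
#' `feature_without_id_prob`) — the raw material match-between-runs
#' recovers. Precursor m/z is computed from the peptide monoisotopic mass
#' at charge 2; retention time is drawn once per peptide with small
#' per-sample jitter.
#'
#' @param db A `protein_db` from [generate_protein_database()].
#' @param config The [sim_config()] used to build `db`.
#' @return Object of class `quant_sim`: list with
#'   * `psms`: tibble `sample`, `scan`, `peptide`, `proteins`
#'     (`;`-joined accessions), `mz`, `rt_min`, `intensity`;
#'   * `features`: identification-free MS1 features
#'     (`sample`, `scan`, `mz`, `rt_min`, `intensity`);
#'   * `samples`: tibble `sample`, `cohort`;
#'   * `truth`: list with `membership` (accession to family),
#'     `differential` (family to signed log2 fold change) and `peptides`
#'     (per-peptide family, m/z and reference retention time).
#' @export
simulate_quant_experiment <- function(db, config) {
  stopifnot(inherits(db, "protein_db"), inherits(config, "sim_config"))
  n_h <- config$n_samples_per_cohort[["healthy"]]
  n_u <- config$n_samples_per_cohort[["uc"]]
  samples <- tibble(
    sample = c(sprintf("H%d", seq_len(n_h)), sprintf("UC%d", seq_len(n_u))),
    cohort = c(rep("healthy", n_h), rep("uc", n_u))
  )

  # peptide -> parent accessions / families (shared peptides keep them all)
  digests <- purrr::map2(db$proteins$accession, db$proteins$sequence,
    function(acc, seq) {
      d <- digest_protein(seq, config$missed_cleavages_max)
      if (nrow(d) == 0) return(NULL)
      tibble(accession = acc, peptide = d$peptide)
    })
  pep_map <- bind_rows(digests) |>
    left_join(db$proteins |> select("accession", "family_id"), by = "accession")
  peptides <- pep_map |>
    group_by(.data$peptide) |>
    summarise(
      proteins = paste(sort(unique(.data$accession)), collapse = ";"),
      family_id = sort(unique(.data$family_id))[1],
      n_families = n_distinct(.data$family_id),
      .groups = "drop"
    )

  with_seed(config$seed + 1L, {
    fams <- sort(unique(db$proteins$family_id))
    baseline <- setNames(
      rnorm(length(fams), config$intensity_log_mean, config$intensity_log_sd),
      fams
    )
    diff_fams <- sample(fams, config$n_diff_groups)
    effect <- setNames(rep(0, length(fams)), fams)
    effect[diff_fams] <- config$log2_effect_size *
      sample(c(-1, 1), length(diff_fams), replace = TRUE)

    peptides <- peptides |>
      mutate(
        offset = rnorm(n(), 0, config$peptide_log_sd),
        mz = peptide_mz(.data$peptide, charge = 2L),
        rt_ref = runif(n(), 0.05, 0.95) * config$rt_gradient_min
      )

    grid <- tidyr::expand_grid(
      peptides |> select("peptide", "proteins", "family_id", "offset",
                         "mz", "rt_ref"),
      samples
    ) |>
      mutate(
        log2_intensity = baseline[.data$family_id] +
          ifelse(.data$cohort == "uc", effect[.data$family_id], 0) +
          .data$offset +
          rnorm(n(), 0, config$residual_log_sd),
        rt_min = pmin(pmax(.data$rt_ref + rnorm(n(), 0, config$rt_jitter_sd), 0),
                      config$rt_gradient_min),
        mz_obs = .data$mz * (1 + rnorm(n(), 0, 3) * 1e-6),
        p_drop = if (is.infinite(config$dropout_midpoint) &&
                     config$dropout_midpoint < 0) {
          0
        } else {
          plogis(config$dropout_steepness *
                   (config$dropout_midpoint - .data$log2_intensity))
        },
        observed = runif(n()) >= .data$p_drop,
        feature_only = !.data$observed &
          runif(n()) < config$feature_without_id_prob
      )

    psms <- grid |>
      filter(.data$observed) |>
      group_by(.data$sample) |>
      mutate(scan = row_number()) |>
      ungroup() |>
      mutate(intensity = 2^.data$log2_intensity) |>
      select("sample", "scan", "peptide", "proteins",
             mz = "mz_obs", "rt_min", "intensity")

    n_id <- psms |> count(.data$sample, name = "n_id")
    features <- grid |>
      filter(.data$feature_only) |>
      left_join(n_id, by = "sample") |>
      group_by(.data$sample) |>
      mutate(scan = dplyr::coalesce(first(.data$n_id), 0L) + row_number()) |>
      ungroup() |>
      mutate(intensity = 2^.data$log2_intensity) |>
      select("sample", "scan", mz = "mz_obs", "rt_min", "intensity")

    truth <- list(
      membership = db$proteins |> select("accession", "family_id"),
      differential = tibble(family_id = fams,
                            log2_fold_change = unname(effect[fams])),
      peptides = peptides |> select("peptide", "family_id", "proteins",
                                    "mz", "rt_ref")
    )
    structure(
      list(psms = psms, features = features, samples = samples, truth = truth,
           config = config),
      class = "quant_sim"
    )
  })
}
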