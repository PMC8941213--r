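#' Configuration for the synthetic metaproteomics experiment
#'
#' A single seeded configuration drives every synthetic input the pipeline
#' consumes: the protein database with near-duplicate families, the
#' two-cohort label-free intensity tables with planted fold changes and
#' intensity-dependent (left-censored) missingness, and the de novo score
#' mixture. Defaults emulate the study design the pipeline was built for:
#' 8 healthy vs 10 ulcerative-colitis samples, a few-percent differential
#' fraction at a 2-fold (log2) planted effect, and log2 MS1 areas centred
#' near 2^20.
#'
#' @param seed Integer seed; every downstream generator derives its stream
#'   from it, so identical configurations give identical outputs.
#' @param n_families Number of protein families (ground-truth groups).
#' @param family_size Sequences per family (near-duplicates of a founder).
#' @param within_family_identity Fraction in (0.5, 1]; sequence identity of
#'   each family member to its founder.
#' @param founder_length Residue length of family founder sequences.
#' @param n_samples_per_cohort Length-2 integer vector, samples in the
#'   healthy and UC cohorts.
#' @param n_diff_groups Number of families with a planted cohort effect;
#'   default `NULL` means 4 percent of `n_families` (rounded, at least 1),
#'   mirroring the few-percent differential fraction of real two-cohort
#'   fecal metaproteomes.
#' @param log2_effect_size Absolute planted log2 fold change (sign is
#'   randomised per group).
#' @param intensity_log_mean,intensity_log_sd Mean and sd of per-family
#'   baseline abundance on the log2 intensity scale.
#' @param peptide_log_sd Sd of the per-peptide ionisation offset (log2).
#' @param residual_log_sd Sd of per-measurement noise (log2).
#' @param dropout_midpoint,dropout_steepness Logistic missingness on log2
#'   intensity: P(missing) = plogis(steepness * (midpoint - log2 intensity)).
#'   A `dropout_midpoint` of `-Inf` disables missingness entirely.
#' @param feature_without_id_prob Probability that a dropped-out peptide
#'   still leaves an identification-free MS1 feature (the raw material for
#'   match-between-runs).
#' @param missed_cleavages_max Maximum missed tryptic cleavages in the
#'   in-silico digest.
#' @param rt_gradient_min Length of the simulated LC gradient in minutes.
#' @param rt_jitter_sd Per-sample retention-time jitter sd (minutes).
#' @param denovo_score_params List with `weights` (named `dark`, `noise`,
#'   summing to 1: the mix of appended unassigned scans), `beta_identified`
#'   and `beta_noise` (each `c(shape1, shape2)` of the Beta distributions
#'   whose draws, times 100, are Novor-style scores).
#' @param denovo_error_rate Per-residue substitution probability of the
#'   simulated de novo read-out.
#' @param n_extra_scans Unassigned MS2 scans appended per sample (split
#'   into database-absent real peptides and noise by `weights`).
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_families = 10, family_size = 2)
#' cfg$n_samples_per_cohort
sim_config <- function(seed = 1L,
                       n_families = 200L,
                       family_size = 3L,
                       within_family_identity = 0.97,
                       founder_length = 300L,
                       n_samples_per_cohort = c(healthy = 8L, uc = 10L),
                       n_diff_groups = NULL,
                       log2_effect_size = 2,
                       intensity_log_mean = 20,
                       intensity_log_sd = 2,
                       peptide_log_sd = 1,
                       residual_log_sd = 0.5,
                       dropout_midpoint = 16,
                       dropout_steepness = 0.8,
                       feature_without_id_prob = 0.5,
                       missed_cleavages_max = 1L,
                       rt_gradient_min = 120,
                       rt_jitter_sd = 0.5,
                       denovo_score_params = list(
                         weights = c(dark = 0.3, noise = 0.7),
                         beta_identified = c(12, 2.5),
                         beta_noise = c(2, 4)
                       ),
                       denovo_error_rate = 0.02,
                       n_extra_scans = 500L) {
  counts <- list(
    n_families = n_families, family_size = family_size,
    founder_length = founder_length, n_samples_per_cohort = n_samples_per_cohort
  )
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || any(v < 1) || any(v != as.integer(v))) {
      abort(paste0("`", nm, "` must be integer count(s) >= 1"))
    }
  }
  if (length(n_samples_per_cohort) != 2) {
    abort("`n_samples_per_cohort` must have length 2 (healthy, uc)")
  }
  if (!is.numeric(within_family_identity) ||
      within_family_identity <= 0.5 || within_family_identity > 1) {
    abort("`within_family_identity` must lie in (0.5, 1]")
  }
  if (is.null(n_diff_groups)) {
    n_diff_groups <- max(1L, round(0.04 * n_families))
  }
  if (n_diff_groups < 0 || n_diff_groups > n_families) {
    abort("`n_diff_groups` must lie in [0, n_families]")
  }
  if (missed_cleavages_max < 0) abort("`missed_cleavages_max` must be >= 0")
  w <- denovo_score_params$weights
  if (is.null(w) || abs(sum(w) - 1) > 1e-8) {
    abort("de novo mixture weights must sum to 1")
  }
  if (!all(c("dark", "noise") %in% names(w))) {
    abort("de novo mixture weights must be named 'dark' and 'noise'")
  }
  for (nm in c("beta_identified", "beta_noise")) {
    b <- denovo_score_params[[nm]]
    if (length(b) != 2 || any(b <= 0)) {
      abort(paste0("`", nm, "` must be two positive Beta shapes"))
    }
  }
  if (denovo_error_rate < 0 || denovo_error_rate > 1) {
    abort("`denovo_error_rate` must lie in [0, 1]")
  }
  if (n_extra_scans < 0) abort("`n_extra_scans` must be >= 0")

  structure(list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    family_size = as.integer(family_size),
    within_family_identity = within_family_identity,
    founder_length = as.integer(founder_length),
    n_samples_per_cohort = setNames(as.integer(n_samples_per_cohort),
                                    c("healthy", "uc")),
    n_diff_groups = as.integer(n_diff_groups),
    log2_effect_size = log2_effect_size,
    intensity_log_mean = intensity_log_mean,
    intensity_log_sd = intensity_log_sd,
    peptide_log_sd = peptide_log_sd,
    residual_log_sd = residual_log_sd,
    dropout_midpoint = dropout_midpoint,
    dropout_steepness = dropout_steepness,
    feature_without_id_prob = feature_without_id_prob,
    missed_cleavages_max = as.integer(missed_cleavages_max),
    rt_gradient_min = rt_gradient_min,
    rt_jitter_sd = rt_jitter_sd,
    denovo_score_params = denovo_score_params,
    denovo_error_rate = denovo_error_rate,
    n_extra_scans = as.integer(n_extra_scans)
  ), class = "sim_config")
}
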