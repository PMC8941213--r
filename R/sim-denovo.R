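#' Simulate a de novo sequencing run over a quantification experiment
#'
#' Every database-assigned scan receives a de novo peptide equal to the true
#' peptide with per-residue substitution probability `denovo_error_rate`,
#' and a Novor-style score drawn from the "identified" Beta component
#' (times 100). `n_extra_scans` additional scans are appended per sample in
#' two flavours chosen by the mixture weights: *dark* scans are real
#' peptides absent from the database (score from the identified component;
#' counted in the ground truth) and *noise* scans are random sequences with
#' scores from the low component.
#'
#' @param sim A `quant_sim` from [simulate_quant_experiment()].
#' @param config The same [sim_config()].
#' @return List of class `denovo_sim` with `denovo` (tibble `sample`,
#'   `scan`, `peptide`, `score`) and `true_dark` (tibble `sample`,
#'   `true_dark_count`).
#' @export
simulate_denovo_run <- function(sim, config) {
  stopifnot(inherits(sim, "quant_sim"), inherits(config, "sim_config"))
  sp <- config$denovo_score_params
  if (abs(sum(sp$weights) - 1) > 1e-8) {
    abort("de novo mixture weights must sum to 1")
  }
  with_seed(config$seed + 2L, {
    eps <- config$denovo_error_rate
    assigned <- sim$psms |>
      mutate(
        peptide_dn = mutate_peptides(.data$peptide, eps),
        score = 100 * rbeta(n(), sp$beta_identified[1], sp$beta_identified[2])
      ) |>
      select("sample", "scan", peptide = "peptide_dn", "score")

    extra <- purrr::map(unique(sim$samples$sample), function(s) {
      n_extra <- config$n_extra_scans
      if (n_extra == 0) {
        return(list(tbl = NULL, dark = tibble(sample = s, true_dark_count = 0L)))
      }
      base_scan <- max(c(0L,
        sim$psms$scan[sim$psms$sample == s],
        sim$features$scan[sim$features$sample == s]))
      is_dark <- runif(n_extra) < sp$weights[["dark"]]
      score <- ifelse(
        is_dark,
        100 * rbeta(n_extra, sp$beta_identified[1], sp$beta_identified[2]),
        100 * rbeta(n_extra, sp$beta_noise[1], sp$beta_noise[2])
      )
      list(
        tbl = tibble(
          sample = s,
          scan = base_scan + seq_len(n_extra),
          peptide = random_peptide(n_extra),
          score = score
        ),
        dark = tibble(sample = s, true_dark_count = sum(is_dark))
      )
    })

    structure(list(
      denovo = bind_rows(assigned, bind_rows(purrr::map(extra, "tbl"))) |>
        arrange(.data$sample, .data$scan),
      true_dark = bind_rows(purrr::map(extra, "dark"))
    ), class = "denovo_sim")
  })
}

# substitute each residue independently with probability eps
mutate_peptides <- function(peptides, eps) {
  if (eps == 0) return(peptides)
  vapply(peptides, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    hit <- runif(length(aa)) < eps
    if (any(hit)) {
      aa[hit] <- vapply(aa[hit], function(orig) {
        sample(setdiff(AA_ALPHABET, orig), 1)
      }, character(1))
    }
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
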