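#' Normalize a peptide string for de novo / database comparison
#'
#' Strips modification annotations (parenthesized or bracketed mass tags,
#' e.g. `"M(+15.99)"`), uppercases, and collapses leucine to isoleucine —
#' de novo sequencing cannot distinguish the two isobaric residues, so
#' comparing without the collapse would systematically penalize true
#' matches.
#'
#' @param x Character vector of peptide strings.
#' @return Character vector of bare I/L-collapsed residue strings.
#' @export
#' @examples
#' normalize_peptide("PEPM(+15.99)TLDE")  # "PEPMTIDE"
normalize_peptide <- function(x) {
  x <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", x)
  x <- gsub("[^A-Za-z]", "", x)
  x <- toupper(x)
  gsub("L", "I", x, fixed = TRUE)
}

#' Scaled Needleman-Wunsch similarity between two peptides
#'
#' Global alignment (match +1, mismatch -1, linear gap -1) of the
#' normalized sequences (see [normalize_peptide()]), with the raw score
#' scaled to
#' `100 * max(0, score) / max(nchar(a), nchar(b))`, so 100 means the
#' processed sequences are identical and 0 means no meaningful global
#' similarity. Symmetric; vectorised over pairs.
#'
#' @param peptide_a,peptide_b Character vectors of non-empty peptides.
#' @return Numeric vector of similarities in [0, 100].
#' @export
#' @examples
#' nw_similarity("PEPTIDE", "PEPTLDE")  # 100 (I/L collapsed)
nw_similarity <- function(peptide_a, peptide_b) {
  a <- normalize_peptide(peptide_a)
  b <- normalize_peptide(peptide_b)
  if (length(a) == 1) a <- rep(a, length(b))
  if (length(b) == 1) b <- rep(b, length(a))
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    abort("peptides must be non-empty after normalization")
  }
  aln <- .nw_align_cpp(a, b)
  100 * pmax(0, aln$score) / pmax(nchar(a), nchar(b))
}

#' Pair de novo and database PSMs per scan
#'
#' Outer join on (sample, scan): records may be de novo-only,
#' database-only, or paired. Paired records receive a Novor-database
#' similarity score from [nw_similarity()]; database-only records carry no
#' de novo score and are excluded from score histograms downstream.
#'
#' @param database_psms Tibble `sample`, `scan`, `peptide` (plus ignored
#'   extras); scan ids must be unique within sample.
#' @param denovo_psms Tibble `sample`, `scan`, `peptide`, `score`.
#' @return Tibble of class `denovo_matches`: `sample`, `scan`,
#'   `denovo_peptide`, `novor_score`, `database_peptide`, `similarity`
#'   (present iff both peptides are).
#' @export
pair_psms <- function(database_psms, denovo_psms) {
  stopifnot(all(c("sample", "scan", "peptide") %in% names(database_psms)),
            all(c("sample", "scan", "peptide", "score") %in% names(denovo_psms)))
  if (anyDuplicated(database_psms[c("sample", "scan")])) {
    abort("duplicate (sample, scan) in database PSMs")
  }
  if (anyDuplicated(denovo_psms[c("sample", "scan")])) {
    abort("duplicate (sample, scan) in de novo PSMs")
  }
  out <- full_join(
    denovo_psms |> select("sample", "scan", denovo_peptide = "peptide",
                          novor_score = "score"),
    database_psms |> select("sample", "scan", database_peptide = "peptide"),
    by = c("sample", "scan")
  ) |>
    mutate(similarity = NA_real_)
  paired <- !is.na(out$denovo_peptide) & !is.na(out$database_peptide)
  if (any(paired)) {
    out$similarity[paired] <- nw_similarity(out$denovo_peptide[paired],
                                            out$database_peptide[paired])
  }
  out <- out |> arrange(.data$sample, .data$scan)
  class(out) <- c("denovo_matches", class(out))
  out
}

#' Stacked Novor-score histograms and the score/similarity joint
#'
#' Bins de novo PSMs by Novor score, splitting each bin into
#' database-assigned and unassigned counts (bin totals conserve the number
#' of de novo PSMs; database-only scans are not binned). Joint
#' (novor_score, similarity) pairs are emitted for paired records only.
#'
#' @param matches A `denovo_matches` tibble from [pair_psms()].
#' @param bin_width Score bin width (default 1).
#' @return List of class `score_histograms`: `histogram` (tibble `sample`,
#'   `bin`, `assigned`, `unassigned`) and `joint` (tibble `sample`,
#'   `scan`, `novor_score`, `similarity`).
#' @export
score_histograms <- function(matches, bin_width = 1) {
  dn <- matches |> filter(!is.na(.data$denovo_peptide))
  hist <- dn |>
    mutate(
      bin = floor(.data$novor_score / bin_width) * bin_width,
      assigned = !is.na(.data$database_peptide)
    ) |>
    group_by(.data$sample, .data$bin) |>
    summarise(assigned = sum(.data$assigned),
              unassigned = sum(!.data$assigned), .groups = "drop")
  joint <- matches |>
    filter(!is.na(.data$similarity)) |>
    select("sample", "scan", "novor_score", "similarity")
  structure(list(histogram = hist, joint = joint),
            class = "score_histograms")
}

#' Dark-peptidome counts per sample
#'
#' Counts de novo PSMs at or above the Novor-score cutoff that have no
#' database assignment — spectra that likely represent peptides the
#' database cannot name.
#'
#' @param matches A `denovo_matches` tibble.
#' @param cutoff Novor-score cutoff (default 75); the comparison is
#'   `>= cutoff`.
#' @return Tibble `sample`, `dark_count`, with the cross-sample mean in
#'   the `average` attribute.
#' @export
dark_count <- function(matches, cutoff = 75) {
  out <- matches |>
    group_by(.data$sample) |>
    summarise(
      dark_count = sum(!is.na(.data$denovo_peptide) &
                         is.na(.data$database_peptide) &
                         .data$novor_score >= cutoff),
      .groups = "drop"
    )
  attr(out, "average") <- mean(out$dark_count)
  out
}

#' Dark-peptidome summary and projection arithmetic
#'
#' Summarises dark counts against the spectral totals: the dark fraction
#' is the average dark count over the average total MS2 per sample, and
#' the projected identification increase is the summed dark count over the
#' total identified spectra. Values are kept at full precision; rounding
#' is presentation-only.
#'
#' @param dark_counts Tibble from [dark_count()] or a numeric vector of
#'   per-sample dark counts.
#' @param total_ms2 Per-sample MS2 totals (same length), or a single grand
#'   total across all samples.
#' @param total_identified Total database-assigned MS2 spectra across all
#'   samples.
#' @return List of class `dark_summary`: `per_sample` tibble, `n_samples`,
#'   `avg_dark`, `avg_total_ms2`, `dark_fraction`,
#'   `projected_increase`.
#' @export
#' @examples
#' s <- dark_summary(rep(14075, 18), 2829920, 523155)
#' round(100 * s$dark_fraction)      # 9 (% of all MS2 per sample)
#' round(100 * s$projected_increase) # 48 (~50% more identifications)
dark_summary <- function(dark_counts, total_ms2, total_identified) {
  if (is.data.frame(dark_counts)) {
    samples <- dark_counts$sample
    dark <- dark_counts$dark_count
  } else {
    samples <- paste0("S", seq_along(dark_counts))
    dark <- as.numeric(dark_counts)
  }
  n <- length(dark)
  if (any(total_ms2 <= 0) || total_identified <= 0) {
    abort("spectral totals must be positive")
  }
  per_sample_total <- if (length(total_ms2) == 1) rep(total_ms2 / n, n) else {
    if (length(total_ms2) != n) abort("total_ms2 must be scalar or per-sample")
    as.numeric(total_ms2)
  }
  if (any(dark > per_sample_total)) {
    abort("dark count exceeds total MS2 in at least one sample")
  }
  per_sample <- tibble(
    sample = samples, dark_count = dark, total_ms2 = per_sample_total,
    dark_fraction = dark / per_sample_total
  )
  structure(list(
    per_sample = per_sample,
    n_samples = n,
    avg_dark = mean(dark),
    avg_total_ms2 = mean(per_sample_total),
    dark_fraction = mean(dark) / mean(per_sample_total),
    projected_increase = sum(dark) / total_identified
  ), class = "dark_summary")
}

#' @export
print.dark_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<dark_summary> %d samples; avg dark %.0f of avg %.0f MS2 ",
           "(%.1f%% of spectra); projected identification increase %.1f%%\n"),
    x$n_samples, x$avg_dark, x$avg_total_ms2,
    100 * x$dark_fraction, 100 * x$projected_increase))
  invisible(x)
}
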