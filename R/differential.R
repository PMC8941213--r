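#' Empirical-Bayes moderated two-sample t-test
#'
#' For each protein group with at least 2 non-missing values per cohort,
#' computes the pooled two-sample variance s^2 on d = n1 + n2 - 2 degrees
#' of freedom, shrinks it toward a prior variance s0^2 estimated across
#' groups, and tests the cohort difference with the moderated statistic
#'
#'   t = (mean_uc - mean_healthy) / (s_post * sqrt(1/n1 + 1/n2)),
#'   s_post^2 = (d0 * s0^2 + d * s^2) / (d0 + d),
#'
#' referred to a Student-t distribution on d0 + d degrees of freedom. The
#' prior (d0, s0^2) is estimated by method of moments on log s^2 using the
#' digamma/trigamma closed forms of the scaled-inverse-chi-square model
#' (Smyth 2004). When the observed log-variances have no excess spread
#' over the chi-square expectation, d0 is infinite and the common prior
#' variance is the geometric mean of the s^2 (so with identical variances
#' the moderated and ordinary t coincide).
#'
#' Groups present in the matrix but with fewer than 2 observations in
#' either cohort are reported with missing statistics and a
#' `presence_absence` flag; they are excluded from prior estimation.
#'
#' @param qm A normalized `quant_matrix` (values on the log scale).
#' @return Object of class `moderated_fit`; see [tidy()] and [glance()]
#'   methods. The `table` element holds per-group statistics; `prior`
#'   holds `d0` and `s02`.
#' @references Smyth, G.K. (2004) Linear models and empirical Bayes
#'   methods for assessing differential expression in microarray
#'   experiments. SAGMB 3(1), Article 3.
#' @export
moderated_ttest <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  samples <- qm_samples(qm)
  m <- qm_values(qm)
  idx_h <- samples$sample[samples$cohort == "healthy"]
  idx_u <- samples$sample[samples$cohort == "uc"]
  if (length(idx_h) == 0 || length(idx_u) == 0) {
    abort("need samples in both cohorts ('healthy' and 'uc')")
  }
  mh <- m[, idx_h, drop = FALSE]
  mu <- m[, idx_u, drop = FALSE]
  n1 <- unname(rowSums(!is.na(mh))); n2 <- unname(rowSums(!is.na(mu)))
  mean_h <- unname(rowMeans(mh, na.rm = TRUE))
  mean_u <- unname(rowMeans(mu, na.rm = TRUE))
  var_h <- unname(apply(mh, 1, var, na.rm = TRUE))
  var_u <- unname(apply(mu, 1, var, na.rm = TRUE))
  testable <- n1 >= 2 & n2 >= 2
  if (sum(testable) < 2) abort("fewer than 2 testable groups: prior not estimable")
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * ifelse(n1 > 1, var_h, 0) +
           (n2 - 1) * ifelse(n2 > 1, var_u, 0)) / d
  s2[!testable] <- NA_real_

  prior <- fit_variance_prior(s2[testable], d[testable])
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  s2_post[!testable] <- NA_real_
  tstat <- (mean_u - mean_h) / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- ifelse(testable, d0 + d, NA_real_)
  p <- 2 * pt(-abs(tstat), df = df_total)

  tbl <- tibble(
    group_id = rownames(m),
    n_healthy = as.integer(n1), n_uc = as.integer(n2),
    mean_healthy = ifelse(n1 > 0, mean_h, NA_real_),
    mean_uc = ifelse(n2 > 0, mean_u, NA_real_),
    log2_fc = ifelse(n1 > 0 & n2 > 0, mean_u - mean_h, NA_real_),
    s2 = s2, s2_post = s2_post,
    df_residual = ifelse(testable, d, NA_real_),
    df_total = df_total,
    t = ifelse(testable, tstat, NA_real_),
    p_value = ifelse(testable, p, NA_real_),
    presence_absence = !testable
  )
  structure(list(table = tbl, prior = prior, samples = samples),
            class = "moderated_fit")
}

# method-of-moments fit of the scaled-inverse-chi-square variance prior
# on log s^2 (Smyth 2004 closed forms); df may vary across groups
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    # no excess spread over the chi-square expectation: infinite prior df.
    # The prior variance is the geometric mean of the observed s^2 (no
    # bias correction), so that identical observed variances shrink to
    # themselves and the moderated t reduces to the ordinary t
    return(list(d0 = Inf, s02 = exp(mean(z))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Storey q-values at a fixed lambda
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #{p > lambda} / ((1 - lambda) * m))` at `lambda = 0.5`
#' (no smoother), then computes
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` on the sorted p-values.
#' With `pi0 = 1` this reduces to Benjamini-Hochberg adjusted p-values.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param lambda Tuning point for the pi0 estimate (default 0.5).
#' @param pi0 Optional override of the estimated null proportion.
#' @return Numeric vector of q-values in the input order.
#' @export
qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (length(p) == 0) abort("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
    if (pi0 <= 0) pi0 <- 1 / m  # all p tiny: fall back to a positive floor
  }
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Call significant protein groups
#'
#' Significance is the conjunction used in the pipeline's headline counts:
#' `p <= p_max` AND `q < q_max`. Direction follows the sign of the log2
#' fold change (UC minus healthy). The absolute-fold-change flag
#' (`|log2FC| > 1`) is reported separately — it colours the volcano plot
#' but does not gate significance.
#'
#' @param results Tibble with `p_value`, `q_value`, `log2_fc` (e.g.
#'   `tidy()` of a `moderated_fit`).
#' @param p_max,q_max Significance thresholds (defaults 0.005 and 0.1).
#' @return `results` with `significant`, `direction`
#'   (`"healthy"`/`"uc"`/`NA`), and `high_fold_change` columns added.
#' @seealso [significance_counts()]
#' @export
call_significant <- function(results, p_max = 0.005, q_max = 0.1) {
  stopifnot(all(c("p_value", "q_value", "log2_fc") %in% names(results)))
  results |>
    mutate(
      significant = !is.na(.data$p_value) & .data$p_value <= p_max &
        !is.na(.data$q_value) & .data$q_value < q_max,
      direction = dplyr::case_when(
        .data$significant & .data$log2_fc > 0 ~ "uc",
        .data$significant & .data$log2_fc < 0 ~ "healthy",
        TRUE ~ NA_character_
      ),
      high_fold_change = !is.na(.data$log2_fc) & abs(.data$log2_fc) > 1
    )
}

#' Cohort-wise enrichment counts
#'
#' @param results Output of [call_significant()].
#' @return One-row tibble `n_healthy_enriched`, `n_uc_enriched`, `total`
#'   (always the sum of the first two).
#' @export
significance_counts <- function(results) {
  stopifnot(all(c("significant", "direction") %in% names(results)))
  nh <- sum(results$significant & results$direction == "healthy", na.rm = TRUE)
  nu <- sum(results$significant & results$direction == "uc", na.rm = TRUE)
  tibble(n_healthy_enriched = nh, n_uc_enriched = nu, total = nh + nu)
}

#' Expected false positives at a q-value threshold
#'
#' At FDR threshold q, about `n * q` of the n significant calls are
#' expected to be false positives; this rounds that product.
#'
#' @param n_significant Number of significant calls.
#' @param q_threshold FDR threshold in (0, 1).
#' @return Integer expected false-positive count.
#' @export
#' @examples
#' expected_false_positives(176, 0.1)  # 18
expected_false_positives <- function(n_significant, q_threshold) {
  stopifnot(n_significant >= 0, q_threshold > 0, q_threshold < 1)
  round(n_significant * q_threshold)
}

# row-mean imputation used only for the sample-structure summaries
impute_row_means <- function(m) {
  rm <- rowMeans(m, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  for (i in seq_len(nrow(m))) m[i, is.na(m[i, ])] <- rm[i]
  m
}

#' PCA sample scores
#'
#' Column-centred singular value decomposition of the samples-by-groups
#' matrix; missing values are mean-imputed per group for this summary only
#' (the differential test never sees imputed values). The sign of each
#' component is fixed by making its largest-magnitude loading positive, so
#' scores are fully deterministic.
#'
#' @param qm A `quant_matrix`.
#' @param n_components Number of components to return (default 2).
#' @return Tibble `sample`, `cohort`, `pc1`, `pc2`, ... with the
#'   fraction of variance explained in the `var_explained` attribute.
#' @export
pca_scores <- function(qm, n_components = 2L) {
  samples <- qm_samples(qm)
  if (nrow(samples) < 2) abort("PCA needs at least 2 samples")
  x <- t(impute_row_means(qm_values(qm)))
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    load_j <- sv$v[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble(sample = samples$sample, cohort = samples$cohort)
  for (j in seq_len(k)) out[[paste0("pc", j)]] <- scores[, j]
  attr(out, "var_explained") <- sv$d^2 / sum(sv$d^2)
  out
}

#' Euclidean sample-distance matrix
#'
#' Pairwise Euclidean distances between samples over all groups, with the
#' same per-group mean imputation as [pca_scores()].
#'
#' @param qm A `quant_matrix`.
#' @return Symmetric numeric matrix with zero diagonal, sample names on
#'   both dimensions.
#' @export
sample_distance_matrix <- function(qm) {
  x <- t(impute_row_means(qm_values(qm)))
  as.matrix(dist(x, method = "euclidean"))
}
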