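norm_qm <- function(m, cohorts) hand_qm(m, cohorts, scale = "normalized-log")

test_that("identical per-group variances give the ordinary t-statistic", {
  set.seed(3)
  # groups engineered to share the same pooled variance exactly
  base <- c(-1.5, -0.5, 0.5, 1.5)          # variance fixed within cohorts
  m <- rbind(
    G1 = c(base, 10 + base),
    G2 = c(2 + base, 5 + base),
    G3 = c(-3 + base, -3 + base)
  )
  qm <- norm_qm(m, rep(c("healthy", "uc"), each = 4))
  fit <- moderated_ttest(qm)
  expect_true(is.infinite(fit$prior$d0))
  for (g in 1:3) {
    x <- m[g, 1:4]; y <- m[g, 5:8]
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(fit$table$s2_post[g], fit$table$s2[g])
    expect_equal(fit$table$t[g], unname(tt$statistic))
  }
})

test_that("moderated variance lies between prior and observed variance", {
  fx <- small_sim(seed = 77, n_families = 60, family_size = 1)
  qm <- aggregate_intensities(fx$sim$psms, fx$map, fx$sim$samples)
  fit <- moderated_ttest(normalize_glog(filter_missing(qm)))
  tbl <- fit$table[!fit$table$presence_absence, ]
  s0 <- fit$prior$s02
  lo <- pmin(tbl$s2, s0) - 1e-12
  hi <- pmax(tbl$s2, s0) + 1e-12
  expect_true(all(tbl$s2_post >= lo & tbl$s2_post <= hi))
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(19)
  # heteroscedastic rows so the prior df is finite and the closed-form
  # branch (not the degenerate equal-variance branch) is exercised
  sds <- exp(rnorm(100, 0, 0.8))
  m <- matrix(rnorm(100 * 18), 100, 18,
              dimnames = list(sprintf("G%03d", 1:100), NULL)) * sds
  cohorts <- c(rep("healthy", 8), rep("uc", 10))
  fit <- moderated_ttest(norm_qm(m, cohorts))
  design <- cbind(1, as.integer(cohorts == "uc"))
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_true(is.finite(lfit$df.prior))
  expect_equal(fit$prior$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s02, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$p_value, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("groups untestable in one cohort become presence/absence calls", {
  set.seed(4)
  m <- matrix(rnorm(5 * 6, 10), 5, 6,
              dimnames = list(paste0("G", 1:5), NULL))
  m[1, 4:6] <- NA  # healthy-only group
  m[2, 3:6] <- NA  # single uc value missing too
  fit <- moderated_ttest(norm_qm(m, rep(c("healthy", "uc"), each = 3)))
  expect_true(fit$table$presence_absence[1])
  expect_true(fit$table$presence_absence[2])
  tl <- tidy(fit)
  expect_true(all(is.na(tl$q_value[tl$presence_absence])))
  # m for q-values excludes presence/absence groups
  expect_equal(glance(fit)$n_tested, 3)
})

test_that("q-values implement the fixed-lambda Storey estimator", {
  expect_equal(qvalues(0.04, pi0 = 1), 0.04)
  expect_equal(qvalues(rep(0.3, 7)), rep(qvalues(rep(0.3, 7))[1], 7))
  expect_error(qvalues(numeric(0)), "empty")
  expect_error(qvalues(c(0.1, 1.2)), "0, 1")
  # monotone in sorted-p order
  set.seed(8)
  p <- runif(500)
  q <- qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("with pi0 = 1 q-values equal Benjamini-Hochberg on 1000 vectors", {
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    p <- round(runif(n), 3)  # ties on purpose
    expect_equal(qvalues(p, pi0 = 1), stats::p.adjust(p, method = "BH"))
  }
})

test_that("significance calls combine the p and q gates with direction", {
  empty <- tibble::tibble(p_value = numeric(0), q_value = numeric(0),
                          log2_fc = numeric(0))
  counts <- significance_counts(call_significant(empty))
  expect_equal(unlist(counts), c(n_healthy_enriched = 0L,
                                 n_uc_enriched = 0L, total = 0L))
  res <- tibble::tibble(
    p_value = c(0.001, 0.001, 0.01, 0.004, NA),
    q_value = c(0.05, 0.2, 0.05, 0.09, NA),
    log2_fc = c(2, 2, 2, -0.5, 1)
  )
  out <- call_significant(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$direction[1], "uc")
  expect_equal(out$direction[4], "healthy")
  expect_equal(out$high_fold_change, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cts <- significance_counts(out)
  expect_equal(cts$total, cts$n_healthy_enriched + cts$n_uc_enriched)
})

test_that("expected false positives follow the rounded product", {
  expect_equal(expected_false_positives(176, 0.1), 18)
  expect_equal(expected_false_positives(0, 0.1), 0)
  expect_equal(expected_false_positives(68, 0.01), 1)
})

test_that("PCA scores match an independent eigendecomposition", {
  set.seed(10)
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:6)))
  qm <- norm_qm(m, rep(c("healthy", "uc"), each = 3))
  sc <- pca_scores(qm)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  expected <- x %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    got <- sc[[paste0("pc", j)]]
    err <- min(max(abs(got - expected[, j])), max(abs(got + expected[, j])))
    expect_lt(err, 1e-8)
  }
  ve <- attr(sc, "var_explained")
  expect_lte(sum(ve), 1 + 1e-12)
  expect_equal(ve[1:2], ev$values[1:2] / sum(ev$values), tolerance = 1e-8)
})

test_that("PCA handles duplicated samples and fixes signs deterministically", {
  m <- cbind(S1 = c(1, 2, 3, 4), S2 = c(1, 2, 3, 4), S3 = c(4, 1, 0, 2))
  rownames(m) <- paste0("G", 1:4)
  sc <- pca_scores(norm_qm(m, c("healthy", "healthy", "uc")))
  expect_equal(sc$pc1[1], sc$pc1[2])
  expect_equal(sc$pc2[1], sc$pc2[2])
  sc2 <- pca_scores(norm_qm(m, c("healthy", "healthy", "uc")))
  expect_identical(sc, sc2)
})

test_that("sample distances are Euclidean, symmetric and exact", {
  set.seed(14)
  m <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("G", 1:8), paste0("S", 1:5)))
  qm <- norm_qm(m, c(rep("healthy", 2), rep("uc", 3)))
  d <- sample_distance_matrix(qm)
  expect_equal(diag(d), stats::setNames(rep(0, 5), paste0("S", 1:5)))
  expect_equal(d, t(d))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sqrt(sum((m[, i] - m[, j])^2)))
  }
  # single-coordinate perturbation has distance delta
  m2 <- m; m2[3, 2] <- m2[3, 1] <- 0; m2[, 2] <- m2[, 1]; m2[3, 2] <- 2.5
  d2 <- sample_distance_matrix(norm_qm(m2, c(rep("healthy", 2), rep("uc", 3))))
  expect_equal(d2["S1", "S2"], 2.5)
})

test_that("null simulations yield uniform moderated p-values", {
  ps <- unlist(lapply(1:20, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_families = 150, family_size = 1,
                      founder_length = 80, n_diff_groups = 0,
                      log2_effect_size = 0, n_extra_scans = 0)
    db <- generate_protein_database(cfg)
    sim <- simulate_quant_experiment(db, cfg)
    map <- build_peptide_group_map(
      sim$psms, dplyr::rename(sim$truth$membership, group_id = family_id))
    qm <- aggregate_intensities(sim$psms, map, sim$samples)
    fit <- moderated_ttest(normalize_glog(filter_missing(qm)))
    fit$table$p_value[!fit$table$presence_absence]
  }))
  expect_gt(length(ps), 2500)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
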