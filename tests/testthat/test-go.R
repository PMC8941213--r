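ann <- function(...) {
  tibble::tribble(~group_id, ~go_id, ~namespace, ~name, ...)
}

test_that("unweighted shares follow the one-count-per-term rule", {
  a <- ann("G1", "GO:1", "molecular_function", "term one")
  m <- cbind(S1 = c(10, NA), S2 = c(5, 7))
  rownames(m) <- c("G1", "G2")
  qm <- hand_qm(m, c("healthy", "uc"))
  tbl <- unweighted_go_abundance(qm, a, other_max_share = 0)
  # S1: only G1 observed, annotated -> share 1.0
  expect_equal(tbl$share[tbl$sample == "S1" & tbl$go_id == "GO:1"], 1.0)
  # S2: G1 (GO:1) + G2 (None), one count each
  expect_equal(tbl$share[tbl$sample == "S2" & tbl$go_id == "GO:1"], 0.5)
  expect_equal(tbl$share[tbl$sample == "S2" & tbl$go_id == "None"], 0.5)
})

test_that("a group with two terms contributes one full count to each", {
  a <- ann("G1", "GO:1", "molecular_function", "one",
           "G1", "GO:2", "molecular_function", "two")
  m <- cbind(S1 = 10); rownames(m) <- "G1"
  qm <- hand_qm(m, "healthy")
  tbl <- unweighted_go_abundance(qm, a, other_max_share = 0)
  # total = 2 counts; each term share 0.5 of the (all-annotated) mass
  expect_equal(sort(tbl$share), c(0.5, 0.5))
})

test_that("unannotated-only samples are pure None", {
  m <- cbind(S1 = 3); rownames(m) <- "G9"
  tbl <- unweighted_go_abundance(hand_qm(m, "uc"),
                                 ann("G1", "GO:1", "molecular_function", "x"),
                                 other_max_share = 0)
  expect_equal(tbl$share[tbl$go_id == "None"], 1.0)
})

test_that("weighted shares use mean peptide intensity per group", {
  a <- ann("G1", "GO:1", "molecular_function", "one",
           "G2", "GO:2", "molecular_function", "two")
  map <- tibble::tibble(peptide = c("AAAAK", "CCCCK", "DDDDK"),
                        group_id = c("G1", "G1", "G2"),
                        shared = FALSE)
  psms <- tibble::tibble(
    sample = "S1", peptide = c("AAAAK", "CCCCK", "DDDDK"),
    intensity = c(2, 4, 9))
  tbl <- weighted_go_abundance(psms, map, a, other_max_share = 0)
  # G1 weight mean(2,4)=3, G2 weight 9 -> shares 3/12 and 9/12
  expect_equal(tbl$share[tbl$go_id == "GO:1"], 3 / 12)
  expect_equal(tbl$share[tbl$go_id == "GO:2"], 9 / 12)
})

test_that("single annotated group saturates its term regardless of peptides", {
  a <- ann("G1", "GO:1", "molecular_function", "one")
  map <- tibble::tibble(peptide = sprintf("P%dK", 1:5), group_id = "G1",
                        shared = FALSE)
  psms <- tibble::tibble(sample = "S1", peptide = sprintf("P%dK", 1:5),
                         intensity = c(1, 10, 100, 1000, 5))
  tbl <- weighted_go_abundance(psms, map, a, other_max_share = 0)
  expect_equal(tbl$share[tbl$go_id == "GO:1"], 1.0)
})

test_that("duplicating a peptide row changes the mean-based weight", {
  # regression guard for the mean (not sum) rule: splitting one peptide's
  # intensity into two equal half-rows changes the group mean
  a <- ann("G1", "GO:1", "molecular_function", "one",
           "G2", "GO:2", "molecular_function", "two")
  map <- tibble::tibble(peptide = c("AAAAK", "AAABK", "DDDDK"),
                        group_id = c("G1", "G1", "G2"), shared = FALSE)
  whole <- tibble::tibble(sample = "S1",
                          peptide = c("AAAAK", "DDDDK"),
                          intensity = c(8, 8))
  halves <- tibble::tibble(sample = "S1",
                           peptide = c("AAAAK", "AAABK", "DDDDK"),
                           intensity = c(4, 4, 8))
  t_whole <- weighted_go_abundance(whole, map, a, other_max_share = 0)
  t_half <- weighted_go_abundance(halves, map, a, other_max_share = 0)
  # sums are conserved (8 either way) but the mean weight halves: 8 vs 4
  expect_equal(t_whole$share[t_whole$go_id == "GO:1"], 0.5)
  expect_equal(t_half$share[t_half$go_id == "GO:1"], 1 / 3)
})

test_that("both modes conserve shares and match brute-force accumulation", {
  fx <- small_sim(seed = 61)
  annotations <- simulate_go_annotations(fx$db, fx$cfg)
  qm <- aggregate_intensities(fx$sim$psms, fx$map, fx$sim$samples)
  un <- unweighted_go_abundance(qm, annotations)
  we <- weighted_go_abundance(fx$sim$psms, fx$map, annotations)
  for (tbl in list(un, we)) {
    sums <- tapply(tbl$share, list(tbl$sample, tbl$namespace), sum)
    expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  }
  # brute-force check of the weighted table (no Other collapsing)
  we0 <- weighted_go_abundance(fx$sim$psms, fx$map, annotations,
                               other_max_share = 0)
  ns <- "molecular_function"
  s <- fx$sim$samples$sample[1]
  obs <- dplyr::inner_join(fx$sim$psms, fx$map, by = "peptide")
  obs <- obs[obs$sample == s & !obs$shared, ]
  w <- tapply(obs$intensity, obs$group_id, mean)
  ann_ns <- annotations[annotations$namespace == ns, ]
  mass <- c()
  for (g in names(w)) {
    terms <- ann_ns$go_id[ann_ns$group_id == g]
    if (length(terms) == 0) terms <- "None"
    for (tt in terms) mass[tt] <- sum(mass[tt], w[[g]], na.rm = TRUE)
  }
  expected <- mass / sum(mass)
  got <- we0[we0$sample == s & we0$namespace == ns, ]
  expect_equal(sort(stats::setNames(got$share, got$go_id)),
               sort(expected), tolerance = 1e-12)
})

test_that("fold expansion averages per-sample share ratios", {
  mk <- function(shares, mode) {
    tibble::tibble(sample = rep(c("S1", "S2"), each = 2),
                   namespace = "molecular_function",
                   go_id = rep(c("GO:1", "GO:2"), 2),
                   name = rep(c("one", "two"), 2),
                   share = shares, mode = mode)
  }
  un <- mk(c(0.5, 0.5, 0.25, 0.75), "unweighted")
  we <- mk(c(0.9, 0.1, 0.75, 0.25), "weighted")
  fe <- fold_expansion(we, un)
  # GO:1 mean(0.9/0.5, 0.75/0.25) = mean(1.8, 3) = 2.4
  expect_equal(fe$fold_expansion[fe$go_id == "GO:1"], 2.4)
  # GO:2 contracts: mean(0.2, 1/3) < 1
  expect_lt(fe$fold_expansion[fe$go_id == "GO:2"], 1)
  # identical tables give 1 everywhere
  fe1 <- fold_expansion(un, un)
  expect_true(all(fe1$fold_expansion == 1))
  # zero unweighted shares are excluded and counted
  un0 <- mk(c(0, 0.5, 0.25, 0.75), "unweighted")
  fe0 <- fold_expansion(we, un0)
  expect_equal(fe0$n_samples_excluded[fe0$go_id == "GO:1"], 1)
  expect_equal(fe0$fold_expansion[fe0$go_id == "GO:1"], 3)
  expect_error(fold_expansion(we, un, go_id = "GO:404"), "not present")
})

test_that("enrichment p-values equal the hypergeometric tail", {
  a <- ann("G1", "GO:1", "molecular_function", "x")
  # significant set == universe -> p = 1
  out <- go_enrichment(c("G1", "G2"), c("G1", "G2"),
                       dplyr::bind_rows(a, ann("G2", "GO:1",
                                               "molecular_function", "x")))
  expect_equal(out$p_value, 1)
  expect_error(go_enrichment(character(0), "G1", a), "empty")

  # 8 of 10 significant annotated, 10 of 100 universe annotated
  universe <- sprintf("U%03d", 1:100)
  sig <- universe[1:10]
  annotated <- c(universe[1:8], universe[50:51])  # 8 in sig, 10 total
  big_ann <- tibble::tibble(group_id = annotated, go_id = "GO:9",
                            namespace = "molecular_function", name = "y")
  out <- go_enrichment(sig, universe, big_ann)
  expect_equal(out$p_value[out$go_id == "GO:9"],
               oracle_hyper_tail(8, 10, 10, 100), tolerance = 1e-12)
  ft <- stats::fisher.test(matrix(c(8, 2, 2, 88), 2), alternative = "greater")
  expect_equal(out$p_value[out$go_id == "GO:9"], ft$p.value, tolerance = 1e-9)
})

test_that("enrichment matches Fisher one-sided on many small tables", {
  # sweep of 2x2 tables via constructed annotation sets
  set.seed(33)
  for (rep in 1:25) {
    N <- sample(8:30, 1)
    n_sig <- sample(2:(N - 2), 1)
    K <- sample(2:(N - 1), 1)
    universe <- sprintf("P%03d", seq_len(N))
    sig <- sample(universe, n_sig)
    annotated <- sample(universe, K)
    k <- length(intersect(sig, annotated))
    a <- tibble::tibble(group_id = annotated, go_id = "GO:7",
                        namespace = "biological_process", name = "z")
    out <- go_enrichment(sig, universe, a)
    expect_equal(out$p_value, oracle_hyper_tail(k, K, n_sig, N),
                 tolerance = 1e-12)
  }
})

test_that("terms never seen in the significant set are not called enriched", {
  universe <- sprintf("P%02d", 1:40)
  sig <- universe[1:10]
  a <- tibble::tibble(group_id = universe[30:35], go_id = "GO:5",
                      namespace = "molecular_function", name = "only null")
  out <- go_enrichment(sig, universe, a)
  expect_gte(out$p_value, 0.99)
  expect_lte(out$odds_ratio, 1)
})
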