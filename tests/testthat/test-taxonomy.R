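test_that("lca covers self, genus and cross-superkingdom cases", {
  tr <- tiny_tree()
  expect_equal(lca(40L, tr), 40L)                 # single taxid: itself
  expect_equal(lca(c(40L, 41L), tr), 33L)         # two species -> genus
  expect_equal(lca(c(40L, 60L), tr), 1L)          # bacterium vs chordate -> root
  expect_error(lca(999L, tr), "unknown taxid")
  expect_error(lca(integer(0), tr), "empty")
})

test_that("lca is idempotent and order-invariant", {
  tr <- tiny_tree()
  sets <- list(c(40L, 41L, 50L), c(50L, 40L, 41L), c(60L, 40L), c(40L, 60L),
               c(40L, 40L, 41L))
  expect_equal(lca(sets[[1]], tr), lca(sets[[2]], tr))
  expect_equal(lca(sets[[3]], tr), lca(sets[[4]], tr))
  expect_equal(lca(sets[[5]], tr), lca(c(40L, 41L), tr))
  for (s in sets) expect_equal(lca(lca(s, tr), tr), lca(s, tr))
})

test_that("taxonomy tree validation rejects multiple roots", {
  bad <- tiny_tree()
  bad$parent[bad$taxid == 3L] <- 3L
  expect_error(lca(2L, bad), "exactly one root")
})

profile_of <- function(pep_taxa, intens, rank, tr = tiny_tree()) {
  peptide_taxon_profile(pep_taxa, intens, tr, rank)
}

test_that("peptide profiles assign by LCA-at-rank with Unassigned overflow", {
  pep_taxa <- tibble::tibble(
    peptide = c("AAK", "BBK", "BBK"),
    taxid = c(40L, 40L, 41L)   # AAK species-unique; BBK spans two species
  )
  intens <- tibble::tibble(sample = "S1", peptide = c("AAK", "BBK"),
                           intensity = c(3, 1))
  # at phylum: both resolve to Firmicutes
  at_phylum <- profile_of(pep_taxa, intens, "phylum")
  expect_equal(at_phylum$share[at_phylum$taxon == "Firmicutes"], 1.0)
  # at species: AAK stays, BBK's genus-level LCA goes Unassigned
  at_species <- profile_of(pep_taxa, intens, "species")
  expect_equal(
    at_species$share[at_species$taxon == "Faecalibacterium prausnitzii"],
    0.75)
  expect_equal(at_species$share[at_species$taxon == "Unassigned"], 0.25)
  expect_error(profile_of(pep_taxa, intens, "strain"), "invalid rank")
})

test_that("missing intermediate ranks roll to the nearest named ancestor", {
  # Blautia obeum (50) sits under genus 20 directly under the phylum:
  # class/order/family are absent from its lineage
  pep_taxa <- tibble::tibble(peptide = "CCK", taxid = 50L)
  intens <- tibble::tibble(sample = "S1", peptide = "CCK", intensity = 5)
  # at family rank the lineage skips straight from genus to phylum, so the
  # nearest named ancestor at-or-above family is the phylum
  fam <- profile_of(pep_taxa, intens, "family")
  expect_equal(fam$taxon, "Firmicutes")
  gen <- profile_of(pep_taxa, intens, "genus")
  expect_equal(gen$taxon, "Blautia")
})

test_that("profiles recover generator ground truth at species rank", {
  fx <- small_sim(seed = 71)
  tax <- simulate_taxonomy(fx$db, fx$sim, fx$cfg, p_shared_peptide = 0)
  prof <- peptide_taxon_profile(tax$peptide_taxa,
                                fx$sim$psms[, c("sample", "peptide",
                                                "intensity")],
                                tax$tree, "species")
  # every peptide is species-unique, so nothing is Unassigned
  expect_false("Unassigned" %in% prof$taxon)
  # ground truth: accumulate intensities by the family's species
  key <- stats::setNames(tax$family_species$taxid,
                         tax$family_species$family_id)
  truth_long <- dplyr::inner_join(fx$sim$psms,
                                  fx$sim$truth$peptides[, c("peptide",
                                                            "family_id")],
                                  by = "peptide")
  truth_long$taxid <- unname(key[truth_long$family_id])
  expected <- tapply(truth_long$intensity,
                     list(truth_long$sample, truth_long$taxid), sum)
  expected[is.na(expected)] <- 0
  expected <- expected / rowSums(expected)
  for (i in seq_len(nrow(prof))) {
    expect_equal(prof$share[i],
                 expected[prof$sample[i], as.character(prof$taxid[i])],
                 tolerance = 1e-9)
  }
})

test_that("unassigned share never grows as the rank coarsens", {
  fx <- small_sim(seed = 72)
  tax <- simulate_taxonomy(fx$db, fx$sim, fx$cfg, p_shared_peptide = 0.5)
  intens <- fx$sim$psms[, c("sample", "peptide", "intensity")]
  unassigned <- vapply(c("species", "genus", "family", "order", "class",
                         "phylum", "superkingdom"), function(r) {
    prof <- peptide_taxon_profile(tax$peptide_taxa, intens, tax$tree, r)
    u <- prof$share[prof$taxon == "Unassigned"]
    if (length(u) == 0) 0 else mean(u)
  }, numeric(1))
  expect_true(all(diff(unassigned) <= 1e-12))
})

test_that("amplicon roll-up matches a brute-force ancestor walk", {
  tr <- tiny_tree()
  counts <- tibble::tibble(
    taxid = c(40L, 41L, 50L, 60L),
    sample = "S1",
    count = c(45L, 45L, 5L, 5L)
  )
  prof <- amplicon_profile(counts, tr, "phylum")
  expect_equal(prof$share[prof$taxon == "Firmicutes"], 0.95)
  expect_equal(prof$share[prof$taxon == "Chordata"], 0.05)
  expect_equal(sum(prof$share), 1)
  # two-phylum base case
  two <- amplicon_profile(
    tibble::tibble(taxid = c(40L, 60L), sample = "S1", count = c(90L, 10L)),
    tr, "phylum")
  expect_equal(sort(two$share), c(0.1, 0.9))
  expect_error(amplicon_profile(
    tibble::tibble(taxid = 777L, sample = "S1", count = 1L), tr, "phylum"),
    "absent from tree")
  # counts on taxa coarser than the rank go to Unassigned
  coarse <- amplicon_profile(
    tibble::tibble(taxid = c(2L, 40L), sample = "S1", count = c(10L, 30L)),
    tr, "phylum")
  expect_equal(coarse$share[coarse$taxon == "Unassigned"], 0.25)
})

test_that("taxon ratios reproduce the 1:x convention", {
  prof <- tibble::tibble(sample = rep(c("S1", "S2"), each = 2),
                         taxon = rep(c("Bacteroidetes", "Firmicutes"), 2),
                         share = c(0.040, 0.230, 0.044, 0.224))
  r <- taxon_ratio(prof, "Bacteroidetes", "Firmicutes")
  expect_equal(r$numerator_share, 0.042)
  expect_equal(r$ratio, 0.042 / 0.227)
  expect_equal(r$label, "1:5")
  eq <- taxon_ratio(tibble::tibble(sample = "S1",
                                   taxon = c("A", "B"), share = c(0.3, 0.3)),
                    "A", "B")
  expect_equal(eq$label, "1:1")
  small <- taxon_ratio(tibble::tibble(sample = "S1", taxon = c("A", "B"),
                                      share = c(0.002, 0.2)), "A", "B")
  expect_equal(small$label, "1:100")
  expect_error(taxon_ratio(tibble::tibble(sample = "S1",
                                          taxon = c("A", "B"),
                                          share = c(0.1, 0)), "A", "B"),
               "zero")
})

test_that("merged-sample profiles equal the intensity-weighted average", {
  fx <- small_sim(seed = 73)
  tax <- simulate_taxonomy(fx$db, fx$sim, fx$cfg)
  intens <- fx$sim$psms[, c("sample", "peptide", "intensity")]
  two <- intens[intens$sample %in% c("H1", "H2"), ]
  merged <- two
  merged$sample <- "ALL"
  p_merged <- peptide_taxon_profile(tax$peptide_taxa, merged, tax$tree,
                                    "phylum")
  p_each <- peptide_taxon_profile(tax$peptide_taxa, two, tax$tree, "phylum")
  tot <- tapply(two$intensity, two$sample, sum)
  for (i in seq_len(nrow(p_merged))) {
    tx <- p_merged$taxon[i]
    sh <- function(s) {
      v <- p_each$share[p_each$sample == s & p_each$taxon == tx]
      if (length(v) == 0) 0 else v
    }
    expected <- (sh("H1") * tot[["H1"]] + sh("H2") * tot[["H2"]]) /
      sum(tot)
    expect_equal(p_merged$share[i], unname(expected), tolerance = 1e-9)
  }
})
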