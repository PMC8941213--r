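# Generators for the annotation-side inputs: GO maps, a small taxonomy and
# 16S-style count tables. These emulate the *shape* of InterProScan / NCBI
# taxdump / amplicon outputs at desk scale.

#' Simulate a GO annotation map for ground-truth protein groups
#'
#' Assigns each family 0 to `max_terms` GO terms drawn from a small pool
#' spanning the three namespaces, leaving a configurable fraction of
#' groups unannotated (the "None" category of the abundance plots).
#'
#' @param db A `protein_db`.
#' @param config The matching [sim_config()].
#' @param n_terms_pool Number of distinct GO ids in the pool.
#' @param max_terms Maximum terms per annotated group.
#' @param p_unannotated Probability a group carries no annotation.
#' @return Tibble `group_id`, `go_id`, `namespace`, `name`.
#' @export
simulate_go_annotations <- function(db, config, n_terms_pool = 30L,
                                    max_terms = 3L, p_unannotated = 0.3) {
  stopifnot(inherits(db, "protein_db"))
  with_seed(config$seed + 3L, {
    ns <- c("molecular_function", "biological_process", "cellular_component")
    pool <- tibble(
      go_id = sprintf("GO:%07d", seq_len(n_terms_pool)),
      namespace = sample(ns, n_terms_pool, replace = TRUE),
      name = sprintf("synthetic term %d", seq_len(n_terms_pool))
    )
    fams <- unique(db$proteins$family_id)
    bind_rows(purrr::map(fams, function(f) {
      if (runif(1) < p_unannotated) return(NULL)
      k <- sample.int(max_terms, 1)
      pool[sample.int(n_terms_pool, k), ] |> mutate(group_id = f)
    })) |>
      select("group_id", "go_id", "namespace", "name")
  })
}

#' Simulate a small taxonomy and a peptide-to-taxon map
#'
#' Builds a fixed seven-rank tree (two superkingdoms, a handful of bacterial
#' phyla plus Chordata, one lineage per species) modelled on NCBI taxdump
#' nodes, assigns every family a species, and maps each peptide to the
#' species set of the proteins containing it. A fraction of peptides gain
#' an extra random species so their LCA climbs above species level, which
#' is what feeds the "Unassigned/unknown" share of taxonomic profiles.
#'
#' @param db A `protein_db`.
#' @param sim The matching `quant_sim` (for the peptide list).
#' @param config The [sim_config()].
#' @param p_shared_peptide Probability a peptide gains one extra species.
#' @return List with `tree` (tibble `taxid`, `parent`, `rank`, `name`),
#'   `peptide_taxa` (tibble `peptide`, `taxid`) and `family_species`
#'   (tibble `family_id`, `taxid`).
#' @export
simulate_taxonomy <- function(db, sim, config, p_shared_peptide = 0.3) {
  stopifnot(inherits(db, "protein_db"), inherits(sim, "quant_sim"))
  with_seed(config$seed + 4L, {
    tree <- synthetic_taxonomy_tree()
    species <- tree$taxid[tree$rank == "species"]
    fams <- unique(db$proteins$family_id)
    family_species <- tibble(
      family_id = fams,
      taxid = sample(species, length(fams), replace = TRUE)
    )
    pep <- sim$truth$peptides |>
      left_join(family_species, by = "family_id") |>
      select("peptide", "taxid")
    extra <- pep |>
      filter(runif(n()) < p_shared_peptide) |>
      mutate(taxid = sample(species, n(), replace = TRUE))
    peptide_taxa <- bind_rows(pep, extra) |> distinct()
    list(tree = tree, peptide_taxa = peptide_taxa,
         family_species = family_species)
  })
}

# a fixed, hand-sized tree spanning the seven canonical ranks
synthetic_taxonomy_tree <- function() {
  tibble::tribble(
    ~taxid, ~parent, ~rank,          ~name,
    1L,     1L,      "root",         "root",
    2L,     1L,      "superkingdom", "Bacteria",
    3L,     1L,      "superkingdom", "Eukaryota",
    10L,    2L,      "phylum",       "Firmicutes",
    11L,    2L,      "phylum",       "Bacteroidetes",
    12L,    2L,      "phylum",       "Proteobacteria",
    13L,    3L,      "phylum",       "Chordata",
    20L,    10L,     "class",        "Clostridia",
    21L,    11L,     "class",        "Bacteroidia",
    22L,    12L,     "class",        "Gammaproteobacteria",
    23L,    13L,     "class",        "Mammalia",
    30L,    20L,     "order",        "Eubacteriales",
    31L,    21L,     "order",        "Bacteroidales",
    32L,    22L,     "order",        "Enterobacterales",
    33L,    23L,     "order",        "Primates",
    40L,    30L,     "family",       "Lachnospiraceae",
    41L,    30L,     "family",       "Ruminococcaceae",
    42L,    31L,     "family",       "Bacteroidaceae",
    43L,    32L,     "family",       "Enterobacteriaceae",
    44L,    33L,     "family",       "Hominidae",
    50L,    40L,     "genus",        "Blautia",
    51L,    41L,     "genus",        "Faecalibacterium",
    52L,    42L,     "genus",        "Bacteroides",
    53L,    43L,     "genus",        "Escherichia",
    54L,    44L,     "genus",        "Homo",
    60L,    50L,     "species",      "Blautia obeum",
    61L,    51L,     "species",      "Faecalibacterium prausnitzii",
    62L,    52L,     "species",      "Bacteroides fragilis",
    63L,    52L,     "species",      "Bacteroides vulgatus",
    64L,    53L,     "species",      "Escherichia coli",
    65L,    54L,     "species",      "Homo sapiens"
  )
}

#' Simulate a 16S-style taxon count table
#'
#' Draws per-sample multinomial read counts over the species of the
#' synthetic tree with a fixed composition vector, emulating the shape of
#' an amplicon-derived count table (taxon by sample).
#'
#' @param config A [sim_config()].
#' @param n_reads Reads per sample.
#' @param tree Taxonomy tibble; defaults to the synthetic tree.
#' @return Tibble `taxid`, `sample`, `count`.
#' @export
simulate_amplicon_counts <- function(config, n_reads = 5000L,
                                     tree = synthetic_taxonomy_tree()) {
  with_seed(config$seed + 5L, {
    species <- tree$taxid[tree$rank == "species"]
    base <- rexp(length(species)) + 0.05
    n_h <- config$n_samples_per_cohort[["healthy"]]
    n_u <- config$n_samples_per_cohort[["uc"]]
    samples <- c(sprintf("H%d", seq_len(n_h)), sprintf("UC%d", seq_len(n_u)))
    bind_rows(purrr::map(samples, function(s) {
      prob <- base * exp(rnorm(length(base), 0, 0.3))
      tibble(taxid = species, sample = s,
             count = as.integer(stats::rmultinom(1, n_reads, prob)))
    }))
  })
}
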