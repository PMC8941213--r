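# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# tiny end-to-end simulation: database, PSMs, ground-truth groups, map
small_sim <- function(seed = 42, n_families = 12, family_size = 2,
                      n_diff_groups = 3, n_extra_scans = 100, ...) {
  cfg <- sim_config(seed = seed, n_families = n_families,
                    family_size = family_size, founder_length = 120,
                    n_diff_groups = n_diff_groups,
                    n_extra_scans = n_extra_scans, ...)
  db <- generate_protein_database(cfg)
  sim <- simulate_quant_experiment(db, cfg)
  groups_truth <- dplyr::rename(sim$truth$membership, group_id = family_id)
  list(cfg = cfg, db = db, sim = sim, groups = groups_truth,
       map = build_peptide_group_map(sim$psms, groups_truth))
}

# hand-built quant matrix with explicit cohort labels
hand_qm <- function(values, cohorts, scale = "raw") {
  n_samples <- ncol(values)
  samples <- tibble::tibble(
    sample = colnames(values) %||% paste0("S", seq_len(n_samples)),
    cohort = cohorts
  )
  colnames(values) <- samples$sample
  tbl <- tibble::tibble(group_id = rownames(values) %||%
                          sprintf("G%03d", seq_len(nrow(values))))
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(values))
  fecalproteo:::new_quant_matrix(tbl, samples, scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal three-level taxonomy used in the taxonomy unit tests
tiny_tree <- function() {
  tibble::tribble(
    ~taxid, ~parent, ~rank,          ~name,
    1L,     1L,      "root",         "root",
    2L,     1L,      "superkingdom", "Bacteria",
    3L,     1L,      "superkingdom", "Eukaryota",
    10L,    2L,      "phylum",       "Firmicutes",
    11L,    2L,      "phylum",       "Bacteroidetes",
    12L,    3L,      "phylum",       "Chordata",
    20L,    10L,     "genus",        "Blautia",       # class/order/family absent
    30L,    10L,     "class",        "Clostridia",
    31L,    30L,     "order",        "Eubacteriales",
    32L,    31L,     "family",       "Oscillospiraceae",
    33L,    32L,     "genus",        "Faecalibacterium",
    40L,    33L,     "species",      "Faecalibacterium prausnitzii",
    41L,    33L,     "species",      "Faecalibacterium duncaniae",
    50L,    20L,     "species",      "Blautia obeum",
    60L,    12L,     "species",      "Homo sapiens"
  )
}
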