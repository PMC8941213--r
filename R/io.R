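# Readers and writers for the pipeline's plain-text interchange formats.
# FASTA goes through Biostrings when available (the standard route); a
# minimal fallback parser keeps the package self-contained.

#' Read protein sequences from a FASTA file
#' @param path FASTA file path.
#' @return Tibble `accession` (first whitespace-delimited token of the
#'   header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    tibble(accession = sub("\\s.*$", "", names(ss)),
           sequence = unname(as.character(ss)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    idx <- cumsum(hdr)
    tibble(
      accession = sub("\\s.*$", "", sub("^>", "", lines[hdr])),
      sequence = vapply(split(lines[!hdr], idx[!hdr]), paste,
                        character(1), collapse = "")
    )
  }
}

#' Write protein sequences to a FASTA file
#' @param proteins Tibble with `accession` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("accession", "sequence") %in% names(proteins)))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                           proteins$accession))
    Biostrings::writeXStringSet(ss, path)
  } else {
    writeLines(paste0(">", proteins$accession, "\n", proteins$sequence), path)
  }
  invisible(path)
}

#' Read / write a PSM table
#'
#' Tab-separated with columns `sample`, `scan`, `peptide`, `proteins`
#' (`;`-joined accessions), `mz`, `rt_min`, `intensity`.
#' @param path File path.
#' @return Tibble of PSM records.
#' @export
read_psm_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", scan = "i", peptide = "c", proteins = "c",
    mz = "d", rt_min = "d", intensity = "d"
  ))
}

#' @rdname read_psm_table
#' @param psms PSM tibble.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms, path)
  invisible(path)
}

#' Read / write a Novor-style de novo table
#'
#' Comma-separated with columns `sample`, `scan`, `peptide`, `score`.
#' @param path File path.
#' @return Tibble of de novo records.
#' @export
read_denovo_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample = "c", scan = "i", peptide = "c", score = "d"
  ))
}

#' @rdname read_denovo_table
#' @param denovo De novo tibble.
#' @export
write_denovo_table <- function(denovo, path) {
  readr::write_csv(denovo, path)
  invisible(path)
}

#' Read / write a quant matrix with its sample sheet
#'
#' The matrix is tab-separated with `group_id` first and one column per
#' sample; empty cells are missing. The sample sheet (`sample`, `cohort`)
#' travels in a sibling file.
#'
#' @param path Matrix TSV path.
#' @param samples_path Sample-sheet TSV path.
#' @return A `quant_matrix`.
#' @export
read_quant_matrix <- function(path, samples_path,
                              scale = c("raw", "normalized-log")) {
  values <- readr::read_tsv(path, col_types = readr::cols(
    group_id = "c", .default = "d"
  ))
  samples <- readr::read_tsv(samples_path,
                             col_types = readr::cols(.default = "c"))
  new_quant_matrix(values, samples, match.arg(scale))
}

#' @rdname read_quant_matrix
#' @param qm A `quant_matrix`.
#' @param scale Intensity scale flag recorded with the matrix.
#' @export
write_quant_matrix <- function(qm, path, samples_path) {
  readr::write_tsv(as_tibble(qm), path, na = "")
  readr::write_tsv(qm_samples(qm), samples_path)
  invisible(path)
}

#' Write protein groups as TSV and a CD-HIT-style .clstr file
#'
#' @param groups A `protein_groups` tibble from [greedy_cluster()].
#' @param path Output TSV path (`group_id`, `representative`,
#'   `accession`, `identity`).
#' @param clstr_path Optional path for a `.clstr`-equivalent layout
#'   (cluster header lines followed by member lines).
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(groups, path, clstr_path = NULL) {
  readr::write_tsv(as_tibble(groups), path)
  if (!is.null(clstr_path)) {
    lines <- unlist(lapply(split(groups, groups$group_id), function(g) {
      c(paste0(">Cluster ", g$group_id[1]),
        sprintf("%d\t%s%s", seq_len(nrow(g)) - 1, g$accession,
                ifelse(g$accession == g$representative, " *",
                       sprintf(" at %.2f%%", 100 * g$identity))))
    }))
    writeLines(lines, clstr_path)
  }
  invisible(path)
}
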