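# The quant matrix container: a wide tibble (group_id + one column per
# sample) carrying the sample sheet and the intensity scale as attributes.
# Missing is NA, never 0: an MS1 non-detection is not a zero measurement.

new_quant_matrix <- function(values, samples, scale = c("raw", "normalized-log")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(values), names(values)[1] == "group_id",
            all(samples$sample %in% names(values)[-1]))
  out <- as_tibble(values)[, c("group_id", samples$sample)]
  attr(out, "samples") <- as_tibble(samples)
  attr(out, "scale") <- scale
  class(out) <- c("quant_matrix", class(as_tibble(values)))
  out
}

#' Sample sheet of a quant matrix
#' @param qm A `quant_matrix`.
#' @return Tibble with `sample` and `cohort`.
#' @export
qm_samples <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  attr(qm, "samples")
}

#' Intensity scale flag of a quant matrix
#' @param qm A `quant_matrix`.
#' @return `"raw"` or `"normalized-log"`.
#' @export
qm_scale <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  attr(qm, "scale")
}

#' Numeric matrix view of a quant matrix
#' @param qm A `quant_matrix`.
#' @return Numeric matrix, groups in rows (rownames = group ids), samples
#'   in columns; missing values are `NA`.
#' @export
qm_values <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  m <- as.matrix(qm[, qm_samples(qm)$sample])
  storage.mode(m) <- "double"
  rownames(m) <- qm$group_id
  m
}

# rebuild preserving metadata after row filtering / value replacement
replace_qm_values <- function(qm, m, scale = qm_scale(qm)) {
  values <- tibble(group_id = rownames(m)) |>
    dplyr::bind_cols(as_tibble(m))
  new_quant_matrix(values, qm_samples(qm), scale)
}

#' @export
print.quant_matrix <- function(x, ...) {
  s <- qm_samples(x)
  cat(sprintf("<quant_matrix> %d groups x %d samples (%s scale; %s)\n",
              nrow(x), nrow(s), qm_scale(x),
              paste(sprintf("%s=%d", unique(s$cohort),
                            as.integer(table(s$cohort)[unique(s$cohort)])),
                    collapse = ", ")))
  NextMethod()
}
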