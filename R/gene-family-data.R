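# Packaged study tables: the published counts and identifier lists that the
# cohort-level operations consume. The full 371-model ERF/AP2 annotation is
# not published as a list, so `erf_annotated_ids()` reconstitutes a set of
# the published size from the published identifiers (the 12 exclusions and
# the 10 promoter genes) padded with clearly labelled synthetic placeholder
# models.

#' Published screening counts of primary hairy roots
#'
#' @return data.frame with columns `n_analyzed`, `n_positive`,
#'   `n_negative`.
#' @export
hairy_root_counts <- function() {
  utils::read.csv(system.file("extdata", "hairy_root_counts.csv",
                              package = "promoterglow"))
}

#' The published ERF/AP2 exclusion list
#'
#' Gene models dropped from the family tree as too divergent or
#' incorrectly predicted.
#'
#' @return character vector of 12 model identifiers.
#' @export
erf_exclusion_ids <- function() {
  readLines(system.file("extdata", "erf_exclusions.txt",
                        package = "promoterglow"))
}

#' The ten ERF gene models whose promoters were studied
#' @return named character vector (promoter label -> model identifier).
#' @export
erf_studied_ids <- function() {
  df <- utils::read.csv(system.file("extdata", "erf_studied_ids.csv",
                                    package = "promoterglow"))
  stats::setNames(df$gene_id, df$promoter)
}

#' Reconstituted annotated ERF/AP2 model set
#'
#' The published identifiers (exclusions first, then the studied genes)
#' padded with synthetic placeholder models (`GlymaSYNnnnn.1`) up to the
#' annotated family size, preserving the published counts for
#' [filter_models()].
#'
#' @param n_total annotated family size (default 371).
#' @return character vector of `n_total` unique identifiers.
#' @export
erf_annotated_ids <- function(n_total = 371) {
  real <- c(erf_exclusion_ids(), unname(erf_studied_ids()))
  if (n_total < length(real))
    stop("n_total smaller than the published identifier count",
         call. = FALSE)
  pad <- sprintf("GlymaSYN%04d.1", seq_len(n_total - length(real)))
  c(real, pad)
}
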