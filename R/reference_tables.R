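#' Reference tables from the motivating published biomarker study
#'
#' The package ships three small transcribed tables from the published
#' low-grade-inflammation biomarker study its workflow models. They are
#' inputs, not outputs: the package's arithmetic and classification
#' operations are applied to them to reproduce the study's derived numbers
#' (gene-set totals and immune percentages, candidate-pool sizes and
#' deduplicated candidate counts, marker tissue assignments, confirmation
#' level tallies).
#'
#' @param which One of `"selection"` (per-parent ontology gene counts, with
#'   atlas-addition rows flagged by `source == "atlas"`), `"candidates"`
#'   (per-parent candidate listings, comma-joined) or `"markers"` (the 18
#'   cohort-verified markers with their Spearman correlations to hepatic
#'   and adipose inflammation — `NA` when the study reported the value only
#'   as lying inside the `[-0.6, 0.6]` no-relation band — and literature
#'   confirmation levels).
#' @return A tibble.
#' @export
reference_table <- function(which = c("selection", "candidates",
                                      "markers")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("reference_", which, ".tsv"),
                      package = "inflamark", mustWork = TRUE)
  read_tsv_base(path, which)
}

#' Deduplicated candidate union from a per-parent candidate table
#'
#' Splits the comma-joined `candidates` column and returns the unique gene
#' set; a gene listed under several parent terms counts once.
#'
#' @param candidate_rows Tibble with a `candidates` column.
#' @return Sorted character vector of unique gene symbols.
#' @export
candidate_union <- function(candidate_rows) {
  genes <- unlist(strsplit(candidate_rows$candidates, ",", fixed = TRUE))
  genes <- trimws(genes)
  sort(unique(toupper(genes[nzchar(genes)])))
}
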