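#' Classify a gene's tissue specificity from a cross-tissue profile
#'
#' Implements the four-fold rule used by tissue expression atlases:
#' *tissue-enriched* if the top tissue's level is at least `fold` times the
#' maximum of all other tissues ("at least" is inclusive, so exactly
#' four-fold qualifies); otherwise *group-enriched* for the smallest prefix
#' group (tissues sorted by level descending, ties broken by tissue name,
#' sizes within `group_range`) whose minimum level is at least `fold` times
#' the maximum outside the group; otherwise *not-specific*. With the `mean`
#' denominator strategy the comparison is against the average, not the
#' maximum, of the non-group tissues — the laxer published variant of the
#' rule; `max` is the default, stricter reading. All-zero profiles are
#' not-specific (no division is attempted).
#'
#' @param levels Named non-negative numeric vector: expression per tissue.
#' @param fold Fold cutoff (> 1), default 4.
#' @param group_range Integer pair, allowed group sizes (default 2..5).
#' @param denominator `"max"` (default) or `"mean"`.
#' @param group_strategy `"min"` (default) or `"mean"`: whether the group is
#'   represented by its minimum or its mean level.
#' @return A list with `class` (one of `"tissue-enriched"`,
#'   `"group-enriched"`, `"not-specific"`) and `tissues` (character vector
#'   of the enriched tissue set, empty for not-specific).
#' @export
classify_gene_specificity <- function(levels, fold = 4,
                                      group_range = c(2L, 5L),
                                      denominator = c("max", "mean"),
                                      group_strategy = c("min", "mean")) {
  stopifnot(fold > 1, length(levels) >= 2L, !is.null(names(levels)))
  denominator <- match.arg(denominator)
  group_strategy <- match.arg(group_strategy)
  if (any(!is.finite(levels)) || any(levels < 0)) {
    stop("expression levels must be finite and >= 0", call. = FALSE)
  }
  not_specific <- list(class = "not-specific", tissues = character())
  if (all(levels == 0)) return(not_specific)
  ord <- order(-levels, names(levels))
  lv <- levels[ord]
  n <- length(lv)
  rest_stat <- function(rest) {
    if (denominator == "max") max(rest) else mean(rest)
  }
  # single tissue
  if (lv[1] > 0 && lv[1] >= fold * rest_stat(lv[-1])) {
    return(list(class = "tissue-enriched", tissues = names(lv)[1]))
  }
  # smallest qualifying prefix group
  for (k in seq(group_range[1], min(group_range[2], n - 1L))) {
    grp <- lv[seq_len(k)]
    rest <- lv[-seq_len(k)]
    grp_stat <- if (group_strategy == "min") min(grp) else mean(grp)
    if (grp_stat > 0 && grp_stat >= fold * rest_stat(rest)) {
      return(list(class = "group-enriched",
                  tissues = sort(names(grp))))
    }
  }
  not_specific
}

#' Call tissue-specific genes from an atlas table
#'
#' Classifies every gene in the atlas and returns those whose enriched
#' tissue set contains `tissue` (tissue-enriched in it, or member of a
#' group-enriched set including it).
#'
#' @param atlas Tibble from [read_atlas_table()].
#' @param tissue Tissue column name to query.
#' @param thresholds A [thresholds()] object.
#' @param config Optional [run_config()] for the denominator / group
#'   strategy variants.
#' @return Sorted character vector of upper-cased gene symbols.
#' @export
atlas_tissue_specific_genes <- function(atlas, tissue,
                                        thresholds = inflamark::thresholds(),
                                        config = NULL) {
  calls <- atlas_specificity_calls(atlas, thresholds, config)
  sort(unique(toupper(calls$gene[vapply(calls$tissues, function(ts)
    tissue %in% ts, logical(1))])))
}

#' Specificity calls for every gene in an atlas
#'
#' @inheritParams atlas_tissue_specific_genes
#' @return A tibble with columns `gene`, `class` and list-column `tissues`.
#' @export
atlas_specificity_calls <- function(atlas,
                                    thresholds = inflamark::thresholds(),
                                    config = NULL) {
  tissues <- attr(atlas, "tissues")
  if (is.null(tissues)) tissues <- setdiff(names(atlas), c("gene", "uniprot"))
  denominator <- if (is.null(config)) "max" else config$specificity_denominator
  group_strategy <- if (is.null(config)) "min" else config$group_strategy
  m <- as.matrix(atlas[tissues])
  rownames(m) <- atlas$gene
  calls <- lapply(seq_len(nrow(m)), function(i) {
    classify_gene_specificity(m[i, ], fold = thresholds$fold_specificity,
                              group_range = thresholds$group_size_range,
                              denominator = denominator,
                              group_strategy = group_strategy)
  })
  tibble::tibble(
    gene = atlas$gene,
    class = vapply(calls, `[[`, character(1), "class"),
    tissues = lapply(calls, `[[`, "tissues")
  )
}

#' Unique atlas additions to the ontology-derived gene set
#'
#' Tissue-specific immune-associated genes from the atlas that the ontology
#' branch did not already select: `(hpa_genes` \eqn{\cap}
#' `immune_genes) \ go_genes`. Symbols are upper-cased before the set
#' algebra.
#'
#' @param hpa_genes Atlas tissue-specific genes.
#' @param go_genes Ontology-derived tissue genes.
#' @param immune_genes Immune gene universe.
#' @return Sorted character vector.
#' @export
unique_hpa_additions <- function(hpa_genes, go_genes, immune_genes) {
  hpa <- toupper(hpa_genes)
  sort(setdiff(intersect(hpa, toupper(immune_genes)), toupper(go_genes)))
}
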