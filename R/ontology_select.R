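#' Round half away from zero
#'
#' Printed immune percentages use conventional rounding (0.5 rounds up), not
#' the round-half-even rule of [base::round()].
#' @param x Numeric vector.
#' @return Integer vector.
#' @noRd
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Curate keyword hits against a whitelist
#'
#' Manual curation (keeping only human, non-embryonic, endogenous,
#' tissue-specific processes) is emulated by an explicit whitelist of parent
#' term ids carried in the run configuration, which keeps the step
#' reproducible. Whitelist ids that are not among the hits are tolerated.
#'
#' @param term_ids Character vector of candidate term ids (keyword hits).
#' @param whitelist Character vector of approved parent term ids.
#' @return Sorted character vector: `intersect(term_ids, whitelist)`.
#' @export
curate_terms <- function(term_ids, whitelist) {
  kept <- intersect(term_ids, whitelist)
  dropped <- setdiff(term_ids, kept)
  if (length(dropped)) {
    rlang::inform(
      paste0("curation removed ", length(dropped), " term(s)"),
      class = "inflamark_curation", .frequency = "always",
      .frequency_id = "curation"
    )
  }
  sort(kept)
}

# Apply the species / object-type filter to an annotation table and
# upper-case gene symbols so human and mouse casings compare equal.
filter_annotations <- function(annotations, config) {
  ok <- annotations$taxon == config$taxon &
    annotations$object_type == config$object_type
  out <- annotations[ok, , drop = FALSE]
  out$gene <- toupper(out$gene)
  out
}

#' Build the immune gene universe
#'
#' Genes annotated (after the species/object-type filter) to the descendant
#' closure of the immune root terms — conventionally "immune system
#' process", "inflammatory response" and "cytokine production".
#'
#' @param onto An [ontology()].
#' @param annotations Annotation tibble from [read_gaf()].
#' @param immune_roots Character vector of immune root term ids.
#' @param config A [run_config()] (supplies the species/type filter).
#' @return Sorted character vector of upper-cased gene symbols.
#' @export
build_immune_gene_set <- function(onto, annotations, immune_roots, config) {
  if (!length(immune_roots)) return(character())
  closure <- descendant_closure(onto, immune_roots)
  ann <- filter_annotations(annotations, config)
  sort(unique(ann$gene[ann$term_id %in% closure]))
}

#' Build per-parent term gene sets
#'
#' For each curated parent term: its descendant closure (the parent plus all
#' child terms), the genes annotated to any member term, and the immune
#' subset of those genes.
#'
#' @param onto An [ontology()].
#' @param annotations Annotation tibble from [read_gaf()].
#' @param parent_ids Curated parent term ids.
#' @param immune_genes Immune gene universe from [build_immune_gene_set()].
#' @param config A [run_config()].
#' @return A list of `term_gene_set` records: `parent_id`, `parent_name`,
#'   `member_terms`, `genes`, `immune_genes`.
#' @export
build_term_gene_sets <- function(onto, annotations, parent_ids,
                                 immune_genes, config) {
  ann <- filter_annotations(annotations, config)
  name_of <- stats::setNames(onto$terms$name, onto$terms$id)
  lapply(sort(parent_ids), function(pid) {
    members <- descendant_closure(onto, pid)
    genes <- sort(unique(ann$gene[ann$term_id %in% members]))
    structure(
      list(
        parent_id = pid,
        parent_name = unname(name_of[pid]),
        member_terms = members,
        genes = genes,
        immune_genes = intersect(genes, immune_genes)
      ),
      class = "term_gene_set"
    )
  })
}

#' Retain parent terms overlapping the immune gene universe
#'
#' A tissue parent term survives only if at least one of its genes is also
#' in an immune-related term — the mechanistic link between the tissue
#' process and inflammation.
#'
#' @param term_gene_sets List from [build_term_gene_sets()].
#' @param immune_genes Immune gene universe.
#' @return The retained subset of `term_gene_sets`, immune subsets
#'   recomputed against `immune_genes`.
#' @export
filter_tissue_terms_by_immune_overlap <- function(term_gene_sets,
                                                  immune_genes) {
  out <- lapply(term_gene_sets, function(s) {
    s$immune_genes <- intersect(s$genes, immune_genes)
    s
  })
  Filter(function(s) length(s$immune_genes) >= 1L, out)
}

#' Summarize a tissue's retained term gene sets
#'
#' One row per parent term (child-term count, gene count, immune count and
#' rounded immune percentage) plus a totals row. Totals are sums of the
#' per-parent counts — a gene annotated under several parents is counted in
#' each, matching how selection tables in this field tabulate per-ontology
#' membership — so the total is not a set union.
#'
#' @param term_gene_sets Retained sets for one tissue.
#' @param tissue Tissue label for the `tissue` column.
#' @return A tibble with columns `tissue`, `accession`, `parent_name`,
#'   `n_children`, `n_genes`, `n_immune`, `pct_immune`; the last row has
#'   accession `"TOTAL"`.
#' @export
summarize_selection <- function(term_gene_sets, tissue) {
  rows <- lapply(term_gene_sets, function(s) {
    n_genes <- length(s$genes)
    n_imm <- length(s$immune_genes)
    tibble::tibble(
      tissue = tissue,
      accession = s$parent_id,
      parent_name = s$parent_name,
      n_children = length(s$member_terms) - 1L,
      n_genes = n_genes,
      n_immune = n_imm,
      pct_immune = if (n_genes > 0) round_half_up(100 * n_imm / n_genes)
                   else NA_integer_
    )
  })
  per_parent <- dplyr::bind_rows(rows)
  if (!nrow(per_parent)) {
    per_parent <- tibble::tibble(
      tissue = character(), accession = character(),
      parent_name = character(), n_children = integer(),
      n_genes = integer(), n_immune = integer(), pct_immune = integer())
  }
  summarize_selection_rows(per_parent, tissue)
}

#' Append a totals row to per-parent selection counts
#'
#' Works on any per-parent count table with columns `n_children`,
#' `n_genes`, `n_immune` — including a transcribed published selection
#' table — applying the same arithmetic as [summarize_selection()]: totals
#' are column sums and the overall immune percentage is
#' `round(100 * sum(n_immune) / sum(n_genes))` (half rounds up).
#'
#' @param per_parent Tibble of per-parent rows.
#' @param tissue Tissue label for the totals row.
#' @return `per_parent` with `pct_immune` (re)computed and a totals row
#'   (accession `"TOTAL"`) appended.
#' @export
summarize_selection_rows <- function(per_parent, tissue) {
  per_parent$pct_immune <- ifelse(
    per_parent$n_genes > 0,
    round_half_up(100 * per_parent$n_immune / per_parent$n_genes),
    NA_integer_)
  tot_genes <- sum(per_parent$n_genes)
  tot_imm <- sum(per_parent$n_immune)
  totals <- tibble::tibble(
    tissue = tissue,
    accession = "TOTAL",
    parent_name = "all parent terms",
    n_children = sum(per_parent$n_children),
    n_genes = tot_genes,
    n_immune = tot_imm,
    pct_immune = if (tot_genes > 0) round_half_up(100 * tot_imm / tot_genes)
                 else NA_integer_
  )
  dplyr::bind_rows(per_parent, totals)
}

#' Run the full ontology selection branch for one tissue
#'
#' Keyword search, curation, descendant expansion, immune-overlap filtering
#' and summary in one call.
#'
#' @param onto An [ontology()].
#' @param annotations Annotation tibble from [read_gaf()].
#' @param tissue `"adipose"` or `"liver"` (selects the keyword list).
#' @param config A [run_config()].
#' @return A list with `hits` (keyword hits), `curated`, `retained` (term
#'   gene sets after the immune filter), `summary` (tibble), and `genes`
#'   (union of retained parents' gene sets).
#' @export
select_tissue_genes <- function(onto, annotations, tissue, config) {
  keywords <- config$keywords[[tissue]]
  if (is.null(keywords)) stop("no keywords configured for tissue ", tissue,
                              call. = FALSE)
  hits <- find_terms_by_keyword(onto, keywords)
  curated <- curate_terms(hits, config$curation_whitelist)
  immune <- build_immune_gene_set(onto, annotations, config$immune_roots,
                                  config)
  sets <- build_term_gene_sets(onto, annotations, curated, immune, config)
  retained <- filter_tissue_terms_by_immune_overlap(sets, immune)
  list(
    hits = hits,
    curated = curated,
    immune_genes = immune,
    retained = retained,
    summary = summarize_selection(retained, tissue),
    genes = sort(unique(unlist(lapply(retained, `[[`, "genes"))))
  )
}
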