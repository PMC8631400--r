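#' Match genes against biomarker records
#'
#' Matching priority: UniProt accession when both the gene entry and the
#' record carry one, otherwise upper-cased gene symbol.
#'
#' @param genes Character vector of symbols, or a tibble with columns `gene`
#'   and optionally `uniprot`.
#' @param db Biomarker record tibble from [read_biomarker_table()].
#' @return Logical matrix-free helper: for each input gene, the row indices
#'   of `db` that match it (a list).
#' @noRd
match_biomarker_records <- function(genes, db) {
  if (is.character(genes)) {
    genes <- tibble::tibble(gene = genes, uniprot = NA_character_)
  }
  if (!"uniprot" %in% names(genes)) genes$uniprot <- NA_character_
  db_gene <- toupper(db$gene)
  db_up <- db$uniprot
  lapply(seq_len(nrow(genes)), function(i) {
    up <- genes$uniprot[i]
    by_up <- if (!is.na(up) && nzchar(up)) which(!is.na(db_up) & db_up == up)
             else integer()
    if (length(by_up)) by_up
    else which(db_gene == toupper(genes$gene[i]))
  })
}

#' Filter genes to established blood protein markers
#'
#' A gene survives if it has at least one record of the accepted marker type
#' (proteome) with an accepted substrate (plasma or serum) and accepted
#' evidence (early human studies, late human studies, recommended/approved).
#'
#' @param genes Character vector of symbols or tibble with `gene`/`uniprot`.
#' @param db Biomarker record tibble.
#' @param config A [run_config()] supplying the accepted label sets.
#' @return Sorted character vector of upper-cased surviving gene symbols.
#' @export
filter_blood_protein_markers <- function(genes, db,
                                         config = run_config()) {
  qualifying <- tolower(db$marker_type) == config$accepted_marker_type &
    tolower(db$substrate) %in% config$accepted_substrates &
    tolower(db$evidence) %in% config$accepted_evidence
  matches <- match_biomarker_records(genes, db)
  symbols <- if (is.character(genes)) genes else genes$gene
  keep <- vapply(matches, function(idx) any(qualifying[idx]), logical(1))
  sort(unique(toupper(symbols[keep])))
}

#' Novelty label from the three rubric criteria
#'
#' A candidate is `"curated"` only if it (i) is described in one of the
#' configured low-grade-inflammation conditions, (ii) is commonly analyzed
#' in the adult population, and (iii) is used as a diagnostic biomarker in
#' those conditions; any `FALSE` makes it `"novel"`.
#'
#' @param cond_disease,cond_common,cond_diagnostic Logical scalars.
#' @return `"curated"` or `"novel"`.
#' @export
novelty_label <- function(cond_disease, cond_common, cond_diagnostic) {
  stopifnot(is.logical(cond_disease), is.logical(cond_common),
            is.logical(cond_diagnostic))
  if (isTRUE(cond_disease) && isTRUE(cond_common) && isTRUE(cond_diagnostic))
    "curated" else "novel"
}

#' Assign novelty to a gene from its biomarker records
#'
#' Evaluates the three criteria over all records for the gene: (i) any
#' record's condition list intersects the disease list; (ii) any record is
#' commonly analyzed; (iii) any record is in diagnostic use in one of those
#' diseases.
#'
#' @param records Biomarker record tibble rows for one gene.
#' @param diseases Character vector of disease labels (lower-cased).
#' @return `"curated"` or `"novel"`.
#' @export
assign_novelty <- function(records, diseases) {
  in_disease <- vapply(records$conditions, function(cl)
    length(intersect(tolower(cl), tolower(diseases))) > 0, logical(1))
  cond_i <- any(in_disease)
  cond_ii <- any(records$commonly_analyzed, na.rm = TRUE)
  cond_iii <- any(records$diagnostic_use & in_disease, na.rm = TRUE)
  novelty_label(cond_i, cond_ii, cond_iii)
}

#' Assemble the candidate biomarker table for one tissue
#'
#' Per-parent rows list each parent term's candidates (its immune genes that
#' survived the blood-marker filter); an extra row lists the atlas-only
#' additions. A gene may appear under several parents but is counted once in
#' the deduplicated union, which defines the tissue's candidate count.
#'
#' @param term_gene_sets Retained term gene sets for the tissue.
#' @param hpa_additions Atlas-unique immune additions
#'   ([unique_hpa_additions()]).
#' @param filtered_genes Genes surviving [filter_blood_protein_markers()].
#' @param tissue Tissue label.
#' @param db Optional biomarker record tibble: when given, each candidate
#'   gets a novelty label via [assign_novelty()].
#' @param config A [run_config()].
#' @param hpa_specific_genes Optional character vector of atlas
#'   tissue-specific genes, used to set each candidate's `hpa_specific`
#'   flag.
#' @return A list with `table` (per-parent tibble: `tissue`, `accession`,
#'   `parent_name`, `n_candidates`, `candidates` comma-joined) and
#'   `candidates` (one row per unique gene: `gene`, `tissue`,
#'   `source_parents`, `hpa_specific`, `novelty`).
#' @export
assemble_candidate_table <- function(term_gene_sets, hpa_additions,
                                     filtered_genes, tissue,
                                     db = NULL, config = run_config(),
                                     hpa_specific_genes = character()) {
  filtered_genes <- toupper(filtered_genes)
  rows <- lapply(term_gene_sets, function(s) {
    cand <- sort(intersect(s$immune_genes, filtered_genes))
    tibble::tibble(
      tissue = tissue, accession = s$parent_id, parent_name = s$parent_name,
      n_candidates = length(cand),
      candidates = paste(cand, collapse = ",")
    )
  })
  hpa_cand <- sort(intersect(toupper(hpa_additions), filtered_genes))
  rows <- c(rows, list(tibble::tibble(
    tissue = tissue, accession = "HPA", parent_name = "additional from atlas",
    n_candidates = length(hpa_cand),
    candidates = paste(hpa_cand, collapse = ",")
  )))
  table <- dplyr::bind_rows(rows)

  per_gene_parents <- list()
  for (s in term_gene_sets) {
    for (g in intersect(s$immune_genes, filtered_genes)) {
      per_gene_parents[[g]] <- c(per_gene_parents[[g]], s$parent_id)
    }
  }
  all_genes <- sort(unique(c(names(per_gene_parents), hpa_cand)))
  novelty <- rep(NA_character_, length(all_genes))
  if (!is.null(db)) {
    matches <- match_biomarker_records(all_genes, db)
    novelty <- vapply(seq_along(all_genes), function(i) {
      idx <- matches[[i]]
      if (!length(idx)) return("novel")
      assign_novelty(db[idx, , drop = FALSE], config$diseases)
    }, character(1))
  }
  candidates <- tibble::tibble(
    gene = all_genes,
    tissue = tissue,
    source_parents = lapply(all_genes, function(g)
      sort(unique(per_gene_parents[[g]] %||% character()))),
    hpa_specific = all_genes %in% toupper(hpa_specific_genes) |
      all_genes %in% hpa_cand,
    novelty = novelty
  )
  list(table = table, candidates = candidates)
}
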