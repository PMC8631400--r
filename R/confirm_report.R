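#' Literature confirmation level from the three evidence conditions
#'
#' The rubric scores human-literature support for a marker: condition (i) a
#' mechanistic rationale links the marker to the tissue; (ii) the marker is
#' associated with tissue-specific diseases; (iii) the marker is associated
#' with one or more metabolic disorders. Level 3 (confirmed) when all three
#' hold; level 2 (putative) when exactly two hold; level 1 (possible) when
#' exactly one holds and it is condition (i) or (ii); level 0 (not
#' confirmed) when none holds or only condition (iii) holds. Vectorized.
#'
#' @param cond_i,cond_ii,cond_iii Logical vectors.
#' @return Integer vector of levels 0-3.
#' @export
assign_confirmation_level <- function(cond_i, cond_ii, cond_iii) {
  stopifnot(is.logical(cond_i), is.logical(cond_ii), is.logical(cond_iii))
  n_met <- cond_i + cond_ii + cond_iii
  ifelse(n_met == 3L, 3L,
    ifelse(n_met == 2L, 2L,
      ifelse(n_met == 1L & (cond_i | cond_ii), 1L, 0L)))
}

#' Read a literature-evidence table
#'
#' TSV with columns `gene`, `tissue`, `cond_i`, `cond_ii`, `cond_iii`
#' (logicals) and optional free-text `notes`. The confirmation level is
#' always recomputed from the three flags via
#' [assign_confirmation_level()].
#'
#' @param path Path to the evidence TSV.
#' @return A tibble with a `level` column appended.
#' @export
read_evidence_table <- function(path) {
  df <- read_tsv_base(path, "evidence")
  need <- c("gene", "tissue", "cond_i", "cond_ii", "cond_iii")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("evidence table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cc in c("cond_i", "cond_ii", "cond_iii")) {
    df[[cc]] <- as.logical(df[[cc]])
  }
  df$level <- assign_confirmation_level(df$cond_i, df$cond_ii, df$cond_iii)
  df
}

#' Tally confirmation levels
#'
#' @param levels Integer vector of levels (0-3).
#' @return Named integer vector with counts for `"0"`, `"1"`, `"2"`, `"3"`;
#'   the counts sum to `length(levels)`.
#' @export
tally_levels <- function(levels) {
  stopifnot(all(levels %in% 0:3))
  out <- stats::setNames(integer(4), as.character(0:3))
  tab <- table(factor(levels, levels = 0:3))
  out[names(tab)] <- as.integer(tab)
  out
}

#' Assemble the final biomarker report
#'
#' Joins the verified candidates with their tissue classification,
#' correlations, literature confirmation level and a biological function
#' category (from the configuration mapping). Verified markers without an
#' evidence record are kept with an `NA` level rather than dropped.
#' Markers classified `both` are listed with that label and belong to
#' neither tissue-specific list. Ordering is deterministic: tissue
#' assignment, then gene.
#'
#' @param verified Named list of verified gene vectors per tissue (names
#'   `liver`, `WAT`).
#' @param correlations Named list of correlation tibbles per tissue from
#'   [correlate_expression_to_histology()].
#' @param evidence Evidence tibble from [read_evidence_table()] (or `NULL`).
#' @param config A [run_config()]; `function_categories` supplies the
#'   gene -> category mapping.
#' @return A tibble with columns `gene`, `assignment`, `rho_liver`,
#'   `rho_wat`, `level`, `category`.
#' @export
final_biomarker_report <- function(verified, correlations, evidence = NULL,
                                   config = run_config()) {
  genes <- sort(unique(unlist(verified)))
  rho_of <- function(tissue) {
    cr <- correlations[[tissue]]
    stats::setNames(cr$rho, cr$gene)[genes]
  }
  rho_liver <- rho_of("liver")
  rho_wat <- rho_of("WAT")
  assignment <- classify_tissue_marker(rho_liver, rho_wat,
                                       config$thresholds$rho_cutoff)
  # a verified candidate only counts for a tissue it was verified in
  assignment[assignment == "hepatic" &
               !(genes %in% verified$liver)] <- "none"
  assignment[assignment == "adipose" & !(genes %in% verified$WAT)] <- "none"
  level <- rep(NA_integer_, length(genes))
  if (!is.null(evidence) && nrow(evidence)) {
    lv <- stats::setNames(evidence$level, toupper(evidence$gene))
    hit <- toupper(genes) %in% names(lv)
    level[hit] <- lv[toupper(genes)[hit]]
  }
  category <- rep(NA_character_, length(genes))
  if (!is.null(config$function_categories)) {
    fc <- config$function_categories
    hit <- toupper(genes) %in% toupper(names(fc))
    category[hit] <- unname(fc[match(toupper(genes)[hit],
                                     toupper(names(fc)))])
  }
  out <- tibble::tibble(
    gene = genes, assignment = assignment,
    rho_liver = unname(rho_liver), rho_wat = unname(rho_wat),
    level = level, category = category
  )
  out[order(out$assignment, out$gene), , drop = FALSE]
}
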