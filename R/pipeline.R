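#' Run the complete biomarker workflow on an input directory
#'
#' Executes every stage in order: ontology selection per tissue, atlas
#' specificity calls and unique additions, blood-marker filtering and
#' candidate assembly, cohort verification (normalization, NB Wald
#' differential expression, criteria a-c, expression-histology correlation,
#' tissue classification), literature confirmation, and the final report.
#' Expects the file layout written by [simulate_inputs()]; any real data
#' snapshot in the same formats works identically.
#'
#' @param input_dir Directory holding `ontology.obo`, `annotations.gaf`,
#'   `atlas.tsv`, `biomarkers.tsv`, `counts_liver.tsv`, `counts_wat.tsv`,
#'   `metadata.tsv`, optionally `evidence.tsv` and `config.yaml`.
#' @param out_dir Optional output directory; when given, every stage's
#'   table is written there deterministically.
#' @param config A [run_config()]; defaults to `config.yaml` in
#'   `input_dir`.
#' @return A list with the intermediate objects of every stage:
#'   `selection` (per tissue), `additions`, `pools`, `candidates`,
#'   `de`, `norm`, `verified`, `correlations`, `report`, `cohort_stats`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, config = NULL) {
  if (is.null(config)) {
    config <- read_config(file.path(input_dir, "config.yaml"))
  }
  thr <- config$thresholds
  onto <- read_obo(file.path(input_dir, "ontology.obo"))
  ann <- read_gaf(file.path(input_dir, "annotations.gaf"))
  atlas <- read_atlas_table(file.path(input_dir, "atlas.tsv"))
  db <- read_biomarker_table(file.path(input_dir, "biomarkers.tsv"))
  counts <- list(
    liver = read_counts_table(file.path(input_dir, "counts_liver.tsv")),
    WAT = read_counts_table(file.path(input_dir, "counts_wat.tsv"))
  )
  meta <- read_sample_metadata(file.path(input_dir, "metadata.tsv"))
  ev_path <- file.path(input_dir, "evidence.tsv")
  evidence <- if (file.exists(ev_path)) read_evidence_table(ev_path)
              else NULL

  cohort_tissue <- c(adipose = "WAT", liver = "liver")
  uniprot_map <- unique(ann[!is.na(ann$uniprot) & nzchar(ann$uniprot),
                            c("gene", "uniprot")])
  uniprot_map$gene <- toupper(uniprot_map$gene)
  uniprot_map <- uniprot_map[!duplicated(uniprot_map$gene), ]

  selection <- list(); additions <- list(); pools <- list()
  candidates <- list(); cand_by_cohort <- list()
  for (tissue in c("adipose", "liver")) {
    sel <- select_tissue_genes(onto, ann, tissue, config)
    hpa <- atlas_tissue_specific_genes(atlas,
                                       config$atlas_tissue_labels[[tissue]],
                                       thr, config)
    add <- unique_hpa_additions(hpa, sel$genes, sel$immune_genes)
    pool <- sort(union(sel$genes, add))
    pool_tbl <- tibble::tibble(gene = pool)
    pool_tbl$uniprot <- uniprot_map$uniprot[match(pool,
                                                  uniprot_map$gene)]
    filtered <- filter_blood_protein_markers(pool_tbl, db, config)
    asm <- assemble_candidate_table(sel$retained, add, filtered, tissue,
                                    db = db, config = config,
                                    hpa_specific_genes = hpa)
    if (config$verify_novelty == "curated") {
      asm$candidates <- asm$candidates[asm$candidates$novelty %in%
                                         "curated", ]
    }
    selection[[tissue]] <- sel
    additions[[tissue]] <- add
    pools[[tissue]] <- pool
    candidates[[tissue]] <- asm
    cand_by_cohort[[cohort_tissue[[tissue]]]] <- asm$candidates$gene
  }

  de <- list(); norm <- list(); correlations <- list()
  cohort_stats <- list()
  for (ts in c("liver", "WAT")) {
    meta_t <- meta[meta$tissue == ts, ]
    cnt <- counts[[ts]][, meta_t$sample_id, drop = FALSE]
    grp <- meta_t$group
    sf <- size_factors(cnt)
    norm[[ts]] <- normalize_counts(cnt, sf)
    de[[ts]] <- nb_wald_test(cnt, grp, sf)
    de[[ts]]$tissue <- ts
    correlations[[ts]] <- correlate_expression_to_histology(
      norm[[ts]], meta_t, thr, config)
    correlations[[ts]]$tissue <- ts
    mw <- mann_whitney_u(meta_t$histology_score[grp == "HFD"],
                         meta_t$histology_score[grp == "chow"])
    cohort_stats[[ts]] <- tibble::tibble(
      tissue = ts,
      n_chow = sum(grp == "chow"), n_hfd = sum(grp == "HFD"),
      histology_fold_change = group_fold_change(meta_t$histology_score,
                                                grp),
      mann_whitney_p = mw$p.value
    )
  }
  cohort_stats <- dplyr::bind_rows(cohort_stats)

  verified <- select_verified_candidates(de, norm, meta, cand_by_cohort,
                                         thr, config)
  report <- final_biomarker_report(verified, correlations, evidence,
                                   config)

  result <- list(
    selection = selection, additions = additions, pools = pools,
    candidates = candidates, de = de, norm = norm, verified = verified,
    correlations = correlations, report = report,
    cohort_stats = cohort_stats, config = config
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) write_tsv_report(df, file.path(out_dir, name))
  w(dplyr::bind_rows(lapply(result$selection, `[[`, "summary")),
    "selection_summary.tsv")
  w(dplyr::bind_rows(lapply(result$candidates, `[[`, "table")),
    "candidate_table.tsv")
  w(dplyr::bind_rows(lapply(result$candidates, `[[`, "candidates")),
    "candidates.tsv")
  de <- dplyr::bind_rows(result$de)
  de[c("base_mean", "log2fc", "se", "stat", "pvalue", "padj")] <-
    lapply(de[c("base_mean", "log2fc", "se", "stat", "pvalue", "padj")],
           signif, digits = 8)
  w(de, "differential_expression.tsv")
  corr <- dplyr::bind_rows(result$correlations)
  corr$rho <- signif(corr$rho, 8)
  w(corr, "correlations.tsv")
  w(tibble::tibble(
    tissue = rep(names(result$verified),
                 lengths(result$verified)),
    gene = unlist(result$verified, use.names = FALSE)
  ), "verified_candidates.tsv")
  rep_out <- result$report
  rep_out[c("rho_liver", "rho_wat")] <-
    lapply(rep_out[c("rho_liver", "rho_wat")], signif, digits = 8)
  w(rep_out, "final_report.tsv")
  stats_out <- result$cohort_stats
  stats_out[c("histology_fold_change", "mann_whitney_p")] <-
    lapply(stats_out[c("histology_fold_change", "mann_whitney_p")],
           signif, digits = 8)
  w(stats_out, "cohort_stats.tsv")
  invisible(out_dir)
}

#' Simulate inputs and run the full pipeline
#'
#' The single-call entry point: writes the synthetic inputs under
#' `<dir>/inputs`, runs every stage, and writes all stage outputs under
#' `<dir>/results`. Byte-identical across repeated calls with the same
#' seed.
#'
#' @param seed Master seed.
#' @param dir Working directory for inputs and results.
#' @param cfg A [synth_config()] (its seed is overridden by `seed`).
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_all <- function(seed, dir, cfg = synth_config()) {
  cfg$seed <- as.integer(seed)
  input_dir <- file.path(dir, "inputs")
  simulate_inputs(cfg, input_dir)
  invisible(run_pipeline(input_dir, out_dir = file.path(dir, "results")))
}
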