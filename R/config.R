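#' Analysis thresholds
#'
#' Bundles the numeric cutoffs used across the workflow: the FDR cutoff for
#' differential expression, the Spearman correlation magnitude that counts as
#' a relevant link between expression and histology, the fold-change rule for
#' tissue specificity in the expression atlas, the tissue-group size range for
#' group-enriched calls, and the minimal normalized count at which a gene is
#' considered detected.
#'
#' @param fdr_cutoff Benjamini-Hochberg adjusted p-value cutoff for calling a
#'   gene differentially expressed. Default 0.01.
#' @param rho_cutoff Spearman correlation magnitude above which (strictly) a
#'   gene-to-histology correlation is considered relevant. Default 0.60;
#'   correlations in the closed range `[-rho_cutoff, rho_cutoff]` do not pass.
#' @param fold_specificity Minimal ratio between a tissue (or tissue group)
#'   and the rest of the tissues for a specificity call; inclusive. Default 4.
#' @param group_size_range Integer pair: allowed sizes for a group-enriched
#'   tissue group. Default `c(2, 5)`.
#' @param detect_min_norm_count Mean normalized count in at least one diet
#'   group required to call a gene detected. Default 1.
#' @return An object of class `inflamark_thresholds` (a validated list).
#' @export
thresholds <- function(fdr_cutoff = 0.01,
                       rho_cutoff = 0.60,
                       fold_specificity = 4.0,
                       group_size_range = c(2L, 5L),
                       detect_min_norm_count = 1.0) {
  stopifnot(
    is.numeric(fdr_cutoff), length(fdr_cutoff) == 1L,
    fdr_cutoff > 0, fdr_cutoff < 1,
    is.numeric(rho_cutoff), length(rho_cutoff) == 1L,
    rho_cutoff > 0, rho_cutoff < 1,
    is.numeric(fold_specificity), length(fold_specificity) == 1L,
    fold_specificity > 1,
    length(group_size_range) == 2L
  )
  group_size_range <- as.integer(group_size_range)
  if (group_size_range[1] < 2L || group_size_range[2] > 5L ||
      group_size_range[1] > group_size_range[2]) {
    stop("group_size_range must lie within 2..5 and be non-decreasing",
         call. = FALSE)
  }
  stopifnot(is.numeric(detect_min_norm_count), detect_min_norm_count >= 0)
  structure(
    list(
      fdr_cutoff = fdr_cutoff,
      rho_cutoff = rho_cutoff,
      fold_specificity = fold_specificity,
      group_size_range = group_size_range,
      detect_min_norm_count = detect_min_norm_count
    ),
    class = "inflamark_thresholds"
  )
}

#' Run configuration for the biomarker workflow
#'
#' Holds everything that parameterizes a run: the keyword lists that find
#' tissue-related ontology terms, the immune root term ids whose descendant
#' closure defines the immune gene universe, the curation whitelist of parent
#' term ids (a reproducible stand-in for manual curation), the species/object
#' type filters applied to gene annotations, the list of low-grade
#' inflammation conditions used by the novelty rubric, a biological function
#' mapping for the final report, and the numeric [thresholds()].
#'
#' @param adipose_keywords,liver_keywords Case-insensitive substrings matched
#'   against term names.
#' @param immune_roots Character vector of immune root term ids.
#' @param curation_whitelist Character vector of parent term ids retained by
#'   curation (empty means nothing survives curation).
#' @param taxon Taxon label annotations must carry (e.g. `"taxon:9606"`).
#' @param object_type Annotation object type retained (e.g. `"protein"`).
#' @param diseases Disease/condition labels defining the low-grade
#'   inflammation context for the novelty rubric.
#' @param accepted_evidence Biomarker-record evidence labels accepted by the
#'   blood-marker filter.
#' @param accepted_substrates Biomarker-record substrates accepted.
#' @param accepted_marker_type Biomarker-record type accepted.
#' @param function_categories Named character vector mapping gene symbol to a
#'   biological function category for the final report (optional).
#' @param atlas_tissue_labels Named character vector mapping the workflow's
#'   tissue keys (`adipose`, `liver`) to atlas column names.
#' @param group_strategy `"min"` (default) or `"mean"`: denominator strategy
#'   for group-enriched specificity calls.
#' @param specificity_denominator `"max"` (default) or `"mean"`: compare the
#'   candidate tissue against the maximum or the average of the other tissues.
#' @param correlation_samples `"all"` (default) or `"hfd"`: animals pooled
#'   for expression-histology correlation.
#' @param criterion_c_samples `"hfd"` (default) or `"all"`: samples used for
#'   the cross-tissue expression comparison.
#' @param verify_novelty `"all"` (default) or `"curated"`: whether novel
#'   candidates proceed to cohort verification.
#' @param seed Non-negative integer seed for any randomized stage.
#' @param thresholds A [thresholds()] object.
#' @return An object of class `inflamark_config`.
#' @export
run_config <- function(adipose_keywords = c("adipose", "adipocyte"),
                       liver_keywords = c("liver", "hepatic", "hepatocyte"),
                       immune_roots = character(),
                       curation_whitelist = character(),
                       taxon = "taxon:9606",
                       object_type = "protein",
                       diseases = default_disease_list(),
                       accepted_evidence = c("early human studies",
                                             "late human studies",
                                             "recommended/approved"),
                       accepted_substrates = c("plasma", "serum"),
                       accepted_marker_type = "proteome",
                       function_categories = NULL,
                       atlas_tissue_labels = c(adipose = "adipose tissue",
                                               liver = "liver"),
                       group_strategy = c("min", "mean"),
                       specificity_denominator = c("max", "mean"),
                       correlation_samples = c("all", "hfd"),
                       criterion_c_samples = c("hfd", "all"),
                       verify_novelty = c("all", "curated"),
                       seed = 1L,
                       thresholds = inflamark::thresholds()) {
  stopifnot(length(adipose_keywords) >= 1L, length(liver_keywords) >= 1L)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed), seed >= 0L)
  structure(
    list(
      keywords = list(adipose = tolower(adipose_keywords),
                      liver = tolower(liver_keywords)),
      immune_roots = immune_roots,
      curation_whitelist = curation_whitelist,
      taxon = taxon,
      object_type = object_type,
      diseases = tolower(diseases),
      accepted_evidence = tolower(accepted_evidence),
      accepted_substrates = tolower(accepted_substrates),
      accepted_marker_type = tolower(accepted_marker_type),
      function_categories = function_categories,
      atlas_tissue_labels = unlist(atlas_tissue_labels),
      group_strategy = match.arg(group_strategy),
      specificity_denominator = match.arg(specificity_denominator),
      correlation_samples = match.arg(correlation_samples),
      criterion_c_samples = match.arg(criterion_c_samples),
      verify_novelty = match.arg(verify_novelty),
      seed = seed,
      thresholds = thresholds
    ),
    class = "inflamark_config"
  )
}

#' Default low-grade-inflammation disease list
#'
#' The ten metabolic conditions that define the disease context of the
#' novelty rubric.
#' @return Character vector of condition labels.
#' @export
default_disease_list <- function() {
  c("metabolic syndrome", "type 2 diabetes", "hyperglycemia", "prediabetes",
    "insulin resistance", "glucose intolerance", "dyslipidemia",
    "hyperlipidemia", "hypertriglyceridemia", "atherosclerosis")
}

#' Read a run configuration from a flat YAML file
#'
#' Every field of [run_config()] has a YAML key of the same name; keys absent
#' from the file keep their defaults. Threshold keys (`fdr_cutoff`,
#' `rho_cutoff`, `fold_specificity`, `group_size_range`,
#' `detect_min_norm_count`) are read at the top level.
#'
#' @param path Path to a YAML file.
#' @return An `inflamark_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  thr_keys <- c("fdr_cutoff", "rho_cutoff", "fold_specificity",
                "group_size_range", "detect_min_norm_count")
  thr_args <- raw[intersect(names(raw), thr_keys)]
  cfg_args <- raw[setdiff(names(raw), thr_keys)]
  cfg_args$thresholds <- do.call(thresholds, thr_args)
  unknown <- setdiff(names(cfg_args), names(formals(run_config)))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, cfg_args)
}
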