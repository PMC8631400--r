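#' Configuration for the synthetic-data generators
#'
#' Defaults encode the reference study design the pipeline is meant to be
#' exercised against: a cohort of 10 chow and 17 high-fat-diet animals, a
#' 31.6-fold hepatic and 9.1-fold adipose histological inflammation effect,
#' tissue ontology terms whose gene sets overlap immune terms at about 44%,
#' an expression atlas over 6 tissues with planted four-fold tissue-enriched
#' genes, and planted markers whose expression tracks each animal's
#' histology score with a target Spearman magnitude of 0.8.
#'
#' @param seed Master seed; every generator derives its own fixed sub-stream
#'   from it, so regenerating one input never perturbs another.
#' @param n_parents Tissue parent terms generated per tissue.
#' @param n_decoy_parents Keyword-matching parent terms left off the
#'   curation whitelist (emulating hits removed by manual curation).
#' @param branching,depth Children per term and descendant depth below each
#'   parent.
#' @param n_immune_children Immune child terms per immune root.
#' @param immune_overlap Probability that a tissue-pool gene is
#'   immune-annotated; each parent's gene set then overlaps the immune
#'   universe at about this fraction. Default 0.44.
#' @param n_genes Size of the gene universe. Default 2000.
#' @param genes_per_parent Expected genes per tissue parent (Poisson mean).
#' @param n_atlas_tissues Number of atlas tissue columns (2..6). Default 6.
#' @param n_enriched_extra Planted tissue-enriched atlas genes per tissue in
#'   addition to the markers.
#' @param enriched_fold_margin Planted separation factor (>= the four-fold
#'   rule). Default 5.
#' @param db_coverage Probability that a non-marker pool gene receives a
#'   qualifying biomarker record. Default 0.8.
#' @param n_chow,n_hfd Animals per diet group. Defaults 10 and 17.
#' @param liver_effect,wat_effect Multiplicative histology effects of the
#'   high-fat diet. Defaults 31.6 and 9.1.
#' @param hist_sdlog Within-group log-scale standard deviation of histology
#'   scores. Default 0.2.
#' @param n_markers_per_tissue Planted markers per tissue. Default 10.
#' @param target_rho Target Spearman magnitude between a planted marker's
#'   expression and its tissue's histology. Default 0.8.
#' @param frac_negative Fraction of planted markers tracking histology
#'   negatively. Default 0.5.
#' @param dispersion NB dispersion of generated counts. Default 0.1.
#' @param count_meanlog,count_sdlog Log-normal parameters of per-gene
#'   baseline expression.
#' @param libsize_sdlog Log-scale spread of per-sample library size factors.
#' @param offtarget_factor Factor by which a marker's baseline is reduced in
#'   its non-target tissue. Default 8.
#' @param plasma_r2 Target squared Pearson correlation between generated
#'   plasma analytes and liver histology. Default 0.7.
#' @param n_plasma_analytes Number of liver markers measured in plasma.
#' @return An object of class `inflamark_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_parents = 8L,
                         n_decoy_parents = 3L,
                         branching = 2L,
                         depth = 2L,
                         n_immune_children = 6L,
                         immune_overlap = 0.44,
                         n_genes = 2000L,
                         genes_per_parent = 60,
                         n_atlas_tissues = 6L,
                         n_enriched_extra = 8L,
                         enriched_fold_margin = 5,
                         db_coverage = 0.8,
                         n_chow = 10L,
                         n_hfd = 17L,
                         liver_effect = 31.6,
                         wat_effect = 9.1,
                         hist_sdlog = 0.2,
                         n_markers_per_tissue = 10L,
                         target_rho = 0.8,
                         frac_negative = 0.5,
                         dispersion = 0.1,
                         count_meanlog = log(200),
                         count_sdlog = 1,
                         libsize_sdlog = 0.25,
                         offtarget_factor = 8,
                         plasma_r2 = 0.7,
                         n_plasma_analytes = 2L) {
  stopifnot(
    immune_overlap >= 0, immune_overlap <= 1,
    db_coverage > 0, db_coverage <= 1,
    liver_effect > 1, wat_effect > 1,
    n_chow >= 3L, n_hfd >= 3L, n_genes >= 100L,
    n_atlas_tissues >= 2L, n_atlas_tissues <= 6L,
    target_rho > 0, target_rho < 1,
    dispersion > 0
  )
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "inflamark_synth_config")
}

# Fixed sub-stream ids keep the generators independent of one another.
stream_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1009L + stream
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

marker_genes <- function(cfg) {
  n <- cfg$n_markers_per_tissue
  list(liver = gene_ids(2L * n)[seq_len(n)],
       WAT = gene_ids(2L * n)[n + seq_len(n)])
}

#' Generate a synthetic ontology, annotation table and planted truth
#'
#' Builds an acyclic DAG with keyword-named tissue parent terms (plus decoy
#' parents excluded from the curation whitelist), three immune root terms
#' with children, and gene-term annotations in which each tissue parent's
#' genes overlap the immune universe at the configured fraction. Planted
#' markers are annotated so they reach the candidate pool: half of each
#' tissue's markers through ontology terms, half only through the atlas.
#' Wrong-taxon and wrong-object-type decoy annotations are included.
#'
#' @param cfg A [synth_config()].
#' @return A list with `ontology`, `annotations` (GAF-shaped tibble),
#'   `whitelist`, `immune_roots`, `truth` (per-gene tibble).
#' @export
gen_ontology_and_annotations <- function(cfg = synth_config()) {
  set.seed(stream_seed(cfg$seed, 1L))
  genes <- gene_ids(cfg$n_genes)
  markers <- marker_genes(cfg)

  terms <- list()
  parents_of <- list()
  add_term <- function(id, name, parent = NULL) {
    terms[[id]] <<- tibble::tibble(id = id, name = name,
                                   namespace = "biological_process")
    parents_of[[id]] <<- if (is.null(parent)) character() else parent
  }
  # immune branch
  immune_roots <- c("IMM:0000001", "IMM:0000002", "IMM:0000003")
  root_names <- c("immune system process", "inflammatory response",
                  "cytokine production")
  immune_terms <- character()
  for (r in seq_along(immune_roots)) {
    add_term(immune_roots[r], root_names[r])
    for (k in seq_len(cfg$n_immune_children)) {
      id <- sprintf("IMM:%03d%04d", r, k)
      add_term(id, sprintf("%s child %d", root_names[r], k), immune_roots[r])
      immune_terms <- c(immune_terms, id)
    }
  }
  # tissue branches
  kw <- list(adipose = c("adipose", "adipocyte"),
             liver = c("liver", "hepatic", "hepatocyte"))
  parent_ids <- list(adipose = character(), liver = character())
  members_of <- list()  # parent id -> descendant term ids (incl. parent)
  for (tissue in c("adipose", "liver")) {
    pfx <- if (tissue == "adipose") "TIS:A" else "TIS:L"
    for (p in seq_len(cfg$n_parents)) {
      pid <- sprintf("%s%03d0000", pfx, p)
      word <- kw[[tissue]][1L + (p - 1L) %% length(kw[[tissue]])]
      add_term(pid, sprintf("%s process %d", word, p))
      parent_ids[[tissue]] <- c(parent_ids[[tissue]], pid)
      members <- pid
      frontier <- pid
      for (d in seq_len(cfg$depth)) {
        nxt <- character()
        for (f in frontier) {
          for (b in seq_len(cfg$branching)) {
            cid <- sprintf("%s%03d%02d%02d", pfx, p, d, length(nxt) + b)
            add_term(cid, sprintf("%s process %d sub %d-%d", word, p, d,
                                  length(nxt) + b), f)
            nxt <- c(nxt, cid)
          }
        }
        members <- c(members, nxt)
        frontier <- nxt
      }
      members_of[[pid]] <- members
    }
    # decoy parents: match the keyword but are not whitelisted
    for (p in seq_len(cfg$n_decoy_parents)) {
      did <- sprintf("%sD%02d0000", pfx, p)
      add_term(did, sprintf("embryonic %s process %d", kw[[tissue]][1], p))
    }
  }
  onto <- ontology(dplyr::bind_rows(terms), parents_of)

  # gene pools per tissue (disjoint backgrounds; markers handled explicitly)
  pool_start <- 2L * cfg$n_markers_per_tissue + 1L
  free <- genes[pool_start:cfg$n_genes]
  half <- floor(length(free) / 2)
  pools <- list(adipose = free[seq_len(half)],
                liver = free[(half + 1L):length(free)])

  # immune status is a property of the gene, not of the parent draw, so
  # each parent's gene set overlaps the immune universe at about the
  # configured fraction without cross-parent inflation
  gene_is_immune <- stats::setNames(
    stats::runif(cfg$n_genes) < cfg$immune_overlap, genes)
  gene_is_immune[unlist(markers)] <- cfg$immune_overlap > 0

  ann_gene <- character(); ann_term <- character()
  go_route <- list()
  for (tissue in c("adipose", "liver")) {
    cohort_tissue <- if (tissue == "adipose") "WAT" else "liver"
    mk <- markers[[cohort_tissue]]
    go_mk <- mk[seq_len(ceiling(length(mk) / 2))]  # ontology-route markers
    go_route[[cohort_tissue]] <- go_mk
    for (p in seq_along(parent_ids[[tissue]])) {
      pid <- parent_ids[[tissue]][p]
      n_p <- max(5L, stats::rpois(1, cfg$genes_per_parent))
      gset <- sample(pools[[tissue]], min(n_p, length(pools[[tissue]])))
      if (p <= 3L) {
        # ontology-route markers spread round-robin over the first parents
        gset <- unique(c(gset, go_mk[seq_along(go_mk) %% 3L + 1L == p]))
      }
      ann_gene <- c(ann_gene, gset)
      ann_term <- c(ann_term, sample(members_of[[pid]], length(gset),
                                     replace = TRUE))
    }
  }
  # one immune annotation per immune gene that entered a tissue term
  imm_in_sets <- unique(ann_gene[gene_is_immune[ann_gene]])
  ann_gene <- c(ann_gene, imm_in_sets)
  ann_term <- c(ann_term, sample(immune_terms, length(imm_in_sets),
                                 replace = TRUE))
  immune_genes_truth <- imm_in_sets
  # atlas-route markers and extra immune genes outside tissue terms
  atlas_mk <- c(setdiff(markers$liver, go_route$liver),
                setdiff(markers$WAT, go_route$WAT))
  extra_imm <- sample(setdiff(genes, c(unlist(markers), ann_gene)), 200L)
  for (g in c(atlas_mk, extra_imm)) {
    ann_gene <- c(ann_gene, g)
    ann_term <- c(ann_term, sample(immune_terms, 1L))
  }
  immune_genes_truth <- unique(c(immune_genes_truth, atlas_mk, extra_imm))

  uniprot <- stats::setNames(sprintf("UP%05d", seq_along(genes)), genes)
  annotations <- tibble::tibble(
    gene = ann_gene,
    uniprot = unname(uniprot[ann_gene]),
    term_id = ann_term,
    object_type = "protein",
    taxon = "taxon:9606"
  )
  # decoys the species/type filter must drop
  decoys <- tibble::tibble(
    gene = sample(genes, 20L),
    uniprot = NA_character_,
    term_id = sample(immune_terms, 20L, replace = TRUE),
    object_type = c(rep("protein", 10L), rep("rna", 10L)),
    taxon = c(rep("taxon:10090", 10L), rep("taxon:9606", 10L))
  )
  annotations <- dplyr::bind_rows(annotations, decoys)
  annotations <- annotations[order(annotations$gene, annotations$term_id), ]

  truth <- tibble::tibble(
    gene = genes,
    uniprot = unname(uniprot),
    immune = genes %in% immune_genes_truth,
    marker_tissue = dplyr::case_when(
      genes %in% markers$liver ~ "liver",
      genes %in% markers$WAT ~ "WAT",
      .default = NA_character_
    ),
    go_route = genes %in% unlist(go_route)
  )
  list(
    ontology = onto,
    annotations = annotations,
    whitelist = sort(unlist(parent_ids)),
    immune_roots = immune_roots,
    truth = truth
  )
}

#' Generate a synthetic cross-tissue expression atlas
#'
#' Planted tissue-enriched genes (all cohort markers plus
#' `n_enriched_extra` per tissue) get at least the configured fold margin
#' over every other tissue; every background gene's profile stays within a
#' 3.9-fold band so the four-fold rule can never fire on it.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble from [gen_ontology_and_annotations()].
#' @return A list with `atlas` (tibble, attribute `tissues`) and `truth`
#'   (with an `enriched_tissue` column appended).
#' @export
gen_tissue_atlas <- function(cfg = synth_config(), truth) {
  set.seed(stream_seed(cfg$seed, 2L))
  tissue_pool <- c("adipose tissue", "liver", "brain", "heart", "kidney",
                   "lung")
  tissues <- tissue_pool[seq_len(cfg$n_atlas_tissues)]
  genes <- truth$gene
  n <- length(genes)
  m <- matrix(stats::runif(n * length(tissues), 10, 39), nrow = n,
              dimnames = list(genes, tissues))
  markers <- marker_genes(cfg)
  extra <- list(
    liver = utils::tail(genes[is.na(truth$marker_tissue)],
                        2L * cfg$n_enriched_extra)[seq_len(cfg$n_enriched_extra)],
    WAT = utils::tail(genes[is.na(truth$marker_tissue)],
                      cfg$n_enriched_extra)
  )
  enriched <- list(liver = c(markers$liver, extra$liver),
                   WAT = c(markers$WAT, extra$WAT))
  atlas_label <- c(liver = "liver", WAT = "adipose tissue")
  enriched_tissue <- stats::setNames(rep(NA_character_, n), genes)
  for (ct in c("liver", "WAT")) {
    lab <- atlas_label[[ct]]
    for (g in enriched[[ct]]) {
      others <- stats::runif(length(tissues) - 1L, 10, 20)
      m[g, ] <- 0
      m[g, setdiff(tissues, lab)] <- others
      m[g, lab] <- cfg$enriched_fold_margin * max(others)
      enriched_tissue[g] <- lab
    }
  }
  truth$enriched_tissue <- unname(enriched_tissue[truth$gene])
  atlas <- tibble::tibble(gene = genes, uniprot = truth$uniprot)
  for (tt in tissues) atlas[[tt]] <- round(m[, tt], 3)
  attr(atlas, "tissues") <- tissues
  list(atlas = atlas, truth = truth)
}

#' Generate a synthetic blood protein-biomarker record table
#'
#' Every planted marker gets a qualifying record (proteome, plasma or
#' serum, accepted evidence); other immune genes get one with probability
#' `db_coverage`. Disqualifying decoy records (urine substrate, preclinical
#' evidence) are added both for covered genes and as sole records for a few
#' genes. The novelty rubric fields are drawn with known truth labels.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble (after [gen_tissue_atlas()]).
#' @return A list with `db` (record tibble) and `truth` (columns
#'   `in_db` and `novelty_truth` appended).
#' @export
gen_biomarker_db <- function(cfg = synth_config(), truth) {
  set.seed(stream_seed(cfg$seed, 3L))
  diseases <- default_disease_list()
  evid_ok <- c("early human studies", "late human studies",
               "recommended/approved")
  is_marker <- !is.na(truth$marker_tissue)
  covered <- is_marker |
    (truth$immune & stats::runif(nrow(truth)) < cfg$db_coverage)
  rows <- list()
  novelty_truth <- rep(NA_character_, nrow(truth))
  for (i in which(covered)) {
    cond_i <- stats::runif(1) < 0.6
    cond_ii <- stats::runif(1) < 0.5
    cond_iii <- cond_i && stats::runif(1) < 0.5
    conds <- character()
    if (cond_i) conds <- sample(diseases, sample(1:3, 1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = truth$gene[i], uniprot = truth$uniprot[i],
      marker_type = "proteome",
      substrate = sample(c("plasma", "serum"), 1),
      evidence = sample(evid_ok, 1),
      conditions = list(conds),
      commonly_analyzed = cond_ii,
      diagnostic_use = cond_iii
    )
    novelty_truth[i] <- novelty_label(cond_i, cond_ii, cond_iii)
    if (stats::runif(1) < 0.2) {  # extra disqualifying record
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = truth$gene[i], uniprot = truth$uniprot[i],
        marker_type = "proteome", substrate = "urine",
        evidence = "preclinical", conditions = list(character()),
        commonly_analyzed = FALSE, diagnostic_use = FALSE
      )
    }
  }
  # genes whose only records are disqualifying
  only_bad <- sample(which(!covered & truth$immune), 15L)
  for (i in only_bad) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = truth$gene[i], uniprot = truth$uniprot[i],
      marker_type = "proteome",
      substrate = sample(c("urine", "plasma"), 1),
      evidence = "preclinical", conditions = list(character()),
      commonly_analyzed = FALSE, diagnostic_use = FALSE
    )
  }
  db <- dplyr::bind_rows(rows)
  db <- db[order(db$gene, db$substrate, db$evidence), ]
  truth$in_db <- covered
  truth$novelty_truth <- novelty_truth
  list(db = db, truth = truth)
}

# log-scale latent noise of an NB count around its mean
nb_log_noise_var <- function(mu, dispersion) log(1 + dispersion + 1 / mu)

# Slope of the log-mean in the standardized score that gives the target
# expected Spearman magnitude at this sample size. A closed form is biased
# here (the diet effect makes the score bimodal, and Spearman attenuates at
# finite n), so the expectation is estimated by simulating the latent noise
# and the slope solved by bisection; common random numbers keep the
# objective monotone in the slope.
calibrate_marker_slope <- function(s, v, target, n_rep = 300L) {
  n <- length(s)
  z <- matrix(stats::rnorm(n * n_rep), nrow = n)
  rs_c <- rank(s) - (n + 1) / 2
  denom <- sum(rs_c^2)
  e_rho <- function(b) {
    lat <- b * s + sqrt(v) * z
    rl <- apply(lat, 2, rank)  # continuous noise: no ties
    mean(crossprod(rl - (n + 1) / 2, rs_c)) / denom
  }
  lo <- 1e-3; hi <- 10 * sqrt(v)
  while (e_rho(hi) < target && hi < 1e3) hi <- hi * 2
  for (i in seq_len(20L)) {
    mid <- (lo + hi) / 2
    if (e_rho(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate the synthetic mouse cohort
#'
#' Histology scores: chow baselines are log-normal with unit-mean noise;
#' HFD multiplies the tissue effect in. Counts are negative binomial with
#' log-normal per-gene baselines and per-sample library size factors.
#' Planted markers follow an affine log-mean in their tissue's standardized
#' log histology score, with the slope calibrated so the expected Spearman
#' magnitude matches `target_rho` (alternating signs); in the non-target
#' tissue their baseline is divided by `offtarget_factor` with no
#' histology link. Plasma analytes track liver histology linearly with
#' noise set for the target R-squared.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble (after [gen_biomarker_db()]).
#' @return A list with `counts` (named list of matrices `liver`, `WAT`),
#'   `meta` (metadata tibble), and `truth` (with `direction` appended).
#' @export
gen_cohort <- function(cfg = synth_config(), truth) {
  set.seed(stream_seed(cfg$seed, 4L))
  n <- cfg$n_chow + cfg$n_hfd
  animals <- sprintf("M%02d", seq_len(n))
  group <- c(rep("chow", cfg$n_chow), rep("HFD", cfg$n_hfd))
  effects <- c(liver = cfg$liver_effect, WAT = cfg$wat_effect)
  base_hist <- c(liver = 1.0, WAT = 2.0)
  sd <- cfg$hist_sdlog
  hist <- list()
  for (ts in c("liver", "WAT")) {
    noise <- exp(stats::rnorm(n, -sd^2 / 2, sd))
    hist[[ts]] <- base_hist[[ts]] * ifelse(group == "HFD",
                                           effects[[ts]], 1) * noise
  }

  genes <- truth$gene
  markers <- marker_genes(cfg)
  baseline <- exp(stats::rnorm(length(genes), cfg$count_meanlog,
                               cfg$count_sdlog))
  names(baseline) <- genes
  # markers get stable mid-range baselines so detection and the rho
  # calibration are not at the mercy of the baseline tail
  for (g in unlist(markers)) {
    baseline[g] <- exp(stats::rnorm(1, log(300), 0.4))
  }
  direction <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (ts in c("liver", "WAT")) {
    direction[markers[[ts]]] <- rep(c(1, -1),
                                    length.out = length(markers[[ts]]))
  }

  counts <- list()
  for (ts in c("liver", "WAT")) {
    s <- as.vector(scale(log(hist[[ts]])))
    lib <- exp(stats::rnorm(n, 0, cfg$libsize_sdlog))
    mu <- matrix(baseline, nrow = length(genes), ncol = n,
                 dimnames = list(genes,
                                 paste0(substr(ts, 1, 1), "_", animals)))
    # calibrate once per tissue at the median marker noise, then scale each
    # marker's slope by its own noise level (noise varies little across the
    # markers' mid-range baselines)
    v_mk <- nb_log_noise_var(baseline[markers[[ts]]], cfg$dispersion)
    b_ref <- calibrate_marker_slope(s, stats::median(v_mk), cfg$target_rho)
    for (g in markers[[ts]]) {
      v <- nb_log_noise_var(baseline[g], cfg$dispersion)
      b <- direction[g] * b_ref * sqrt(v / stats::median(v_mk))
      mu[g, ] <- baseline[g] * exp(b * s)
    }
    other <- setdiff(c("liver", "WAT"), ts)
    mu[markers[[other]], ] <- baseline[markers[[other]]] /
      cfg$offtarget_factor
    mu <- sweep(mu, 2, lib, "*")
    cnt <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$dispersion,
                                 mu = mu),
                  nrow = nrow(mu), dimnames = dimnames(mu))
    storage.mode(cnt) <- "integer"
    counts[[ts]] <- cnt
  }

  # plasma analytes track liver histology with noise set for the target R2
  analytes <- markers$liver[seq_len(cfg$n_plasma_analytes)]
  plasma <- list()
  h <- hist$liver
  for (a in analytes) {
    sd_noise <- stats::sd(h) * sqrt((1 - cfg$plasma_r2) / cfg$plasma_r2)
    plasma[[paste0("plasma_", a)]] <-
      round(pmax(50 + h + stats::rnorm(n, 0, sd_noise), 0), 4)
  }

  meta <- dplyr::bind_rows(lapply(c("liver", "WAT"), function(ts) {
    tibble::tibble(
      sample_id = paste0(substr(ts, 1, 1), "_", animals),
      animal = animals, group = group, tissue = ts,
      histology_score = round(hist[[ts]], 5),
      !!!plasma
    )
  }))
  truth$direction <- unname(direction[truth$gene])
  list(counts = counts, meta = meta, truth = truth)
}

#' Generate every pipeline input in memory
#'
#' Runs all four generators off one master seed and returns the complete
#' set of inputs plus the planted ground truth and a matching
#' [run_config()].
#'
#' @param cfg A [synth_config()].
#' @return A list with `ontology`, `annotations`, `atlas`, `db`, `counts`,
#'   `meta`, `evidence`, `truth`, `run_config`.
#' @export
gen_all <- function(cfg = synth_config()) {
  oa <- gen_ontology_and_annotations(cfg)
  at <- gen_tissue_atlas(cfg, oa$truth)
  db <- gen_biomarker_db(cfg, at$truth)
  co <- gen_cohort(cfg, db$truth)
  truth <- co$truth
  ev <- gen_evidence(cfg, truth)
  rc <- run_config(
    immune_roots = oa$immune_roots,
    curation_whitelist = oa$whitelist,
    seed = cfg$seed
  )
  list(ontology = oa$ontology, annotations = oa$annotations,
       atlas = at$atlas, db = db$db, counts = co$counts, meta = co$meta,
       evidence = ev, truth = truth, run_config = rc)
}

#' Generate literature-evidence flags for the planted markers
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble.
#' @return Evidence tibble (`gene`, `tissue`, `cond_i..iii`, `level`).
#' @export
gen_evidence <- function(cfg = synth_config(), truth) {
  set.seed(stream_seed(cfg$seed, 5L))
  idx <- which(!is.na(truth$marker_tissue))
  ev <- tibble::tibble(
    gene = truth$gene[idx],
    tissue = truth$marker_tissue[idx],
    cond_i = stats::runif(length(idx)) < 0.8,
    cond_ii = stats::runif(length(idx)) < 0.7,
    cond_iii = stats::runif(length(idx)) < 0.6,
    notes = ""
  )
  ev$level <- assign_confirmation_level(ev$cond_i, ev$cond_ii, ev$cond_iii)
  ev[order(ev$tissue, ev$gene), ]
}

#' Ground-truth table for the acceptance suite
#'
#' One deterministic row per gene with every planted label.
#'
#' @param truth Truth tibble from [gen_all()].
#' @return A tibble ordered by gene.
#' @export
ground_truth_table <- function(truth) {
  truth[order(truth$gene), , drop = FALSE]
}

#' Write an ontology as OBO 1.2
#' @param onto An [ontology()].
#' @param path Output path.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in order(onto$terms$id)) {
    id <- onto$terms$id[i]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", onto$terms$name[i]),
      paste0("namespace: ", onto$terms$namespace[i]),
      paste0("is_a: ", sort(onto$parents[[id]])),
      ""
    ), con)
  }
  invisible(path)
}

#' Write annotations as GAF 2.2
#' @param annotations Annotation tibble (as from [read_gaf()]).
#' @param path Output path.
#' @export
write_gaf <- function(annotations, path) {
  ann <- annotations[order(annotations$gene, annotations$term_id,
                           annotations$taxon), ]
  rows <- sprintf(
    "SYN\t%s\t%s\t\t%s\tREF:0000001\tIEA\t\tP\t\t\t%s\t%s\t20240101\tSYN\t\t",
    ifelse(is.na(ann$uniprot), "", ann$uniprot), ann$gene, ann$term_id,
    ann$object_type, ann$taxon
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("!gaf-version: 2.2", rows), con)
  invisible(path)
}

#' Write every synthetic input to a directory
#'
#' Produces the complete file set the pipeline consumes — ontology
#' (`ontology.obo`), annotations (`annotations.gaf`), atlas, biomarker
#' records, per-tissue counts, sample metadata, literature evidence, run
#' configuration (`config.yaml`) — plus `ground_truth.tsv` for recovery
#' tests. Deterministic for a fixed seed.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
simulate_inputs <- function(cfg = synth_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- gen_all(cfg)
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  write_gaf(sim$annotations, file.path(dir, "annotations.gaf"))
  write_atlas_table(sim$atlas, file.path(dir, "atlas.tsv"))
  write_biomarker_table(sim$db, file.path(dir, "biomarkers.tsv"))
  write_counts_table(sim$counts$liver, file.path(dir, "counts_liver.tsv"))
  write_counts_table(sim$counts$WAT, file.path(dir, "counts_wat.tsv"))
  write_sample_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  write_tsv_report(sim$evidence, file.path(dir, "evidence.tsv"))
  write_tsv_report(ground_truth_table(sim$truth),
                   file.path(dir, "ground_truth.tsv"))
  yaml::write_yaml(list(
    immune_roots = sim$run_config$immune_roots,
    curation_whitelist = sim$run_config$curation_whitelist,
    seed = cfg$seed
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}
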