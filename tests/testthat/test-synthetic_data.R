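test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 7)
  a <- gen_all(cfg)
  b <- gen_all(cfg)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$atlas, b$atlas)
  expect_identical(a$db, b$db)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
})

test_that("generated structures satisfy their basic invariants", {
  sim <- gen_all(synth_config(seed = 2))
  # DAG acyclicity is asserted by the ontology constructor itself
  expect_s3_class(sim$ontology, "inflamark_ontology")
  for (ts in c("liver", "WAT")) {
    expect_true(all(sim$counts[[ts]] >= 0))
    expect_true(is.integer(sim$counts[[ts]]))
  }
  lvls <- as.matrix(sim$atlas[attr(sim$atlas, "tissues")])
  expect_true(all(lvls >= 0))
  expect_true(all(sim$meta$histology_score >= 0))
  expect_equal(sum(sim$meta$tissue == "liver" & sim$meta$group == "chow"),
               10L)
  expect_equal(sum(sim$meta$tissue == "liver" & sim$meta$group == "HFD"),
               17L)
})

test_that("every planted marker is wired into all four inputs", {
  sim <- gen_all(synth_config(seed = 5))
  markers <- sim$truth$gene[!is.na(sim$truth$marker_tissue)]
  expect_length(markers, 20L)
  expect_true(all(markers %in% sim$annotations$gene))
  expect_true(all(markers %in% sim$atlas$gene))
  expect_true(all(markers %in% sim$db$gene))
  expect_true(all(markers %in% rownames(sim$counts$liver)))
  expect_true(all(markers %in% rownames(sim$counts$WAT)))
  # qualifying records for all of them
  cfg <- sim$run_config
  kept <- filter_blood_protein_markers(markers, sim$db, cfg)
  expect_setequal(kept, toupper(markers))
  # known novelty labels reproduce through assign_novelty
  for (g in markers) {
    recs <- sim$db[sim$db$gene == g &
                     sim$db$evidence != "preclinical", ]
    expect_equal(assign_novelty(recs, cfg$diseases),
                 sim$truth$novelty_truth[sim$truth$gene == g])
  }
})

test_that("zero immune overlap drops every tissue parent downstream", {
  cfg <- synth_config(seed = 3, immune_overlap = 0)
  oa <- gen_ontology_and_annotations(cfg)
  rc <- run_config(immune_roots = oa$immune_roots,
                   curation_whitelist = oa$whitelist)
  sel <- suppressMessages(
    select_tissue_genes(oa$ontology, oa$annotations, "adipose", rc))
  expect_length(sel$retained, 0L)
  expect_length(sel$genes, 0L)
})

test_that("per-tissue immune percentage concentrates around the target", {
  pcts <- c()
  for (sd in 1:4) {
    oa <- gen_ontology_and_annotations(synth_config(seed = sd))
    rc <- run_config(immune_roots = oa$immune_roots,
                     curation_whitelist = oa$whitelist)
    for (ts in c("adipose", "liver")) {
      sel <- suppressMessages(
        select_tissue_genes(oa$ontology, oa$annotations, ts, rc))
      pcts <- c(pcts,
                sel$summary$pct_immune[sel$summary$accession == "TOTAL"])
    }
  }
  # ~960 gene slots per tissue: binomial 3-sigma around 44 is about +-5,
  # and the mean over eight draws should sit within +-3
  expect_true(all(abs(pcts - 44) <= 6))
  expect_lt(abs(mean(pcts) - 44), 3)
})

test_that("histology fold-change estimates track the configured effects", {
  fc <- t(vapply(1:6, function(sd) {
    cfg <- synth_config(seed = sd)
    co <- gen_cohort(cfg, gen_ontology_and_annotations(cfg)$truth)
    m <- co$meta
    vapply(c("liver", "WAT"), function(ts)
      group_fold_change(m$histology_score[m$tissue == ts],
                        m$group[m$tissue == ts]), numeric(1))
  }, numeric(2)))
  expect_true(all(fc[, "liver"] > 25 & fc[, "liver"] < 40))
  expect_true(all(fc[, "WAT"] > 7 & fc[, "WAT"] < 12))
})

test_that("planted marker correlations are calibrated to the target", {
  rhos <- c()
  for (sd in 21:25) {
    cfg <- synth_config(seed = sd)
    tr <- gen_ontology_and_annotations(cfg)$truth
    co <- gen_cohort(cfg, tr)
    for (ts in c("liver", "WAT")) {
      m <- co$meta[co$meta$tissue == ts, ]
      norm <- normalize_counts(co$counts[[ts]][, m$sample_id])
      mk <- tr$gene[!is.na(tr$marker_tissue) & tr$marker_tissue == ts]
      rhos <- c(rhos, vapply(mk, function(g)
        abs(spearman_rho(norm[g, ], m$histology_score)), numeric(1)))
    }
  }
  expect_length(rhos, 100L)
  expect_lt(abs(mean(rhos) - 0.8), 0.1)
  # direction signs are honoured
  cfg <- synth_config(seed = 21)
  co <- gen_cohort(cfg, gen_ontology_and_annotations(cfg)$truth)
  tr <- co$truth
  m <- co$meta[co$meta$tissue == "liver", ]
  norm <- normalize_counts(co$counts$liver[, m$sample_id])
  for (g in tr$gene[!is.na(tr$marker_tissue) & tr$marker_tissue == "liver"]) {
    dir <- tr$direction[tr$gene == g]
    expect_equal(sign(spearman_rho(norm[g, ], m$histology_score)), dir)
  }
})

test_that("null genes rarely cross the correlation cutoff", {
  cfg <- synth_config(seed = 31)
  tr <- gen_ontology_and_annotations(cfg)$truth
  co <- gen_cohort(cfg, tr)
  m <- co$meta[co$meta$tissue == "liver", ]
  norm <- normalize_counts(co$counts$liver[, m$sample_id])
  nulls <- setdiff(rownames(norm), tr$gene[!is.na(tr$marker_tissue)])
  nulls <- sample(nulls, 600)
  rho <- vapply(nulls, function(g) {
    y <- norm[g, ]
    if (length(unique(y)) == 1L) return(0)
    spearman_rho(y, m$histology_score)
  }, numeric(1))
  expect_lt(mean(abs(rho) > 0.6), 0.10)
})

test_that("plasma analytes recover the target R-squared on average", {
  r2 <- c()
  for (sd in 41:50) {
    cfg <- synth_config(seed = sd)
    co <- gen_cohort(cfg, gen_ontology_and_annotations(cfg)$truth)
    m <- co$meta[co$meta$tissue == "liver", ]
    pc <- grep("^plasma_", names(m), value = TRUE)
    for (p in pc) {
      r2 <- c(r2, plasma_marker_r2(m[[p]], m$histology_score)$r2)
    }
  }
  expect_lt(abs(mean(r2) - 0.7), 0.15)
})

test_that("ground-truth table is complete and deterministic", {
  sim <- gen_all(synth_config(seed = 6))
  gt <- ground_truth_table(sim$truth)
  expect_equal(nrow(gt), 2000L)
  expect_identical(gt, ground_truth_table(sim$truth[sample(2000), ]))
  markers <- gt$gene[!is.na(gt$marker_tissue)]
  expect_true(all(markers %in% sim$atlas$gene))
})

test_that("simulate_inputs writes a complete, re-readable file set", {
  dir <- file.path(tempdir(), "synthio")
  simulate_inputs(synth_config(seed = 8), dir)
  files <- c("ontology.obo", "annotations.gaf", "atlas.tsv",
             "biomarkers.tsv", "counts_liver.tsv", "counts_wat.tsv",
             "metadata.tsv", "evidence.tsv", "ground_truth.tsv",
             "config.yaml")
  expect_true(all(file.exists(file.path(dir, files))))
  onto <- read_obo(file.path(dir, "ontology.obo"))
  expect_gt(n_terms(onto), 50L)
  ann <- read_gaf(file.path(dir, "annotations.gaf"))
  expect_gt(nrow(ann), 500L)
  cnt <- read_counts_table(file.path(dir, "counts_liver.tsv"))
  expect_equal(dim(cnt), c(2000L, 27L))
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(meta), 54L)
})
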