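#!/usr/bin/env Rscript
# Candidate selection: call tissue-enriched genes from the atlas with the
# four-fold rule, add unique immune-associated atlas genes to the ontology
# sets, filter the pools against the blood protein-biomarker records, and
# assemble the per-parent candidate table with novelty labels.

library(inflamark)

dir <- "results/inputs"
cfg <- read_config(file.path(dir, "config.yaml"))
onto <- read_obo(file.path(dir, "ontology.obo"))
ann <- read_gaf(file.path(dir, "annotations.gaf"))
atlas <- read_atlas_table(file.path(dir, "atlas.tsv"))
db <- read_biomarker_table(file.path(dir, "biomarkers.tsv"))

tables <- list(); cands <- list()
for (tissue in c("adipose", "liver")) {
  sel <- select_tissue_genes(onto, ann, tissue, cfg)
  hpa <- atlas_tissue_specific_genes(atlas, cfg$atlas_tissue_labels[[tissue]],
                                     cfg$thresholds, cfg)
  add <- unique_hpa_additions(hpa, sel$genes, sel$immune_genes)
  pool <- union(sel$genes, add)
  filt <- filter_blood_protein_markers(pool, db, cfg)
  asm <- assemble_candidate_table(sel$retained, add, filt, tissue,
                                  db = db, config = cfg,
                                  hpa_specific_genes = hpa)
  tables[[tissue]] <- asm$table
  cands[[tissue]] <- asm$candidates
  cat(sprintf(
    "%s: %d atlas-specific, %d unique additions, pool %d -> %d blood markers -> %d candidates (%d novel)\n",
    tissue, length(hpa), length(add), length(pool), length(filt),
    nrow(asm$candidates), sum(asm$candidates$novelty == "novel")))
}
write_tsv_report(dplyr::bind_rows(tables), "results/candidate_table.tsv")
write_tsv_report(dplyr::bind_rows(cands), "results/candidates.tsv")
cat("Candidate tables written to results/candidate_table.tsv, results/candidates.tsv\n")
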