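#!/usr/bin/env Rscript
# Derived arithmetic on the shipped reference tables from the motivating
# published study: gene-set totals and immune percentages, candidate pools
# and deduplicated candidate counts, marker tissue classification under the
# strict |rho| > 0.6 rule, and the confirmation-level tally.

library(inflamark)

sel <- reference_table("selection")
go <- sel[sel$source == "ontology", ]
atl <- sel[sel$source == "atlas", ]
rows <- list()
for (ts in c("adipose", "liver")) {
  s <- summarize_selection_rows(go[go$tissue == ts, ], ts)
  tot <- s[s$accession == "TOTAL", ]
  pool <- tot$n_genes + atl$n_immune[atl$tissue == ts]
  cat(sprintf("%s: %d ontology genes, %d%% immune; + %d atlas additions = pool of %d\n",
              ts, tot$n_genes, tot$pct_immune,
              atl$n_immune[atl$tissue == ts], pool))
  rows[[ts]] <- s
}
write_tsv_report(dplyr::bind_rows(rows), "results/reference_selection_summary.tsv")

cand <- reference_table("candidates")
for (ts in c("adipose", "liver")) {
  cat(sprintf("%s: %d unique candidates after dedup\n", ts,
              length(candidate_union(cand[cand$tissue == ts, ]))))
}

mk <- reference_table("markers")
cls <- classify_tissue_marker(mk$rho_liver, mk$rho_wat)
cat(sprintf("Classification of the %d verified markers: %d hepatic, %d adipose\n",
            nrow(mk), sum(cls == "hepatic"), sum(cls == "adipose")))
cat("Confirmation levels:\n")
print(tally_levels(mk$level))
write_tsv_report(
  tibble::tibble(gene = mk$gene, assignment = cls, level = mk$level),
  "results/reference_marker_classification.tsv")
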