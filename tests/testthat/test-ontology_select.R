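make_named_onto <- function() {
  ontology(
    tibble::tibble(
      id = c("T:1", "T:2", "T:3", "T:4"),
      name = c("adipose tissue development", "liver development",
               "bone growth", "adipocyte differentiation"),
      namespace = "bp"),
    list(`T:1` = character(), `T:2` = character(), `T:3` = character(),
         `T:4` = "T:1")
  )
}

test_that("keyword search is case-insensitive substring on names", {
  onto <- make_named_onto()
  expect_equal(find_terms_by_keyword(onto, "adipose"), "T:1")
  expect_equal(find_terms_by_keyword(onto, "LIVER"), "T:2")
  expect_equal(find_terms_by_keyword(onto, c("adipose", "adipocyte")),
               c("T:1", "T:4"))
  expect_length(find_terms_by_keyword(onto, "kidney"), 0L)
})

test_that("curation intersects with the whitelist", {
  hits <- c("T:1", "T:2", "T:3")
  expect_equal(suppressMessages(curate_terms(hits, c("T:2", "T:9"))), "T:2")
  expect_length(curate_terms(hits, character()), 0L)
  expect_equal(curate_terms(hits, c(hits, "T:8")), sort(hits))
})

test_that("descendant closure has set semantics on chains and diamonds", {
  onto <- read_obo(obo_chain())
  expect_equal(descendant_closure(onto, "T:a"), c("T:a", "T:b", "T:c"))
  expect_equal(descendant_closure(onto, "T:c"), "T:c")

  dia <- toy_diamond()
  cl <- descendant_closure(dia, "a")
  expect_equal(cl, c("a", "b", "c", "d"))
  expect_length(cl, 4L)  # d reached via two paths, counted once
  expect_error(descendant_closure(dia, "zz"), "unknown term id.*zz")
})

test_that("closure matches the recursive oracle and igraph on random DAGs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:8) {
    onto <- random_dag(sample(5:50, 1))
    roots <- sample(onto$terms$id, sample(1:3, 1))
    got <- descendant_closure(onto, roots)
    expect_equal(got, closure_oracle(onto, roots))
    edges <- do.call(rbind, lapply(onto$terms$id, function(id) {
      ps <- onto$parents[[id]]
      if (length(ps)) cbind(ps, id) else NULL
    }))
    g <- igraph::graph_from_data_frame(
      as.data.frame(edges), directed = TRUE,
      vertices = onto$terms$id)
    ig <- sort(unique(unlist(lapply(roots, function(r)
      names(igraph::subcomponent(g, r, mode = "out"))))))
    expect_equal(got, ig)
  }
})

test_that("closure is idempotent and monotone", {
  set.seed(11)
  for (rep in 1:5) {
    onto <- random_dag(30)
    s <- sample(onto$terms$id, 3)
    t <- union(s, sample(onto$terms$id, 2))
    cs <- descendant_closure(onto, s)
    expect_equal(descendant_closure(onto, cs), cs)
    expect_true(all(cs %in% descendant_closure(onto, t)))
  }
})

test_that("immune gene set honours closure and the species/type filter", {
  onto <- ontology(
    tibble::tibble(id = c("I:r", "I:c", "I:gc", "X:1"),
                   name = c("inflammatory response", "child", "grandchild",
                            "other"),
                   namespace = "bp"),
    list(`I:r` = character(), `I:c` = "I:r", `I:gc` = "I:c",
         `X:1` = character())
  )
  ann <- tibble::tibble(
    gene = c("deep", "outside", "mouse"),
    uniprot = NA_character_,
    term_id = c("I:gc", "X:1", "I:r"),
    object_type = "protein",
    taxon = c("taxon:9606", "taxon:9606", "taxon:10090")
  )
  cfg <- run_config(immune_roots = "I:r")
  imm <- build_immune_gene_set(onto, ann, "I:r", cfg)
  expect_equal(imm, "DEEP")  # grandchild annotation included, upper-cased
  expect_false("OUTSIDE" %in% imm)
  expect_false("MOUSE" %in% imm)
})

test_that("immune-overlap filter keeps only parents sharing immune genes", {
  mk <- function(id, genes, immune) {
    structure(list(parent_id = id, parent_name = id, member_terms = id,
                   genes = genes, immune_genes = immune),
              class = "term_gene_set")
  }
  sets <- list(mk("P1", "A", character()), mk("P2", c("A", "B"), character()))
  kept <- filter_tissue_terms_by_immune_overlap(sets, immune_genes = "A")
  expect_equal(vapply(kept, `[[`, character(1), "parent_id"), c("P1", "P2"))
  none <- filter_tissue_terms_by_immune_overlap(sets, immune_genes = "Z")
  expect_length(none, 0L)
  # 1-gene parent fully immune: kept with 100%
  one <- filter_tissue_terms_by_immune_overlap(list(mk("P3", "G",
                                                       character())), "G")
  s <- summarize_selection(one, "adipose")
  expect_equal(s$pct_immune[1], 100L)
})

test_that("selection summary totals are sums of per-parent counts", {
  mk <- function(id, n, k) {
    genes <- paste0(id, "_", seq_len(n))
    structure(list(parent_id = id, parent_name = id,
                   member_terms = c(id, paste0(id, "c")),
                   genes = genes, immune_genes = genes[seq_len(k)]),
              class = "term_gene_set")
  }
  sets <- list(mk("P1", 8, 1), mk("P2", 5, 4))
  s <- summarize_selection(sets, "liver")
  tot <- s[s$accession == "TOTAL", ]
  expect_equal(tot$n_genes, 13L)
  expect_equal(tot$n_immune, 5L)
  expect_equal(tot$pct_immune, 38L)  # 5/13 = 38.46 -> 38
  # per-row percentage rounds half up: 1/8 = 12.5 -> 13
  expect_equal(s$pct_immune[s$accession == "P1"], 13L)
  expect_true(all(s$n_immune <= s$n_genes))
  expect_true(all(s$pct_immune >= 0 & s$pct_immune <= 100))
})

test_that("summarize_selection_rows applies the same arithmetic to plain rows", {
  rows <- tibble::tibble(
    tissue = "adipose", accession = c("P1", "P2"), parent_name = c("x", "y"),
    n_children = c(2L, 3L), n_genes = c(10L, 30L), n_immune = c(5L, 10L))
  out <- summarize_selection_rows(rows, "adipose")
  expect_equal(out$n_genes[out$accession == "TOTAL"], 40L)
  expect_equal(out$pct_immune[out$accession == "TOTAL"], 38L)
})
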