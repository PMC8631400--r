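# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# chain c is_a b is_a a
obo_chain <- function() write_lines_tmp(c(
  "format-version: 1.2", "",
  "[Term]", "id: T:a", "name: root process", "namespace: bp", "",
  "[Term]", "id: T:b", "name: mid process", "namespace: bp", "is_a: T:a", "",
  "[Term]", "id: T:c", "name: leaf process", "namespace: bp", "is_a: T:b", ""
), ".obo")

# diamond: d child of b and c, both children of a
toy_diamond <- function() {
  ontology(
    tibble::tibble(id = c("a", "b", "c", "d"),
                   name = paste("term", c("a", "b", "c", "d")),
                   namespace = "bp"),
    list(a = character(), b = "a", c = "a", d = c("b", "c"))
  )
}

gaf_line <- function(gene, term, taxon = "taxon:9606", type = "protein",
                     uniprot = paste0("UP_", gene)) {
  paste(c("DB", uniprot, gene, "", term, "REF:1", "IEA", "", "P", "", "",
          type, taxon, "20240101", "DB", "", ""), collapse = "\t")
}

# random parent-pointer DAG: node i may have parents among 1..(i-1)
random_dag <- function(n, p_edge = 0.15) {
  ids <- sprintf("n%02d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    if (i == 1) { parents[[i]] <- character(); next }
    sel <- which(stats::runif(i - 1) < p_edge)
    parents[[i]] <- ids[sel]
  }
  ontology(tibble::tibble(id = ids, name = ids, namespace = "bp"), parents)
}

# independent closure oracle: recursive descent over child edges
closure_oracle <- function(onto, roots) {
  out <- character()
  visit <- function(id) {
    if (id %in% out) return(invisible())
    out <<- c(out, id)
    for (ch in onto$children[[id]]) visit(ch)
  }
  for (r in roots) visit(r)
  sort(out)
}

# brute-force Spearman: Pearson on average ranks
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force BH: q_i = p_i * m / i with monotone enforcement from the top
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force two-sided Mann-Whitney by enumeration of group assignments
mwu_oracle <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  m <- nx * length(y) / 2
  us <- apply(utils::combn(length(r), nx), 2,
              function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  list(U = u_obs, p.value = mean(abs(us - m) >= abs(u_obs - m) - 1e-12))
}

# exhaustive specificity oracle: try the single top tissue and every
# candidate group of allowed size against the max of the rest
specificity_oracle <- function(levels, fold = 4, sizes = 2:5) {
  if (all(levels == 0)) return(list(class = "not-specific",
                                    tissues = character()))
  ord <- order(-levels, names(levels))
  lv <- levels[ord]
  if (lv[1] > 0 && lv[1] >= fold * max(lv[-1])) {
    return(list(class = "tissue-enriched", tissues = names(lv)[1]))
  }
  for (k in sizes) {
    if (k >= length(lv)) break
    grp <- lv[seq_len(k)]
    if (min(grp) > 0 && min(grp) >= fold * max(lv[-seq_len(k)])) {
      return(list(class = "group-enriched", tissues = sort(names(grp))))
    }
  }
  list(class = "not-specific", tissues = character())
}

default_synth_truth <- function(seed = 1) {
  cfg <- synth_config(seed = seed)
  list(cfg = cfg, oa = gen_ontology_and_annotations(cfg))
}
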