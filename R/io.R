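#' Read a GAF 2.2 gene-annotation table
#'
#' Tab-separated, 17 columns, comment lines starting with `!`. The reader
#' performs no filtering: taxon and object-type columns are preserved so the
#' species/type filter can be applied downstream when immune and tissue gene
#' sets are built.
#'
#' @param path Path to a GAF file.
#' @return A tibble with one row per annotation and columns `gene` (symbol,
#'   column 3), `uniprot` (object id, column 2), `term_id` (column 5),
#'   `object_type` (column 12) and `taxon` (column 13).
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^!", lines) & nzchar(lines)
  rows <- which(keep)
  if (!length(rows)) {
    return(tibble::tibble(gene = character(), uniprot = character(),
                          term_id = character(), object_type = character(),
                          taxon = character()))
  }
  # sentinel preserves trailing empty fields, which strsplit would drop
  fields <- strsplit(paste0(lines[rows], "\tEOL"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  nf <- lengths(fields)
  if (any(nf != 17L)) {
    bad <- which(nf != 17L)[1L]
    stop(sprintf("GAF row %d (file line %d) has %d columns, expected 17",
                 bad, rows[bad], nf[bad]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  tibble::tibble(
    gene = m[, 3L],
    uniprot = m[, 2L],
    term_id = m[, 5L],
    object_type = m[, 12L],
    taxon = m[, 13L]
  )
}

read_tsv_base <- function(path, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cross-tissue expression atlas table
#'
#' TSV with columns `gene`, `uniprot`, then one numeric column per tissue
#' (TPM-like, non-negative).
#'
#' @param path Path to the atlas TSV.
#' @return A tibble; attribute `tissues` holds the tissue column names.
#' @export
read_atlas_table <- function(path) {
  df <- read_tsv_base(path, "atlas")
  stopifnot(all(c("gene", "uniprot") %in% names(df)))
  tissues <- setdiff(names(df), c("gene", "uniprot"))
  if (length(tissues) < 2L) {
    stop("atlas needs at least two tissue columns", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene in atlas: ",
         df$gene[duplicated(df$gene)][1L], call. = FALSE)
  }
  levels <- as.matrix(df[tissues])
  if (any(!is.finite(levels)) || any(levels < 0)) {
    stop("atlas expression levels must be finite and >= 0", call. = FALSE)
  }
  attr(df, "tissues") <- tissues
  df
}

#' Write an atlas table
#' @param atlas Tibble as returned by [read_atlas_table()].
#' @param path Output path.
#' @export
write_atlas_table <- function(atlas, path) {
  write_tsv_base(atlas[order(atlas$gene, method = "radix"), , drop = FALSE],
                 path)
}

#' Read a blood protein-biomarker record table
#'
#' TSV with columns `gene`, `uniprot`, `marker_type`, `substrate`,
#' `evidence`, `conditions` (semicolon-joined disease labels),
#' `commonly_analyzed`, `diagnostic_use` (logicals).
#'
#' @param path Path to the biomarker TSV.
#' @return A tibble of biomarker records; `conditions` is a list column.
#' @export
read_biomarker_table <- function(path) {
  df <- read_tsv_base(path, "biomarker")
  need <- c("gene", "uniprot", "marker_type", "substrate", "evidence",
            "conditions", "commonly_analyzed", "diagnostic_use")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("biomarker table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$conditions <- lapply(strsplit(ifelse(is.na(df$conditions), "",
                                          df$conditions), ";", fixed = TRUE),
                          function(x) x[nzchar(x)])
  df$commonly_analyzed <- as.logical(df$commonly_analyzed)
  df$diagnostic_use <- as.logical(df$diagnostic_use)
  df
}

#' Write a biomarker record table
#' @param db Tibble of biomarker records (list-column `conditions` allowed).
#' @param path Output path.
#' @export
write_biomarker_table <- function(db, path) {
  db <- db[order(db$gene, db$substrate, db$evidence,
                 method = "radix"), , drop = FALSE]
  if (is.list(db$conditions)) {
    db$conditions <- vapply(db$conditions, paste, character(1),
                            collapse = ";")
  }
  write_tsv_base(db, path)
}

#' Read a gene-by-sample count matrix
#'
#' TSV whose first column `gene` holds gene ids and remaining columns hold
#' non-negative integer counts, one column per sample.
#'
#' @param path Path to the counts TSV.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts_table <- function(path) {
  df <- read_tsv_base(path, "counts")
  stopifnot(names(df)[1] == "gene")
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene id in counts: ",
         df$gene[duplicated(df$gene)][1L], call. = FALSE)
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in counts", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' Write a count matrix
#' @param counts Integer matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @export
write_counts_table <- function(counts, path) {
  counts <- counts[order(rownames(counts), method = "radix"), , drop = FALSE]
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_base(df, path)
}

#' Read cohort sample metadata
#'
#' TSV with columns `sample_id`, `group` (`chow` or `HFD`), `tissue`
#' (`liver` or `WAT`), `histology_score` (liver: inflammatory aggregates per
#' mm^2; WAT: crown-like structures per 1000 adipocytes), plus optional
#' `plasma_<analyte>` concentration columns.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble of samples.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_base(path, "metadata")
  need <- c("sample_id", "group", "tissue", "histology_score")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("metadata lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  bad_group <- setdiff(unique(df$group), c("chow", "HFD"))
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_tissue <- setdiff(unique(df$tissue), c("liver", "WAT"))
  if (length(bad_tissue)) {
    stop("unknown tissue label(s): ", paste(bad_tissue, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$histology_score)) || any(df$histology_score < 0)) {
    stop("histology_score must be finite and >= 0", call. = FALSE)
  }
  df
}

#' Write cohort sample metadata
#' @param meta Tibble of samples.
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  write_tsv_base(meta[order(meta$tissue, meta$sample_id,
                            method = "radix"), , drop = FALSE], path)
}

#' Write a report table deterministically
#'
#' Rows are sorted by `tissue` then `gene` when those columns exist (else by
#' all columns left to right), so repeated runs produce byte-identical
#' output.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_report <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (nm in names(rows)) {
    if (is.list(rows[[nm]])) {
      rows[[nm]] <- vapply(rows[[nm]], function(x)
        paste(sort(as.character(x)), collapse = ","), character(1))
    }
  }
  if (nrow(rows)) {
    key <- intersect(c("tissue", "gene"), names(rows))
    if (!length(key)) key <- names(rows)
    # radix order is locale-independent, keeping output byte-stable
    rows <- rows[do.call(order, c(unname(rows[key]),
                                  list(method = "radix"))), , drop = FALSE]
  }
  write_tsv_base(rows, path)
}
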