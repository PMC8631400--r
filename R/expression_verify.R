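#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with strictly
#' positive counts in every sample) of the ratio of the gene's count to its
#' across-sample geometric mean. Equal library compositions give factors of
#' 1; scaling a sample's counts scales its factor.
#'
#' @param counts Non-negative count matrix, genes in rows.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    stop("no gene has positive counts in every sample; ",
         "filter low-count genes before normalization", call. = FALSE)
  }
  lc <- log(counts[allpos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by size factors
#' @param counts Count matrix.
#' @param sf Size factors from [size_factors()] (computed if missing).
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Method-of-moments negative-binomial dispersion per gene
#'
#' On normalized counts, NB variance is approximately
#' \eqn{\mu \cdot \overline{1/s} + \alpha \mu^2} (the Poisson part is
#' inflated by normalization). Dispersion is estimated within each diet
#' group, combined as a degrees-of-freedom weighted mean, and floored.
#' There is no empirical-Bayes sharing across genes — a documented
#' simplification relative to shrinkage-based DE tools.
#'
#' @param counts Count matrix.
#' @param groups Factor or vector with one entry per sample (2 levels).
#' @param sf Size factors.
#' @param floor Lower bound for the estimate. Default 1e-8.
#' @return Numeric vector of dispersions, one per gene.
#' @export
estimate_dispersions <- function(counts, groups, sf = size_factors(counts),
                                 floor = 1e-8) {
  groups <- as.factor(groups)
  norm <- normalize_counts(counts, sf)
  disp <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    num <- 0; den <- 0
    for (g in levels(groups)) {
      idx <- groups == g
      if (sum(idx) < 2L) next
      y <- norm[i, idx]
      m <- mean(y)
      if (m <= 0) next
      v <- stats::var(y)
      pois <- m * mean(1 / sf[idx])
      w <- sum(idx) - 1L
      num <- num + w * (v - pois) / m^2
      den <- den + w
    }
    disp[i] <- if (den > 0) num / den else NA_real_
  }
  pmax(disp, floor, na.rm = FALSE)
}

# One-gene NB regression with log link, known dispersion, offset log(sf).
# Fisher scoring to tolerance 1e-8, max 100 iterations; coefficients are
# clamped so genes with an all-zero group converge to a finite, extreme
# fold change instead of diverging.
nb_fit_gene <- function(y, x, offset, alpha,
                        tol = 1e-8, max_iter = 100L, clamp = 15) {
  X <- cbind(1, x)
  mu0 <- tapply(y / exp(offset), x, mean)
  beta <- c(log(mu0[["0"]] + 0.1), log(mu0[["1"]] + 0.1) - log(mu0[["0"]] + 0.1))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + X %*% beta
    mu <- pmax(exp(eta), 1e-12)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- as.vector(eta - offset + (y - mu) / mu)
    xtw <- t(X * w)
    beta_new <- tryCatch(solve(xtw %*% X, xtw %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- pmin(pmax(as.vector(beta_new), -clamp), clamp)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- offset + X %*% beta
  mu <- pmax(exp(eta), 1e-12)
  w <- as.vector(mu / (1 + alpha * mu))
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
  list(beta = as.vector(beta), se = se, converged = converged)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Per gene: NB regression with logarithmic link, a diet-group indicator
#' covariate and log size factors as offsets, with per-gene
#' method-of-moments dispersion ([estimate_dispersions()]). The Wald
#' statistic is the group coefficient over its standard error, with a
#' two-sided normal p-value; p-values are Benjamini-Hochberg adjusted over
#' the genes with defined tests. All-zero genes are flagged not detected
#' and carry `NA` statistics.
#'
#' @param counts Count matrix (genes x samples).
#' @param groups Vector/factor of length `ncol(counts)` with exactly two
#'   levels; the first level (or `"chow"` if present) is the reference.
#' @param sf Size factors (computed if missing).
#' @param dispersions Optional numeric vector of per-gene dispersions.
#' @return A tibble with columns `gene`, `base_mean`, `log2fc`, `se`
#'   (log2 scale), `stat`, `pvalue`, `padj`, `detected`.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL, dispersions = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if ("chow" %in% levels(groups)) groups <- stats::relevel(groups, "chow")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, groups, sf)
  }
  x <- as.numeric(groups == levels(groups)[2])
  offset <- log(sf)
  norm <- normalize_counts(counts, sf)
  n_genes <- nrow(counts)
  log2fc <- se <- stat <- pvalue <- rep(NA_real_, n_genes)
  detected <- rowSums(counts) > 0
  for (i in seq_len(n_genes)) {
    if (!detected[i]) next
    fit <- nb_fit_gene(counts[i, ], x, offset, dispersions[i])
    if (is.na(fit$se) || fit$se <= 0) next
    log2fc[i] <- fit$beta[2] / log(2)
    se[i] <- fit$se / log(2)
    stat[i] <- fit$beta[2] / fit$se
    pvalue[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  padj <- rep(NA_real_, n_genes)
  ok <- !is.na(pvalue)
  padj[ok] <- bh_adjust(pvalue[ok])
  tibble::tibble(
    gene = rownames(counts) %||% as.character(seq_len(n_genes)),
    base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, stat = stat,
    pvalue = pvalue, padj = padj, detected = detected
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved and adjusted values are
#' never below the raw p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return The correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("spearman_rho undefined for a constant vector",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Mann-Whitney U test
#'
#' Two-tailed. With a combined sample size of at most 12 the p-value is
#' computed by full enumeration of all group assignments of the observed
#' (possibly tied) values; larger samples use the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A list with `U` (statistic for `x`) and `p.value`.
#' @export
mann_whitney_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1L, ny >= 1L)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= 12L) {
    m <- nx * ny / 2
    assignments <- utils::combn(nx + ny, nx)
    us <- apply(assignments, 2, function(idx)
      sum(r[idx]) - nx * (nx + 1) / 2)
    p <- mean(abs(us - m) >= abs(u - m) - 1e-12)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(U = unname(u), p.value = min(1, p))
}

#' Ratio of group means (HFD over chow)
#'
#' @param scores Numeric vector (e.g. histology scores).
#' @param groups Vector with values `chow`/`HFD` matching `scores`.
#' @return `mean(scores[HFD]) / mean(scores[chow])`.
#' @export
group_fold_change <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  chow <- mean(scores[groups == "chow"])
  hfd <- mean(scores[groups == "HFD"])
  if (!is.finite(chow) || chow <= 0) {
    stop("chow group mean must be positive for a fold change",
         call. = FALSE)
  }
  hfd / chow
}

#' Squared Pearson correlation of a plasma analyte with histology
#'
#' @param plasma,scores Paired numeric vectors, n >= 3.
#' @return A list with `r2` and the two-sided `p.value` from the
#'   t-distribution.
#' @export
plasma_marker_r2 <- function(plasma, scores) {
  stopifnot(length(plasma) == length(scores))
  if (length(plasma) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (length(unique(plasma)) == 1L || length(unique(scores)) == 1L) {
    stop("plasma_marker_r2 undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(plasma, scores, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p.value = ct$p.value)
}

#' Apply the three verification criteria to candidate genes
#'
#' A candidate is verified for a target tissue when it is (a) detected
#' there — mean normalized count at least `detect_min_norm_count` in at
#' least one diet group; (b) differentially expressed there at the FDR
#' cutoff; and (c) more highly expressed in the target than in the
#' non-target tissue, comparing mean normalized counts across the inflamed
#' (HFD) samples by default (each tissue's matrix normalized
#' independently).
#'
#' @param de Named list of DE tibbles from [nb_wald_test()], one per tissue.
#' @param norm Named list of normalized count matrices, one per tissue.
#' @param meta Sample metadata tibble ([read_sample_metadata()]).
#' @param candidates Named list of candidate gene vectors per target tissue.
#' @param thresholds A [thresholds()].
#' @param config A [run_config()] (for the criterion-(c) sample option).
#' @return Named list of verified gene vectors per target tissue.
#' @export
select_verified_candidates <- function(de, norm, meta, candidates,
                                       thresholds = inflamark::thresholds(),
                                       config = run_config()) {
  tissues <- names(candidates)
  missing <- setdiff(tissues, names(de))
  if (length(missing)) {
    stop("tissue(s) missing from DE results: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mean_expr <- function(tissue, genes) {
    ids <- meta$sample_id[meta$tissue == tissue &
      (config$criterion_c_samples == "all" | meta$group == "HFD")]
    ids <- intersect(ids, colnames(norm[[tissue]]))
    rowMeans(norm[[tissue]][genes, ids, drop = FALSE])
  }
  out <- list()
  for (target in tissues) {
    other <- setdiff(names(de), target)[1]
    genes <- intersect(candidates[[target]], rownames(norm[[target]]))
    if (!length(genes)) { out[[target]] <- character(); next }
    # (a) detection in at least one diet group of the target tissue
    det <- vapply(genes, function(g) {
      any(vapply(c("chow", "HFD"), function(grp) {
        ids <- meta$sample_id[meta$tissue == target & meta$group == grp]
        ids <- intersect(ids, colnames(norm[[target]]))
        mean(norm[[target]][g, ids]) >= thresholds$detect_min_norm_count
      }, logical(1)))
    }, logical(1))
    # (b) FDR in the target tissue
    de_t <- de[[target]]
    padj <- stats::setNames(de_t$padj, de_t$gene)[genes]
    sig <- !is.na(padj) & padj < thresholds$fdr_cutoff
    # (c) target expression above non-target expression
    in_other <- genes %in% rownames(norm[[other]])
    higher <- rep(FALSE, length(genes))
    higher[in_other] <- mean_expr(target, genes[in_other]) >
      mean_expr(other, genes[in_other])
    higher[!in_other] <- TRUE  # absent from the other tissue's matrix
    out[[target]] <- genes[det & sig & higher]
  }
  out
}

#' Correlate per-gene expression with histological inflammation
#'
#' For one tissue: Spearman correlation between each gene's normalized
#' counts and each animal's histology score, across all animals by default
#' (chow and HFD pooled). Genes with constant expression get `NA` rho and
#' do not pass. A correlation passes only if its magnitude strictly exceeds
#' the cutoff: values in the closed range `[-cutoff, cutoff]` are treated
#' as no relation.
#'
#' @param norm_counts Normalized count matrix for the tissue.
#' @param meta_tissue Metadata rows for that tissue's samples.
#' @param thresholds A [thresholds()].
#' @param config A [run_config()] (for the pooled vs HFD-only option).
#' @return Tibble with columns `gene`, `rho`, `n`, `passes`.
#' @export
correlate_expression_to_histology <- function(norm_counts, meta_tissue,
                                              thresholds = inflamark::thresholds(),
                                              config = run_config()) {
  ids <- intersect(colnames(norm_counts), meta_tissue$sample_id)
  if (config$correlation_samples == "hfd") {
    ids <- intersect(ids,
                     meta_tissue$sample_id[meta_tissue$group == "HFD"])
  }
  if (length(ids) < 3L) {
    stop("need at least 3 animals with both expression and histology",
         call. = FALSE)
  }
  scores <- stats::setNames(meta_tissue$histology_score,
                            meta_tissue$sample_id)[ids]
  expr <- norm_counts[, ids, drop = FALSE]
  rho <- vapply(seq_len(nrow(expr)), function(i) {
    y <- expr[i, ]
    if (length(unique(y)) == 1L) return(NA_real_)
    spearman_rho(y, scores)
  }, numeric(1))
  tibble::tibble(
    gene = rownames(norm_counts),
    rho = rho,
    n = length(ids),
    passes = !is.na(rho) & abs(rho) > thresholds$rho_cutoff
  )
}

#' Classify a marker's tissue assignment from its two correlations
#'
#' `hepatic` when the liver correlation passes and the adipose one does
#' not; `adipose` for the converse; `both` when both pass (such markers are
#' excluded from either tissue-specific list); `none` otherwise. `NA`
#' correlations count as not passing. Vectorized.
#'
#' @param rho_liver,rho_wat Numeric vectors of Spearman correlations.
#' @param rho_cutoff Correlation magnitude cutoff (strict). Default 0.60.
#' @return Character vector of labels.
#' @export
classify_tissue_marker <- function(rho_liver, rho_wat, rho_cutoff = 0.60) {
  pl <- !is.na(rho_liver) & abs(rho_liver) > rho_cutoff
  pw <- !is.na(rho_wat) & abs(rho_wat) > rho_cutoff
  dplyr::case_when(
    pl & !pw ~ "hepatic",
    pw & !pl ~ "adipose",
    pl & pw ~ "both",
    .default = "none"
  )
}
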