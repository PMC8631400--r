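test_that("size factors follow the median-of-ratios construction", {
  cnt <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- size_factors(cnt)
  # second sample is a doubled copy: factors (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- cbind(a = c(5, 9, 14), b = c(5, 9, 14))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))

  perm <- cnt[c(3, 1, 2), ]
  expect_equal(size_factors(perm), sf)

  zero <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("g1", "g2"), NULL))
  expect_error(size_factors(zero), "no gene has positive counts")
})

test_that("normalized matrices have unit median-of-ratios per sample", {
  set.seed(2)
  cnt <- matrix(rnbinom(600, mu = 150, size = 10) + 1L, ncol = 6,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  norm <- normalize_counts(cnt)
  refit <- size_factors(norm)
  # residual factors of an already-normalized matrix are equal across
  # samples and essentially 1
  expect_lt(diff(range(refit)), 1e-10)
  expect_equal(unname(refit), rep(1, 6), tolerance = 0.02)
})

test_that("BH adjustment matches the step-up formula and base properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (rep in 1:10) {
    p <- stats::runif(sample(1:8, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-12))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p-order
  }
})

test_that("spearman_rho equals Pearson on average ranks", {
  expect_equal(spearman_rho(1:3, 1:3), 1)
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 0.9487,
               tolerance = 1e-4)
  set.seed(4)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    x <- sample(1:5, n, replace = TRUE) + stats::runif(n, 0, 0.01)
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(y)) == 1L) y[1] <- y[1] + 1
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y))
    # invariance under strictly monotone transforms
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_gte(spearman_rho(x, y), -1)
    expect_lte(spearman_rho(x, y), 1)
  }
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Mann-Whitney U: exact enumeration, symmetry, ties, approximation", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)  # 2 / choose(6, 3)

  same <- mann_whitney_u(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$p.value, 1, tolerance = 1e-9)

  set.seed(5)
  for (rep in 1:10) {
    x <- sample(1:4, sample(2:5, 1), replace = TRUE)
    y <- sample(1:4, sample(2:5, 1), replace = TRUE)
    got <- mann_whitney_u(x, y)
    want <- mwu_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p.value, want$p.value)
    swapped <- mann_whitney_u(y, x)
    expect_equal(swapped$p.value, got$p.value)
  }
  # large-sample branch agrees with the corrected normal approximation
  set.seed(6)
  x <- stats::rnorm(15); y <- stats::rnorm(12, 0.5)
  expect_equal(mann_whitney_u(x, y)$p.value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value)
})

test_that("NB Wald test: null genes are centred, Poisson limit matches glm", {
  grp <- c(rep("chow", 10), rep("HFD", 17))
  # identical group means
  cnt <- matrix(rep(c(100L, 110L), length.out = 27 * 3), nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:27)))
  de <- nb_wald_test(cnt, grp, sf = rep(1, 27), dispersions = rep(0.05, 3))
  expect_true(all(abs(de$log2fc) < 0.15))
  expect_true(all(de$pvalue > 0.2))

  # dispersion -> 0 recovers the Poisson regression statistic
  set.seed(8)
  y <- stats::rpois(12, 30)
  x <- rep(c(0, 1), each = 6)
  sf <- exp(stats::rnorm(12, 0, 0.1))
  m <- matrix(y, nrow = 1, dimnames = list("g", paste0("s", 1:12)))
  fit <- nb_wald_test(m, ifelse(x == 1, "HFD", "chow"), sf = sf,
                      dispersions = 1e-10)
  g <- stats::glm(y ~ x, family = stats::poisson, offset = log(sf))
  expect_equal(fit$stat, unname(summary(g)$coefficients[2, 3]),
               tolerance = 1e-6)
  expect_equal(fit$log2fc, unname(stats::coef(g)[2]) / log(2),
               tolerance = 1e-6)

  # all-zero genes flagged not detected with NA statistics
  z <- rbind(g1 = rep(0L, 27), g2 = rep(c(40L, 60L), length.out = 27))
  colnames(z) <- paste0("s", 1:27)
  dez <- nb_wald_test(z, grp, sf = rep(1, 27))
  expect_false(dez$detected[1])
  expect_true(is.na(dez$pvalue[1]))
  expect_true(dez$detected[2])
})

test_that("a planted four-fold change is detected at FDR 0.01 with high power", {
  grp <- c(rep("chow", 10), rep("HFD", 17))
  set.seed(9)
  rej <- replicate(200, {
    y <- c(stats::rnbinom(10, size = 1 / 0.05, mu = 100),
           stats::rnbinom(17, size = 1 / 0.05, mu = 400))
    m <- matrix(y, nrow = 1, dimnames = list("g", paste0("s", 1:27)))
    nb_wald_test(m, grp, sf = rep(1, 27))$pvalue < 0.01
  })
  expect_gte(mean(rej), 0.95)
})

test_that("agreement with DESeq2 Wald inference on a small dataset", {
  skip_if_not_installed("DESeq2")
  set.seed(10)
  n <- 27
  grp <- factor(c(rep("chow", 10), rep("HFD", 17)), levels = c("chow", "HFD"))
  base <- exp(stats::rnorm(60, log(150), 0.8))
  fc <- sample(c(1, 1, 2, 0.5), 60, replace = TRUE)
  mu <- outer(base, rep(1, n))
  mu[, grp == "HFD"] <- mu[, grp == "HFD"] * fc
  cnt <- matrix(stats::rnbinom(60 * n, size = 10, mu = mu), nrow = 60,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:n)))
  de <- nb_wald_test(cnt, grp)
  dds <- DESeq2::DESeqDataSetFromMatrix(cnt, S4Vectors::DataFrame(grp),
                                        ~grp)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ok <- !is.na(res$log2FoldChange) & !is.na(de$log2fc)
  # same sign and strongly correlated effect estimates / statistics
  expect_gt(stats::cor(de$log2fc[ok], res$log2FoldChange[ok]), 0.95)
  expect_gt(stats::cor(de$stat[ok], res$stat[ok]), 0.9)
})

test_that("verification criteria a-c gate candidates as specified", {
  meta <- tibble::tibble(
    sample_id = c(paste0("L", 1:4), paste0("W", 1:4)),
    group = rep(c("chow", "chow", "HFD", "HFD"), 2),
    tissue = rep(c("liver", "WAT"), each = 4),
    histology_score = 1
  )
  norm <- list(
    liver = rbind(gA = c(100, 110, 220, 230), gB = c(50, 60, 55, 52),
                  gC = c(5, 6, 9, 8), gD = c(0.1, 0.2, 0.3, 0.2)),
    WAT = rbind(gA = c(5, 6, 5, 4), gB = c(40, 50, 45, 44),
                gC = c(100, 120, 200, 210), gD = c(0.1, 0.1, 0.2, 0.1))
  )
  for (ts in names(norm)) {
    colnames(norm[[ts]]) <- meta$sample_id[meta$tissue == ts]
  }
  de <- list(
    liver = tibble::tibble(gene = c("gA", "gB", "gC", "gD"),
                           padj = c(0.005, 0.02, 0.004, 0.001)),
    WAT = tibble::tibble(gene = c("gA", "gB", "gC", "gD"),
                         padj = c(0.5, 0.5, 0.002, 0.5))
  )
  cand <- list(liver = c("gA", "gB", "gC", "gD"), WAT = c("gC"))
  got <- select_verified_candidates(de, norm, meta, cand)
  # gA passes everything; gB fails (b) at 0.02; gC fails (c) in liver
  # (higher in WAT); gD fails detection (a)
  expect_equal(got$liver, "gA")
  expect_equal(got$WAT, "gC")
  expect_error(select_verified_candidates(de, norm, meta,
                                          list(brain = "gA")),
               "missing from DE")
})

test_that("expression-histology correlation: monotone link, strict cutoff, nulls", {
  meta <- tibble::tibble(
    sample_id = paste0("L", 1:27), group = c(rep("chow", 10), rep("HFD", 17)),
    tissue = "liver",
    histology_score = c(stats::runif(10, 0.5, 1.5), stats::runif(17, 20, 45))
  )
  expr <- rbind(
    up = 2 * meta$histology_score^1.3 + 5,   # strictly monotone, rho 1
    flat = rep(3, 27)
  )
  colnames(expr) <- meta$sample_id
  got <- correlate_expression_to_histology(expr, meta)
  expect_equal(got$rho[got$gene == "up"], 1)
  expect_true(got$passes[got$gene == "up"])
  expect_true(is.na(got$rho[got$gene == "flat"]))
  expect_false(got$passes[got$gene == "flat"])

  # a coefficient of exactly 0.60 does not pass (closed no-relation band)
  expect_false(abs(0.60) > thresholds()$rho_cutoff)

  # null pass rate at n = 27 stays below 10%
  set.seed(12)
  nulls <- replicate(500, spearman_rho(stats::rnorm(27),
                                       meta$histology_score))
  expect_lt(mean(abs(nulls) > 0.6), 0.10)
})

test_that("tissue classification follows the two-correlation rule", {
  # shapes seen in the reference study: HP hepatic, MMP9 adipose
  expect_equal(classify_tissue_marker(0.85, 0.2), "hepatic")
  expect_equal(classify_tissue_marker(0.1, -0.76), "adipose")
  expect_equal(classify_tissue_marker(0.9, -0.8), "both")
  expect_equal(classify_tissue_marker(0.3, -0.2), "none")
  expect_equal(classify_tissue_marker(NA, 0.7), "adipose")
  expect_equal(classify_tissue_marker(0.60, 0.0), "none")  # boundary strict
  expect_equal(classify_tissue_marker(c(0.85, 0.1), c(0.2, -0.76)),
               c("hepatic", "adipose"))
})

test_that("group fold change is the ratio of group means", {
  expect_equal(group_fold_change(c(rep(1, 10), rep(31.6, 17)),
                                 c(rep("chow", 10), rep("HFD", 17))), 31.6)
  expect_equal(group_fold_change(c(2, 2, 2, 2), c("chow", "chow", "HFD",
                                                  "HFD")), 1)
  expect_error(group_fold_change(c(0, 0, 1), c("chow", "chow", "HFD")),
               "chow group mean")
})

test_that("plasma R2: perfect line, null expectation, error on constants", {
  x <- 1:10
  expect_equal(plasma_marker_r2(2 * x + 3, x)$r2, 1)
  set.seed(13)
  nulls <- replicate(500, plasma_marker_r2(stats::rnorm(27),
                                           stats::rnorm(27))$r2)
  expect_equal(mean(nulls), 1 / 26, tolerance = 0.3)  # E[r^2] = 1/(n-1)
  expect_error(plasma_marker_r2(rep(1, 5), 1:5), "constant")
})
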