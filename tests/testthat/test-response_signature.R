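test_that("exact NB test matches the tail-enumeration oracle", {
  set.seed(22)
  for (i in 1:25) {
    y1 <- rpois(1, 40)
    y2 <- rpois(1, 40)
    l1 <- runif(1, 0.5, 2) * 1e4
    l2 <- runif(1, 0.5, 2) * 1e4
    phi <- sample(c(0.05, 0.1, 0.2), 1)
    expect_equal(nb_exact_test(y1, y2, l1, l2, phi),
                 oracle_nb_exact_p(y1, y2, l1, l2, phi), tolerance = 1e-12)
  }
  expect_equal(nb_exact_test(0, 0, 1e4, 1e4), 1)
})

test_that("per-line response: identical arms give logFC 0 and p 1", {
  counts <- tibble::tibble(gene = sprintf("g%d", 1:60))
  set.seed(23)
  base <- rnbinom(60, mu = 120, size = 5) + 1L
  counts$A_dmso <- base
  counts$A_treated <- base
  meta <- tibble::tibble(sample = c("A_dmso", "A_treated"), cell_line = "A",
                         treatment = c("dmso", "treated"))
  r <- per_line_response(counts, meta)
  expect_equal(r$logfc, rep(0, 60))
  expect_equal(r$p_value, rep(1, 60))
  # zero in treated, large in dmso: finite negative logFC
  counts$A_treated[1] <- 0L
  counts$A_dmso[1] <- 1000L
  r2 <- per_line_response(counts, meta)
  expect_true(is.finite(r2$logfc[1]) && r2$logfc[1] < 0)
  expect_error(per_line_response(counts, meta, lines = "B"), "arm")
})

test_that("group contrast matches the Welch oracle and flips under swap", {
  set.seed(24)
  lines <- c(sprintf("S%d", 1:6), sprintf("I%d", 1:6))
  groups <- tibble::tibble(cell_line = lines,
                           group = rep(c("sensitive", "insensitive"),
                                       each = 6))
  resp <- tidyr::expand_grid(gene = sprintf("g%d", 1:40), cell_line = lines)
  resp$logfc <- rnorm(nrow(resp), sd = 0.5)
  gc1 <- group_response_contrast(resp, groups)
  for (g in sample(gc1$gene, 10)) {
    x <- resp$logfc[resp$gene == g & resp$cell_line %in% lines[1:6]]
    y <- resp$logfc[resp$gene == g & resp$cell_line %in% lines[7:12]]
    tt <- t.test(x, y)
    row <- gc1[gc1$gene == g, ]
    expect_equal(row$delta, mean(x) - mean(y), tolerance = 1e-12)
    expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
  swapped <- dplyr::mutate(groups, group = ifelse(group == "sensitive",
                                                  "insensitive", "sensitive"))
  gc2 <- group_response_contrast(resp, swapped)
  expect_equal(gc2$delta, -gc1$delta)
  expect_equal(gc2$p_value, gc1$p_value, tolerance = 1e-12)
  expect_error(group_response_contrast(resp, groups[-(1:5), ]), "two cell")
})

test_that("group contrast degenerate variance cases", {
  groups <- tibble::tibble(cell_line = c("a", "b", "c", "d"),
                           group = rep(c("sensitive", "insensitive"), each = 2))
  resp <- tidyr::expand_grid(gene = c("flat", "shift"),
                             cell_line = groups$cell_line)
  resp$logfc <- c(0, 0, 0, 0, -1, -1, 0, 0)
  gc_ <- group_response_contrast(resp, groups)
  expect_equal(gc_$p_value[gc_$gene == "flat"], 1)
  expect_equal(gc_$delta[gc_$gene == "shift"], -1)
  expect_true(gc_$zero_var[gc_$gene == "shift"])
  expect_gt(gc_$p_value[gc_$gene == "shift"], 0)
})

test_that("target-set thresholds: inclusive on fold change, strict on p", {
  contrast <- tibble::tibble(
    gene = c("in1", "bound_lfc", "bound_p", "weak", "up"),
    delta = c(-0.9, -0.7, -2, -0.3, 1.5),
    p_value = c(1e-12, 1e-12, 1e-10, 1e-12, 1e-12))
  ts <- define_target_set(contrast, lfc_threshold = 0.7,
                          p_threshold = 1e-10)
  expect_true("in1" %in% ts$genes)
  expect_true("bound_lfc" %in% ts$genes)    # |delta| == threshold kept
  expect_false("bound_p" %in% ts$genes)     # p == threshold excluded
  expect_false("weak" %in% ts$genes)
  expect_false("up" %in% ts$genes)
  up <- define_target_set(contrast, 0.7, 1e-10, direction = "up")
  expect_equal(up$genes, "up")
})

test_that("target-set membership is monotone in both thresholds", {
  set.seed(25)
  contrast <- tibble::tibble(gene = sprintf("g%d", 1:200),
                             delta = rnorm(200),
                             p_value = runif(200)^4)
  strict <- define_target_set(contrast, 0.8, 1e-4)$genes
  relax_lfc <- define_target_set(contrast, 0.5, 1e-4)$genes
  relax_p <- define_target_set(contrast, 0.8, 1e-2)$genes
  expect_true(all(strict %in% relax_lfc))
  expect_true(all(strict %in% relax_p))
})

test_that("baseline DE applies inclusive 4-fold and adjusted-p thresholds", {
  sim <- simulate_expression_panel(
    expression_sim_config(n_genes = 800, module_size = 10,
                          baseline_de_fraction = 0.03), seed = 26)
  bde <- baseline_group_de(sim$counts, sim$meta, dispersion = 0.1)
  expect_gte(mean(sim$truth$baseline_up %in% bde$up), 0.9)
  expect_gte(mean(sim$truth$baseline_down %in% bde$down), 0.9)
  null_genes <- setdiff(sim$counts$gene,
                        c(sim$truth$baseline_up, sim$truth$baseline_down,
                          sim$truth$module))
  expect_lte(mean(null_genes %in% c(bde$up, bde$down)), 0.01)
  # identical groups: no calls
  flat <- simulate_expression_panel(
    expression_sim_config(n_genes = 300, module_size = 5, module_effect = 0,
                          baseline_de_fraction = 0), seed = 27)
  bflat <- baseline_group_de(flat$counts, flat$meta, dispersion = 0.1)
  expect_length(bflat$up, 0)
  expect_length(bflat$down, 0)
})

test_that("2-fold planted genes are excluded by the 4-fold filter", {
  sim <- simulate_expression_panel(
    expression_sim_config(n_genes = 600, module_size = 5,
                          baseline_de_fraction = 0.05,
                          baseline_de_effect = 1), seed = 28)
  bde <- baseline_group_de(sim$counts, sim$meta, dispersion = 0.1)
  expect_length(intersect(sim$truth$baseline_up, bde$up), 0)
  expect_length(intersect(sim$truth$baseline_down, bde$down), 0)
})

test_that("downregulation overlap obeys inclusion-exclusion and filters", {
  mk <- function(genes, down, p = 1e-4) {
    tibble::tibble(gene = genes,
                   logfc = ifelse(genes %in% down, -1, 0.5),
                   p_adj = ifelse(genes %in% down, p, 0.5))
  }
  genes <- sprintf("g%02d", 1:40)
  ov <- downregulated_overlap(list(
    inhibitor = mk(genes, genes[1:10]),
    knockout = mk(genes, genes[11:20]),
    combination = mk(genes, genes[21:30])))
  expect_equal(ov$regions$n[ov$regions$region == "111"], 0L)
  # nested sets: A subset of B subset of C
  ov2 <- downregulated_overlap(list(
    inhibitor = mk(genes, genes[1:5]),
    knockout = mk(genes, genes[1:12]),
    combination = mk(genes, genes[1:30])))
  expect_equal(ov2$regions$n[ov2$regions$region == "111"], 5L)
  # random sets satisfy inclusion-exclusion
  set.seed(29)
  sets <- lapply(1:3, function(i) sample(genes, sample(5:25, 1)))
  ov3 <- downregulated_overlap(list(a = mk(genes, sets[[1]]),
                                    b = mk(genes, sets[[2]]),
                                    c = mk(genes, sets[[3]])))
  r <- setNames(ov3$regions$n, ov3$regions$region)
  union_size <- length(unique(unlist(sets)))
  expect_equal(sum(r[c("100", "010", "001", "110", "101", "011", "111")]),
               union_size)
  expect_equal(unname(r["total_a"] + r["total_b"] + r["total_c"]
                      - sum(r[c("110", "101", "011")]) - 2 * r["111"]),
               union_size)
})

test_that("extra fold filter restricts only the combination condition", {
  genes <- sprintf("g%d", 1:6)
  res <- list(
    inhibitor = tibble::tibble(gene = genes, logfc = -1, p_adj = 0.001),
    knockout = tibble::tibble(gene = genes, logfc = -1, p_adj = 0.001),
    combination = tibble::tibble(gene = genes,
                                 logfc = c(-0.3, -0.3, -0.7, -1, -2, -0.59),
                                 p_adj = 0.001))
  ov <- downregulated_overlap(res, extra_fold = 1.5)
  # log2(1.5) ~ 0.585: only genes at or beyond -0.585 survive
  expect_equal(sort(ov$sets$combination), sort(genes[3:6]))
  expect_equal(length(ov$sets$inhibitor), 6L)
  # padj boundary inclusive
  res$combination$p_adj <- c(0.01, 0.0100001, rep(0.001, 4))
  ov2 <- downregulated_overlap(res, padj = 0.01)
  expect_true("g1" %in% ov2$sets$combination)
  expect_false("g2" %in% ov2$sets$combination)
})

test_that("cpm and tpm follow their defining formulas", {
  y <- matrix(c(1, 1, 2, 2, 2, 4), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cpm <- compute_cpm(y)
  expect_equal(cpm[, "s1"], c(a = 250000, b = 250000, c = 500000))
  len <- c(1000, 2000, 500)
  tpm <- compute_tpm(y, len)
  expect_equal(unname(colSums(tpm)), rep(1e6, 2))
  set.seed(30)
  yr <- matrix(rpois(50 * 3, 60), nrow = 50)
  lenr <- sample(200:5000, 50)
  expect_equal(compute_cpm(yr), sweep(yr, 2, colSums(yr), "/") * 1e6)
  rate <- yr / lenr
  expect_equal(compute_tpm(yr, lenr),
               sweep(rate, 2, colSums(rate), "/") * 1e6)
  # tibble interface preserves the gene column
  tb <- tibble::tibble(gene = letters[1:3], s1 = y[, 1], s2 = y[, 2])
  expect_equal(compute_cpm(tb)$s1, unname(cpm[, "s1"]))
})

test_that("PCA scores: duplicates coincide, reconstruction is exact", {
  set.seed(31)
  x <- matrix(rnorm(200 * 6), nrow = 200,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  x <- cbind(x, s7 = x[, 3])
  sc <- pca_scores(x, n_components = 2, n_top = 200)
  expect_equal(unlist(sc[sc$sample == "s3", -1]),
               unlist(sc[sc$sample == "s7", -1]), tolerance = 1e-9)
  # rank-1 structure: PC1 explains all variance
  u <- rnorm(100); v <- rnorm(5)
  r1 <- u %*% t(v)
  colnames(r1) <- sprintf("r%d", 1:5)
  s1 <- pca_scores(r1, n_components = 1, n_top = 100)
  ve <- attr(s1, "var_explained")
  expect_equal(ve[1], 1, tolerance = 1e-10)
  # reconstruction from all retained components equals the centered input
  x5 <- matrix(rnorm(200 * 5), nrow = 200,
               dimnames = list(NULL, sprintf("q%d", 1:5)))
  scf <- pca_scores(x5, n_components = 4, n_top = 200)  # centered rank is 4
  recon <- as.matrix(scf[, -1]) %*% t(attr(scf, "rotation"))
  xc <- t(x5 - rowMeans(x5))
  expect_equal(unname(recon), unname(xc), tolerance = 1e-8)
  expect_error(pca_scores(x, n_components = 7, n_top = 200), "rank")
  expect_error(pca_scores(x[, 1, drop = FALSE]), "two samples")
})

test_that("suppressed module is recovered end-to-end in the panel", {
  sim <- simulate_expression_panel(
    expression_sim_config(n_genes = 1200, module_size = 15), seed = 32)
  resp <- per_line_response(sim$counts, sim$meta)
  gc_ <- group_response_contrast(resp,
                                 dplyr::distinct(sim$meta, cell_line, group))
  ts <- define_target_set(gc_, lfc_threshold = 0.5, p_threshold = 1e-3)
  expect_gte(mean(sim$truth$module %in% ts$genes), 0.9)
  null_genes <- setdiff(gc_$gene, unlist(sim$truth[c("module", "baseline_up",
                                                     "baseline_down")]))
  expect_lte(mean(null_genes %in% ts$genes), 0.01)
  mod_delta <- gc_$delta[gc_$gene %in% sim$truth$module]
  expect_equal(mean(mod_delta), -1, tolerance = 0.15)
})
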