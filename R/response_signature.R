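#' Exact negative-binomial test for an unreplicated pair
#'
#' Two-sided exact test of differential abundance between two counts with a
#' fixed common dispersion, conditional on their total. Under the null the
#' two counts are NB with means proportional to the effective library sizes;
#' the p-value sums the conditional probabilities of all outcomes no more
#' probable than the observed one.
#'
#' @param y1,y2 Observed counts (scalars or equal-length vectors).
#' @param lib1,lib2 Effective library sizes.
#' @param dispersion Fixed NB dispersion.
#' @return Vector of two-sided p-values.
#' @export
nb_exact_test <- function(y1, y2, lib1, lib2, dispersion = 0.2) {
  mapply(function(a, b) nb_exact_p1(a, b, lib1, lib2, dispersion), y1, y2)
}

nb_exact_p1 <- function(y1, y2, lib1, lib2, dispersion) {
  n <- y1 + y2
  if (n == 0) return(1)
  lambda <- n / (lib1 + lib2)
  k <- 0:n
  logp <- dnbinom(k, size = 1 / dispersion, mu = lambda * lib1, log = TRUE) +
    dnbinom(n - k, size = 1 / dispersion, mu = lambda * lib2, log = TRUE)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  min(sum(pr[pr <= pr[y1 + 1] * (1 + 1e-12)]), 1)
}

counts_matrix <- function(tab, id_col = "gene") {
  samples <- setdiff(names(tab), c("sgrna", "gene"))
  m <- as.matrix(tab[, samples])
  rownames(m) <- tab[[id_col]]
  m
}

#' Per-cell-line treatment response
#'
#' Treatment-versus-vehicle differential expression within each cell line:
#' TMM-normalized effective library sizes, prior-shrunken log2 fold
#' changes, and a p-value from the exact conditional NB test with fixed
#' dispersion when the line has one sample per arm, or a likelihood-ratio
#' test on the NB GLM when replicated. P-values are BH-adjusted within each
#' line.
#'
#' @param expr Wide expression tibble (`gene` plus sample columns).
#' @param meta Sample metadata with `sample`, `cell_line`, `treatment` in
#'   `{"dmso", "treated"}`.
#' @param lines Cell lines to analyse (default all).
#' @param dispersion Fixed NB dispersion (default 0.2).
#' @param prior_count Prior count for fold-change shrinkage (default 12).
#' @return Long tibble: `gene`, `cell_line`, `logfc`, `p_value`, `p_adj`.
#' @export
per_line_response <- function(expr, meta, lines = NULL, dispersion = 0.2,
                              prior_count = 12) {
  y <- counts_matrix(expr)
  if (is.null(lines)) lines <- unique(meta$cell_line)
  purrr::map_dfr(lines, function(ln) {
    tr <- meta$sample[meta$cell_line == ln & meta$treatment == "treated"]
    ct <- meta$sample[meta$cell_line == ln & meta$treatment == "dmso"]
    tr <- intersect(tr, colnames(y))
    ct <- intersect(ct, colnames(y))
    if (!length(tr) || !length(ct)) {
      abort(sprintf("cell line '%s' is missing a treatment arm", ln))
    }
    ys <- rowSums(y[, tr, drop = FALSE])
    yr <- rowSums(y[, ct, drop = FALSE])
    f <- tmm_pair_factor(ys, yr)
    l_s <- sum(ys) * f
    l_r <- sum(yr) / f
    lfc <- shrunken_logfc_libs(ys, yr, l_s, l_r, prior_count)
    if (length(tr) == 1L && length(ct) == 1L) {
      p <- nb_exact_test(ys, yr, l_s, l_r, dispersion)
    } else {
      samples <- c(ct, tr)
      design <- cbind(1, c(rep(0, length(ct)), rep(1, length(tr))))
      colnames(design) <- c("(Intercept)", "treatmenttreated")
      null_design <- design[, 1, drop = FALSE]
      per_lib <- colSums(y[, samples, drop = FALSE])
      per_lib[ct] <- per_lib[ct] / f
      per_lib[tr] <- per_lib[tr] * f
      offs <- log(per_lib)
      p <- vapply(seq_len(nrow(y)), function(i) {
        full <- nb_glm_fit(y[i, samples], design, offs, dispersion)
        null <- nb_glm_fit(y[i, samples], null_design, offs, dispersion)
        treatment_contrast_test(full, null)$p_value
      }, numeric(1))
    }
    tibble::tibble(gene = rownames(y), cell_line = ln,
                   logfc = unname(lfc), p_value = unname(p),
                   p_adj = unname(bh_adjust(p)))
  })
}

#' Sensitive-versus-insensitive group contrast of treatment responses
#'
#' For each gene, the group difference of per-line treatment log2 fold
#' changes (mean over sensitive lines minus mean over insensitive lines)
#' and a two-sided Welch t-test p-value on the per-line fold changes. With
#' zero variance in both groups the p-value is 1 when the difference is
#' zero and the smallest representable positive value otherwise (flagged in
#' `zero_var`).
#'
#' @param responses Long per-line response tibble (`gene`, `cell_line`,
#'   `logfc`), e.g. from [per_line_response()].
#' @param groups Tibble mapping `cell_line` to `group` in
#'   `{"sensitive", "insensitive"}`; each group needs at least two lines.
#' @return Tibble per gene: `delta`, `t_stat`, `df`, `p_value`, `p_adj`,
#'   `zero_var`.
#' @export
group_response_contrast <- function(responses, groups) {
  sens <- groups$cell_line[groups$group == "sensitive"]
  insens <- groups$cell_line[groups$group == "insensitive"]
  if (length(sens) < 2L || length(insens) < 2L) {
    abort("each group needs at least two cell lines")
  }
  wide <- responses |>
    dplyr::select("gene", "cell_line", "logfc") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "logfc")
  xs <- as.matrix(wide[, sens])
  xi <- as.matrix(wide[, insens])
  n1 <- ncol(xs)
  n2 <- ncol(xi)
  m1 <- rowMeans(xs)
  m2 <- rowMeans(xi)
  v1 <- rowSums((xs - m1)^2) / (n1 - 1)
  v2 <- rowSums((xi - m2)^2) / (n2 - 1)
  delta <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t_stat <- delta / sqrt(se2)
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  zero_var <- se2 == 0
  p[zero_var & delta == 0] <- 1
  p[zero_var & delta != 0] <- .Machine$double.xmin
  t_stat[zero_var & delta == 0] <- 0
  tibble::tibble(gene = wide$gene, delta = delta, t_stat = t_stat, df = df,
                 p_value = p, p_adj = bh_adjust(p), zero_var = zero_var)
}

#' Define a response target gene set by thresholds
#'
#' Membership is the conjunction of an inclusive fold-change threshold and a
#' strict p-value threshold: for `direction = "down"`, genes with
#' `delta <= -lfc_threshold` and `p_value < p_threshold`. The default
#' thresholds (0.68 log2 units, 1e-10) are the preset used for
#' inhibitor-target definition; 0.7 is the companion preset quoted for the
#' suppressed-transcript selection.
#'
#' @param contrast Group-contrast tibble from [group_response_contrast()]
#'   (columns `gene`, `delta`, `p_value`).
#' @param lfc_threshold Absolute log2 fold-change threshold (inclusive).
#' @param p_threshold P-value threshold (strict).
#' @param direction `"down"` or `"up"`.
#' @return An object of class `gene_set_definition` with fields `genes`,
#'   `direction`, `lfc_threshold`, `p_threshold`.
#' @export
define_target_set <- function(contrast, lfc_threshold = 0.68,
                              p_threshold = 1e-10,
                              direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(lfc_threshold > 0, p_threshold > 0)
  hit <- if (direction == "down") {
    contrast$delta <= -lfc_threshold
  } else {
    contrast$delta >= lfc_threshold
  }
  hit <- hit & contrast$p_value < p_threshold
  structure(list(genes = contrast$gene[hit & !is.na(hit)],
                 direction = direction,
                 lfc_threshold = lfc_threshold,
                 p_threshold = p_threshold),
            class = "gene_set_definition")
}

#' @export
print.gene_set_definition <- function(x, ...) {
  cat(sprintf("%d genes %sregulated (|log2FC| >= %g, p < %g)\n",
              length(x$genes), x$direction, x$lfc_threshold, x$p_threshold))
  invisible(x)
}

#' Baseline differential expression between sensitivity groups
#'
#' Compares untreated (vehicle) expression between sensitive and insensitive
#' cell lines, treating lines as replicates: per-gene NB GLM (`~ group`,
#' fixed dispersion) with TMM effective library offsets, likelihood-ratio
#' test, BH adjustment. Gene sets use an inclusive adjusted-p threshold and
#' an inclusive fold threshold ("at least `fold_threshold`-fold").
#'
#' @param expr Wide expression tibble (`gene` plus sample columns).
#' @param meta Sample metadata with `sample`, `cell_line`, `group`,
#'   `treatment`; only `treatment == "dmso"` samples are used.
#' @param padj_threshold Adjusted-p threshold, inclusive (default 1e-10).
#' @param fold_threshold Linear fold-change threshold, inclusive
#'   (default 4).
#' @param dispersion Fixed NB dispersion.
#' @return List with `table` (per-gene tibble: `logfc` of sensitive over
#'   insensitive, `p_value`, `p_adj`), and gene-id vectors `up` and `down`.
#' @export
baseline_group_de <- function(expr, meta, padj_threshold = 1e-10,
                              fold_threshold = 4, dispersion = 0.2) {
  meta <- meta[meta$treatment == "dmso", ]
  if (length(unique(meta$cell_line[meta$group == "sensitive"])) < 2L ||
      length(unique(meta$cell_line[meta$group == "insensitive"])) < 2L) {
    abort("each group needs at least two cell lines")
  }
  y <- counts_matrix(expr)
  samples <- intersect(meta$sample, colnames(y))
  meta <- meta[match(samples, meta$sample), ]
  y <- y[, samples, drop = FALSE]
  pool <- rowMeans(y)
  libs <- vapply(samples, function(s) sum(y[, s]) * tmm_pair_factor(y[, s], pool),
                 numeric(1))
  offs <- log(libs)
  grp <- as.integer(meta$group == "sensitive")
  design <- cbind("(Intercept)" = 1, groupsensitive = grp)
  null_design <- design[, 1, drop = FALSE]
  res <- purrr::map_dfr(seq_len(nrow(y)), function(i) {
    full <- nb_glm_fit(y[i, ], design, offs, dispersion)
    null <- nb_glm_fit(y[i, ], null_design, offs, dispersion)
    treatment_contrast_test(full, null)
  })
  tab <- tibble::tibble(gene = rownames(y), logfc = res$logfc,
                        p_value = res$p_value,
                        p_adj = bh_adjust(res$p_value))
  lfc_min <- log2(fold_threshold)
  keep <- !is.na(tab$p_adj) & tab$p_adj <= padj_threshold
  list(table = tab,
       up = tab$gene[keep & tab$logfc >= lfc_min],
       down = tab$gene[keep & tab$logfc <= -lfc_min])
}

#' Overlap of significantly downregulated genes across conditions
#'
#' Builds the per-condition downregulated sets (negative fold change with
#' inclusive adjusted-p threshold) and all Venn region cardinalities for
#' three conditions. Optionally the designated combination condition is
#' further restricted to genes reduced at least `extra_fold`-fold.
#'
#' @param results Named list of three per-condition tibbles with columns
#'   `gene`, `logfc`, `p_adj`, all over the same gene universe.
#' @param padj Adjusted-p threshold, inclusive (default 0.01).
#' @param extra_fold Optional linear fold filter applied to the combination
#'   condition (e.g. 1.5 keeps `logfc <= -log2(1.5)`).
#' @param combination Name of the condition receiving `extra_fold`
#'   (default `"combination"` when present, else the last condition).
#' @return List with `sets` (named list of gene-id vectors) and `regions`
#'   (tibble of the 7 exclusive Venn regions plus per-set totals).
#' @export
downregulated_overlap <- function(results, padj = 0.01, extra_fold = NULL,
                                  combination = NULL) {
  if (length(results) != 3L || is.null(names(results))) {
    abort("results must be a named list of three conditions")
  }
  universe <- results[[1]]$gene
  for (r in results) {
    if (!setequal(r$gene, universe)) abort("conditions must share a gene universe")
  }
  if (is.null(combination)) {
    combination <- if ("combination" %in% names(results)) "combination" else
      names(results)[3L]
  }
  sets <- purrr::imap(results, function(r, nm) {
    keep <- !is.na(r$p_adj) & r$p_adj <= padj & r$logfc < 0
    if (!is.null(extra_fold) && nm == combination) {
      keep <- keep & r$logfc <= -log2(extra_fold)
    }
    r$gene[keep]
  })
  nm <- names(sets)
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  code <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  codes <- apply(expand.grid(rep(list(0:1), 3))[, 3:1], 1,
                 paste, collapse = "")
  codes <- setdiff(codes, "000")
  codes <- unname(codes)
  regions <- tibble::tibble(
    region = codes,
    label = vapply(codes, function(cc) {
      paste(nm[strsplit(cc, "")[[1]] == "1"], collapse = "&")
    }, character(1), USE.NAMES = FALSE),
    n = vapply(codes, function(cc) sum(code == cc), integer(1),
               USE.NAMES = FALSE)
  )
  totals <- tibble::tibble(region = paste0("total_", nm),
                           label = nm,
                           n = unname(vapply(sets, length, integer(1))))
  list(sets = sets, regions = dplyr::bind_rows(regions, totals))
}

#' Counts per million
#'
#' @param counts Numeric matrix or wide tibble (`gene` plus sample columns).
#' @return Same shape with each column scaled to counts per million.
#' @export
compute_cpm <- function(counts) {
  tab <- inherits(counts, "data.frame")
  y <- if (tab) counts_matrix(counts) else as.matrix(counts)
  n <- colSums(y)
  if (any(n <= 0)) abort("zero library size")
  out <- sweep(y, 2, n, "/") * 1e6
  if (tab) {
    res <- counts
    res[, colnames(out)] <- as.data.frame(out)
    res
  } else out
}

#' Transcripts per million
#'
#' @param counts Numeric matrix or wide tibble (`gene` plus sample columns).
#' @param gene_length Gene lengths in bp, aligned with the rows.
#' @return Same shape; every column sums to 1e6.
#' @export
compute_tpm <- function(counts, gene_length) {
  tab <- inherits(counts, "data.frame")
  y <- if (tab) counts_matrix(counts) else as.matrix(counts)
  if (any(gene_length <= 0)) abort("gene lengths must be positive")
  r <- y / gene_length
  denom <- colSums(r)
  if (any(denom <= 0)) abort("zero library size")
  out <- sweep(r, 2, denom, "/") * 1e6
  if (tab) {
    res <- counts
    res[, colnames(out)] <- as.data.frame(out)
    res
  } else out
}

#' Principal-component scores of expression samples
#'
#' Centers each gene across samples and computes sample coordinates by
#' singular value decomposition of log-scale expression. Component signs
#' follow a deterministic convention: the largest-magnitude gene loading of
#' each component is positive.
#'
#' @param log_expr Genes-by-samples numeric matrix (e.g. `log2(cpm + 1)`).
#' @param n_components Number of components (default 2).
#' @param n_top Use only the `n_top` most variable genes (default 2000, or
#'   all genes if fewer).
#' @return Tibble with `sample`, `PC1..PCk`; the proportion of variance
#'   explained is in attribute `"var_explained"`.
#' @export
pca_scores <- function(log_expr, n_components = 2, n_top = 2000) {
  x <- as.matrix(log_expr)
  if (ncol(x) < 2L) abort("need at least two samples")
  v <- apply(x, 1, stats::var)
  keep <- sort(head(order(v, decreasing = TRUE), min(n_top, nrow(x))))
  xc <- x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])
  sv <- svd(t(xc))
  k <- min(n_components, length(sv$d))
  if (n_components > sum(sv$d > sv$d[1] * 1e-12)) {
    abort("n_components exceeds the rank of the centered matrix")
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rotation <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(rotation[which.max(abs(rotation[, j])), j])
    if (s < 0) {
      scores[, j] <- -scores[, j]
      rotation[, j] <- -rotation[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- tibble::tibble(sample = colnames(x) %||% as.character(seq_len(ncol(x))))
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  attr(out, "var_explained") <- sv$d^2 / sum(sv$d^2)
  attr(out, "rotation") <- rotation
  out
}
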