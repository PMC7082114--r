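#' Summarize guide counts to gene counts by the median
#'
#' The gene-level abundance of a sample is the median raw count of the
#' guides targeting the gene (arithmetic mean of the two central order
#' statistics for an even number of guides). Medians may be non-integer;
#' downstream NB likelihoods are evaluated with continuous gamma terms.
#'
#' @param counts Wide guide-level tibble with columns `sgrna`, `gene` and
#'   one column per sample.
#' @param library Optional guide library tibble (`sgrna`, `gene`); when
#'   supplied, every library gene must be present in `counts`.
#' @return Wide tibble with column `gene` and one median-summarized column
#'   per sample.
#' @export
median_summarize <- function(counts, library = NULL) {
  if (!is.null(library)) {
    missing <- setdiff(unique(library$gene), unique(counts$gene))
    if (length(missing)) {
      abort(sprintf("gene '%s' has no guides in the count matrix",
                    missing[1L]))
    }
  }
  samples <- setdiff(names(counts), c("sgrna", "gene"))
  counts |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), median),
                     .groups = "drop")
}

nb_deviance <- function(y, mu, dispersion) {
  mu <- pmax(mu, 1e-12)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / dispersion) * log((1 + dispersion * y) / (1 + dispersion * mu))
  2 * sum(t1 - t2)
}

#' Fit a negative-binomial log-linear model with fixed dispersion
#'
#' Maximizes the NB log-likelihood with a log link and fixed dispersion by
#' iteratively reweighted least squares with step halving, so the deviance
#' is non-increasing over iterations. Convergence is declared when the
#' relative deviance change falls below `tol` (default 1e-8), with at most
#' `max_iter` iterations. Responses may be non-integer (median-summarized
#' counts); an all-zero response is fitted on counts augmented by 0.5.
#'
#' @param y Non-negative response vector (one gene across samples).
#' @param design Full-rank design matrix (samples by coefficients).
#' @param offset Log effective library sizes (recycled).
#' @param dispersion Fixed NB dispersion, variance `mu + dispersion * mu^2`
#'   (default 0.2).
#' @param tol Relative deviance convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `nb_glm`: coefficients, fitted means,
#'   deviance, the per-iteration deviance trace and convergence flag.
#'   [tidy()] and [glance()] methods are provided.
#' @export
nb_glm_fit <- function(y, design, offset = 0, dispersion = 0.2,
                       tol = 1e-8, max_iter = 100) {
  x <- as.matrix(design)
  if (qr(x)$rank < ncol(x)) abort("design matrix is not full rank")
  if (dispersion <= 0) abort("dispersion must be positive")
  if (all(y == 0)) y <- y + 0.5
  offset <- rep_len(offset, length(y))
  # initialization: one WLS step from a crude positive mean
  mu <- pmax(y, mean(y) / 8, 1e-4)
  eta <- log(mu)
  beta <- stats::lm.wfit(x, (eta - offset) + (y - mu) / mu,
                         mu / (1 + dispersion * mu))$coefficients
  eta <- pmin(drop(x %*% beta) + offset, 700)
  mu <- pmax(exp(eta), 1e-12)
  dev <- nb_deviance(y, mu, dispersion)
  trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + dispersion * mu)
    z <- (eta - offset) + (y - mu) / mu
    beta_new <- stats::lm.wfit(x, z, w)$coefficients
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- pmin(drop(x %*% beta_try) + offset, 700)
      dev_try <- nb_deviance(y, exp(eta_try), dispersion)
      if (dev_try <= dev + 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta_try
    eta <- pmin(drop(x %*% beta) + offset, 700)
    mu <- pmax(exp(eta), 1e-12)
    dev_new <- nb_deviance(y, mu, dispersion)
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(x)),
    fitted = mu,
    deviance = dev,
    deviance_trace = trace,
    iterations = length(trace) - 1L,
    converged = converged,
    dispersion = dispersion,
    df_residual = length(y) - ncol(x)
  ), class = "nb_glm")
}

#' @export
print.nb_glm <- function(x, ...) {
  cat("NB log-linear fit (fixed dispersion ", x$dispersion, ")\n", sep = "")
  print(x$coefficients)
  cat("deviance:", format(x$deviance), "in", x$iterations, "iterations\n")
  invisible(x)
}

#' @rdname nb_glm_fit
#' @param x An `nb_glm` object.
#' @param ... Unused.
#' @method tidy nb_glm
#' @export
tidy.nb_glm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 estimate_log2 = unname(x$coefficients) / log(2))
}

#' @rdname nb_glm_fit
#' @method glance nb_glm
#' @export
glance.nb_glm <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, iterations = x$iterations,
                 converged = x$converged, df_residual = x$df_residual,
                 dispersion = x$dispersion)
}

#' Likelihood-ratio test for the treatment contrast
#'
#' Compares a full NB fit with a nested null fit lacking exactly the
#' treatment coefficient. The statistic is the deviance difference, referred
#' to a chi-square distribution with one degree of freedom; the reported
#' fold change is the treatment coefficient converted to log2. A deviance
#' difference below -1e-6 marks a failed fit and yields `p_value = NA`.
#'
#' @param fit Full-model `nb_glm` fit.
#' @param null_fit Nested `nb_glm` fit without the treatment coefficient.
#' @return One-row tibble: `logfc`, `lrt_stat`, `p_value`.
#' @export
treatment_contrast_test <- function(fit, null_fit) {
  extra <- setdiff(names(fit$coefficients), names(null_fit$coefficients))
  if (length(extra) != 1L) {
    abort("designs must be nested and differ by exactly one coefficient")
  }
  stat <- null_fit$deviance - fit$deviance
  if (stat < -1e-6) {
    return(tibble::tibble(logfc = fit$coefficients[[extra]] / log(2),
                          lrt_stat = NA_real_, p_value = NA_real_))
  }
  stat <- max(stat, 0)
  tibble::tibble(
    logfc = fit$coefficients[[extra]] / log(2),
    lrt_stat = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with running minimum, capped at
#' one. Missing values are excluded from the ranking and propagated.
#'
#' @param p Vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Sensitizer/rescuer contrast between treated and control screen arms
#'
#' Gene-level chemogenomic analysis of a screen run with and without an
#' inhibitor: guide counts are median-summarized per gene, effective library
#' sizes are recomputed by TMM against the pooled control (DMSO) samples,
#' and a blocked NB generalized log-linear model (`~ cell_line + treatment`,
#' fixed dispersion) is fitted per gene. The treatment effect is tested by a
#' likelihood-ratio test, adjusted by Benjamini-Hochberg; the reported fold
#' change is the mean of per-line prior-shrunken log2 fold changes (treated
#' versus control, replicates pooled within arm), matching a volcano plot
#' of mean fold change against joint significance.
#'
#' @param gene_counts Wide gene-level tibble (`gene` plus sample columns),
#'   e.g. from [median_summarize()].
#' @param meta Sample metadata with `sample`, `cell_line`, `arm` in
#'   `{"dmso", "treated"}` (plasmid samples are ignored).
#' @param lines Cell lines to include (default: all in `meta`).
#' @param dispersion Fixed NB dispersion for the gene-level model.
#' @param prior_count Prior count for the reported per-line fold changes.
#' @param lib_sizes Optional named effective library sizes overriding the
#'   TMM recomputation.
#' @return Tibble with one row per gene: `logfc` (mean across lines),
#'   per-line `logfc_<line>` columns, `lrt_stat`, `p_value`, `p_adj`.
#' @export
screen_contrast <- function(gene_counts, meta, lines = NULL,
                            dispersion = 0.2, prior_count = 12,
                            lib_sizes = NULL) {
  meta <- meta[meta$arm %in% c("dmso", "treated"), ]
  if (!is.null(lines)) meta <- meta[meta$cell_line %in% lines, ]
  samples <- intersect(meta$sample, names(gene_counts))
  if (!length(samples)) abort("no usable samples for the contrast")
  meta <- meta[match(samples, meta$sample), ]
  y <- as.matrix(gene_counts[, samples])
  rownames(y) <- gene_counts$gene

  if (is.null(lib_sizes)) {
    dmso_pool <- rowMeans(y[, meta$arm == "dmso", drop = FALSE])
    lib_sizes <- vapply(samples, function(s) {
      sum(y[, s]) * tmm_pair_factor(y[, s], dmso_pool)
    }, numeric(1))
  } else {
    lib_sizes <- lib_sizes[samples]
  }
  offsets <- log(lib_sizes)

  treatment <- factor(meta$arm, levels = c("dmso", "treated"))
  if (length(unique(meta$cell_line)) > 1L) {
    design <- stats::model.matrix(~ cell_line + treatment,
                                  data = data.frame(cell_line = meta$cell_line,
                                                    treatment = treatment))
  } else {
    design <- stats::model.matrix(~ treatment,
                                  data = data.frame(treatment = treatment))
  }
  null_design <- design[, colnames(design) != "treatmenttreated", drop = FALSE]

  tests <- purrr::map_dfr(seq_len(nrow(y)), function(i) {
    full <- nb_glm_fit(y[i, ], design, offsets, dispersion)
    null <- nb_glm_fit(y[i, ], null_design, offsets, dispersion)
    treatment_contrast_test(full, null)
  })

  per_line <- per_line_shrunken_logfc(y, meta, lib_sizes, prior_count)
  out <- tibble::tibble(
    gene = gene_counts$gene,
    logfc = rowMeans(per_line),
    lrt_stat = tests$lrt_stat,
    p_value = tests$p_value,
    p_adj = bh_adjust(tests$p_value)
  )
  for (ln in colnames(per_line)) out[[paste0("logfc_", ln)]] <- per_line[, ln]
  out
}

per_line_shrunken_logfc <- function(y, meta, lib_sizes, prior_count) {
  lines <- unique(meta$cell_line)
  out <- vapply(lines, function(ln) {
    tr <- meta$sample[meta$cell_line == ln & meta$arm == "treated"]
    ct <- meta$sample[meta$cell_line == ln & meta$arm == "dmso"]
    if (!length(tr) || !length(ct)) {
      abort(sprintf("cell line '%s' is missing an arm", ln))
    }
    ys <- rowSums(y[, tr, drop = FALSE])
    yr <- rowSums(y[, ct, drop = FALSE])
    l_s <- sum(lib_sizes[tr])
    l_r <- sum(lib_sizes[ct])
    shrunken_logfc_libs(ys, yr, l_s, l_r, prior_count)
  }, numeric(nrow(y)))
  colnames(out) <- lines
  out
}

shrunken_logfc_libs <- function(ys, yr, l_s, l_r, prior_count) {
  l_bar <- (l_s + l_r) / 2
  p_s <- prior_count * l_s / l_bar
  p_r <- prior_count * l_r / l_bar
  log2(((ys + p_s) / (l_s + 2 * p_s)) / ((yr + p_r) / (l_r + 2 * p_r)))
}

#' Volcano summary across cell lines from per-line results
#'
#' Averages per-line log2 fold changes over a subset of cell lines and
#' combines the per-line p-values by the signed Stouffer method. The joint
#' blocked GLM of [screen_contrast()] is the default analysis route; this
#' helper serves when only per-line results are available.
#'
#' @param results Long tibble with columns `gene`, `cell_line`, `logfc`,
#'   `p_value`.
#' @param cell_lines Cell lines to combine (default: all present).
#' @return Tibble per gene: `logfc` (mean), `p_value` (Stouffer combined),
#'   `p_adj`, `n_lines`. Genes missing in any selected line are dropped
#'   with a warning.
#' @export
volcano_table <- function(results, cell_lines = NULL) {
  if (is.null(cell_lines)) cell_lines <- unique(results$cell_line)
  res <- results[results$cell_line %in% cell_lines, ]
  counts <- table(res$gene)
  incomplete <- names(counts)[counts < length(cell_lines)]
  if (length(incomplete)) {
    warn(sprintf("%d genes missing in some selected lines were dropped",
                 length(incomplete)))
    res <- res[!res$gene %in% incomplete, ]
  }
  res |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      logfc = mean(.data$logfc),
      p_value = stouffer_p(.data$p_value, sign(.data$logfc)),
      n_lines = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_value))
}

stouffer_p <- function(p, s) {
  p <- pmin(pmax(p, 1e-300), 1)
  z <- stats::qnorm(p / 2, lower.tail = FALSE) * ifelse(s == 0, 1, s)
  zc <- sum(z) / sqrt(length(z))
  2 * stats::pnorm(abs(zc), lower.tail = FALSE)
}
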