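#' Pairwise TMM scale factor against a reference sample
#'
#' Computes the trimmed-mean-of-M-values scale factor of one count vector
#' relative to a paired reference (here, day-14 screen sample against the
#' initial plasmid pool). Only features with positive counts in both members
#' enter the estimate. M-values (log2 ratio of library-size-scaled counts)
#' are doubly trimmed: `trim_m` from each tail of M and `trim_a` from each
#' tail of A (average log abundance), and the remainder averaged with
#' inverse-asymptotic-variance (delta-method binomial) weights. The pair is
#' rescaled so that the sample's factor and the reference's implied factor
#' (its reciprocal) multiply to one.
#'
#' @param sample,reference Equal-length non-negative count vectors with
#'   positive totals.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return A single positive scale factor for `sample`; the paired
#'   reference's factor is its reciprocal. Multiply raw library sizes by
#'   these factors to obtain effective library sizes.
#' @export
tmm_pair_factor <- function(sample, reference, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(length(sample) == length(reference))
  sample <- as.numeric(sample)
  reference <- as.numeric(reference)
  n_s <- sum(sample)
  n_r <- sum(reference)
  if (n_s <= 0 || n_r <= 0) abort("both members need a positive total count")
  keep <- sample > 0 & reference > 0
  ys <- sample[keep]
  yr <- reference[keep]
  m <- log2((ys / n_s) / (yr / n_r))
  a <- 0.5 * log2((ys / n_s) * (yr / n_r))
  # delta-method asymptotic variance of M; weights are its inverse
  v <- (n_s - ys) / (n_s * ys) + (n_r - yr) / (n_r * yr)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  in_trim <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (sum(in_trim) < 10) {
    abort(sprintf(
      "only %d co-detected features remain after trimming (need >= 10); use smaller trim_m/trim_a",
      sum(in_trim)))
  }
  wm <- sum(m[in_trim] / v[in_trim]) / sum(1 / v[in_trim])
  # raw factors (2^wm, 1) rescaled so the pair multiplies to 1
  2^(wm / 2)
}

#' Prior-shrunken negative-binomial log2 fold change versus a paired reference
#'
#' The dropout statistic of the screen: log2 fold change of a day-14 sample
#' against the plasmid pool under the NB model with a fixed prior count.
#' Counts are augmented by the prior count scaled by each member's effective
#' library size relative to the pair mean, and the fold change taken on
#' augmented counts per augmented library. For a saturated two-sample fit
#' this equals the NB GLM maximum-likelihood estimate with prior counts, and
#' is independent of the dispersion.
#'
#' @inheritParams tmm_pair_factor
#' @param sample_factor TMM factor of `sample` versus `reference`; computed
#'   with [tmm_pair_factor()] when `NULL`.
#' @param prior_count Prior count shrinking low-count fold changes
#'   (default 12).
#' @return Numeric vector of finite log2 fold changes, one per feature.
#' @export
sgrna_dropout_logfc <- function(sample, reference, sample_factor = NULL,
                                prior_count = 12, trim_m = 0.30,
                                trim_a = 0.05) {
  stopifnot(length(sample) == length(reference))
  f <- sample_factor %||% tmm_pair_factor(sample, reference, trim_m, trim_a)
  l_s <- sum(sample) * f
  l_r <- sum(reference) / f
  if (l_s <= 0 || l_r <= 0) abort("zero effective library size")
  l_bar <- (l_s + l_r) / 2
  p_s <- prior_count * l_s / l_bar
  p_r <- prior_count * l_r / l_bar
  log2(((sample + p_s) / (l_s + 2 * p_s)) /
         ((reference + p_r) / (l_r + 2 * p_r)))
}

#' Quantile normalization with tie averaging
#'
#' Classic rank-based quantile normalization: the target distribution is the
#' across-column mean of column-sorted values, and each column's values are
#' replaced by the target value of their rank. Tied values within a column
#' receive the mean of the target quantiles their ranks occupy. A single
#' column is returned unchanged; a single row collapses every value to the
#' row mean.
#'
#' @param x Numeric matrix (features by samples) without missing values.
#' @return A matrix of the same shape whose columns share an identical
#'   sorted multiset of values.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) abort("quantile_normalize does not accept missing values")
  n <- nrow(x)
  target <- rowMeans(matrix(
    vapply(seq_len(ncol(x)), function(j) sort(x[, j]), numeric(n)),
    nrow = n))
  for (j in seq_len(ncol(x))) {
    v <- numeric(n)
    v[order(x[, j])] <- target
    x[, j] <- ave(v, x[, j], FUN = mean)
  }
  x
}

#' First quartile by linear interpolation
#'
#' Empirical quantile at probability 0.25 with linear interpolation on
#' `(n - 1)` spacing between order statistics (the convention of
#' `stats::quantile(type = 7)`).
#'
#' @param x Numeric vector with at least one value.
#' @return The first-quartile value; a singleton returns itself.
#' @export
quartile1 <- function(x) {
  quantile(x, probs = 0.25, type = 7, names = FALSE)
}

#' Summarize guide-level sensitivity scores to gene level by Q1
#'
#' The per-gene screen score of a cell line is the first quartile of the
#' normalized log2 fold changes of the guides targeting that gene, so a gene
#' scores strongly only when most of its guides drop out.
#'
#' @param scores Long tibble with columns `gene`, `sample` and a score
#'   column.
#' @param score_col Name of the score column (default `"score"`).
#' @return Tibble with columns `gene`, `sample`, `score` (the Q1 summary),
#'   one row per gene and sample.
#' @export
gene_q1 <- function(scores, score_col = "score") {
  scores |>
    dplyr::group_by(.data$gene, .data$sample) |>
    dplyr::summarise(score = quartile1(.data[[score_col]]), .groups = "drop")
}

#' Guide-level dropout sensitivity scores for a whole screen
#'
#' Runs the day-14 dropout scoring pipeline over every non-plasmid sample of
#' a screen count table: pairwise TMM normalization of each sample against
#' the plasmid pool, prior-shrunken NB log2 fold change per guide, then
#' quantile normalization across all scored samples jointly so the scores
#' are comparable between cell lines.
#'
#' @param counts Wide tibble from [read_count_table()] with columns `sgrna`,
#'   `gene` and one column per sample.
#' @param meta Sample metadata tibble with columns `sample`, `cell_line`,
#'   `arm` (exactly one `"plasmid"` sample).
#' @param samples Samples to score; default all non-plasmid samples.
#' @inheritParams sgrna_dropout_logfc
#' @param normalize Quantile-normalize the fold changes across samples
#'   (default `TRUE`).
#' @return Long tibble with columns `sgrna`, `gene`, `sample`, `cell_line`,
#'   `arm`, `logfc` (pre-normalization) and `score` (normalized).
#' @export
screen_sgrna_scores <- function(counts, meta, samples = NULL,
                                prior_count = 12, trim_m = 0.30,
                                trim_a = 0.05, normalize = TRUE) {
  check_plasmid_column(counts, meta)
  plasmid <- meta$sample[meta$arm == "plasmid"]
  plasmid <- intersect(plasmid, names(counts))
  if (is.null(samples)) {
    samples <- setdiff(intersect(meta$sample, names(counts)), plasmid)
  }
  ref <- counts[[plasmid]]
  lfc <- vapply(samples, function(s) {
    sgrna_dropout_logfc(counts[[s]], ref, prior_count = prior_count,
                        trim_m = trim_m, trim_a = trim_a)
  }, numeric(nrow(counts)))
  score <- if (normalize && length(samples) > 1L) quantile_normalize(lfc) else lfc
  out <- tibble::tibble(
    sgrna = rep(counts$sgrna, length(samples)),
    gene = rep(counts$gene, length(samples)),
    sample = rep(samples, each = nrow(counts)),
    logfc = as.vector(lfc),
    score = as.vector(score)
  )
  dplyr::left_join(out, meta[, intersect(c("sample", "cell_line", "arm"),
                                         names(meta))], by = "sample")
}

#' Gene-level screen score table
#'
#' Convenience wrapper chaining [screen_sgrna_scores()] and [gene_q1()]:
#' per-gene, per-sample Q1-summarized dropout sensitivity scores.
#'
#' @inheritParams screen_sgrna_scores
#' @param ... Passed to [screen_sgrna_scores()].
#' @return Tibble with columns `gene`, `sample`, `cell_line`, `arm`, `score`.
#' @export
screen_gene_scores <- function(counts, meta, ...) {
  sg <- screen_sgrna_scores(counts, meta, ...)
  gene_q1(sg) |>
    dplyr::left_join(meta[, intersect(c("sample", "cell_line", "arm"),
                                      names(meta))], by = "sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
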