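#' Total signal of a coverage track
#'
#' Integral of the step function: sum of interval length times value.
#'
#' @param cov Coverage tibble from [read_coverage()].
#' @param which `"experimental"`, `"spike"` or `"all"` contigs.
#' @return Total signal (base pairs times coverage value).
#' @export
coverage_signal <- function(cov, which = c("experimental", "spike", "all")) {
  which <- match.arg(which)
  keep <- switch(which, experimental = !cov$spike, spike = cov$spike,
                 all = rep(TRUE, nrow(cov)))
  sum((cov$end[keep] - cov$start[keep]) * cov$value[keep])
}

#' Spike-in normalization factor
#'
#' ChIP with exogenous reference chromatin: the per-sample scale factor is
#' the reference spike signal divided by the sample's spike signal, so that
#' multiplying all of a sample's signal (experimental and spike) by any
#' constant leaves the normalized experimental signal unchanged. Global
#' shifts of the histone mark are thereby preserved instead of being
#' normalized away.
#'
#' @param cov Coverage tibble with a `spike` column ([read_coverage()]).
#' @param reference_spike_signal Spike signal of the designated reference
#'   sample (or a fixed target).
#' @return A one-row tibble: `sample_spike_signal`,
#'   `reference_spike_signal`, `scale_factor`.
#' @export
spike_scale_factor <- function(cov, reference_spike_signal) {
  s <- coverage_signal(cov, "spike")
  if (s <= 0) abort("track has no positive spike-in signal")
  tibble::tibble(sample_spike_signal = s,
                 reference_spike_signal = reference_spike_signal,
                 scale_factor = reference_spike_signal / s)
}

step_integrator <- function(start, end, value) {
  ci <- c(0, cumsum((end - start) * value))
  function(x) {
    i <- findInterval(x, start)
    res <- numeric(length(x))
    pos <- i > 0
    ii <- i[pos]
    res[pos] <- ci[ii] + value[ii] * pmax(pmin(x[pos], end[ii]) - start[ii], 0)
    res
  }
}

#' Strand-aware TSS window signal matrix
#'
#' For each gene, the mean per-base spike-scaled signal in consecutive bins
#' of a window centered on the transcription start site. Rows of
#' minus-strand genes are reversed so that upstream is always on the left.
#' Windows extending past the start of the contig or past the last covered
#' position are dropped with a warning.
#'
#' @param cov Coverage tibble ([read_coverage()]); spike contigs are
#'   ignored for profiling.
#' @param annotation Gene annotation tibble ([read_gene_annotation()]).
#' @param gene_ids Genes to profile (default: all annotated genes on
#'   contigs present in the track).
#' @param window Half-width of the TSS window in bp (default 5000).
#' @param bin Bin width in bp (default 50); `2 * window / bin` bins.
#' @param scale_factor Spike-in scale factor applied to the signal.
#' @return Numeric matrix, genes by bins, in gene orientation.
#' @export
tss_signal_matrix <- function(cov, annotation, gene_ids = NULL,
                              window = 5000, bin = 50, scale_factor = 1) {
  if ((2 * window) %% bin != 0) abort("2 * window must be a multiple of bin")
  n_bins <- 2 * window %/% bin
  cov <- cov[!cov$spike, , drop = FALSE]
  if (is.null(gene_ids)) gene_ids <- annotation$gene
  unknown <- setdiff(gene_ids, annotation$gene)
  if (length(unknown)) abort(sprintf("unknown gene id '%s'", unknown[1L]))
  anno <- annotation[match(gene_ids, annotation$gene), ]
  extents <- cov |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(extent = max(.data$end), .groups = "drop")
  anno <- dplyr::left_join(anno, extents, by = "contig")
  if (anyNA(anno$extent)) {
    abort(sprintf("gene '%s' lies on a contig absent from the track",
                  anno$gene[which(is.na(anno$extent))[1L]]))
  }
  clipped <- anno$tss - window < 0 | anno$tss + window > anno$extent
  if (any(clipped)) {
    warn(sprintf("%d gene windows clipped at contig ends were dropped",
                 sum(clipped)))
    anno <- anno[!clipped, ]
  }
  mat <- matrix(0, nrow(anno), n_bins,
                dimnames = list(anno$gene, NULL))
  for (ctg in unique(anno$contig)) {
    d <- cov[cov$contig == ctg, ]
    fint <- step_integrator(d$start, d$end, d$value)
    rows <- which(anno$contig == ctg)
    for (i in rows) {
      edges <- anno$tss[i] - window + bin * (0:n_bins)
      prof <- diff(fint(edges)) / bin
      if (anno$strand[i] == "-") prof <- rev(prof)
      mat[i, ] <- prof
    }
  }
  mat * scale_factor
}

#' Average metagene profile over a gene set
#'
#' Column-wise mean and standard error of a TSS window matrix over a set of
#' genes.
#'
#' @param mat TSS window matrix from [tss_signal_matrix()].
#' @param gene_set Genes to average (default: all rows); must be rows of
#'   `mat`.
#' @param window,bin Window half-width and bin size used to build `mat`
#'   (for the position axis).
#' @return Tibble of class `metagene_profile`: `bin`, `position` (bp of bin
#'   center relative to the TSS, upstream negative), `mean`, `se`, `n`.
#' @export
metagene_average <- function(mat, gene_set = NULL, window = 5000, bin = 50) {
  if (is.null(gene_set)) gene_set <- rownames(mat)
  if (!length(gene_set)) abort("empty gene set")
  missing <- setdiff(gene_set, rownames(mat))
  if (length(missing)) abort(sprintf("gene '%s' not in matrix", missing[1L]))
  m <- mat[gene_set, , drop = FALSE]
  n <- nrow(m)
  mu <- colMeans(m)
  se <- if (n > 1) apply(m, 2, sd) / sqrt(n) else rep(0, ncol(m))
  pos <- -window + (seq_len(ncol(m)) - 0.5) * bin
  out <- tibble::tibble(
    bin = seq_len(ncol(m)),
    position = pos,
    mean = unname(mu), se = unname(se), n = n
  )
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Group genes into expression bins
#'
#' Quantile-based grouping on `log2(cpm + 1)` into `n_groups` bins of sizes
#' differing by at most one, lowest expression first. Ties are broken by
#' stable gene-id order so the split is deterministic.
#'
#' @param expression Tibble with columns `gene` and `cpm` (or a named
#'   numeric vector of cpm values).
#' @param n_groups Number of bins (>= 2).
#' @return Tibble `gene`, `cpm`, `bin` (integer, 1 = lowest expression).
#' @export
expression_bins <- function(expression, n_groups) {
  if (n_groups < 2L) abort("n_groups must be at least 2")
  if (!inherits(expression, "data.frame")) {
    expression <- tibble::tibble(gene = names(expression),
                                 cpm = as.numeric(expression))
  }
  n <- nrow(expression)
  if (n < n_groups) abort("fewer genes than groups")
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(log2(expression$cpm + 1), expression$gene)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_groups), times = sizes)
  dplyr::mutate(expression, bin = bin)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Expression-matched control gene set
#'
#' Samples a control set from a universe of non-target genes so that its
#' basal expression distribution matches the target set's: the pooled
#' (target plus universe) expression is cut into quantile bins, and within
#' each bin as many universe genes as there are targets are drawn without
#' replacement using the seeded generator. Bins whose universe is too
#' shallow contribute all their genes and flag the match as partial.
#'
#' @param targets Character vector of target gene ids.
#' @param universe Candidate control gene ids (targets are excluded).
#' @param expression Named numeric vector of basal expression (cpm)
#'   covering targets and universe.
#' @param n_bins Number of quantile bins for matching (default 20).
#' @param seed Integer seed; required for reproducibility.
#' @return List of class `matched_controls`: `target_set`, `control_set`,
#'   `n_bins`, `seed`, `complete` (FALSE when some bin was exhausted).
#' @export
matched_control_set <- function(targets, universe, expression, n_bins = 20,
                                seed) {
  universe <- setdiff(universe, targets)
  if (!length(universe)) abort("empty control universe after excluding targets")
  all_genes <- c(targets, universe)
  missing <- setdiff(all_genes, names(expression))
  if (length(missing)) abort(sprintf("no expression for gene '%s'", missing[1L]))
  x <- log2(expression[all_genes] + 1)
  # quantile bins on the pooled distribution via ranks, so tied values can
  # never straddle a bin boundary
  bin <- cut(rank(x, ties.method = "min"), breaks = n_bins, labels = FALSE)
  names(bin) <- all_genes
  complete <- TRUE
  picks <- with_seed(seed, {
    unlist(lapply(sort(unique(bin[targets])), function(b) {
      need <- sum(bin[targets] == b)
      pool <- universe[bin[universe] == b]
      if (length(pool) < need) {
        complete <<- FALSE
        warn(sprintf("expression bin %d has only %d controls for %d targets",
                     b, length(pool), need))
        pool
      } else {
        sample(pool, need)
      }
    }), use.names = FALSE)
  })
  structure(list(target_set = targets, control_set = picks,
                 n_bins = n_bins, seed = seed, complete = complete),
            class = "matched_controls")
}

#' @export
print.matched_controls <- function(x, ...) {
  cat(sprintf("%d targets matched by %d controls over %d expression bins%s\n",
              length(x$target_set), length(x$control_set), x$n_bins,
              if (x$complete) "" else " (partial)"))
  invisible(x)
}
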