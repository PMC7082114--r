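#' Configuration for the synthetic CRISPR screen
#'
#' Defaults mirror the screen design the package analyses: 10 guides per
#' gene, four cell lines screened with and without the inhibitor (two
#' replicate infections per arm), NB counts with common dispersion 0.2
#' around a log-normal plasmid pool, 5% of genes essential (dropout effect
#' -2 log2), 2% sensitizers (treated-arm-only extra effect -1.5 log2) and
#' 1% rescuers (+1.5 log2, treated arm only). Guide-efficacy variation is a
#' per-guide N(0, 0.3) log2 jitter; per-sample sequencing depth varies
#' log-normally.
#'
#' @param n_genes Number of genes (default 1000).
#' @param sgrnas_per_gene Guides per gene (default 10).
#' @param n_lines Number of cell lines (default 4).
#' @param replicates_per_arm Replicate samples per arm and line (default 2).
#' @param plasmid_meanlog,plasmid_sdlog Log-normal expected plasmid counts
#'   (defaults `6 * log(2)` and `log(2)`: median 64).
#' @param dispersion NB dispersion of simulated counts (default 0.2).
#' @param essential_fraction,essential_effect Fraction and log2 dropout
#'   effect of essential genes (defaults 0.05, -2).
#' @param sensitizer_fraction,sensitizer_effect Fraction and treated-only
#'   log2 effect of sensitizers (defaults 0.02, -1.5).
#' @param rescuer_fraction,rescuer_effect Fraction and treated-only log2
#'   effect of rescuers (defaults 0.01, +1.5).
#' @param sgrna_sd Per-guide log2 jitter SD (default 0.3).
#' @param depth_sdlog Per-sample depth log-normal SD (default 0.15).
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 1000, sgrnas_per_gene = 10,
                              n_lines = 4, replicates_per_arm = 2,
                              plasmid_meanlog = 6 * log(2),
                              plasmid_sdlog = log(2), dispersion = 0.2,
                              essential_fraction = 0.05,
                              essential_effect = -2,
                              sensitizer_fraction = 0.02,
                              sensitizer_effect = -1.5,
                              rescuer_fraction = 0.01,
                              rescuer_effect = 1.5,
                              sgrna_sd = 0.3, depth_sdlog = 0.15) {
  cfg <- as.list(environment())
  if (essential_fraction + sensitizer_fraction + rescuer_fraction >= 1) {
    abort("planted fractions must sum to less than 1")
  }
  structure(cfg, class = "screen_sim_config")
}

#' Simulate a pooled CRISPR screen with planted ground truth
#'
#' Draws NB guide counts for a plasmid pool plus day-14 samples of
#' `n_lines` cell lines, each with a DMSO and a treated arm. The expected
#' count of a guide in a day-14 sample is its plasmid abundance times
#' `2^(gene effect + guide jitter)` times the arm effect and the sample's
#' depth factor. Essential genes drop out in both arms; sensitizers and
#' rescuers act in the treated arm only. Identical `(config, seed)` give
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config A [screen_sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (tibble `sgrna`, `gene`, plasmid and sample
#'   columns), `meta` (sample metadata) and `truth` (planted gene sets and
#'   per-gene true log2 effects).
#' @export
simulate_screen <- function(config = screen_sim_config(), seed = 1) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(seed, {
    c_ <- config
    genes <- sprintf("g%04d", seq_len(c_$n_genes))
    n_e <- round(c_$essential_fraction * c_$n_genes)
    n_s <- round(c_$sensitizer_fraction * c_$n_genes)
    n_r <- round(c_$rescuer_fraction * c_$n_genes)
    special <- sample(genes, n_e + n_s + n_r)
    essential <- special[seq_len(n_e)]
    sensitizer <- special[n_e + seq_len(n_s)]
    rescuer <- special[n_e + n_s + seq_len(n_r)]

    base_effect <- setNames(numeric(c_$n_genes), genes)
    base_effect[essential] <- c_$essential_effect
    treat_effect <- setNames(numeric(c_$n_genes), genes)
    treat_effect[sensitizer] <- c_$sensitizer_effect
    treat_effect[rescuer] <- c_$rescuer_effect

    n_sg <- c_$n_genes * c_$sgrnas_per_gene
    sg_gene <- rep(genes, each = c_$sgrnas_per_gene)
    sgrna <- paste0(sg_gene, "_sg", rep(seq_len(c_$sgrnas_per_gene),
                                        times = c_$n_genes))
    abundance <- rlnorm(n_sg, c_$plasmid_meanlog, c_$plasmid_sdlog)
    jitter <- rnorm(n_sg, 0, c_$sgrna_sd)

    lines <- sprintf("L%d", seq_len(c_$n_lines))
    meta <- tidyr::expand_grid(cell_line = lines,
                               arm = c("dmso", "treated"),
                               replicate = seq_len(c_$replicates_per_arm))
    meta$sample <- sprintf("%s_%s_%d", meta$cell_line, meta$arm,
                           meta$replicate)
    meta$day <- 14L

    size <- 1 / c_$dispersion
    counts <- tibble::tibble(sgrna = sgrna, gene = sg_gene)
    counts$plasmid <- as.integer(rnbinom(n_sg, size = size,
                              mu = abundance * rlnorm(1, 0, c_$depth_sdlog)))
    for (i in seq_len(nrow(meta))) {
      eff <- base_effect[sg_gene] +
        if (meta$arm[i] == "treated") treat_effect[sg_gene] else 0
      depth <- rlnorm(1, 0, c_$depth_sdlog)
      mu <- abundance * 2^(eff + jitter) * depth
      counts[[meta$sample[i]]] <- as.integer(rnbinom(n_sg, size = size, mu = mu))
    }
    meta <- dplyr::bind_rows(
      tibble::tibble(cell_line = NA_character_, arm = "plasmid",
                     replicate = 1L, sample = "plasmid", day = 0L),
      meta)

    truth <- list(
      essential = essential, sensitizer = sensitizer, rescuer = rescuer,
      effects = tibble::tibble(gene = genes,
                               dropout_logfc = unname(base_effect),
                               treatment_logfc = unname(treat_effect)),
      config = c_)
    list(counts = counts, meta = meta[, c("sample", "cell_line", "arm",
                                          "replicate", "day")],
         truth = truth)
  })
}

#' Configuration for the synthetic expression panel
#'
#' Defaults emulate a 12-line panel (6 sensitive, 6 insensitive) profiled
#' untreated and after inhibitor treatment, one sample per line and
#' condition: 5000 genes with log-normal basal means, NB dispersion 0.1, a
#' 20-gene responsive module suppressed by 1 log2 unit in treated sensitive
#' lines only, and 2% of genes with an 8-fold baseline shift between the
#' groups (half up, half down in sensitive lines, present in both arms).
#'
#' The dispersion represents biological variation *between* cell lines: a
#' gamma factor with variance `dispersion` is drawn per gene and line and
#' shared by that line's two arms, and per-sample counts are Poisson around
#' it, so counts are marginally NB while the within-line treatment ratio is
#' measured at sequencing precision - the situation of a real unreplicated
#' cell-line panel. Module and baseline-shift genes are drawn from genes
#' with basal mean at least `special_min_mean`, reflecting that the
#' ER-stress/translation genes this emulates are abundant transcripts.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_sensitive,n_insensitive Cell lines per group (defaults 6, 6).
#' @param module_size Responsive module size (default 20).
#' @param module_effect Log2 suppression of module genes in treated
#'   sensitive cells (default -1).
#' @param baseline_de_fraction Fraction of genes with a baseline group
#'   shift (default 0.02).
#' @param baseline_de_effect Log2 magnitude of the baseline shift
#'   (default 3, i.e. 8-fold).
#' @param dispersion NB dispersion (default 0.1).
#' @param base_meanlog,base_sdlog Log-normal basal gene means (defaults
#'   `5 * log(2)`, `1.5 * log(2)`).
#' @param depth_sdlog Per-sample depth log-normal SD (default 0.2).
#' @param special_min_mean Minimum basal mean for module and baseline-shift
#'   genes (default 128).
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 5000, n_sensitive = 6,
                                  n_insensitive = 6, module_size = 20,
                                  module_effect = -1,
                                  baseline_de_fraction = 0.02,
                                  baseline_de_effect = 3,
                                  dispersion = 0.1,
                                  base_meanlog = 5 * log(2),
                                  base_sdlog = 1.5 * log(2),
                                  depth_sdlog = 0.2,
                                  special_min_mean = 128) {
  cfg <- as.list(environment())
  if (module_size >= n_genes) abort("module larger than gene universe")
  structure(cfg, class = "expression_sim_config")
}

#' Simulate the sensitive/insensitive expression panel
#'
#' NB counts per gene for each line and treatment. Module genes are
#' suppressed by `module_effect` only in treated sensitive samples;
#' baseline-shift genes differ between groups in both arms. The module and
#' the baseline-shift set are disjoint.
#'
#' @param config An [expression_sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (tibble `gene` plus one column per sample),
#'   `meta` (`sample`, `cell_line`, `group`, `treatment`, `replicate`) and
#'   `truth` (`module`, `baseline_up`, `baseline_down`, per-gene true
#'   group-difference `delta`).
#' @export
simulate_expression_panel <- function(config = expression_sim_config(),
                                      seed = 1) {
  stopifnot(inherits(config, "expression_sim_config"))
  with_seed(seed, {
    c_ <- config
    genes <- sprintf("e%05d", seq_len(c_$n_genes))
    base <- setNames(rlnorm(c_$n_genes, c_$base_meanlog, c_$base_sdlog),
                     genes)
    n_de <- round(c_$baseline_de_fraction * c_$n_genes)
    abundant <- genes[base >= c_$special_min_mean]
    if (length(abundant) < c_$module_size + n_de) {
      abort("too few abundant genes to plant module and baseline shifts")
    }
    special <- sample(abundant, c_$module_size + n_de)
    module <- special[seq_len(c_$module_size)]
    de <- special[c_$module_size + seq_len(n_de)]
    up <- de[seq_len(n_de %/% 2)]
    down <- setdiff(de, up)

    lines <- c(sprintf("S%d", seq_len(c_$n_sensitive)),
               sprintf("I%d", seq_len(c_$n_insensitive)))
    group <- rep(c("sensitive", "insensitive"),
                 c(c_$n_sensitive, c_$n_insensitive))
    meta <- tidyr::expand_grid(
      line_ix = seq_along(lines), treatment = c("dmso", "treated"))
    meta <- tibble::tibble(
      sample = sprintf("%s_%s", lines[meta$line_ix], meta$treatment),
      cell_line = lines[meta$line_ix],
      group = group[meta$line_ix],
      treatment = meta$treatment,
      replicate = 1L)

    shift <- setNames(numeric(c_$n_genes), genes)
    shift[up] <- c_$baseline_de_effect
    shift[down] <- -c_$baseline_de_effect

    # gamma line factor (mean 1, variance = dispersion) shared by both arms
    line_factor <- matrix(
      rgamma(c_$n_genes * length(lines), shape = 1 / c_$dispersion,
             scale = c_$dispersion),
      nrow = c_$n_genes, dimnames = list(genes, lines))
    counts <- tibble::tibble(gene = genes)
    for (i in seq_len(nrow(meta))) {
      eff <- numeric(c_$n_genes)
      if (meta$group[i] == "sensitive") {
        eff <- eff + shift
        if (meta$treatment[i] == "treated") {
          eff[genes %in% module] <- eff[genes %in% module] + c_$module_effect
        }
      }
      depth <- rlnorm(1, 0, c_$depth_sdlog)
      mu <- base * line_factor[, meta$cell_line[i]] * 2^eff * depth
      counts[[meta$sample[i]]] <- as.integer(rpois(c_$n_genes, lambda = mu))
    }
    delta <- setNames(numeric(c_$n_genes), genes)
    delta[module] <- c_$module_effect
    truth <- list(module = module, baseline_up = up, baseline_down = down,
                  delta = tibble::tibble(gene = genes,
                                         delta = unname(delta)),
                  config = c_)
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Configuration for synthetic TSS coverage tracks
#'
#' One experimental contig per `genes_per_contig` genes plus one spike-in
#' contig. Each gene carries a triangular signal peak at its TSS decaying
#' to zero over `half_width` bp, with amplitude proportional to
#' `log2(cpm + 1)`; the spike contig carries `spike_fraction` of the
#' track's total expected signal (default 5%, matching the exogenous
#' chromatin fraction added at ChIP), scaled with the per-sample depth.
#'
#' @param genes_per_contig Genes laid out per contig (default 50).
#' @param tss_spacing Distance between neighbouring TSSs in bp
#'   (default 20000).
#' @param margin Distance of the first TSS from the contig start, and the
#'   tail kept after the last TSS (default 10000).
#' @param half_width Half-width of the triangular peak in bp
#'   (default 2000).
#' @param step Step size of the emitted bedGraph intervals (default 50).
#' @param spike_fraction Fraction of total signal on the spike contig
#'   (default 0.05).
#' @param spike_contig Name of the spike contig (default `"spike_chr"`).
#' @param depth Per-sample depth multiplier (default 1).
#' @param treatment_effect Multiplier on all experimental signal, e.g. a
#'   global mark loss under treatment (default 1).
#' @param noise_sdlog Log-normal multiplicative noise per interval
#'   (default 0.05).
#' @return A `coverage_sim_config` list.
#' @export
coverage_sim_config <- function(genes_per_contig = 50, tss_spacing = 20000,
                                margin = 10000, half_width = 2000,
                                step = 50, spike_fraction = 0.05,
                                spike_contig = "spike_chr", depth = 1,
                                treatment_effect = 1, noise_sdlog = 0.05) {
  if (spike_fraction <= 0 || spike_fraction >= 1) {
    abort("spike_fraction must be in (0, 1)")
  }
  structure(as.list(environment()), class = "coverage_sim_config")
}

#' Simulate a spike-in ChIP coverage track with matching annotation
#'
#' @param config A [coverage_sim_config()].
#' @param expression Tibble with columns `gene` and `cpm` (or a named cpm
#'   vector); one simulated gene per entry.
#' @param seed Integer seed.
#' @return List with `coverage` (tibble `contig`, `start`, `end`, `value`,
#'   `spike`), `annotation` ([read_gene_annotation()] layout) and `truth`
#'   (per-gene peak amplitude and the spike fraction).
#' @export
simulate_coverage <- function(config = coverage_sim_config(), expression,
                              seed = 1) {
  stopifnot(inherits(config, "coverage_sim_config"))
  if (!inherits(expression, "data.frame")) {
    expression <- tibble::tibble(gene = names(expression),
                                 cpm = as.numeric(expression))
  }
  if (!nrow(expression) || all(expression$cpm == 0)) {
    abort("expression must be non-empty with some positive cpm")
  }
  with_seed(seed, {
    c_ <- config
    n <- nrow(expression)
    contig_ix <- (seq_len(n) - 1L) %/% c_$genes_per_contig
    pos_ix <- (seq_len(n) - 1L) %% c_$genes_per_contig
    anno <- tibble::tibble(
      gene = expression$gene,
      contig = sprintf("chrS%d", contig_ix + 1L),
      tss = as.integer(c_$margin + pos_ix * c_$tss_spacing),
      strand = rep_len(c("+", "-"), n),
      gene_length = as.integer(round(runif(n, 1000, 10000)))
    )
    anno$start <- ifelse(anno$strand == "+", anno$tss,
                         anno$tss + 1L - anno$gene_length)
    anno$start <- pmax(anno$start, 0L)
    anno$end <- ifelse(anno$strand == "+", anno$tss + anno$gene_length,
                       anno$tss + 1L)
    anno <- anno[, c("gene", "contig", "start", "end", "tss", "strand",
                     "gene_length")]

    amp <- log2(expression$cpm + 1) * c_$depth * c_$treatment_effect
    offs <- seq(-c_$half_width, c_$half_width - c_$step, by = c_$step)
    mids <- offs + c_$step / 2
    shape <- pmax(0, 1 - abs(mids) / c_$half_width)

    cov <- purrr::map_dfr(seq_len(n), function(i) {
      v <- amp[i] * shape * rlnorm(length(shape), 0, c_$noise_sdlog)
      tibble::tibble(contig = anno$contig[i],
                     start = as.integer(anno$tss[i] + offs),
                     end = as.integer(anno$tss[i] + offs + c_$step),
                     value = v)
    })
    # zero tails pin each contig's extent so TSS windows are not clipped
    tails <- cov |>
      dplyr::group_by(.data$contig) |>
      dplyr::summarise(start = max(.data$end), .groups = "drop") |>
      dplyr::mutate(end = .data$start + c_$margin, value = 0)
    cov <- dplyr::bind_rows(cov, tails) |>
      dplyr::arrange(.data$contig, .data$start)
    cov$spike <- FALSE

    total <- sum((cov$end - cov$start) * cov$value)
    spike_total <- c_$spike_fraction / (1 - c_$spike_fraction) * total
    spike <- tibble::tibble(contig = c_$spike_contig, start = 0L,
                            end = 10000L, value = spike_total / 10000,
                            spike = TRUE)
    cov <- dplyr::bind_rows(cov, spike)
    truth <- list(amplitude = tibble::tibble(gene = anno$gene,
                                             amplitude = amp),
                  spike_fraction = c_$spike_fraction, config = c_)
    list(coverage = cov, annotation = anno, truth = truth)
  })
}
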