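#' Read a feature-by-sample count table
#'
#' Reads a tab-separated count table with a header line. The first column is
#' the feature identifier; for `kind = "sgrna"` the second column must be the
#' gene identifier that each guide targets. Remaining columns are sample
#' counts and must be non-negative integers. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to a TSV file.
#' @param kind `"sgrna"` for a guide-level screen table (sgrna, gene, sample
#'   columns) or `"gene"` for a gene-level expression table (gene, sample
#'   columns).
#' @param meta Optional sample metadata tibble (see [read_sample_meta()]).
#'   When supplied with `kind = "sgrna"` the table must contain exactly one
#'   sample whose `arm` is `"plasmid"`.
#' @return A tibble with the identifier column(s) followed by one integer
#'   column per sample, rows and columns in file order.
#' @export
read_count_table <- function(path, kind = c("sgrna", "gene"), meta = NULL) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  id_cols <- if (kind == "sgrna") 2L else 1L
  if (ncol(tab) <= id_cols) {
    abort(sprintf("'%s' has no sample columns", path))
  }
  names(tab)[1L] <- if (kind == "sgrna") "sgrna" else "gene"
  if (kind == "sgrna") names(tab)[2L] <- "gene"
  validate_count_table(tab, n_id_cols = id_cols, file = path)
  for (j in seq.int(id_cols + 1L, ncol(tab))) {
    if (max(tab[[j]]) < .Machine$integer.max) {
      tab[[j]] <- as.integer(tab[[j]])
    }
  }
  if (kind == "sgrna" && !is.null(meta)) {
    check_plasmid_column(tab, meta)
  }
  tab
}

#' Read the sample metadata sidecar
#'
#' A TSV keyed by sample column name: a `sample` column matching the count
#' table's sample columns, plus experiment descriptors such as `cell_line`,
#' `arm` (`plasmid`, `dmso`, `treated`), `day`, `group` (`sensitive`,
#' `insensitive`), `treatment` or `replicate`. Metadata is explicit rather
#' than being parsed out of column names.
#'
#' @param path Path to a TSV file with a `sample` column.
#' @return A tibble of per-sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (!"sample" %in% names(meta)) abort("metadata must have a 'sample' column")
  if (anyDuplicated(meta$sample)) abort("duplicate sample names in metadata")
  meta
}

validate_count_table <- function(tab, n_id_cols, file = "count table") {
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    abort(sprintf("duplicate feature id '%s' in %s", dup, file))
  }
  for (j in seq.int(n_id_cols + 1L, ncol(tab))) {
    x <- tab[[j]]
    if (!is.numeric(x)) {
      abort(sprintf("column '%s' of %s is not numeric", names(tab)[j], file))
    }
    bad <- which(is.na(x) | x < 0 | x != floor(x))
    if (length(bad)) {
      abort(sprintf(
        "invalid count %s at row '%s', column '%s' of %s: counts must be non-negative integers",
        format(x[bad[1L]]), ids[bad[1L]], names(tab)[j], file))
    }
  }
  invisible(tab)
}

check_plasmid_column <- function(tab, meta) {
  samples <- setdiff(names(tab), c("sgrna", "gene"))
  plasmid <- meta$sample[meta$arm == "plasmid"]
  n <- sum(plasmid %in% samples)
  if (n != 1L) {
    abort(sprintf("expected exactly one plasmid sample column, found %d", n))
  }
  invisible(tab)
}

#' Write a count table to TSV
#'
#' @param tab A count tibble as returned by [read_count_table()].
#' @param path Output path.
#' @export
write_count_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read gene annotation from BED6+1
#'
#' Expects BED with at least seven columns: chrom, start, end, name, score,
#' strand and gene length in bp. Coordinates are 0-based, half-open. The
#' transcription start site is `start` for `+`-strand genes and `end - 1`
#' for `-`-strand genes.
#'
#' @param path Path to a BED6+1 file (no header; `#` comments allowed).
#' @return A tibble with columns `gene`, `contig`, `start`, `end`, `tss`,
#'   `strand`, `gene_length`.
#' @export
read_gene_annotation <- function(path) {
  bed <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(bed) < 7L) abort("annotation must be BED6+1 (7 columns)")
  bed <- bed[, 1:7]
  names(bed) <- c("contig", "start", "end", "gene", "score", "strand",
                  "gene_length")
  if (anyDuplicated(bed$gene)) abort("duplicate gene id in annotation")
  if (!all(bed$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (any(bed$start >= bed$end)) abort("BED interval with start >= end")
  if (any(bed$start < 0)) abort("negative BED start")
  if (any(bed$gene_length <= 0)) abort("gene_length must be positive")
  tibble::tibble(
    gene = bed$gene,
    contig = bed$contig,
    start = as.integer(bed$start),
    end = as.integer(bed$end),
    tss = as.integer(ifelse(bed$strand == "+", bed$start, bed$end - 1L)),
    strand = bed$strand,
    gene_length = as.integer(bed$gene_length)
  )
}

#' Write gene annotation to BED6+1
#'
#' @param anno Annotation tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(anno, path) {
  bed <- tibble::tibble(anno$contig, anno$start, anno$end, anno$gene,
                        0L, anno$strand, anno$gene_length)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a coverage track from bedGraph
#'
#' Intervals are 0-based half-open with a non-negative signal value. Within
#' each contig intervals must be non-overlapping; they are returned sorted.
#' Contigs whose name starts with `spike_prefix` are flagged as exogenous
#' spike-in reference chromatin.
#'
#' @param path Path to a bedGraph file (`track` and `#` lines are skipped).
#' @param spike_prefix Contig-name prefix identifying spike-in contigs
#'   (e.g. `"dm6_"` for Drosophila reference chromatin).
#' @return A tibble with columns `contig`, `start`, `end`, `value`, `spike`.
#' @export
read_coverage <- function(path, spike_prefix = "spike_") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  cov <- readr::read_tsv(I(lines), col_names = c("contig", "start", "end", "value"),
                         show_col_types = FALSE, progress = FALSE)
  cov$start <- as.integer(cov$start)
  cov$end <- as.integer(cov$end)
  validate_coverage(cov)
  cov <- dplyr::arrange(cov, .data$contig, .data$start)
  check_no_overlap(cov)
  cov$spike <- startsWith(cov$contig, spike_prefix)
  cov
}

validate_coverage <- function(cov) {
  if (any(cov$start >= cov$end)) abort("coverage interval with start >= end")
  if (any(cov$start < 0)) abort("negative coverage start")
  if (any(!is.finite(cov$value))) abort("non-finite coverage value")
  if (any(cov$value < 0)) abort("negative coverage value")
  invisible(cov)
}

check_no_overlap <- function(cov) {
  bad <- cov |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(ok = all(.data$start[-1] >= .data$end[-dplyr::n()]) ||
                       dplyr::n() <= 1L) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("overlapping intervals on contig '%s'", bad$contig[1L]))
  }
  invisible(cov)
}

#' Write a coverage track to bedGraph
#'
#' @param cov Coverage tibble as returned by [read_coverage()].
#' @param path Output path.
#' @export
write_coverage <- function(cov, path) {
  readr::write_tsv(cov[, c("contig", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
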