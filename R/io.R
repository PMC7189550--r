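# Readers and writers for the tab-delimited formats the pipeline consumes:
# SEG-style segment tables, mutation tables (MAF-compatible aliases),
# binned count tables, expression matrices with a coordinate sidecar, BED
# peaks, and per-study 2x2 tables.

MAD_GENES <- c("MEN1", "ATRX", "DAXX")

first_match <- function(nms, aliases) {
  hit <- intersect(aliases, nms)
  if (length(hit) == 0) NULL else hit[1]
}

#' Read a SEG-style segment table
#'
#' Tab-delimited with columns `sample_id`, `chrom`, `start`, `end`,
#' `total_cn` and either `minor_cn` or `zygosity` (both accepted).
#'
#' @param path File path.
#' @return Segment tibble; `zygosity` derived from `minor_cn` (LOH iff 0)
#'   when absent.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) %>%
    mutate(chrom = normalize_chrom(.data$chrom))
  if (!"zygosity" %in% names(seg) && "minor_cn" %in% names(seg)) {
    seg <- seg %>%
      mutate(zygosity = case_when(
        is.na(.data$minor_cn) ~ "unknown",
        .data$minor_cn == 0 ~ "LOH",
        TRUE ~ "HET"
      ))
  }
  if ("minor_cn" %in% names(seg) &&
      any(!is.na(seg$minor_cn) & seg$minor_cn > seg$total_cn)) {
    abort("minor_cn exceeds total_cn in segment table")
  }
  seg
}

#' @rdname read_segments
#' @param segments Segment tibble.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(segments, path)
  invisible(path)
}

#' Read a somatic mutation table
#'
#' Tab-delimited; MAF-compatible column aliases are accepted
#' (`Tumor_Sample_Barcode`/`sample`, `Hugo_Symbol`/`gene`,
#' `Chromosome`/`chrom`, `Start_Position`/`pos`, `t_alt_count` + `t_depth`
#' or precomputed `af_obs`/`af` + `depth`).
#'
#' @param path File path.
#' @param mad_genes Genes defining `is_mad` (default MEN1, ATRX, DAXX).
#' @return Mutation tibble: `sample_id`, `gene`, `chrom`, `pos`, `af_obs`,
#'   `depth`, `is_mad`.
#' @export
read_mutations <- function(path, mad_genes = MAD_GENES) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nms <- names(raw)
  col <- function(aliases) first_match(nms, aliases)
  sample_col <- col(c("sample_id", "sample", "Tumor_Sample_Barcode"))
  gene_col <- col(c("gene", "Hugo_Symbol"))
  chrom_col <- col(c("chrom", "Chromosome"))
  pos_col <- col(c("pos", "Start_Position", "position"))
  if (is.null(sample_col) || is.null(gene_col) || is.null(chrom_col)) {
    abort("mutation table needs sample, gene and chromosome columns")
  }
  out <- tibble(
    sample_id = as.character(raw[[sample_col]]),
    gene = raw[[gene_col]],
    chrom = normalize_chrom(raw[[chrom_col]]),
    pos = if (!is.null(pos_col)) raw[[pos_col]] else NA_real_
  )
  af_col <- col(c("af_obs", "af", "allelic_fraction"))
  depth_col <- col(c("depth", "t_depth"))
  if (!is.null(af_col)) {
    out$af_obs <- raw[[af_col]]
    out$depth <- if (!is.null(depth_col)) raw[[depth_col]] else NA_real_
  } else if (all(c("t_alt_count", "t_depth") %in% nms)) {
    out$af_obs <- raw$t_alt_count / raw$t_depth
    out$depth <- raw$t_depth
  } else {
    abort("mutation table needs af_obs or t_alt_count/t_depth")
  }
  if (any(out$af_obs < 0 | out$af_obs > 1, na.rm = TRUE)) {
    abort("allelic fractions must lie in [0, 1]")
  }
  out %>% mutate(is_mad = .data$gene %in% mad_genes)
}

#' @rdname read_mutations
#' @param mutations Mutation tibble.
#' @export
write_mutations <- function(mutations, path) {
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' Read / write binned count tables
#'
#' Tab-delimited `sample_id`, `chrom`, `start`, `end`, `read_count`,
#' `het_snp_count`.
#'
#' @param path File path.
#' @return Bin tibble.
#' @export
read_binned_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) %>%
    mutate(chrom = normalize_chrom(.data$chrom))
}

#' @rdname read_binned_counts
#' @param bins Bin tibble.
#' @export
write_binned_counts <- function(bins, path) {
  readr::write_tsv(bins, path)
  invisible(path)
}

#' Read an expression matrix with a coordinate sidecar
#'
#' The matrix is tab-delimited genes x samples with a `gene` column; the
#' sidecar is BED4 (`chrom`, `start`, `end`, `gene`).
#'
#' @param expr_path Expression matrix path.
#' @param coords_path Gene-coordinate BED path.
#' @return List with `expr` (long tibble `gene`, `sample_id`, `value`) and
#'   `genes` (coordinates).
#' @export
read_expression <- function(expr_path, coords_path) {
  wide <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  expr <- wide %>%
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  genes <- readr::read_tsv(
    coords_path,
    col_names = c("chrom", "start", "end", "gene"),
    show_col_types = FALSE, progress = FALSE
  ) %>%
    mutate(chrom = normalize_chrom(.data$chrom))
  list(expr = expr, genes = genes)
}

#' @rdname read_expression
#' @param expr Long expression tibble.
#' @param genes Gene coordinate tibble.
#' @export
write_expression <- function(expr, genes, expr_path, coords_path) {
  expr %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") %>%
    readr::write_tsv(expr_path)
  genes %>%
    select("chrom", "start", "end", "gene") %>%
    readr::write_tsv(coords_path, col_names = FALSE)
  invisible(expr_path)
}

#' Read / write peak BED files
#'
#' BED4+ with `chrom`, `start`, `end`, `height` and optionally `reads`.
#'
#' @param path File path.
#' @return Peak tibble.
#' @export
read_peaks <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- c("chrom", "start", "end", "height", "reads")[
    seq_len(ncol(raw))]
  raw %>% mutate(chrom = normalize_chrom(.data$chrom))
}

#' @rdname read_peaks
#' @param peaks Peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  peaks %>%
    select(dplyr::any_of(c("chrom", "start", "end", "height", "reads"))) %>%
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' Read per-study 2x2 tables
#'
#' CSV with columns `study_id`, `a`, `b`, `c`, `d`.
#'
#' @param path File path.
#' @return Table tibble for [pooled_or()].
#' @export
read_study_tables <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
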