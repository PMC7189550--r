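# CENP-A peak summaries: overlap classification between depleted and
# control peak sets, per-cytoband RPKM and KS statistics, and correlation
# of per-chromosome features with mis-segregation fractions.

# Any-overlap (>= 1 bp) test of one interval against a set on one strandless
# genome; half-open coordinates.
overlaps_any <- function(chrom, start, end, set) {
  out <- logical(length(start))
  for (i in seq_along(start)) {
    s <- set[set$chrom == chrom[i], , drop = FALSE]
    out[i] <- any(s$start < end[i] & s$end > start[i])
  }
  out
}

#' Classify peaks as acquired, maintained or lost between two conditions
#'
#' Partitions the union of a depleted-condition and a control peak set by
#' any-overlap (>= 1 bp): depleted-only peaks are `acquired`, overlapping
#' peaks `maintained`, control-only peaks `lost`.
#'
#' @param depleted,control Peak tibbles (`chrom`, `start`, `end`, ...).
#' @return Tibble of all input peaks with added `source`
#'   (`depleted`/`control`) and `class` columns.
#' @export
classify_peaks <- function(depleted, control) {
  depleted <- as_tibble(depleted) %>% mutate(source = "depleted")
  control <- as_tibble(control) %>% mutate(source = "control")
  d_hit <- overlaps_any(depleted$chrom, depleted$start, depleted$end, control)
  c_hit <- overlaps_any(control$chrom, control$start, control$end, depleted)
  bind_rows(
    depleted %>% mutate(class = if_else(d_hit, "maintained", "acquired")),
    control %>% mutate(class = if_else(c_hit, "maintained", "lost"))
  )
}

#' Welch t-test of shared peak heights between conditions
#'
#' Compares heights of maintained (overlapping) peaks between the depleted
#' and control sources.
#'
#' @param classified Output of [classify_peaks()] (needs `height`).
#' @return Tibble: `t`, `df`, `p_value`, `mean_depleted`, `mean_control`.
#' @export
shared_peak_ttest <- function(classified) {
  shared <- classified %>% filter(.data$class == "maintained")
  ht <- t.test(height ~ source, data = shared)
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_depleted = unname(ht$estimate["mean in group depleted"]),
    mean_control = unname(ht$estimate["mean in group control"])
  )
}

#' Per-cytoband RPKM of peak reads
#'
#' Reads per kilobase of peak per million mapped reads, aggregated per
#' cytoband. Peaks spanning a band boundary contribute reads and bases to
#' each band in proportion to their overlap, so splitting a peak into
#' adjacent sub-peaks covering the same reads and bases leaves the result
#' unchanged.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `reads`).
#' @param bands Cytoband tibble.
#' @param total_mapped_reads Library size for the per-million scaling.
#' @return Tibble per band: `chrom`, `band`, `n_peaks`, `coverage_bp`,
#'   `reads`, `rpkm`.
#' @export
#' @examples
#' bands <- synthetic_cytobands()
#' pk <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1e6 + 1000,
#'                      reads = 1000, height = 5)
#' rpkm(pk, bands, total_mapped_reads = 1e6)  # 1000 for the hit band
rpkm <- function(peaks, bands, total_mapped_reads) {
  hits <- assign_to_cytoband(peaks, bands) %>%
    mutate(
      overlap_bp = pmin(.data$end, .data$band_end) -
        pmax(.data$start, .data$band_start),
      frac = .data$overlap_bp / (.data$end - .data$start),
      reads_in = .data$reads * .data$frac
    )
  hits %>%
    group_by(.data$chrom, .data$band) %>%
    summarise(
      n_peaks = dplyr::n(),
      coverage_bp = sum(.data$overlap_bp),
      reads = sum(.data$reads_in),
      .groups = "drop"
    ) %>%
    mutate(rpkm = .data$reads /
             ((.data$coverage_bp / 1000) * (total_mapped_reads / 1e6)))
}

#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' Maximum gap between the empirical cumulative distributions of a
#' cytoband's peak values and the genome-wide values.
#'
#' @param band_values,genome_values Numeric vectors (e.g. peak heights).
#' @return D in `[0, 1]`.
#' @export
band_ks <- function(band_values, genome_values) {
  if (length(band_values) == 0 || length(genome_values) == 0) {
    abort("band_ks needs non-empty samples")
  }
  pts <- sort(unique(c(band_values, genome_values)))
  f1 <- ecdf(band_values)(pts)
  f2 <- ecdf(genome_values)(pts)
  max(abs(f1 - f2))
}

#' Per-cytoband peak statistics
#'
#' Summarizes a peak set per cytoband: peak count, base coverage, RPKM, and
#' the KS D statistic of the band's peak heights against the genome-wide
#' height distribution.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `height`, `reads`).
#' @param bands Cytoband tibble.
#' @param total_mapped_reads Library size.
#' @return Tibble per band with `n_peaks`, `coverage_bp`, `rpkm`, `ks_d`.
#' @export
cytoband_peak_stats <- function(peaks, bands, total_mapped_reads) {
  base <- rpkm(peaks, bands, total_mapped_reads)
  hits <- assign_to_cytoband(peaks, bands)
  ks <- hits %>%
    group_by(.data$chrom, .data$band) %>%
    summarise(ks_d = band_ks(.data$height, .env$peaks$height),
              .groups = "drop")
  base %>% left_join(ks, by = c("chrom", "band"))
}

#' Correlate per-chromosome features with mis-segregation fractions
#'
#' Pearson correlations (with two-sided p from the t-transform) between a
#' chromosome-level mis-segregation fraction and continuous features
#' (centromere size, periCEN flank size, CENP-A levels near the
#' centromere, ...), plus the point-biserial correlation with LOH-set
#' membership.
#'
#' @param misseg Tibble: `chrom`, `missegregation_fraction`, optional
#'   logical `loh_member`.
#' @param features Tibble: `chrom` plus numeric feature columns.
#' @return Tidy tibble: `feature`, `type`, `n`, `r`, `p_value`.
#' @export
missegregation_correlations <- function(misseg, features = NULL) {
  cor_row <- function(x, y, feature, type) {
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      # a constant variable carries no association
      return(tibble(feature = feature, type = type, n = sum(ok),
                    r = 0, p_value = 1))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    tibble(feature = feature, type = type, n = sum(ok),
           r = unname(ct$estimate), p_value = ct$p.value)
  }
  out <- list()
  if (!is.null(features)) {
    df <- misseg %>% inner_join(features, by = "chrom")
    num_cols <- setdiff(names(features)[purrr::map_lgl(features, is.numeric)],
                        "chrom")
    out <- purrr::map(num_cols, function(col) {
      cor_row(df$missegregation_fraction, df[[col]], col, "pearson")
    })
  }
  if ("loh_member" %in% names(misseg)) {
    out$pb <- cor_row(misseg$missegregation_fraction,
                      as.numeric(misseg$loh_member),
                      "loh_member", "point_biserial")
  }
  bind_rows(out)
}
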