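# Expression-based signature inference: per-gene z-scores of MAD+ against
# MAD- samples, arm-level expression percentiles, loess smoothing along the
# genome, and pericentromeric repression curves against fractional
# centromere distance.

#' Per-gene expression z-scores of MAD+ against MAD- samples
#'
#' `z = (mean over MAD+ - mean over MAD-) / sd over MAD-`. The MAD- group
#' alone defines the reference mean and dispersion. Genes with fewer than
#' two MAD- values or zero MAD- variance are dropped with a message.
#'
#' @param expr Long expression tibble: `gene`, `sample_id`, `value`
#'   (normalized expression).
#' @param meta Sample sheet: `sample_id`, `mad_status` (`"MAD+"`/`"MAD-"`).
#' @return Tibble per gene: `gene`, `z`, `mean_pos`, `mean_neg`, `sd_neg`,
#'   `n_pos`, `n_neg`.
#' @export
gene_zscores <- function(expr, meta) {
  status <- meta$mad_status[match(expr$sample_id, meta$sample_id)]
  # grouped sums via rowsum: orders of magnitude faster than per-gene
  # summarise on microarray-scale tables, and re-run per label permutation
  pos <- status == "MAD+"
  g_pos <- expr$gene[pos]
  g_neg <- expr$gene[!pos]
  s_pos <- rowsum(expr$value[pos], g_pos)
  n_pos <- rowsum(rep(1, sum(pos)), g_pos)
  s_neg <- rowsum(expr$value[!pos], g_neg)
  s2_neg <- rowsum(expr$value[!pos]^2, g_neg)
  n_neg <- rowsum(rep(1, sum(!pos)), g_neg)
  genes <- intersect(rownames(s_pos), rownames(s_neg))
  mp <- s_pos[genes, 1] / n_pos[genes, 1]
  nn <- n_neg[genes, 1]
  mn <- s_neg[genes, 1] / nn
  vn <- (s2_neg[genes, 1] - nn * mn^2) / pmax(nn - 1, 1)
  scores <- tibble(
    gene = genes, mean_pos = unname(mp), mean_neg = unname(mn),
    sd_neg = unname(sqrt(pmax(vn, 0))),
    n_pos = unname(as.integer(n_pos[genes, 1])),
    n_neg = unname(as.integer(nn))
  )
  bad <- scores$n_neg < 2 | is.na(scores$sd_neg) | scores$sd_neg == 0
  if (any(bad)) {
    rlang::inform(sprintf(
      "dropping %d gene(s) with undefined MAD- dispersion", sum(bad)))
  }
  scores %>%
    filter(!bad) %>%
    mutate(z = (.data$mean_pos - .data$mean_neg) / .data$sd_neg) %>%
    select("gene", "z", dplyr::everything())
}

#' Arm-level expression percentiles
#'
#' Positions each gene's z-score within its chromosome arm by the empirical
#' cumulative distribution: percentile = rank / number of genes on the arm,
#' with mid-ranks for ties. The lowest-z gene on a 100-gene arm gets 0.01,
#' the highest 1.
#'
#' @param genes Tibble with `chrom`, `arm` and a z column.
#' @param z_col Name of the z column (default `"z"`).
#' @return `genes` with an added `arm_percentile` column.
#' @export
arm_percentiles <- function(genes, z_col = "z") {
  genes %>%
    group_by(.data$chrom, .data$arm) %>%
    mutate(arm_percentile = rank(.data[[z_col]], ties.method = "average") /
             dplyr::n()) %>%
    ungroup()
}

#' Loess smoothing of gene z-scores along the genome
#'
#' Fits a locally weighted regression (tricube kernel, degree 2, span as a
#' fraction of points) of z against genomic position, per chromosome, and
#' evaluates it on a regular grid.
#'
#' @param genes Tibble with `chrom`, a position column and a z column.
#' @param span Loess span (default 0.5, i.e. a 50% smoothing window).
#' @param degree Local polynomial degree (default 2).
#' @param pos_col,z_col Column names (defaults `"pos"`-or-midpoint, `"z"`).
#' @param n_grid Grid points per chromosome.
#' @param min_genes Minimum genes per chromosome to fit (default 10).
#' @return Tibble: `chrom`, `pos`, `fit`.
#' @export
genomic_loess <- function(genes, span = 0.5, degree = 2, pos_col = NULL,
                          z_col = "z", n_grid = 200, min_genes = 10) {
  genes <- as_tibble(genes)
  pos <- if (!is.null(pos_col)) {
    genes[[pos_col]]
  } else if ("pos" %in% names(genes)) {
    genes$pos
  } else {
    (genes$start + genes$end) / 2
  }
  genes$.pos <- pos
  genes %>%
    group_by(.data$chrom) %>%
    dplyr::group_split() %>%
    purrr::keep(~ nrow(.x) >= min_genes) %>%
    purrr::map(function(df) {
      fit <- loess(df[[z_col]] ~ df$.pos, span = span, degree = degree,
                   family = "gaussian")
      grid <- seq(min(df$.pos), max(df$.pos), length.out = n_grid)
      tibble(chrom = df$chrom[1], pos = grid,
             fit = predict(fit, newdata = grid))
    }) %>%
    bind_rows()
}

#' Pericentromeric repression curves over fractional centromere distance
#'
#' Fits separate loess curves of arm-level expression percentile (or raw z)
#' against fractional distance to the centromere for genes on LOH
#' chromosomes and on heterozygous chromosomes, evaluates both on a shared
#' grid, and reports their difference (LOH minus heterozygous). Repression
#' immediately adjacent to the centromere appears as a negative difference
#' near fractional distance 0.
#'
#' @param genes Tibble with `chrom`, `arm`, `frac_dist` and a z column
#'   (output of [gene_zscores()] joined to coordinates, or any table with
#'   those columns).
#' @param loh_set,het_set Chromosome sets; default to the signature sets.
#' @param span Loess span (default 0.5).
#' @param value `"percentile"` (arm-level ECDF, default) or `"z"`.
#' @param z_col Z column used (default `"z"`).
#' @param grid Evaluation grid on `[0, 1]`.
#' @param window Fractional-distance window summarized (default
#'   `[0, 0.025]`, the band immediately adjacent to the centromere).
#' @return Object of class `repression_curves`: list with `curves`
#'   (`frac_dist`, `fit_loh`, `fit_het`, `difference`), `window_mean`,
#'   `window_negative`, `value`, `n_loh`, `n_het`.
#' @export
repression_curves <- function(genes,
                              loh_set = signature_chromosomes()$loh,
                              het_set = signature_chromosomes()$het,
                              span = 0.5,
                              value = c("percentile", "z"),
                              z_col = "z",
                              grid = seq(0, 1, by = 0.005),
                              window = c(0, 0.025)) {
  value <- match.arg(value)
  genes <- as_tibble(genes)
  if (value == "percentile") {
    genes <- arm_percentiles(genes, z_col = z_col)
    ycol <- "arm_percentile"
  } else {
    ycol <- z_col
  }
  loh <- genes %>% filter(.data$chrom %in% normalize_chrom(loh_set))
  het <- genes %>% filter(.data$chrom %in% normalize_chrom(het_set))
  if (nrow(loh) < 10 || nrow(het) < 10) {
    abort("need >= 10 genes in each chromosome group")
  }
  fit_on <- function(df) {
    fit <- loess(df[[ycol]] ~ df$frac_dist, span = span, degree = 2)
    predict(fit, newdata = grid)
  }
  curves <- tibble(
    frac_dist = grid,
    fit_loh = fit_on(loh),
    fit_het = fit_on(het)
  ) %>%
    mutate(difference = .data$fit_loh - .data$fit_het)
  in_win <- curves$frac_dist >= window[1] & curves$frac_dist <= window[2] &
    !is.na(curves$difference)
  structure(
    list(
      curves = curves,
      window = window,
      window_mean = mean(curves$difference[in_win]),
      window_negative = all(curves$difference[in_win] < 0),
      value = value,
      n_loh = nrow(loh),
      n_het = nrow(het)
    ),
    class = "repression_curves"
  )
}

#' @export
print.repression_curves <- function(x, ...) {
  cat(sprintf(
    paste0("Repression curves (%s): mean LOH-minus-het difference on ",
           "[%g, %g] = %.4f (%s)\n"),
    x$value, x$window[1], x$window[2], x$window_mean,
    if (x$window_negative) "uniformly negative" else "not uniformly negative"
  ))
  invisible(x)
}

#' Permutation null for the pericentromeric repression window
#'
#' Re-runs the z-score / percentile / loess chain with MAD labels shuffled,
#' returning the window-mean difference for each permutation. The observed
#' window mean can be compared to this null band.
#'
#' @param expr,meta As in [gene_zscores()].
#' @param genes Gene coordinate tibble with `gene`, `chrom`, `arm`,
#'   `frac_dist`.
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutations.
#' @param ... Passed to [repression_curves()].
#' @return Numeric vector of permuted window means.
#' @export
repression_window_null <- function(expr, meta, genes, n_perm = 20,
                                   seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dbl(seq_len(n_perm), function(i) {
    shuffled <- meta %>% mutate(mad_status = sample(.data$mad_status))
    z <- gene_zscores(expr, shuffled) %>%
      inner_join(genes %>% select("gene", "chrom", "arm", "frac_dist"),
                 by = "gene")
    repression_curves(z, ...)$window_mean
  })
}
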