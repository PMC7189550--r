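# Monoallelic-expression testing from RNA SNP allelic fractions, and
# trio-based parental skewing of LOH chromosomes.

# Fold an allelic fraction towards its major allele: monoallelic expression
# shows up as AF near 0 or 1; folding makes both tails point the same way.
fold_af <- function(af) pmax(af, 1 - af)

# Depth-weighted z statistic of a set of folded AFs against the
# sample-wide folded-AF background: the depth-weighted set mean, displaced
# from the background weighted mean, scaled by the background sd over the
# square root of the set's effective sample size (sum w)^2 / sum w^2. The
# background supplies the dispersion: with 2-3 SNPs per gene a within-set
# variance estimate is so unstable that incidentally tight random sets
# would dominate the null tail.
weighted_z <- function(f, w, bg_mean, bg_sd) {
  sw <- sum(w)
  mw <- sum(w * f) / sw
  n_eff <- sw^2 / sum(w^2)
  (mw - bg_mean) / (bg_sd / sqrt(n_eff))
}

# Vectorized bootstrap: mean weighted z over B resamples (with replacement)
# of one SNP set against fixed background moments.
boot_mean_z <- function(f, w, bg_mean, bg_sd, n_boot) {
  g <- length(f)
  idx <- matrix(sample.int(g, g * n_boot, replace = TRUE), nrow = g)
  fm <- matrix(f[idx], nrow = g)
  wm <- matrix(w[idx], nrow = g)
  sw <- colSums(wm)
  mw <- colSums(wm * fm) / sw
  n_eff <- sw^2 / colSums(wm^2)
  mean((mw - bg_mean) / (bg_sd / sqrt(n_eff)))
}

# Weighted background moments of the folded sample-wide AF distribution.
background_moments <- function(af, depth) {
  f <- fold_af(af)
  sw <- sum(depth)
  m <- sum(depth * f) / sw
  v <- sum(depth * (f - m)^2) / sw
  list(mean = m, sd = sqrt(v))
}

#' Monoallelic-expression test for one gene
#'
#' Tests whether a gene's SNP allelic fractions are skewed towards one
#' allele relative to the whole sample. Per bootstrap replicate, the gene's
#' SNPs are resampled with replacement and a depth-weighted t-statistic of
#' their folded allelic fractions against the sample-wide folded
#' distribution is computed; the mean z over `n_boot` replicates is
#' compared to a null distribution built by replacing the gene set with
#' equally sized random SNP sets.
#'
#' @param gene_snps Tibble of the gene's SNPs (`af`, `depth`); needs >= 2.
#' @param all_snps Tibble of all SNPs in the sample (`af`, `depth`).
#' @param n_boot Bootstrap replicates per set (default 1000).
#' @param n_null Random null sets (default 500).
#' @param null_quantile Flagging quantile of the null (default 0.95).
#' @param seed Optional seed for reproducible resampling.
#' @return One-row tibble: `n_snps`, `mean_z`, `null_q` (position of
#'   `mean_z` in the null ECDF), `mae_flag`.
#' @export
mae_test <- function(gene_snps, all_snps, n_boot = 1000, n_null = 500,
                     null_quantile = 0.95, seed = NULL) {
  if (nrow(gene_snps) < 2) abort("mae_test requires >= 2 SNPs in the gene")
  if (!is.null(seed)) set.seed(seed)
  bg <- background_moments(all_snps$af, all_snps$depth)
  f_all <- fold_af(all_snps$af)
  w_all <- all_snps$depth
  gz <- boot_mean_z(fold_af(gene_snps$af), gene_snps$depth,
                    bg$mean, bg$sd, n_boot)
  g <- nrow(gene_snps)
  null_z <- purrr::map_dbl(seq_len(n_null), function(i) {
    pick <- sample.int(length(f_all), g, replace = FALSE)
    boot_mean_z(f_all[pick], w_all[pick], bg$mean, bg$sd, n_boot)
  })
  thr <- quantile(null_z, null_quantile, names = FALSE)
  tibble(
    n_snps = g,
    mean_z = gz,
    null_q = mean(null_z < gz),
    mae_flag = gz > thr
  )
}

#' Monoallelic-expression scan over all genes in a sample
#'
#' Runs [mae_test()] for every gene with at least `min_snps` SNPs, sharing
#' one null distribution per distinct gene size (null sets are drawn from
#' the same sample-wide SNP pool).
#'
#' @param snps Tibble with `gene`, `af`, `depth` for one sample.
#' @param n_boot,n_null,null_quantile,seed As in [mae_test()].
#' @param min_snps Minimum SNPs for a gene to be tested (default 2).
#' @return Tibble per tested gene: `gene`, `n_snps`, `mean_z`, `null_q`,
#'   `mae_flag`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 11, mae_gene_fraction = 0.1)
#' snps <- simulate_rna_snps(cfg, n_genes = 40)
#' res <- mae_scan(snps, n_boot = 100, n_null = 100, seed = 1)
#' table(res$mae_flag, snps$true_mae[match(res$gene, snps$gene)])
mae_scan <- function(snps, n_boot = 1000, n_null = 500,
                     null_quantile = 0.95, seed = NULL, min_snps = 2) {
  if (!is.null(seed)) set.seed(seed)
  bg <- background_moments(snps$af, snps$depth)
  f_all <- fold_af(snps$af)
  w_all <- snps$depth
  sizes <- snps %>% count(.data$gene) %>% filter(.data$n >= min_snps)
  null_by_size <- sizes %>%
    distinct(.data$n) %>%
    pull(.data$n) %>%
    setNames(nm = .) %>%
    purrr::map(function(g) {
      purrr::map_dbl(seq_len(n_null), function(i) {
        pick <- sample.int(length(f_all), g, replace = FALSE)
        boot_mean_z(f_all[pick], w_all[pick], bg$mean, bg$sd, n_boot)
      })
    })
  purrr::map(seq_len(nrow(sizes)), function(i) {
    g <- sizes$gene[i]
    sub <- snps[snps$gene == g, ]
    gz <- boot_mean_z(fold_af(sub$af), sub$depth, bg$mean, bg$sd, n_boot)
    null_z <- null_by_size[[as.character(nrow(sub))]]
    thr <- quantile(null_z, null_quantile, names = FALSE)
    tibble(gene = g, n_snps = nrow(sub), mean_z = gz,
           null_q = mean(null_z < gz), mae_flag = gz > thr)
  }) %>% bind_rows()
}

# Discretize an allelic fraction into genotype classes: homozygous when
# AF >= 0.8 or <= 0.2, heterozygous strictly in between.
discretize_genotype <- function(af, hom_threshold = 0.8) {
  lo <- 1 - hom_threshold + 1e-12  # guard the boundary against 1 - 0.8 != 0.2
  case_when(
    af >= hom_threshold ~ "hom_alt",
    af <= lo ~ "hom_ref",
    TRUE ~ "het"
  )
}

#' Parental skewing of LOH chromosomes from trio genotypes
#'
#' Restricts to informative SNPs (homozygous in the mother, heterozygous in
#' the child's germline) and, per chromosome, computes the fraction of
#' tumor SNPs that are homozygous matching the maternal genotype
#' ("maternal" retained homolog), homozygous for the other allele
#' ("paternal"), or still heterozygous. Each chromosome is labelled by the
#' majority class (all-heterozygous chromosomes are labelled `no-LOH`), and
#' the maternal vs paternal chromosome counts are tested against a fair
#' coin with the exact binomial test.
#'
#' @param trio_snps Tibble: `chrom`, `pos`, `af_child_germline`,
#'   `af_maternal`, `af_tumor`.
#' @param loh_chromosomes Chromosomes to analyse (the sample's LOH set);
#'   `NULL` analyses all chromosomes present.
#' @param hom_threshold Homozygous AF cutoff (default 0.8).
#' @return Object of class `parental_skew`: list with `per_chromosome`
#'   (fractions and label), `n_maternal`, `n_paternal`, `p_value`.
#' @export
parental_skew <- function(trio_snps, loh_chromosomes = NULL,
                          hom_threshold = 0.8) {
  snps <- as_tibble(trio_snps) %>%
    mutate(chrom = normalize_chrom(.data$chrom))
  if (!is.null(loh_chromosomes)) {
    snps <- snps %>% filter(.data$chrom %in% normalize_chrom(loh_chromosomes))
  }
  snps <- snps %>%
    mutate(
      gt_child = discretize_genotype(.data$af_child_germline, hom_threshold),
      gt_mother = discretize_genotype(.data$af_maternal, hom_threshold),
      gt_tumor = discretize_genotype(.data$af_tumor, hom_threshold)
    ) %>%
    filter(.data$gt_child == "het", .data$gt_mother != "het")
  per_chrom <- snps %>%
    group_by(.data$chrom) %>%
    summarise(
      n_informative = dplyr::n(),
      frac_maternal = mean(.data$gt_tumor != "het" &
                             .data$gt_tumor == .data$gt_mother),
      frac_paternal = mean(.data$gt_tumor != "het" &
                             .data$gt_tumor != .data$gt_mother),
      frac_het = mean(.data$gt_tumor == "het"),
      .groups = "drop"
    ) %>%
    mutate(label = case_when(
      .data$frac_het >= pmax(.data$frac_maternal, .data$frac_paternal) ~
        "no-LOH",
      .data$frac_maternal > .data$frac_paternal ~ "maternal",
      .data$frac_paternal > .data$frac_maternal ~ "paternal",
      TRUE ~ "tie"
    ))
  n_mat <- sum(per_chrom$label == "maternal")
  n_pat <- sum(per_chrom$label == "paternal")
  p <- if (n_mat + n_pat > 0) {
    binomial_enrichment(n_mat, n_mat + n_pat, p0 = 0.5, sided = "two")
  } else {
    NA_real_
  }
  structure(
    list(per_chromosome = per_chrom, n_maternal = n_mat,
         n_paternal = n_pat, p_value = p),
    class = "parental_skew"
  )
}

#' @export
print.parental_skew <- function(x, ...) {
  cat(sprintf(
    "Parental skew: %d maternal vs %d paternal chromosomes (p = %.3g)\n",
    x$n_maternal, x$n_paternal, x$p_value
  ))
  print(x$per_chromosome)
  invisible(x)
}
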