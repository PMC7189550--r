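small_expr <- function(z_shift_genes = character(), shift = 0,
                       n_pos = 10, n_neg = 10, n_genes = 30, seed = 1) {
  set.seed(seed)
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_pos + n_neg)),
    mad_status = c(rep("MAD+", n_pos), rep("MAD-", n_neg))
  )
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- tidyr::expand_grid(gene = genes, sample_id = meta$sample_id)
  expr <- dplyr::left_join(expr, meta, by = "sample_id")
  expr$value <- rnorm(nrow(expr)) +
    ifelse(expr$gene %in% z_shift_genes & expr$mad_status == "MAD+",
           shift, 0)
  list(expr = expr[, c("gene", "sample_id", "value")], meta = meta)
}

test_that("z-scores are zero for equal means and 1 for a +1 sd shift", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         mad_status = c("MAD+", "MAD+", "MAD-", "MAD-"))
  expr <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 4),
    sample_id = rep(c("a", "b", "c", "d"), 2),
    # g1: MAD+ mean equals MAD- mean; g2: MAD+ shifted by one MAD- sd
    value = c(2, 4, 1, 5, 5, 5, 2, 4)
  )
  z <- gene_zscores(expr, meta)
  expect_equal(z$z[z$gene == "g1"], 0)
  # g2: MAD- mean 3, sd sqrt(2); MAD+ mean 5 -> z = 2/sqrt(2)
  expect_equal(z$z[z$gene == "g2"], 2 / sqrt(2))
})

test_that("genes with zero MAD- dispersion are dropped with a message", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         mad_status = c("MAD+", "MAD-", "MAD-"))
  expr <- tibble::tibble(gene = "g1", sample_id = c("a", "b", "c"),
                         value = c(1, 2, 2))
  expect_message(z <- gene_zscores(expr, meta), "undefined")
  expect_equal(nrow(z), 0)
})

test_that("simulated repression is recovered in the z-scores", {
  sim <- small_expr(z_shift_genes = sprintf("g%03d", 1:10), shift = -0.8,
                    n_pos = 40, n_neg = 40, n_genes = 40, seed = 5)
  z <- gene_zscores(sim$expr, sim$meta)
  hit <- mean(z$z[z$gene %in% sprintf("g%03d", 1:10)])
  miss <- mean(z$z[!z$gene %in% sprintf("g%03d", 1:10)])
  se <- sqrt(1 / 40 + 1 / 40)
  expect_lt(abs(hit - (-0.8)), 3 * se / sqrt(10) + 0.15)
  expect_lt(abs(miss), 0.2)
})

test_that("arm percentiles follow rank arithmetic with mid-rank ties", {
  df <- tibble::tibble(chrom = "chr1", arm = "q",
                       z = c(5, 1, 3, 2, 4))
  out <- arm_percentiles(df)
  expect_equal(out$arm_percentile, c(1, 0.2, 0.6, 0.4, 0.8))
  # 100-gene arm: lowest gene gets 0.01, highest 1
  df100 <- tibble::tibble(chrom = "chr1", arm = "p", z = sample(1:100))
  out100 <- arm_percentiles(df100)
  expect_equal(out100$arm_percentile[which.min(df100$z)], 0.01)
  expect_equal(out100$arm_percentile[which.max(df100$z)], 1)
  # all-equal z: everything at the shared mid-rank
  ties <- tibble::tibble(chrom = "chr2", arm = "q", z = rep(7, 50))
  out_t <- arm_percentiles(ties)
  expect_true(all(out_t$arm_percentile == out_t$arm_percentile[1]))
  expect_equal(out_t$arm_percentile[1], 0.51)
  # permutation invariance: percentiles are a function of ranks only
  perm <- sample(nrow(df))
  expect_equal(arm_percentiles(df[perm, ])$arm_percentile,
               out$arm_percentile[perm])
})

test_that("loess with a full-span window reproduces a straight line", {
  set.seed(3)
  genes <- tibble::tibble(chrom = "chr1", pos = seq(1e6, 9e7, length.out = 60))
  genes$z <- 0.5 + 2e-9 * genes$pos  # exactly collinear
  fit <- genomic_loess(genes, span = 1, degree = 1)
  expected <- 0.5 + 2e-9 * fit$pos
  expect_lt(max(abs(fit$fit - expected)), 1e-8)
})

test_that("genomic loess requires a minimum gene count per chromosome", {
  genes <- tibble::tibble(chrom = "chr1", pos = 1:5, z = rnorm(5))
  expect_equal(nrow(genomic_loess(genes)), 0)
})

test_that("repression curves localize an injected pericentromeric dip", {
  cfg <- sim_config(n_samples = 60, seed = 12)
  ex <- simulate_expression(cfg, n_genes = 6000)
  z <- gene_zscores(ex$expr, ex$meta)
  zg <- dplyr::inner_join(z, ex$genes, by = "gene")
  rc <- repression_curves(zg)
  expect_true(rc$window_negative)
  expect_lt(rc$window_mean, -0.1)
  # far from the centromere the curves agree
  far <- rc$curves$difference[rc$curves$frac_dist > 0.3]
  expect_lt(max(abs(far), na.rm = TRUE), 0.1)

  # identical expression in both groups: difference ~ 0 everywhere
  cfg0 <- sim_config(n_samples = 60, seed = 13, repression_depth = 0)
  ex0 <- simulate_expression(cfg0, n_genes = 6000)
  z0 <- gene_zscores(ex0$expr, ex0$meta)
  zg0 <- dplyr::inner_join(z0, ex0$genes, by = "gene")
  rc0 <- repression_curves(zg0)
  expect_lt(max(abs(rc0$curves$difference), na.rm = TRUE), 0.08)

  # repression injected on the heterozygous set instead flips the sign
  rc_flip <- repression_curves(zg, loh_set = signature_chromosomes()$het,
                               het_set = signature_chromosomes()$loh)
  expect_gt(rc_flip$window_mean, 0.1)
})

test_that("label-shuffled repression stays within the permutation null band", {
  cfg <- sim_config(n_samples = 40, seed = 15)
  ex <- simulate_expression(cfg, n_genes = 4000)
  nulls <- repression_window_null(ex$expr, ex$meta, ex$genes,
                                  n_perm = 12, seed = 16)
  band <- quantile(nulls[-1], c(0.025, 0.975))
  expect_gte(nulls[1], band[[1]] - 0.05)
  expect_lte(nulls[1], band[[2]] + 0.05)
  # the true labels fall far outside the same band
  z <- gene_zscores(ex$expr, ex$meta)
  zg <- dplyr::inner_join(z, ex$genes, by = "gene")
  expect_lt(repression_curves(zg)$window_mean, band[[1]] - 0.05)
})
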