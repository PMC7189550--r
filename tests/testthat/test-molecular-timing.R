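test_that("implied purity inverts the AF model at the hand-checked points", {
  expect_equal(implied_purity(0.25, 1, 2), 0.5)
  expect_equal(implied_purity(0.5, 2, 2), 0.5)
  expect_equal(implied_purity(0.5, 1, 2), 1)
  # infeasible: purity would exceed 1
  expect_true(is.na(implied_purity(0.6, 1, 2)))
  # male chrX: one normal copy
  expect_equal(implied_purity(0.5, 1, 1, normal_copy = 1), 0.5)
})

test_that("implied purity inverts the forward model over a dense grid", {
  grid <- expand.grid(p = seq(0.05, 1, by = 0.05), n = 1:6)
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; n <- grid$n[i]
    for (m in 1:n) {
      af <- expected_af(p, m, n)
      expect_equal(implied_purity(af, m, n), p, tolerance = 1e-12)
    }
  }
})

test_that("simplest consistent copy model is selected (spec fixed points)", {
  meta <- tibble::tibble(sample_id = "s1", pathologist_purity = 0.5,
                         sex = "female")
  mut <- function(af) {
    tibble::tibble(sample_id = "s1", gene = "MEN1", chrom = "chr11",
                   pos = 1e6, af_obs = af, depth = 200, is_mad = TRUE)
  }
  # af 0.5 at purity 0.5: homozygous (2,2), tumor AF 1
  hom <- select_copy_model(mut(0.5), meta)
  expect_equal(c(hom$m, hom$n), c(2, 2))
  expect_equal(hom$tumor_af, 1)
  expect_equal(hom$ccf_class, "early")
  # af 0.25 at purity 0.5: heterozygous (1,2), tumor AF 0.5
  het <- select_copy_model(mut(0.25), meta)
  expect_equal(c(het$m, het$n), c(1, 2))
  expect_equal(het$tumor_af, 0.5)
  expect_equal(het$ccf_class, "late")
  # af 0.05 at purity 0.9, n_max 4: nothing reaches the tolerance
  meta9 <- tibble::tibble(sample_id = "s1", pathologist_purity = 0.9,
                          sex = "female")
  none <- select_copy_model(mut(0.05), meta9, n_max = 4)
  expect_equal(none$status, "unresolved")
  # exhaustive oracle: no (m, n) up to 4 implies purity within 0.9 +/- 0.15
  feas <- expand.grid(n = 1:4, m = 1:4)
  feas <- feas[feas$m <= feas$n, ]
  ip <- implied_purity(0.05, feas$m, feas$n)
  expect_false(any(!is.na(ip) & abs(ip - 0.9) <= 0.15))
})

test_that("samples below 30% pathologist purity are excluded", {
  meta <- tibble::tibble(sample_id = "s1", pathologist_purity = 0.25,
                         sex = "female")
  mut <- tibble::tibble(sample_id = "s1", gene = "MEN1", chrom = "chr11",
                        pos = 1, af_obs = 0.2, depth = 100, is_mad = TRUE)
  out <- select_copy_model(mut, meta)
  expect_equal(out$status, "excluded_low_purity")
})

test_that("segment constraints pin the total copy number", {
  meta <- tibble::tibble(sample_id = "s1", pathologist_purity = 0.6,
                         sex = "female")
  mut <- tibble::tibble(sample_id = "s1", gene = "MEN1", chrom = "chr11",
                        pos = 1, af_obs = 0.6, depth = 500, is_mad = TRUE)
  seg <- tibble::tibble(sample_id = "s1", chrom = "chr11",
                        start = 0, end = 1e8, total_cn = 2, minor_cn = 0)
  out <- select_copy_model(mut, meta, segments = seg)
  expect_equal(out$n, 2)
  expect_equal(out$m, 2)
})

test_that("male chrX uses one normal copy for ATRX", {
  meta <- tibble::tibble(sample_id = "s1", pathologist_purity = 0.6,
                         sex = "male")
  # af = p at (1,1) with one normal copy
  mut <- tibble::tibble(sample_id = "s1", gene = "ATRX", chrom = "chrX",
                        pos = 1, af_obs = 0.6, depth = 400, is_mad = TRUE)
  out <- select_copy_model(mut, meta)
  expect_equal(c(out$m, out$n), c(1, 1))
  expect_false(out$chrx_flagged)
  # unknown sex: flagged, treated autosomally
  meta_na <- tibble::tibble(sample_id = "s1", pathologist_purity = 0.6,
                            sex = NA_character_)
  out_na <- select_copy_model(mut, meta_na)
  expect_true(out_na$chrx_flagged)
})

test_that("timing summary counts early samples and respects the cutoff", {
  cfg <- sim_config(n_samples = 16, seed = 31)
  co <- simulate_cohort(cfg)
  tc <- suppressWarnings(
    select_copy_model(co$mutations, co$meta, segments = co$segments))
  ts <- timing_summary(tc, cutoff = 0.85)
  expect_true(all(ts$n_early + ts$n_late == ts$n_samples))
  # monotonicity: a stricter cutoff never increases the early count
  stricter <- timing_summary(tc, cutoff = 0.95)
  looser <- timing_summary(tc, cutoff = 0.5)
  expect_lte(stricter$n_early, ts$n_early)
  expect_gte(looser$n_early, ts$n_early)
})

test_that("exact binomial agrees with enumeration and base R for n <= 20", {
  set.seed(9)
  for (i in 1:60) {
    n <- sample(1:20, 1)
    k <- sample(0:n, 1)
    p0 <- sample(c(0.25, 0.5, 0.7), 1)
    expect_equal(binomial_enrichment(k, n, p0),
                 brute_binomial(k, n, p0), tolerance = 1e-12)
    expect_equal(binomial_enrichment(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-9)
    expect_equal(binomial_enrichment(k, n, p0, sided = "greater"),
                 brute_binomial(k, n, p0, sided = "greater"),
                 tolerance = 1e-12)
  }
  expect_equal(binomial_enrichment(5, 10), 1)  # symmetric midpoint
  expect_error(binomial_enrichment(0, 0), "n must be")
})

test_that("per-gene enrichment applies the Bonferroni factor and cap", {
  calls <- tibble::tibble(
    gene = c(rep("MEN1", 10), rep("DAXX", 6)),
    status = "ok",
    tumor_af = c(rep(1, 9), 0.5, rep(1, 3), rep(0.5, 3))
  )
  out <- gene_enrichment(calls, cutoff = 0.85)
  men1 <- out[out$gene == "MEN1", ]
  expect_equal(men1$k_early, 9L)
  expect_equal(men1$p_adj, min(1, 3 * binomial_enrichment(9, 10)))
  daxx <- out[out$gene == "DAXX", ]
  expect_equal(daxx$p_adj, 1)  # capped
  expect_true(is.na(out$p_raw[out$gene == "ATRX"]))
})
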