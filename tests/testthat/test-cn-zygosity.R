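test_that("purity-adjusted AF hits its closed-form fixed points", {
  expect_equal(purity_adjusted_af(0.5, 1, 2), 0.5)    # identity at purity 1
  expect_equal(purity_adjusted_af(0.75, 0.5, 2), 1)   # complete LOH
  # balanced het site is a fixed point at any purity
  for (p in c(0.2, 0.5, 0.8, 1)) {
    expect_equal(purity_adjusted_af(0.5, p, 2), 0.5)
  }
  expect_error(purity_adjusted_af(0.5, 0.5, 0), "total_cn")
})

test_that("purity-adjusted AF inverts the forward model to 1e-12", {
  grid <- expand.grid(af_t = seq(0.05, 1, by = 0.05),
                      p = seq(0.1, 1, by = 0.1))
  # forward: bulk AF of a site with tumor-compartment AF af_t at copy 2
  fwd <- (grid$af_t * grid$p * 2 + (1 - grid$p)) /
    (grid$p * 2 + 2 * (1 - grid$p))
  back <- purity_adjusted_af(fwd, grid$p, 2)
  expect_true(all(abs(back - grid$af_t) < 1e-12))
})

test_that("chromosome state calling is exact on clean high-purity data", {
  cfg <- sim_config(seed = 3, background_aberration_rate = 0)
  set.seed(10)
  s <- simulate_sample(cfg, "MAD+", purity = 1)
  bins <- simulate_binned_counts(s$segments, purity = 1, cfg)
  called <- call_chromosome_states(bins, purity = 1,
                                   germline_het_density = cfg$het_snps_per_bin)
  merged <- dplyr::inner_join(
    called, s$segments, by = c("sample_id", "chrom"),
    suffix = c("", ".true"))
  expect_equal(merged$zygosity, merged$zygosity.true)
  expect_equal(merged$total_cn, merged$total_cn.true)
})

test_that("all-zero het counts at purity 1 give LOH; full retention gives HET", {
  bins <- tidyr::expand_grid(chrom = c("chr3", "chr7"),
                             start = seq(0, 4.5e6, by = 5e5))
  bins$sample_id <- "s1"
  bins$end <- bins$start + 5e5
  bins$read_count <- 1000
  bins$het_snp_count <- ifelse(bins$chrom == "chr3", 0, 100)
  called <- call_chromosome_states(bins, purity = 1,
                                   germline_het_density = 100)
  expect_equal(called$zygosity[called$chrom == "chr3"], "LOH")
  expect_equal(called$zygosity[called$chrom == "chr7"], "HET")
})

test_that("state recovery at purity 0.6 matches truth on >= 21/22 autosomes", {
  cfg <- sim_config(seed = 19)
  set.seed(42)
  s <- simulate_sample(cfg, "MAD+", purity = 0.6)
  bins <- simulate_binned_counts(s$segments, purity = 0.6, cfg)
  called <- call_chromosome_states(bins, purity = 0.6,
                                   germline_het_density = cfg$het_snps_per_bin)
  merged <- dplyr::inner_join(called, s$segments,
                              by = c("sample_id", "chrom"),
                              suffix = c("", ".true"))
  expect_gte(sum(merged$zygosity == merged$zygosity.true), 21)
})

test_that("low purity triggers the obscured-signal warning", {
  bins <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                         start = c(0, 5e5), end = c(5e5, 1e6),
                         read_count = c(1000, 1010),
                         het_snp_count = c(95, 100))
  expect_warning(
    call_chromosome_states(bins, purity = 0.2, germline_het_density = 100),
    "obscured"
  )
})

test_that("cohort motif reports modes, frequencies and ties", {
  segs <- dplyr::bind_rows(
    toy_profile("a", loh = "chr1"),
    toy_profile("b", loh = "chr1"),
    toy_profile("c", loh = "chr1")
  )
  m <- cohort_motif(segs)
  expect_equal(m$modal_zygosity[m$chrom == "chr1"], "LOH")
  expect_equal(m$zygosity_freq[m$chrom == "chr1"], 1)
  # 2 LOH vs 2 HET on chr2 is reported multi-modal, not silently broken
  segs2 <- dplyr::bind_rows(
    toy_profile("a", loh = "chr2"), toy_profile("b", loh = "chr2"),
    toy_profile("c"), toy_profile("d")
  )
  m2 <- cohort_motif(segs2)
  expect_true(m2$multimodal_zygosity[m2$chrom == "chr2"])
  expect_equal(m2$modal_zygosity[m2$chrom == "chr2"], "HET/LOH")
})

test_that("simulated MAD+ cohort motif equals the configured signature", {
  cfg <- sim_config(n_samples = 12, seed = 7, mad_positive_fraction = 1)
  co <- simulate_cohort(cfg)
  m <- cohort_motif(co$segments)
  sig <- signature_from_motif(m)
  expect_setequal(sig$loh, cfg$loh_chromosomes)
  expect_setequal(sig$het, cfg$het_chromosomes)
})

test_that("phi co-occurrence hits +1, -1 and ~0 in the canonical cases", {
  ids <- sprintf("s%02d", 1:40)
  set.seed(77)
  present <- c(rep(TRUE, 20), rep(FALSE, 20))
  segs <- purrr::map2(ids, present, function(id, pr) {
    toy_profile(id,
                loh = if (pr) c("chr1", "chr2") else character(),
                gain = if (!pr) "chr3" else character())
  })
  segs <- dplyr::bind_rows(segs)
  cooc <- signature_cooccurrence(segs)
  identical_pair <- cooc[cooc$aberration_a == "chr1:loh" &
                           cooc$aberration_b == "chr2:loh", ]
  expect_equal(identical_pair$phi, 1)
  expect_equal(identical_pair$flag, "synchronous")
  anti <- cooc[cooc$aberration_a == "chr1:loh" &
                 cooc$aberration_b == "chr3:gain", ]
  expect_equal(anti$phi, -1)
  expect_equal(anti$flag, "antagonistic")
  # independent 50/50 aberrations: phi near 0 across samples
  segs_ind <- purrr::map(1:200, function(i) {
    toy_profile(sprintf("r%03d", i),
                loh = if (runif(1) < 0.5) "chr1" else character(),
                gain = if (runif(1) < 0.5) "chr3" else character())
  })
  cooc_ind <- signature_cooccurrence(dplyr::bind_rows(segs_ind))
  ind_pair <- cooc_ind[cooc_ind$aberration_a == "chr1:loh" &
                         cooc_ind$aberration_b == "chr3:gain", ]
  expect_lt(abs(ind_pair$phi), 2.5 / sqrt(200))
})

test_that("Jaccard concordance counts state-matched aberrant bands", {
  a <- tibble::tibble(band = c("b1", "b2", "b3"),
                      status = c("loss", "loss", "loss"))
  b <- tibble::tibble(band = c("b1", "b2", "b4"),
                      status = c("loss", "loss", "loss"))
  expect_equal(jaccard_concordance(a, b), 0.5)
  expect_equal(jaccard_concordance(a, a), 1)
  disjoint <- tibble::tibble(band = c("b7", "b8"),
                             status = c("gain", "loss"))
  expect_equal(jaccard_concordance(a, disjoint), 0)
  # a gain does not match a loss on the same band
  flipped <- tibble::tibble(band = "b1", status = "gain")
  expect_equal(jaccard_concordance(tibble::tibble(band = "b1",
                                                  status = "loss"),
                                   flipped), 0)
})

test_that("Jaccard agrees with brute-force sets on random 20-band profiles", {
  set.seed(123)
  for (i in 1:50) {
    mk <- function() {
      tibble::tibble(
        band = paste0("b", 1:20),
        status = sample(c("loss", "gain", "neutral"), 20, replace = TRUE,
                        prob = c(0.3, 0.3, 0.4))
      )
    }
    a <- mk(); b <- mk()
    expect_equal(jaccard_concordance(a, b), brute_jaccard(a, b))
    expect_equal(jaccard_concordance(a, b), jaccard_concordance(b, a))
  }
})

test_that("Scarpa groups follow their genome-fraction definitions", {
  expect_equal(classify_scarpa_group(toy_profile("s")), "G2")
  lossy <- toy_profile("s", loss = paste0("chr", 1:14))  # > 50% lost
  expect_equal(classify_scarpa_group(lossy), "G1")
  gained <- toy_profile("s", gain = paste0("chr", 1:22))
  expect_equal(classify_scarpa_group(gained), "G3")
  mixed <- toy_profile("s", loh = paste0("chr", c(1, 2, 3, 6, 8, 10, 11)),
                       gain = paste0("chr", c(4, 5, 7)))
  expect_equal(classify_scarpa_group(mixed), "G4")
})

test_that("CI stratum thresholds on the aberrant genome fraction", {
  expect_equal(ci_stratum(toy_profile("s")), "low-CI")
  expect_equal(ci_stratum(toy_profile("s", loh = paste0("chr", 1:8))),
               "high-CI")
  # threshold is configurable
  expect_equal(ci_stratum(toy_profile("s", loh = "chr1"), threshold = 0.01),
               "high-CI")
})
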