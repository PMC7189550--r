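test_that("CGH listings expand to cytoband profiles with conflict flags", {
  bands <- synthetic_cytobands()
  listings <- tibble::tibble(
    study_id = "s1",
    sample_id = c("t1", "t1", "t1", "t2"),
    region = c("3", "11q", "11q", "1p"),
    direction = c("loss", "gain", "loss", "gain")
  )
  prof <- ingest_cgh(listings, bands)
  # whole chr3 loss covers every non-acen chr3 band
  chr3 <- prof[prof$sample_id == "t1" & prof$chrom == "chr3", ]
  expect_equal(sort(unique(chr3$status)), "loss")
  expect_equal(nrow(chr3),
               sum(bands$chrom == "chr3" & bands$stain != "acen"))
  # 11q reported both gained and lost: conflict
  chr11q <- prof[prof$sample_id == "t1" & prof$chrom == "chr11" &
                   grepl("^q", prof$band), ]
  expect_true(all(chr11q$status == "conflict"))
  # conflicts are ignored by concordance
  a <- prof[prof$sample_id == "t1", ]
  expect_equal(jaccard_concordance(chr11q, chr11q), NA_real_)
  expect_error(ingest_cgh(tibble::tibble(study_id = "s", sample_id = "x",
                                         region = "banana",
                                         direction = "loss"), bands),
               "cannot parse")
})

test_that("profile clustering separates identical-profile groups", {
  mk <- function(id, bands_aber) {
    tibble::tibble(sample_id = id, band = paste0("b", 1:20),
                   status = ifelse(paste0("b", 1:20) %in% bands_aber,
                                   "loss", "neutral"))
  }
  profiles <- dplyr::bind_rows(
    purrr::map(paste0("x", 1:4), mk, bands_aber = paste0("b", 1:8)),
    purrr::map(paste0("y", 1:4), mk, bands_aber = paste0("b", 13:20))
  )
  cl <- cluster_profiles(profiles, k = 2)
  groups <- split(cl$cluster, substr(cl$sample_id, 1, 1))
  expect_equal(length(unique(groups$x)), 1)
  expect_equal(length(unique(groups$y)), 1)
  expect_false(groups$x[1] == groups$y[1])
  # k = n gives singletons
  cl_n <- cluster_profiles(profiles, k = 8)
  expect_equal(sort(unique(cl_n$cluster)), 1:8)
})

test_that("five noisy archetypes are recovered with high adjusted agreement", {
  skip_if_not_installed("mclust")
  set.seed(55)
  archetypes <- purrr::map(1:5, function(i) {
    sample(c("loss", "gain", "neutral"), 40, replace = TRUE,
           prob = c(0.3, 0.3, 0.4))
  })
  truth <- rep(1:5, each = 12)
  profiles <- purrr::imap(truth, function(arch, i) {
    status <- archetypes[[arch]]
    flip <- runif(40) < 0.05
    status[flip] <- sample(c("loss", "gain", "neutral"), sum(flip),
                           replace = TRUE)
    tibble::tibble(sample_id = sprintf("s%03d", i), band = paste0("b", 1:40),
                   status = status)
  })
  cl <- cluster_profiles(dplyr::bind_rows(profiles), k = 5)
  ari <- mclust::adjustedRandIndex(cl$cluster, truth)
  expect_gte(ari, 0.9)
})

test_that("pooled OR reproduces single-table and homogeneous fixed points", {
  t1 <- tibble::tibble(study_id = "s1", a = 10, b = 10, c = 10, d = 10)
  expect_equal(pooled_or(t1)$or, 1)
  t2 <- tibble::tibble(study_id = "s2", a = 20, b = 5, c = 5, d = 20)
  expect_equal(pooled_or(t2)$or, 16)
  # two identical tables: pooled OR unchanged, Q = 0
  both <- dplyr::bind_rows(t2, dplyr::mutate(t2, study_id = "s3"))
  res <- pooled_or(both)
  expect_equal(res$or, 16)
  expect_equal(res$q, 0, tolerance = 1e-12)
  expect_gte(res$q, 0)
})

test_that("swapping outcome columns inverts the pooled OR exactly", {
  set.seed(66)
  tabs <- tibble::tibble(study_id = paste0("s", 1:5),
                         a = rpois(5, 15) + 1, b = rpois(5, 8) + 1,
                         c = rpois(5, 6) + 1, d = rpois(5, 20) + 1)
  fwd <- pooled_or(tabs)$or
  swapped <- dplyr::rename(tabs, a = "b", b = "a", c = "d", d = "c")
  expect_equal(pooled_or(swapped)$or, 1 / fwd, tolerance = 1e-12)
})

test_that("pooled OR and CI match the independent Mantel-Haenszel oracle", {
  skip_if_not_installed("metafor")
  cfg <- sim_config(seed = 11)
  tabs <- simulate_cgh_cohort(cfg)$tables
  res <- pooled_or(tabs)
  mh <- metafor::rma.mh(ai = a, bi = b, ci = c, di = d, data = tabs,
                        measure = "OR", correct = FALSE)
  expect_equal(res$or, exp(as.numeric(coef(mh))), tolerance = 1e-10)
  expect_equal(res$ci_low, exp(mh$ci.lb), tolerance = 1e-10)
  expect_equal(res$ci_high, exp(mh$ci.ub), tolerance = 1e-10)
})

test_that("degenerate and zero-cell tables are handled explicitly", {
  degenerate <- tibble::tibble(study_id = "s", a = 0, b = 0, c = 5, d = 5)
  expect_error(pooled_or(degenerate), "degenerate")
  zero_cell <- tibble::tibble(study_id = c("s1", "s2"),
                              a = c(10, 0), b = c(5, 4),
                              c = c(4, 3), d = c(8, 9))
  res <- pooled_or(zero_cell)
  expect_true(res$per_study$continuity[2])
  expect_false(res$per_study$continuity[1])
  expect_true(is.finite(res$or) && is.finite(res$q))
})

test_that("tidy and glance expose per-study and pooled summaries", {
  tabs <- tibble::tibble(study_id = c("s1", "s2"),
                         a = c(12, 9), b = c(4, 6),
                         c = c(5, 4), d = c(11, 13))
  res <- pooled_or(tabs)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_equal(td$estimate[1], 12 * 11 / (4 * 5))
  gl <- glance(res)
  expect_equal(gl$n_studies, 2)
  expect_true(gl$conf_low < gl$estimate & gl$estimate < gl$conf_high)
})

test_that("CI stratification of CGH profiles uses the aberrant fraction", {
  prof <- dplyr::bind_rows(
    tibble::tibble(sample_id = "hi", band = paste0("b", 1:10),
                   status = c(rep("loss", 5), rep("neutral", 5))),
    tibble::tibble(sample_id = "lo", band = paste0("b", 1:10),
                   status = c("gain", rep("neutral", 9)))
  )
  out <- cgh_ci_stratum(prof, threshold = 0.2)
  expect_equal(out$ci[out$sample_id == "hi"], "high-CI")
  expect_equal(out$ci[out$sample_id == "lo"], "low-CI")
  expect_equal(out$aberrant_fraction[out$sample_id == "hi"], 0.5)
})
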