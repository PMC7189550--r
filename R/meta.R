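# Meta-analysis of CGH-style gain/loss profiles: cytoband mapping,
# Jaccard-distance clustering, CI stratification, and the pooled
# Mantel-Haenszel odds ratio with Cochran's Q heterogeneity.

#' Map CGH gain/loss listings to cytoband-level profiles
#'
#' Expands per-sample region calls (whole chromosome, arm, or band prefix,
#' e.g. `"3"`, `"11q"`, `"1p36"`) to binary status over the cytobands they
#' cover. A band reported both gained and lost within one sample is flagged
#' `conflict` and ignored by concordance measures.
#'
#' @param listings Tibble: `study_id`, `sample_id`, `region`, `direction`
#'   (`"gain"`/`"loss"`).
#' @param bands Cytoband tibble.
#' @return Long tibble: `study_id`, `sample_id`, `chrom`, `band`, `status`
#'   (`loss`/`gain`/`conflict`); bands not listed are implicitly neutral.
#' @export
ingest_cgh <- function(listings, bands) {
  bands <- bands %>% filter(.data$stain != "acen")
  parse_region <- function(region) {
    m <- stringr::str_match(region,
                            "^(?:chr)?(\\d+|X|Y)\\s*([pq][0-9.]*)?$")
    if (is.na(m[1, 1])) {
      abort(sprintf("cannot parse CGH region '%s'", region))
    }
    list(chrom = paste0("chr", m[1, 2]), band_prefix = m[1, 3])
  }
  expanded <- purrr::pmap(listings, function(study_id, sample_id, region,
                                             direction, ...) {
    r <- parse_region(region)
    hit <- bands %>% filter(.data$chrom == r$chrom)
    if (!is.na(r$band_prefix)) {
      hit <- hit %>% filter(stringr::str_starts(.data$band, r$band_prefix))
    }
    if (nrow(hit) == 0) return(NULL)
    tibble(study_id = study_id, sample_id = sample_id,
           chrom = hit$chrom, band = hit$band, status = direction)
  }) %>% bind_rows()
  expanded %>%
    group_by(.data$study_id, .data$sample_id, .data$chrom, .data$band) %>%
    summarise(
      status = if (dplyr::n_distinct(.data$status) > 1) "conflict"
               else .data$status[1],
      .groups = "drop"
    )
}

#' Cluster copy-number profiles on Jaccard distance
#'
#' Hierarchical agglomerative clustering of samples on `1 - J` (Jaccard
#' concordance of state-matched aberrant bands), cut at `k` clusters.
#'
#' @param profiles Long tibble (`sample_id`, band key, `status`).
#' @param k Number of clusters.
#' @param linkage Agglomeration method (default `"average"`).
#' @return Tibble: `sample_id`, `cluster`.
#' @export
cluster_profiles <- function(profiles, k, linkage = "average") {
  jm <- jaccard_matrix(profiles)
  hc <- hclust(as.dist(1 - jm), method = linkage)
  cl <- cutree(hc, k = k)
  tibble(sample_id = names(cl), cluster = unname(cl))
}

#' CI stratum of CGH profiles
#'
#' @param profiles Long tibble (`sample_id`, `status`, one row per band or
#'   chromosome actually assessed, neutral rows included).
#' @param threshold Aberrant fraction at or above which a sample is
#'   high-CI (default 0.2).
#' @return Tibble: `sample_id`, `aberrant_fraction`, `ci`.
#' @export
cgh_ci_stratum <- function(profiles, threshold = 0.2) {
  profiles %>%
    group_by(.data$sample_id) %>%
    summarise(
      aberrant_fraction = mean(.data$status %in% c("loss", "gain")),
      .groups = "drop"
    ) %>%
    mutate(ci = if_else(.data$aberrant_fraction >= threshold,
                        "high-CI", "low-CI"))
}

#' Build per-study 2x2 tables from sample-level strata and outcomes
#'
#' @param samples Tibble: `study_id`, logical `high_ci`, logical `outcome`
#'   (e.g. metastasis).
#' @return Tibble per study: `study_id`, `a` (high-CI outcome+), `b`
#'   (high-CI outcome-), `c` (low-CI outcome+), `d` (low-CI outcome-).
#' @export
study_tables <- function(samples) {
  samples %>%
    group_by(.data$study_id) %>%
    summarise(
      a = sum(.data$high_ci & .data$outcome),
      b = sum(.data$high_ci & !.data$outcome),
      c = sum(!.data$high_ci & .data$outcome),
      d = sum(!.data$high_ci & !.data$outcome),
      .groups = "drop"
    )
}

#' Pooled odds ratio across studies (Mantel-Haenszel, fixed effect)
#'
#' Pools per-study 2x2 tables with the Mantel-Haenszel estimator, builds a
#' 95% confidence interval from the Robins-Breslow-Greenland variance of
#' the log odds ratio, and measures heterogeneity with Cochran's Q
#' (inverse-variance weights on the per-study log odds ratios). A Haldane
#' continuity correction of 0.5 is added to all four cells of a study only
#' when that study has a zero cell. Studies with an empty row or column
#' margin carry no information and are dropped.
#'
#' @param tables Tibble: `study_id`, `a`, `b`, `c`, `d` (`a`/`b` =
#'   exposed with/without outcome, `c`/`d` = unexposed).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `meta_or`: per-study ORs, pooled `or`,
#'   `ci_low`/`ci_high`, `q`, `q_df`, `q_p`.
#' @export
#' @examples
#' tabs <- tibble::tibble(study_id = "s1", a = 20, b = 5, c = 5, d = 20)
#' pooled_or(tabs)$or  # (20*20)/(5*5) = 16
pooled_or <- function(tables, conf_level = 0.95) {
  tables <- as_tibble(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  if (!"study_id" %in% names(tables)) {
    tables$study_id <- paste0("study", seq_len(nrow(tables)))
  }
  degenerate <- with(tables, (a + b) == 0 | (c + d) == 0 |
                       (a + c) == 0 | (b + d) == 0)
  if (all(degenerate)) abort("all tables are degenerate")
  if (any(degenerate)) {
    warn(sprintf("dropping %d degenerate table(s)", sum(degenerate)))
    tables <- tables[!degenerate, , drop = FALSE]
  }
  zero_cell <- with(tables, a == 0 | b == 0 | c == 0 | d == 0)
  cc <- ifelse(zero_cell, 0.5, 0)
  a <- tables$a + cc; b <- tables$b + cc
  c <- tables$c + cc; d <- tables$d + cc
  n <- a + b + c + d

  # Mantel-Haenszel pooled OR
  R <- a * d / n
  S <- b * c / n
  or_mh <- sum(R) / sum(S)

  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (a + d) / n
  Q <- (b + c) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or_mh) + c(-1, 1) * zc * sqrt(var_log))

  # Cochran's Q on per-study log ORs, inverse-variance (Woolf) weights
  log_or_i <- log(a * d / (b * c))
  var_i <- 1 / a + 1 / b + 1 / c + 1 / d
  w <- 1 / var_i
  q <- sum(w * (log_or_i - log(or_mh))^2)
  q_df <- nrow(tables) - 1
  q_p <- if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_

  structure(
    list(
      per_study = tables %>%
        mutate(or = (.data$a + cc) * (.data$d + cc) /
                 ((.data$b + cc) * (.data$c + cc)),
               log_or = log(.data$or), var_log_or = var_i,
               continuity = cc > 0),
      or = or_mh, var_log_or = var_log,
      ci_low = ci[1], ci_high = ci[2], conf_level = conf_level,
      q = q, q_df = q_df, q_p = q_p,
      n_studies = nrow(tables), n_samples = sum(n - 4 * cc)
    ),
    class = "meta_or"
  )
}

#' @export
print.meta_or <- function(x, ...) {
  cat(sprintf(
    "Pooled OR %.2f, %d%% CI [%.2f, %.2f] (%d studies, n = %d)\n",
    x$or, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$n_studies, round(x$n_samples)
  ))
  cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3g)\n",
              x$q, x$q_df, x$q_p))
  invisible(x)
}
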