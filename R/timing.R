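# Molecular timing of somatic mutations relative to LOH and genome
# doubling: enumerate (m, n) copy models per mutation, back-compute the
# purity each model implies, keep models consistent with pathologist purity
# +/- a tolerance, pick the simplest, and test enrichment of early (cancer
# chromosome fraction ~1) MAD mutations.

#' Purity implied by a copy model for an observed allelic fraction
#'
#' Inverts the bulk allelic-fraction model
#' `af = p*m / (p*n + normal_copy*(1-p))` for the purity:
#' `p = normal_copy*af / (m + af*(normal_copy - n))`. Models whose implied
#' purity falls outside (0, 1] are infeasible and return `NA`.
#'
#' @param af_obs Observed allelic fraction(s).
#' @param m Mutation-bearing tumor copies (1 <= m <= n).
#' @param n Total tumor copies at the locus.
#' @param normal_copy Copies in normal cells (2 autosomal; 1 male chrX).
#' @return Implied purity, or `NA` when infeasible.
#' @export
#' @examples
#' implied_purity(0.25, 1, 2)  # 0.5
#' implied_purity(0.5, 2, 2)   # 0.5
#' implied_purity(0.5, 1, 2)   # 1: fully clonal het at purity 1
implied_purity <- function(af_obs, m, n, normal_copy = 2) {
  denom <- m + af_obs * (normal_copy - n)
  p <- ifelse(denom > 0, normal_copy * af_obs / denom, NA_real_)
  # tolerate floating-point spill just past 1 from the forward model
  ifelse(!is.na(p) & p > 0 & p <= 1 + 1e-9, pmin(p, 1), NA_real_)
}

# Enumerate all copy models for one observed AF: returns tibble of feasible
# and infeasible models with implied purity and tumor AF m/n.
enumerate_copy_models <- function(af_obs, n_max = 8, n_allowed = NULL,
                                  normal_copy = 2) {
  grid <- tidyr::expand_grid(n = seq_len(n_max), m = seq_len(n_max)) %>%
    filter(.data$m <= .data$n)
  if (!is.null(n_allowed)) grid <- grid %>% filter(.data$n %in% n_allowed)
  grid %>%
    mutate(
      implied_purity = implied_purity(af_obs, .data$m, .data$n, normal_copy),
      tumor_af = .data$m / .data$n
    )
}

#' Select the simplest copy model consistent with pathologist purity
#'
#' For every somatic mutation, enumerates copy models `(m, n)` up to
#' `n_max`, keeps those whose implied purity lies within
#' `pathologist_purity +/- tolerance`, and returns the minimal-complexity
#' model: nearest the diploid baseline (smallest `|n - 2|`), then smallest
#' total copy number `n`, then smallest `m`. Without this diploid-proximity
#' rule a haploid model (1, 1) would routinely pre-empt the ordinary
#' heterozygous call (1, 2) that the allelic data supports.
#' When a segment profile is supplied, `n` is constrained to the called
#' total copy number of the mutation's chromosome. When a sample carries
#' several mutations, models are additionally required to share one purity:
#' the intersection of per-mutation feasible-purity ranges; if that
#' intersection is empty the selection falls back to per-mutation with a
#' warning.
#'
#' Samples with `pathologist_purity < 0.3` are excluded (low cellularity
#' obscures the allelic signal); their rows are returned flagged. chrX
#' mutations use `normal_copy = 1` in males; if sex is unknown the call is
#' flagged and treated autosomally.
#'
#' @param mutations Tibble with `sample_id`, `gene`, `chrom`, `af_obs`,
#'   `depth`, `is_mad`.
#' @param meta Tibble with `sample_id`, `pathologist_purity`, optional
#'   `sex`, optional `cohort`.
#' @param segments Optional segment tibble supplying per-chromosome
#'   `total_cn` copy constraints.
#' @param n_max Largest total copy number enumerated (default 8, covering
#'   genome-doubled CN-LOH states).
#' @param tolerance Purity tolerance (default 0.15).
#' @param ccf_cutoff Cancer-chromosome-fraction cutoff for the early/late
#'   class (default 0.85).
#' @return Timing-call tibble: inputs plus `m`, `n`, `implied_purity`,
#'   `tumor_af`, `ccf_class` (`early`/`late`), `status`
#'   (`ok`/`unresolved`/`excluded_low_purity`), `chrx_flagged`.
#' @export
select_copy_model <- function(mutations, meta, segments = NULL, n_max = 8,
                              tolerance = 0.15, ccf_cutoff = 0.85) {
  stopifnot(tolerance >= 0)
  calls <- as_tibble(mutations) %>%
    left_join(meta %>% select(dplyr::any_of(
      c("sample_id", "pathologist_purity", "sex", "cohort")
    )), by = "sample_id")
  if (!"sex" %in% names(calls)) calls$sex <- NA_character_
  if (anyNA(calls$pathologist_purity)) {
    abort("pathologist_purity missing for some samples")
  }
  if (!is.null(segments)) {
    calls <- calls %>%
      left_join(segments %>% select("sample_id", "chrom", "total_cn") %>%
                  rename(seg_total_cn = "total_cn"),
                by = c("sample_id", "chrom"))
  } else {
    calls$seg_total_cn <- NA_real_
  }

  one_call <- function(row, purity_window = NULL) {
    is_x <- row$chrom %in% c("chrX", "X")
    chrx_flagged <- is_x && (is.na(row$sex) || !nzchar(row$sex))
    normal_copy <- if (is_x && identical(row$sex, "male")) 1 else 2
    n_allowed <- if (!is.na(row$seg_total_cn)) row$seg_total_cn else NULL
    models <- enumerate_copy_models(row$af_obs, n_max, n_allowed,
                                    normal_copy) %>%
      filter(!is.na(.data$implied_purity),
             abs(.data$implied_purity - row$pathologist_purity) <= tolerance)
    if (!is.null(purity_window)) {
      models <- models %>%
        filter(.data$implied_purity >= purity_window[1] - 1e-9,
               .data$implied_purity <= purity_window[2] + 1e-9)
    }
    if (nrow(models) == 0) {
      return(tibble(m = NA_real_, n = NA_real_,
                    implied_purity = NA_real_, tumor_af = NA_real_,
                    status = "unresolved", chrx_flagged = chrx_flagged))
    }
    # parsimony: closest to the diploid baseline first, then fewest total
    # copies, then fewest mutated copies
    best <- models %>%
      arrange(abs(.data$n - 2), .data$n, .data$m) %>%
      slice(1)
    tibble(m = best$m, n = best$n, implied_purity = best$implied_purity,
           tumor_af = best$tumor_af, status = "ok",
           chrx_flagged = chrx_flagged)
  }

  one_sample <- function(df) {
    if (df$pathologist_purity[1] < 0.3) {
      return(df %>% mutate(m = NA_real_, n = NA_real_,
                           implied_purity = NA_real_, tumor_af = NA_real_,
                           status = "excluded_low_purity",
                           chrx_flagged = FALSE))
    }
    rows <- purrr::map(seq_len(nrow(df)), ~ df[.x, ])
    window <- NULL
    if (nrow(df) > 1) {
      # intersection of per-mutation feasible purity ranges
      ranges <- purrr::map(rows, function(r) {
        is_x <- r$chrom %in% c("chrX", "X")
        nc <- if (is_x && identical(r$sex, "male")) 1 else 2
        n_allowed <- if (!is.na(r$seg_total_cn)) r$seg_total_cn else NULL
        feas <- enumerate_copy_models(r$af_obs, n_max, n_allowed, nc) %>%
          filter(!is.na(.data$implied_purity),
                 abs(.data$implied_purity - r$pathologist_purity) <= tolerance)
        if (nrow(feas) == 0) {
          NULL
        } else {
          # inflate by half the tolerance: implied purities are point
          # estimates under binomial AF noise, not exact constraints
          range(feas$implied_purity) + c(-1, 1) * tolerance / 2
        }
      })
      ranges <- purrr::compact(ranges)
      if (length(ranges) == nrow(df)) {
        lo <- max(purrr::map_dbl(ranges, 1))
        hi <- min(purrr::map_dbl(ranges, 2))
        if (lo <= hi) {
          window <- c(lo, hi)
        } else {
          warn(sprintf(
            "sample %s: no shared purity across mutations; per-mutation selection",
            df$sample_id[1]))
        }
      }
    }
    picked <- purrr::map(rows, one_call, purity_window = window) %>%
      bind_rows()
    bind_cols(df, picked)
  }

  calls %>%
    group_by(.data$sample_id) %>%
    dplyr::group_split() %>%
    purrr::map(one_sample) %>%
    bind_rows() %>%
    mutate(ccf_class = case_when(
      .data$status != "ok" ~ NA_character_,
      .data$tumor_af >= ccf_cutoff ~ "early",
      TRUE ~ "late"
    )) %>%
    select(-"seg_total_cn")
}

#' Per-cohort counts of samples with an early MAD mutation
#'
#' A sample counts as "early" when its MAD mutation's tumor allelic
#' fraction (cancer chromosome fraction) is at or above the cutoff, i.e.
#' the mutation is carried on every tumor copy and therefore preceded the
#' LOH / genome-doubling event.
#'
#' @param timing_calls Output of [select_copy_model()].
#' @param cutoff Cancer-chromosome-fraction cutoff (default 0.85).
#' @return Tibble per cohort (plus a `pooled` row when several):
#'   `cohort`, `n_samples`, `n_early`, `n_late`.
#' @export
timing_summary <- function(timing_calls, cutoff = 0.85) {
  mad <- timing_calls %>%
    filter(.data$is_mad, .data$status == "ok")
  if (!"cohort" %in% names(mad)) mad$cohort <- "all"
  mad <- mad %>%
    group_by(.data$sample_id, .data$cohort) %>%
    summarise(early = any(.data$tumor_af >= cutoff), .groups = "drop")
  out <- mad %>%
    group_by(.data$cohort) %>%
    summarise(
      n_samples = dplyr::n(),
      n_early = sum(.data$early),
      n_late = sum(!.data$early),
      .groups = "drop"
    )
  if (nrow(out) > 1) {
    out <- bind_rows(out, tibble(
      cohort = "pooled",
      n_samples = sum(out$n_samples),
      n_early = sum(out$n_early),
      n_late = sum(out$n_late)
    ))
  }
  out
}

#' Exact binomial test by outcome enumeration
#'
#' Sums the binomial probability mass directly. The two-sided p-value uses
#' the minimum-likelihood convention: the sum of probabilities of all
#' outcomes no more likely than the observed one.
#'
#' @param k Observed successes.
#' @param n Trials (> 0).
#' @param p0 Null success probability (default 0.5).
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @return p-value.
#' @export
#' @examples
#' binomial_enrichment(35, 39)  # 3.4e-7: early MAD mutations in 35/39
#' binomial_enrichment(8, 11)   # 0.23: maternal LOH on 8/11 chromosomes
binomial_enrichment <- function(k, n, p0 = 0.5, sided = c("two", "greater",
                                                          "less")) {
  sided <- match.arg(sided)
  if (n == 0) abort("n must be > 0")
  if (k < 0 || k > n) abort("k must lie in [0, n]")
  d <- dbinom(0:n, n, p0)
  p <- switch(
    sided,
    greater = sum(d[(k:n) + 1]),
    less = sum(d[0:k + 1]),
    two = sum(d[d <= d[k + 1] * (1 + 1e-7)])
  )
  min(1, p)
}

#' Per-gene enrichment of early mutations, Bonferroni-adjusted
#'
#' For each MAD gene, tests whether the count of mutations with tumor
#' allelic fraction at or above the cutoff exceeds the binomial null
#' (p0 = 0.5), multiplying p by the number of genes tested (capped at 1).
#'
#' @param timing_calls Output of [select_copy_model()].
#' @param cutoff Cancer-chromosome-fraction cutoff.
#' @param genes Genes tested (default MEN1, ATRX, DAXX).
#' @param p0 Null probability of an early call.
#' @return Tibble: `gene`, `n`, `k_early`, `p_raw`, `p_adj`.
#' @export
gene_enrichment <- function(timing_calls, cutoff = 0.85,
                            genes = c("MEN1", "ATRX", "DAXX"), p0 = 0.5) {
  purrr::map(genes, function(g) {
    calls <- timing_calls %>%
      filter(.data$gene == g, .data$status == "ok")
    if (nrow(calls) == 0) {
      return(tibble(gene = g, n = 0L, k_early = 0L,
                    p_raw = NA_real_, p_adj = NA_real_))
    }
    k <- sum(calls$tumor_af >= cutoff)
    p <- binomial_enrichment(k, nrow(calls), p0 = p0)
    tibble(gene = g, n = nrow(calls), k_early = as.integer(k),
           p_raw = p, p_adj = min(1, p * length(genes)))
  }) %>% bind_rows()
}
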