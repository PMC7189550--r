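# Per-chromosome copy/zygosity calling from binned sWGS counts, cohort
# motif summaries, co-occurrence of copy-number states, Jaccard concordance
# of aberrant profiles, Scarpa karyotype groups, and CI stratification.

#' Purity-adjusted allelic fraction
#'
#' Removes the normal-cell contribution from an observed allelic fraction at
#' a germline-heterozygous site, giving the allelic fraction within the
#' tumor compartment:
#' `af_t = (af_obs * (p*total_cn + 2*(1-p)) - (1-p)) / (p*total_cn)`,
#' clipped to `[0, 1]`.
#'
#' @param af_obs Observed bulk allelic fraction(s).
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Total tumor copy number at the locus (> 0).
#' @return Tumor-compartment allelic fraction(s).
#' @export
#' @examples
#' purity_adjusted_af(0.75, purity = 0.5, total_cn = 2)  # 1: complete LOH
#' purity_adjusted_af(0.5, purity = 0.7, total_cn = 2)   # 0.5: balanced site
purity_adjusted_af <- function(af_obs, purity, total_cn) {
  if (any(total_cn == 0)) abort("total_cn must be positive")
  if (any(purity <= 0 | purity > 1)) abort("purity must be in (0, 1]")
  mix <- purity * total_cn + 2 * (1 - purity)
  pmin(1, pmax(0, (af_obs * mix - (1 - purity)) / (purity * total_cn)))
}

# Expected fraction of germline het SNPs still observed het when the tumor
# compartment has lost one allele completely: only admixed normal DNA
# contributes the second allele.
loh_het_retention <- function(purity, total_cn = 2) {
  2 * (1 - purity) / (purity * total_cn + 2 * (1 - purity))
}

#' Call per-chromosome copy and zygosity states from binned counts
#'
#' Pseudo allele-specific calling from shallow-WGS bins: the copy state of a
#' chromosome comes from its median normalized read count (anchored on the
#' modal chromosome, taken as copy 2, and corrected for the purity mixture),
#' and its zygosity from the heterozygous-SNP retention ratio
#' `r = observed / expected`. A chromosome is called LOH when `r` falls
#' below the midpoint between the retention expected under complete tumor
#' LOH and 1, HET when `r` is near 1, and unknown in between.
#'
#' @param binned Bin tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `read_count`, `het_snp_count`) for one sample.
#' @param purity Tumor purity; below 0.3 the call is still made but flagged,
#'   since low cellularity can obscure the signal.
#' @param germline_het_density Expected het SNPs per bin in germline.
#' @return Whole-chromosome segment tibble: `sample_id`, `chrom`, `start`,
#'   `end`, `total_cn`, `minor_cn`, `zygosity` (`LOH`/`HET`/`unknown`),
#'   `het_retention`, `low_purity`.
#' @export
call_chromosome_states <- function(binned, purity, germline_het_density) {
  if (germline_het_density <= 0) abort("germline_het_density must be > 0")
  low_purity <- purity <= 0.3
  if (low_purity) {
    warn("purity <= 0.3: copy/zygosity signal may be obscured")
  }
  per_chrom <- binned %>%
    group_by(.data$sample_id, .data$chrom) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      med_reads = median(.data$read_count),
      het_retention = sum(.data$het_snp_count) /
        (germline_het_density * dplyr::n()),
      .groups = "drop"
    )
  baseline <- median(per_chrom$med_reads)  # modal chromosome ~ copy 2
  per_chrom %>%
    mutate(
      ratio = .data$med_reads / baseline,
      total_cn = pmax(0, round((2 * .data$ratio - 2 * (1 - purity)) / purity)),
      loh_floor = loh_het_retention(purity, pmax(1, .data$total_cn)),
      thr_loh = (.data$loh_floor + 1) / 2,
      thr_het = (.data$thr_loh + 1) / 2,
      zygosity = case_when(
        .data$het_retention < .data$thr_loh ~ "LOH",
        .data$het_retention >= .data$thr_het ~ "HET",
        TRUE ~ "unknown"
      ),
      minor_cn = case_when(
        .data$zygosity == "LOH" ~ 0,
        .data$zygosity == "HET" ~ 1,
        TRUE ~ NA_real_
      ),
      low_purity = low_purity
    ) %>%
    select("sample_id", "chrom", "start", "end", "total_cn", "minor_cn",
           "zygosity", "het_retention", "low_purity") %>%
    arrange(factor(.data$chrom, levels = chrom_levels()))
}

#' Cohort motif: most recurrent state per chromosome
#'
#' Summarizes a cohort of segment profiles into the modal zygosity and copy
#' state of each chromosome, with their frequencies. Ties are reported as
#' multi-modal (states joined with "/"), never silently broken.
#'
#' @param segments Cohort segment tibble (whole-chromosome rows).
#' @return Tibble per chromosome: `chrom`, `modal_zygosity`,
#'   `zygosity_freq`, `multimodal_zygosity`, `modal_copy`, `copy_freq`,
#'   `multimodal_copy`, `n_samples`.
#' @export
cohort_motif <- function(segments) {
  modal <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    list(state = paste(sort(top), collapse = "/"),
         freq = max(tab) / length(x),
         multi = length(top) > 1)
  }
  copy_state <- function(cn) {
    case_when(cn < 2 ~ "loss", cn == 2 ~ "neutral", TRUE ~ "gain")
  }
  segments %>%
    group_by(.data$chrom) %>%
    summarise(
      z = list(modal(.data$zygosity)),
      k = list(modal(copy_state(.data$total_cn))),
      n_samples = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    ) %>%
    mutate(
      modal_zygosity = purrr::map_chr(.data$z, "state"),
      zygosity_freq = purrr::map_dbl(.data$z, "freq"),
      multimodal_zygosity = purrr::map_lgl(.data$z, "multi"),
      modal_copy = purrr::map_chr(.data$k, "state"),
      copy_freq = purrr::map_dbl(.data$k, "freq"),
      multimodal_copy = purrr::map_lgl(.data$k, "multi")
    ) %>%
    select(-"z", -"k") %>%
    arrange(factor(.data$chrom, levels = chrom_levels()))
}

#' Co-occurrence and antagonism of chromosome-level aberrations
#'
#' Builds per-sample binary indicators for each chromosome-level aberration
#' (LOH, copy loss, copy gain) and computes the pairwise phi coefficient
#' across samples. Pairs with `phi >= tau` are flagged synchronous, pairs
#' with `phi <= -tau` antagonistic.
#'
#' @param segments Cohort segment tibble.
#' @param tau Flagging threshold on |phi| (default 0.5).
#' @param min_support Minimum samples carrying an aberration for it to enter
#'   the matrix.
#' @return Tibble of aberration pairs: `aberration_a`, `aberration_b`,
#'   `phi`, `n_a`, `n_b`, `flag` (`synchronous`/`antagonistic`/`none`).
#' @export
signature_cooccurrence <- function(segments, tau = 0.5, min_support = 2) {
  ind <- segments %>%
    mutate(
      loh = .data$zygosity == "LOH",
      loss = .data$total_cn < 2,
      gain = .data$total_cn > 2
    ) %>%
    select("sample_id", "chrom", "loh", "loss", "gain") %>%
    tidyr::pivot_longer(c("loh", "loss", "gain"),
                        names_to = "kind", values_to = "present") %>%
    mutate(aberration = paste0(.data$chrom, ":", .data$kind)) %>%
    select("sample_id", "aberration", "present") %>%
    tidyr::pivot_wider(names_from = "aberration", values_from = "present")
  mat <- as.matrix(ind[, -1]) * 1
  support <- colSums(mat)
  keep <- support >= min_support & support <= nrow(mat) - min_support
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) < 2) {
    return(tibble(aberration_a = character(), aberration_b = character(),
                  phi = double(), n_a = integer(), n_b = integer(),
                  flag = character()))
  }
  phi_mat <- suppressWarnings(cor(mat))
  pairs <- which(upper.tri(phi_mat), arr.ind = TRUE)
  phi_v <- phi_mat[pairs]
  tibble(
    aberration_a = colnames(phi_mat)[pairs[, 1]],
    aberration_b = colnames(phi_mat)[pairs[, 2]],
    phi = phi_v,
    n_a = as.integer(support[keep][pairs[, 1]]),
    n_b = as.integer(support[keep][pairs[, 2]]),
    flag = case_when(
      phi_v >= tau ~ "synchronous",
      phi_v <= -tau ~ "antagonistic",
      TRUE ~ "none"
    )
  )
}

#' Jaccard concordance of two aberrant-band profiles
#'
#' `J = |A intersect B| / |A union B|` over cytobands marked aberrant,
#' state-matched (a loss only matches a loss, a gain only a gain). Joint
#' absences (both neutral) are uninformative and ignored.
#'
#' @param profile_a,profile_b Tibbles with a band key column (`band` or
#'   `chrom`) and a `status` column in `{loss, neutral, gain}`.
#' @param key Name of the band key column.
#' @return Jaccard index in `[0, 1]`; 1 when both profiles have no aberrant
#'   bands at all (identical empty sets) is defined as `NA`.
#' @export
#' @examples
#' a <- tibble::tibble(band = c("b1", "b2", "b3"),
#'                     status = c("loss", "loss", "loss"))
#' b <- tibble::tibble(band = c("b1", "b2", "b4"),
#'                     status = c("loss", "loss", "loss"))
#' jaccard_concordance(a, b)  # 2 shared / 4 in union = 0.5
jaccard_concordance <- function(profile_a, profile_b, key = NULL) {
  if (is.null(key)) {
    key <- if ("band" %in% names(profile_a)) "band" else "chrom"
  }
  lab <- function(p) {
    p <- as_tibble(p)
    # only loss/gain states enter; neutral, unknown and conflicting bands
    # are uninformative for concordance
    p <- p[p$status %in% c("loss", "gain"), , drop = FALSE]
    if (nrow(p) == 0) return(character(0))
    paste0(p[[key]], ":", p$status)
  }
  a <- unique(lab(profile_a))
  b <- unique(lab(profile_b))
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard concordance across a cohort
#'
#' @param profiles Long tibble (`sample_id`, band key, `status`).
#' @param key Band key column (default `band` if present, else `chrom`).
#' @return Symmetric matrix of Jaccard indices (diagonal 1).
#' @export
jaccard_matrix <- function(profiles, key = NULL) {
  if (is.null(key)) {
    key <- if ("band" %in% names(profiles)) "band" else "chrom"
  }
  ids <- unique(profiles$sample_id)
  split_p <- split(profiles, profiles$sample_id)
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jc <- jaccard_concordance(split_p[[ids[i]]], split_p[[ids[j]]], key)
      m[i, j] <- m[j, i] <- ifelse(is.na(jc), 0, jc)
    }
  }
  m
}

# Genome fractions (by base pairs) in each karyotype class for one sample.
genome_fractions <- function(segments) {
  w <- segments$end - segments$start
  total <- sum(w)
  tibble(
    loss = sum(w[segments$total_cn < 2]) / total,
    cnloh = sum(w[segments$total_cn == 2 & segments$zygosity == "LOH"]) / total,
    gain = sum(w[segments$total_cn > 2]) / total
  ) %>%
    mutate(aberrant = .data$loss + .data$cnloh + .data$gain)
}

#' Classify a profile into Scarpa karyotype groups G1-G4
#'
#' Rule-based labels from genome fractions: G1 when copy loss affects more
#' than half the genome; G3 when gains affect (nearly) all of it; G2 when
#' the genome is essentially diploid with little LOH or loss; G4 otherwise
#' (the mixed CN-LOH / gain karyotype).
#'
#' @param segments Segment tibble for one sample.
#' @param g3_gain_fraction Gain fraction treated as "~100% of the genome".
#' @param g2_aberrant_max Maximum aberrant fraction still called diploid.
#' @return `"G1"`, `"G2"`, `"G3"` or `"G4"`.
#' @export
classify_scarpa_group <- function(segments, g3_gain_fraction = 0.9,
                                  g2_aberrant_max = 0.1) {
  f <- genome_fractions(segments)
  if (f$loss > 0.5) return("G1")
  if (f$gain >= g3_gain_fraction) return("G3")
  if (f$aberrant <= g2_aberrant_max) return("G2")
  "G4"
}

#' Chromosomal-instability stratum of a profile
#'
#' @param segments Segment tibble for one sample.
#' @param threshold Aberrant genome fraction at or above which the sample is
#'   high-CI (default 0.2).
#' @return `"high-CI"` or `"low-CI"`.
#' @export
ci_stratum <- function(segments, threshold = 0.2) {
  f <- genome_fractions(segments)
  if (f$aberrant >= threshold) "high-CI" else "low-CI"
}

#' Extract the recurrent zygosity signature from a cohort motif
#'
#' Chromosomes whose modal zygosity recurs in at least `min_freq` of
#' samples are assigned to the LOH or heterozygous signature set;
#' chromosomes below that recurrence (or with tied modes) are reported as
#' variable. The threshold separates consistently aberrant chromosomes
#' from those aberrant in only about half the cohort.
#'
#' @param motif Output of [cohort_motif()].
#' @param min_freq Minimal modal-state frequency for a chromosome to count
#'   as part of the signature (default 0.75).
#' @return List with `loh`, `het` and `variable` chromosome vectors.
#' @export
signature_from_motif <- function(motif, min_freq = 0.75) {
  consistent <- !motif$multimodal_zygosity & motif$zygosity_freq >= min_freq
  list(
    loh = motif$chrom[consistent & motif$modal_zygosity == "LOH"],
    het = motif$chrom[consistent & motif$modal_zygosity == "HET"],
    variable = motif$chrom[!consistent]
  )
}
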