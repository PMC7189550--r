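# Synthetic-cohort generator: emulates the statistical structure of every
# input the pipeline consumes (purity, allele-specific copy states, somatic
# allelic fractions, binned sWGS counts, RNA allelic fractions, expression
# with pericentromeric repression, trio genotypes, CGH gain/loss profiles)
# so the full analysis chain runs without external data. Ground-truth labels
# are always emitted alongside the data.

# Approximate hg19 chromosome lengths and centromere (acen) spans, used to
# build a synthetic ideogram at realistic genomic scale.
HG19_SCALE <- tibble::tribble(
  ~chrom,   ~length,    ~cen_start, ~cen_end,
  "chr1",   249250621L, 121500000L, 128900000L,
  "chr2",   243199373L,  90500000L,  96800000L,
  "chr3",   198022430L,  87900000L,  93900000L,
  "chr4",   191154276L,  48200000L,  52700000L,
  "chr5",   180915260L,  45800000L,  50700000L,
  "chr6",   171115067L,  58400000L,  63300000L,
  "chr7",   159138663L,  58000000L,  61700000L,
  "chr8",   146364022L,  43100000L,  48100000L,
  "chr9",   141213431L,  47300000L,  50700000L,
  "chr10",  135534747L,  38000000L,  42300000L,
  "chr11",  135006516L,  51600000L,  55700000L,
  "chr12",  133851895L,  33300000L,  38200000L,
  "chr13",  115169878L,  16300000L,  19500000L,
  "chr14",  107349540L,  16100000L,  19100000L,
  "chr15",  102531392L,  15800000L,  20700000L,
  "chr16",   90354753L,  34600000L,  38600000L,
  "chr17",   81195210L,  22200000L,  25800000L,
  "chr18",   78077248L,  15400000L,  19000000L,
  "chr19",   59128983L,  24400000L,  28600000L,
  "chr20",   63025520L,  25600000L,  29400000L,
  "chr21",   48129895L,  10900000L,  14300000L,
  "chr22",   51304566L,  12200000L,  17900000L,
  "chrX",   155270560L,  58100000L,  63000000L
)

#' Synthetic hg19-scale cytoband ideogram
#'
#' Builds a deterministic cytoband table with approximately-hg19 chromosome
#' lengths and centromere positions: each arm carries one periCEN band
#' flanking the acen pair plus three outer bands. It is a synthetic stand-in
#' for a real cytoBandIdeo annotation, adequate for fractional-distance and
#' band-assignment analyses; it is not the UCSC band structure.
#'
#' @return Cytoband tibble in the same shape as [read_cytobands()] output.
#' @export
synthetic_cytobands <- function() {
  one <- function(chrom, len, cs, ce) {
    mid <- round((cs + ce) / 2)
    rows <- list()
    add <- function(start, end, band, stain) {
      if (end > start) {
        rows[[length(rows) + 1]] <<- tibble(
          chrom = chrom, start = start, end = end, band = band, stain = stain
        )
      }
    }
    # p arm (telomere -> centromere): three outer bands, then the periCEN
    # flank band. Flank width scales with arm length so flank sizes differ
    # across chromosomes.
    p_flank <- max(1e6, min(round(0.06 * cs), 8e6))
    outer_end <- cs - p_flank
    cuts <- round(seq(0, outer_end, length.out = 4))
    add(cuts[1], cuts[2], "p13", "gneg")
    add(cuts[2], cuts[3], "p12.2", "gpos50")
    add(cuts[3], outer_end, "p12.1", "gneg")
    add(outer_end, cs, "p11.2", "gneg")
    # acen pair
    add(cs, mid, "p11.1", "acen")
    add(mid, ce, "q11.1", "acen")
    # q arm (centromere -> telomere): flank band then three outer bands
    q_flank <- max(1e6, min(round(0.06 * (len - ce)), 8e6))
    add(ce, ce + q_flank, "q11.2", "gneg")
    cuts <- round(seq(ce + q_flank, len, length.out = 4))
    add(cuts[1], cuts[2], "q12", "gpos50")
    add(cuts[2], cuts[3], "q21", "gneg")
    add(cuts[3], cuts[4], "q22", "gpos50")
    bind_rows(rows)
  }
  out <- purrr::pmap(
    list(HG19_SCALE$chrom, HG19_SCALE$length,
         HG19_SCALE$cen_start, HG19_SCALE$cen_end),
    one
  ) %>% bind_rows()
  validate_cytobands(out)
}

#' Simulation configuration
#'
#' Defines the cohort conditions the generator emulates: the MAD+ LOH/gain
#' signature chromosome sets, tumor purity range, sequencing depth, genome
#' doubling frequency, monoallelic-expression gene fraction, and the depth
#' and width of pericentromeric expression repression.
#'
#' @param n_samples Cohort size.
#' @param seed Integer seed fixing all draws.
#' @param purity_range Tumor purity sampled uniformly from this interval.
#' @param mad_positive_fraction Fraction of samples carrying a MAD mutation.
#' @param loh_chromosomes,het_chromosomes,variable_chromosomes Disjoint
#'   signature sets; defaults are the recurrent MAD+ karyotype
#'   ([signature_chromosomes()]).
#' @param depth_mean Mean sequencing depth at somatic mutation loci.
#' @param genome_doubled_fraction Probability a MAD+ sample is genome
#'   doubled (gains on the heterozygous chromosomes).
#' @param mae_gene_fraction Fraction of genes with monoallelic expression in
#'   the RNA SNP simulation.
#' @param repression_depth Pericentromeric repression effect, in z-units.
#' @param repression_width Fractional-distance window of the repression.
#' @param background_aberration_rate Per-chromosome aberration rate in MAD-
#'   (and off-signature MAD+) genomes.
#' @param reads_per_bin Expected sWGS read count per 500 kb bin at copy 2.
#' @param het_snps_per_bin Expected germline heterozygous SNPs per bin.
#' @param bin_size Bin width in bp.
#' @param mad_gene_probs Named probabilities for which MAD gene is mutated.
#' @param true_or True high-CI vs metastasis odds ratio in the CGH cohort.
#' @param baseline_met_rate Metastasis probability in low-CI samples.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 30,
                       seed = 1L,
                       purity_range = c(0.4, 0.9),
                       mad_positive_fraction = 0.6,
                       loh_chromosomes = signature_chromosomes()$loh,
                       het_chromosomes = signature_chromosomes()$het,
                       variable_chromosomes = signature_chromosomes()$variable,
                       depth_mean = 200,
                       genome_doubled_fraction = 0.5,
                       mae_gene_fraction = 0.02,
                       repression_depth = 0.8,
                       repression_width = 0.025,
                       background_aberration_rate = 0.05,
                       reads_per_bin = 1000,
                       het_snps_per_bin = 100,
                       bin_size = 5e5,
                       mad_gene_probs = c(MEN1 = 0.6, DAXX = 0.4),
                       true_or = 4.35,
                       baseline_met_rate = 0.25) {
  loh_chromosomes <- normalize_chrom(loh_chromosomes)
  het_chromosomes <- normalize_chrom(het_chromosomes)
  variable_chromosomes <- normalize_chrom(variable_chromosomes)
  if (length(intersect(loh_chromosomes, het_chromosomes)) > 0 ||
      length(intersect(loh_chromosomes, variable_chromosomes)) > 0 ||
      length(intersect(het_chromosomes, variable_chromosomes)) > 0) {
    abort("signature chromosome sets must be disjoint")
  }
  if (length(purity_range) != 2 || purity_range[1] <= 0 ||
      purity_range[2] > 1 || purity_range[1] > purity_range[2]) {
    abort("purity_range must be an interval within (0, 1]")
  }
  if (repression_width <= 0 || repression_width >= 1) {
    abort("repression_width must be a fractional distance in (0, 1)")
  }
  structure(
    list(
      n_samples = n_samples, seed = as.integer(seed),
      purity_range = purity_range,
      mad_positive_fraction = mad_positive_fraction,
      loh_chromosomes = loh_chromosomes,
      het_chromosomes = het_chromosomes,
      variable_chromosomes = variable_chromosomes,
      depth_mean = depth_mean,
      genome_doubled_fraction = genome_doubled_fraction,
      mae_gene_fraction = mae_gene_fraction,
      repression_depth = repression_depth,
      repression_width = repression_width,
      background_aberration_rate = background_aberration_rate,
      reads_per_bin = reads_per_bin,
      het_snps_per_bin = het_snps_per_bin,
      bin_size = bin_size,
      mad_gene_probs = mad_gene_probs,
      true_or = true_or,
      baseline_met_rate = baseline_met_rate
    ),
    class = "sim_config"
  )
}

# Fan one global seed out to per-stage child seeds (stable string hash,
# kept below 2^31 so it is a valid R integer seed).
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Expected observed allelic fraction under the purity/copy model
#'
#' The bulk allelic fraction of a somatic mutation carried on `m` of `n`
#' tumor copies in a sample of purity `p`, with `normal_copy` copies in the
#' admixed normal cells: `p*m / (p*n + normal_copy*(1-p))`.
#'
#' @param purity Tumor purity in (0, 1].
#' @param m Mutation-bearing copies.
#' @param n Total tumor copies at the locus.
#' @param normal_copy Copies in normal cells (2 autosomal, 1 male chrX).
#' @return Expected observed allelic fraction.
#' @export
expected_af <- function(purity, m, n, normal_copy = 2) {
  purity * m / (purity * n + normal_copy * (1 - purity))
}

#' Simulate one tumor sample
#'
#' Draws a whole-chromosome allele-specific copy profile, a truncal MAD
#' mutation (for MAD+ samples; mutated on every tumor copy of its LOH
#' chromosome, i.e. m = n, so it precedes the LOH event), and a handful of
#' late passenger mutations. Observed allelic fractions are binomial draws
#' around the purity/copy model expectation.
#'
#' @param config A [sim_config()].
#' @param mad_status `"MAD+"` or `"MAD-"`.
#' @param sample_id Sample label.
#' @param purity Optional fixed purity; drawn from `config$purity_range`
#'   when `NULL`.
#' @return List with `segments`, `mutations` (including ground-truth
#'   `true_m`, `true_n`, `true_timing`), and one-row `meta`.
#' @export
simulate_sample <- function(config, mad_status = c("MAD+", "MAD-"),
                            sample_id = "S1", purity = NULL) {
  mad_status <- match.arg(mad_status)
  if (is.null(purity)) {
    purity <- runif(1, config$purity_range[1], config$purity_range[2])
  }
  doubled <- mad_status == "MAD+" &&
    runif(1) < config$genome_doubled_fraction
  chroms <- AUTOSOMES
  lens <- HG19_SCALE$length[match(chroms, HG19_SCALE$chrom)]

  state_of <- function(chrom) {
    if (mad_status == "MAD+") {
      if (chrom %in% config$loh_chromosomes) {
        c(total = 2, minor = 0)                      # copy-neutral LOH
      } else if (chrom %in% config$het_chromosomes) {
        if (doubled) c(total = 3, minor = 1) else c(total = 2, minor = 1)
      } else if (chrom %in% config$variable_chromosomes) {
        if (runif(1) < 0.5) c(total = 2, minor = 0) else c(total = 2, minor = 1)
      } else {
        c(total = 2, minor = 1)
      }
    } else {
      if (runif(1) < config$background_aberration_rate) {
        # sporadic aberration with no chromosome preference
        if (runif(1) < 0.5) c(total = 1, minor = 0) else c(total = 3, minor = 1)
      } else {
        c(total = 2, minor = 1)
      }
    }
  }
  states <- purrr::map(chroms, state_of)
  segments <- tibble(
    sample_id = sample_id,
    chrom = chroms,
    start = 0,
    end = lens,
    total_cn = purrr::map_dbl(states, "total"),
    minor_cn = purrr::map_dbl(states, "minor")
  ) %>%
    mutate(zygosity = if_else(.data$minor_cn == 0, "LOH", "HET"))

  draw_mutation <- function(gene, chrom, m, n, is_mad) {
    depth <- max(30L, rpois(1, config$depth_mean))
    af_true <- expected_af(purity, m, n)
    tibble(
      sample_id = sample_id, gene = gene, chrom = chrom,
      pos = round(runif(1, 1e6, lens[match(chrom, chroms)] - 1e6)),
      af_obs = rbinom(1, depth, af_true) / depth,
      depth = depth, is_mad = is_mad,
      true_m = m, true_n = n,
      true_timing = if (m == n && n >= 2) "early" else "late"
    )
  }

  muts <- list()
  if (mad_status == "MAD+") {
    gene <- sample(names(config$mad_gene_probs), 1,
                   prob = config$mad_gene_probs)
    gchrom <- c(MEN1 = "chr11", DAXX = "chr6", ATRX = "chrX")[[gene]]
    seg <- segments[segments$chrom == gchrom, ]
    n_tot <- seg$total_cn[1]
    # truncal MAD mutation precedes LOH: present on every retained copy
    muts$mad <- draw_mutation(gene, gchrom, m = n_tot, n = n_tot, is_mad = TRUE)
  }
  n_pass <- rpois(1, 3)
  if (n_pass > 0) {
    for (i in seq_len(n_pass)) {
      pchrom <- sample(chroms, 1)
      n_tot <- segments$total_cn[segments$chrom == pchrom]
      muts[[paste0("p", i)]] <- draw_mutation(
        paste0("PASS", i), pchrom, m = 1, n = n_tot, is_mad = FALSE
      )
    }
  }
  mutations <- bind_rows(muts)

  meta <- tibble(
    sample_id = sample_id,
    mad_status = mad_status,
    purity = purity,
    pathologist_purity = pmin(1, pmax(0.05, purity + rnorm(1, 0, 0.03))),
    genome_doubled = doubled,
    sex = sample(c("female", "male"), 1)
  )
  list(segments = segments, mutations = mutations, meta = meta)
}

#' Simulate a tumor cohort
#'
#' @param config A [sim_config()]; `config$seed` fixes all draws.
#' @return List with cohort-level `segments`, `mutations`, `meta` tibbles.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 4, seed = 7))
#' cohort$meta
simulate_cohort <- function(config) {
  set.seed(child_seed(config$seed, "cohort"))
  n_pos <- round(config$n_samples * config$mad_positive_fraction)
  status <- c(rep("MAD+", n_pos), rep("MAD-", config$n_samples - n_pos))
  sims <- purrr::imap(status, function(st, i) {
    simulate_sample(config, st, sample_id = sprintf("S%03d", i))
  })
  list(
    segments = purrr::map(sims, "segments") %>% bind_rows(),
    mutations = purrr::map(sims, "mutations") %>% bind_rows(),
    meta = purrr::map(sims, "meta") %>% bind_rows()
  )
}

#' Simulate binned shallow-WGS counts for a segment profile
#'
#' Tiles fixed-size bins across each chromosome and draws per-bin read
#' counts as Poisson around the purity-mixture copy ratio, and heterozygous
#' SNP counts as binomial thinning of the germline density: on LOH
#' chromosomes only the admixed normal cells contribute het SNPs, with
#' retention `2(1-p) / (p*total_cn + 2(1-p))`.
#'
#' @param segments Whole-chromosome segment tibble for one sample.
#' @param purity Tumor purity of the sample.
#' @param config A [sim_config()] (bin size, read and het densities).
#' @return Tibble of bins: `sample_id`, `chrom`, `start`, `end`,
#'   `read_count`, `het_snp_count`.
#' @export
simulate_binned_counts <- function(segments, purity, config = sim_config()) {
  one_chrom <- function(seg) {
    len <- seg$end[1]
    starts <- seq(0, len - 1, by = config$bin_size)
    ends <- pmin(starts + config$bin_size, len)
    mix <- purity * seg$total_cn[1] + 2 * (1 - purity)
    ratio <- mix / 2
    retention <- if (seg$minor_cn[1] == 0) {
      2 * (1 - purity) / mix
    } else {
      1
    }
    tibble(
      sample_id = seg$sample_id[1], chrom = seg$chrom[1],
      start = starts, end = ends,
      read_count = rpois(length(starts), config$reads_per_bin * ratio),
      het_snp_count = rbinom(length(starts), config$het_snps_per_bin,
                             retention)
    )
  }
  segments %>%
    group_by(.data$chrom) %>%
    dplyr::group_split() %>%
    purrr::map(one_chrom) %>%
    bind_rows()
}

#' Simulate an expression cohort with pericentromeric repression
#'
#' Places genes uniformly along chromosome arms, draws normalized expression
#' for MAD+ and MAD- samples, and represses genes within
#' `config$repression_width` fractional distance of the centromere on the
#' LOH chromosomes in MAD+ samples by `config$repression_depth` z-units.
#'
#' @param config A [sim_config()]; the cohort is split MAD+/MAD- by
#'   `mad_positive_fraction`.
#' @param arms Arm tibble; defaults to the synthetic ideogram.
#' @param n_genes Number of genes to place.
#' @return List with `genes` (coordinates + `arm`, `frac_dist` +
#'   ground-truth `true_repressed`), `expr` (long tibble gene x sample), and
#'   `meta` (sample MAD labels).
#' @export
simulate_expression <- function(config,
                                arms = chromosome_arms(synthetic_cytobands()),
                                n_genes = 15000) {
  set.seed(child_seed(config$seed, "expression"))
  arms <- arms %>% filter(.data$chrom %in% AUTOSOMES, .data$has_centromere)
  n_per_arm <- pmax(1, round(n_genes * arms$arm_length / sum(arms$arm_length)))
  genes <- purrr::map2(seq_len(nrow(arms)), n_per_arm, function(i, k) {
    a <- arms[i, ]
    mid <- round(runif(k, a$arm_start, a$arm_end))
    tibble(chrom = a$chrom, arm = a$arm, start = mid - 500, end = mid + 500,
           frac_dist = abs(mid - a$centromere_boundary) / a$arm_length)
  }) %>%
    bind_rows() %>%
    mutate(gene = sprintf("G%05d", row_number())) %>%
    select("gene", dplyr::everything())

  n_pos <- round(config$n_samples * config$mad_positive_fraction)
  meta <- tibble(
    sample_id = sprintf("S%03d", seq_len(config$n_samples)),
    mad_status = c(rep("MAD+", n_pos), rep("MAD-", config$n_samples - n_pos))
  )
  genes$true_repressed <- genes$chrom %in% config$loh_chromosomes &
    genes$frac_dist < config$repression_width

  base <- rnorm(nrow(genes), 0, 1)  # gene-level baseline
  expr <- tidyr::expand_grid(gene = genes$gene, sample_id = meta$sample_id) %>%
    left_join(meta, by = "sample_id") %>%
    left_join(genes %>% select("gene", "true_repressed") %>%
                mutate(.base = base), by = "gene") %>%
    mutate(
      value = .data$.base + rnorm(dplyr::n(), 0, 1) -
        if_else(.data$true_repressed & .data$mad_status == "MAD+",
                config$repression_depth, 0)
    ) %>%
    select("gene", "sample_id", "value")
  list(genes = genes, expr = expr, meta = meta)
}

#' Simulate RNA SNP allelic fractions with monoallelic genes
#'
#' Draws per-gene SNP allelic fractions for one sample: biallelic genes
#' scatter around 0.5; a `config$mae_gene_fraction` subset is monoallelic
#' with folded allelic fraction near `mae_af`.
#'
#' @param config A [sim_config()].
#' @param n_genes Genes with at least `snps_per_gene` SNPs.
#' @param snps_per_gene SNP count per gene (recycled).
#' @param depth_mean Mean read support per SNP.
#' @param mae_af Folded allelic fraction of monoallelic genes.
#' @return Tibble of SNP observations: `gene`, `chrom`, `pos`, `af`,
#'   `depth`, ground-truth `true_mae`.
#' @export
simulate_rna_snps <- function(config, n_genes = 200, snps_per_gene = 3,
                              depth_mean = 50, mae_af = 0.95) {
  set.seed(child_seed(config$seed, "rna_snps"))
  snps_per_gene <- rep_len(snps_per_gene, n_genes)
  is_mae <- runif(n_genes) < config$mae_gene_fraction
  purrr::map(seq_len(n_genes), function(g) {
    k <- snps_per_gene[g]
    depth <- pmax(10L, rpois(k, depth_mean))
    p <- if (is_mae[g]) mae_af else 0.5
    # each SNP independently picks which haplotype is over-expressed
    p_snp <- ifelse(runif(k) < 0.5, p, 1 - p)
    tibble(
      gene = sprintf("G%04d", g),
      chrom = sample(AUTOSOMES, 1),
      pos = sort(round(runif(k, 1e6, 1e8))),
      af = rbinom(k, depth, p_snp) / depth,
      depth = depth,
      true_mae = is_mae[g]
    )
  }) %>% bind_rows()
}

#' Simulate trio genotypes for parental-skew analysis
#'
#' For each LOH chromosome draws a ground-truth retained parent and emits
#' SNP allelic fractions for the child germline (heterozygous), the mother,
#' and the tumor, consistent with copy-neutral LOH at the given purity.
#' Heterozygous chromosomes retain tumor heterozygosity.
#'
#' @param config A [sim_config()].
#' @param purity Tumor purity (discretization at AF 0.8/0.2 needs >= 0.6).
#' @param n_snps SNPs per chromosome.
#' @param maternal_prob Probability the retained homolog is maternal.
#' @param frac_informative Fraction of SNPs homozygous in the mother.
#' @return List with `snps` (tibble: `chrom`, `pos`, `af_child_germline`,
#'   `af_maternal`, `af_tumor`) and `truth` (per-chromosome retained parent).
#' @export
simulate_trio <- function(config, purity = 0.9, n_snps = 200,
                          maternal_prob = 0.5, frac_informative = 0.4) {
  set.seed(child_seed(config$seed, "trio"))
  chroms <- c(config$loh_chromosomes, config$het_chromosomes)
  truth <- tibble(
    chrom = chroms,
    loh = chroms %in% config$loh_chromosomes
  ) %>%
    mutate(retained_parent = if_else(
      .data$loh,
      if_else(runif(dplyr::n()) < maternal_prob, "maternal", "paternal"),
      NA_character_
    ))
  jitter_af <- function(p, depth = 60) rbinom(length(p), depth, p) / depth
  snps <- purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    informative <- runif(n_snps) < frac_informative
    # informative: mother homozygous (alt or ref), child heterozygous, so the
    # child's maternal allele is the mother's allele
    mother_alt <- runif(n_snps) < 0.5
    af_maternal <- ifelse(informative, ifelse(mother_alt, 1, 0), 0.5)
    if (tr$loh) {
      retained_is_alt <- ifelse(
        rep(tr$retained_parent == "maternal", n_snps),
        mother_alt, !mother_alt
      )
      # bulk AF under copy-neutral LOH with normal admixture
      af_t <- ifelse(retained_is_alt, (1 + purity) / 2, (1 - purity) / 2)
    } else {
      af_t <- rep(0.5, n_snps)
    }
    tibble(
      chrom = tr$chrom,
      pos = sort(round(runif(n_snps, 1e6, 1e8))),
      af_child_germline = jitter_af(rep(0.5, n_snps)),
      af_maternal = jitter_af(af_maternal),
      af_tumor = jitter_af(af_t)
    )
  }) %>% bind_rows()
  list(snps = snps, truth = truth)
}

#' Simulate a multi-study CGH cohort with CI strata and metastasis labels
#'
#' Emulates a meta-analysis input: per study, samples are high- or
#' low-chromosomal-instability; high-CI genomes carry losses of the LOH
#' chromosomes and gains of the retained chromosomes, low-CI genomes are
#' near-flat. Metastasis is drawn so that the true high-CI vs low-CI odds
#' ratio equals `config$true_or`.
#'
#' @param config A [sim_config()].
#' @param study_sizes Samples per study.
#' @param high_ci_prob Probability a sample is high-CI.
#' @return List with `profiles` (long tibble sample x chromosome status),
#'   `meta` (sample: study, true CI stratum, metastasis), and `tables`
#'   (per-study 2x2 counts: high-CI met+, high-CI met-, low-CI met+,
#'   low-CI met-).
#' @export
simulate_cgh_cohort <- function(config,
                                study_sizes = c(28, 30, 25, 32, 20, 35, 26, 30),
                                high_ci_prob = 0.5) {
  set.seed(child_seed(config$seed, "cgh"))
  p0 <- config$baseline_met_rate
  odds1 <- config$true_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  samples <- purrr::imap(study_sizes, function(sz, si) {
    tibble(
      study_id = sprintf("study%02d", si),
      sample_id = sprintf("study%02d_s%03d", si, seq_len(sz)),
      high_ci = runif(sz) < high_ci_prob
    )
  }) %>%
    bind_rows() %>%
    mutate(metastasis = runif(dplyr::n()) < if_else(.data$high_ci, p1, p0))

  profile_one <- function(high_ci) {
    if (high_ci) {
      status <- case_when(
        AUTOSOMES %in% config$loh_chromosomes &
          runif(22) < 0.9 ~ "loss",
        AUTOSOMES %in% config$het_chromosomes &
          runif(22) < 0.6 ~ "gain",
        runif(22) < 0.05 ~ sample(c("loss", "gain"), 22, replace = TRUE),
        TRUE ~ "neutral"
      )
    } else {
      status <- ifelse(runif(22) < config$background_aberration_rate,
                       sample(c("loss", "gain"), 22, replace = TRUE),
                       "neutral")
    }
    tibble(chrom = AUTOSOMES, status = status)
  }
  profiles <- purrr::map2(samples$sample_id, samples$high_ci, function(id, hc) {
    profile_one(hc) %>% mutate(sample_id = id)
  }) %>%
    bind_rows() %>%
    left_join(samples %>% select("sample_id", "study_id"), by = "sample_id") %>%
    select("study_id", "sample_id", "chrom", "status")

  tables <- samples %>%
    group_by(.data$study_id) %>%
    summarise(
      a = sum(.data$high_ci & .data$metastasis),
      b = sum(.data$high_ci & !.data$metastasis),
      c = sum(!.data$high_ci & .data$metastasis),
      d = sum(!.data$high_ci & !.data$metastasis),
      .groups = "drop"
    )
  list(profiles = profiles, meta = samples, tables = tables)
}

#' Simulate CENP-A-like peaks concentrated near centromeres
#'
#' Places peaks along arms with an excess within the periCEN flanking bands,
#' for exercising the peak/cytoband summaries.
#'
#' @param config A [sim_config()].
#' @param arms Arm tibble.
#' @param n_peaks Total peaks.
#' @param pericen_fraction Fraction of peaks placed within the flank bands.
#' @return Peak tibble: `chrom`, `start`, `end`, `height`, `reads`.
#' @export
simulate_peaks <- function(config,
                           arms = chromosome_arms(synthetic_cytobands()),
                           n_peaks = 500, pericen_fraction = 0.5) {
  set.seed(child_seed(config$seed, "peaks"))
  arms <- arms %>% filter(.data$has_centromere)
  pick <- sample(nrow(arms), n_peaks, replace = TRUE,
                 prob = arms$arm_length)
  near <- runif(n_peaks) < pericen_fraction
  a <- arms[pick, ]
  offset <- ifelse(near,
                   runif(n_peaks, 0, pmin(a$flank_size, a$arm_length)),
                   runif(n_peaks, 0, a$arm_length - 1000))
  start <- round(ifelse(a$arm == "p",
                        a$centromere_boundary - offset - 500,
                        a$centromere_boundary + offset))
  start <- pmax(a$arm_start, pmin(start, a$arm_end - 500))
  width <- round(runif(n_peaks, 200, 2000))
  tibble(
    chrom = a$chrom,
    start = start,
    end = pmin(start + width, a$arm_end),
    height = round(exp(rnorm(n_peaks, log(10), 0.6)), 2),
    reads = rpois(n_peaks, 100)
  ) %>% arrange(factor(.data$chrom, levels = chrom_levels()), .data$start)
}
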