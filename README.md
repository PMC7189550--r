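# panetsig

Copy-number signature, molecular timing and pericentromeric expression
analysis for pancreatic neuroendocrine tumors (PANETs).

PANETs with somatic mutations in *MEN1*, *ATRX* or *DAXX* (MAD+) carry a
highly recurrent karyotype: loss of heterozygosity (LOH) of chromosomes
1, 2, 3, 6, 8, 10, 11, 16, 21 and 22 — largely copy-neutral — with
retained heterozygosity and, after genome doubling, copy gains of
chromosomes 4, 5, 7, 9, 12, 13, 14, 17, 19 and 20. `panetsig` is a
tidyverse-native toolkit for every quantitative step used to establish
and interrogate that choreography:

- **Signature calling** — pseudo allele-specific copy/zygosity states per
  chromosome from 500 kb binned shallow-WGS read and heterozygous-SNP
  counts (`call_chromosome_states()`), cohort motifs and recurrence
  (`cohort_motif()`, `signature_from_motif()`), aberration co-occurrence
  (phi coefficient), Jaccard concordance, Scarpa G1–G4 karyotype groups,
  and chromosomal-instability strata.
- **Molecular timing** — for each somatic mutation, enumerate copy models
  `(m, n)` under the bulk allelic-fraction model
  `AF = p·m / (p·n + 2(1−p))`, keep models consistent with pathologist
  purity ± 0.15, pick the simplest (`select_copy_model()`), and test
  enrichment of early (cancer chromosome fraction ≈ 1) MAD mutations
  with an exact binomial test (`binomial_enrichment()`,
  `gene_enrichment()`).
- **Allelic tests** — a depth-weighted bootstrap test for monoallelic
  expression against a random-SNP null (`mae_test()`, `mae_scan()`), and
  trio-based parental skewing of LOH chromosomes (`parental_skew()`).
- **Pericentromeric repression** — per-gene MAD+ vs MAD− z-scores,
  arm-level expression percentiles, and loess repression curves over
  fractional centromere distance (`repression_curves()`).
- **CENP-A ChIP summaries** — acquired/maintained/lost peak
  classification, per-cytoband RPKM and Kolmogorov–Smirnov statistics,
  and correlations of centromere features with mis-segregation fractions.
- **CGH meta-analysis** — cytoband mapping of published gain/loss tables,
  Jaccard-distance clustering, and a pooled Mantel–Haenszel odds ratio
  with Robins–Breslow–Greenland confidence interval and Cochran's Q
  (`pooled_or()`).
- **Synthetic cohorts** — `simulate_cohort()` and friends generate every
  input the pipeline consumes (segments, mutations, binned counts,
  expression, RNA SNPs, trios, CGH studies, peaks) with ground-truth
  labels, so the whole chain is testable without any external download.

All functions take tibbles and return tibbles; fitted results have
broom-style `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
visualizations. `run_pipeline()` orchestrates the stages end-to-end with
deterministic seeding and a provenance manifest.

## Worked example

Simulate a small MAD+/MAD− cohort, call the signature motif, and time the
MAD mutations against the LOH events:

```r
library(panetsig)
library(dplyr)

cfg    <- sim_config(n_samples = 12, seed = 42)
cohort <- simulate_cohort(cfg)

# per-chromosome recurrent states in the MAD+ samples
cohort_motif(semi_join(cohort$segments,
                       filter(cohort$meta, mad_status == "MAD+"),
                       by = "sample_id")) %>%
  select(chrom, modal_zygosity, zygosity_freq, modal_copy) %>%
  head(6)
#> # A tibble: 6 x 4
#>   chrom modal_zygosity zygosity_freq modal_copy
#>   <chr> <chr>                  <dbl> <chr>
#> 1 chr1  LOH                        1 neutral
#> 2 chr2  LOH                        1 neutral
#> 3 chr3  LOH                        1 neutral
#> 4 chr4  HET                        1 gain
#> 5 chr5  HET                        1 gain
#> 6 chr6  LOH                        1 neutral

calls <- select_copy_model(cohort$mutations, cohort$meta,
                           segments = cohort$segments)
timing_summary(calls, cutoff = 0.85)
#> # A tibble: 1 x 4
#>   cohort n_samples n_early n_late
#>   <chr>      <int>   <int>  <int>
#> 1 all            5       5      0
```

Every sample with a resolvable MAD mutation carries it at cancer
chromosome fraction 1.0 — on every tumor copy of its (copy-neutral LOH)
chromosome — so the mutation preceded the LOH event. The signature motif
shows copy-neutral LOH on the signature chromosomes and gains of the
retained set in genome-doubled samples.

Pool a simulated multi-study CGH cohort for the chromosomal-instability
vs metastasis association:

```r
pooled_or(simulate_cgh_cohort(cfg)$tables)
#> Pooled OR 5.82, 95% CI [3.17, 10.69] (8 studies, n = 226)
#> Cochran's Q = 6.27 on 7 df (p = 0.508)
```

Or run everything at once:

```r
cfg <- run_config(seed = 7, outdir = "panetsig_out")
run_pipeline("all", cfg)
```

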