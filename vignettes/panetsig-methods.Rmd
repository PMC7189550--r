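---
title: "Models and methods behind panetsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panetsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panetsig)
library(dplyr)
```

# The biological setting

Pancreatic neuroendocrine tumors (PANETs) with somatic mutations in
*MEN1*, *ATRX* or *DAXX* ("MAD+") carry a strikingly recurrent karyotype:
loss of heterozygosity (LOH) of chromosomes 1, 2, 3, 6, 8, 10, 11, 16, 21
and 22 — typically copy-neutral — with retained heterozygosity (and, after
genome doubling, copy gains) of chromosomes 4, 5, 7, 9, 12, 13, 14, 17, 19
and 20. Chromosomes 15 and 18 behave inconsistently. `panetsig` implements
the computational chain used to characterize this choreography: calling
the signature from binned shallow-WGS counts, timing the MAD mutations
relative to the LOH and doubling events, testing monoallelic expression
and parental skewing as candidate selective explanations, quantifying
pericentromeric expression repression, summarizing ectopic CENP-A peaks
per cytoband, and pooling chromosomal-instability versus metastasis
association across CGH studies.

Every stage operates on plain tibbles and every result type has
`tidy()`/`glance()` and plotting methods, so the whole chain composes with
ordinary dplyr pipelines.

# The purity/copy allelic-fraction model

Everything in the copy-number and timing stages rests on one mixture
identity. A somatic mutation carried on $m$ of the $n$ tumor copies of its
locus, in a bulk sample of purity $p$ (normal cells contributing $c$
copies, 2 on autosomes, 1 on male chrX), is observed at allelic fraction

$$\mathrm{AF} = \frac{p\,m}{p\,n + c\,(1 - p)}.$$

`expected_af()` is the forward model, `implied_purity()` its inversion
for $p$, and `purity_adjusted_af()` the related transform that removes
the normal contribution from a germline-heterozygous site. All three
invert each other to machine precision; the tests exercise this on dense
$(p, m, n)$ grids.

## Copy-model selection and timing

For each mutation, `select_copy_model()` enumerates all $(m, n)$ with
$1 \le m \le n \le n_\max$ (default $n_\max = 8$, enough for
genome-doubled CN-LOH states), keeps models whose implied purity lies
within the pathologist estimate ± 0.15, and picks the least complex one.
Complexity is ordered by distance from the diploid baseline
($|n-2|$, then $n$, then $m$): a strictly smallest-$n$ rule would let the
haploid model $(1,1)$ pre-empt the ordinary heterozygous call $(1,2)$
whenever the observed fraction is compatible with both, which contradicts
what the allelic data supports at diploid loci. When segment calls are
available, $n$ is pinned to the called total copy number — the "relative
copy-state" constraint. When a sample carries several mutations they must
additionally share a purity: we intersect the per-mutation ranges of
feasible implied purities, inflated by half the tolerance because each is
a point estimate under binomial read noise; an empty intersection falls
back to independent selection with a warning.

The cancer chromosome fraction of the chosen model is $m/n$: 1.0 means
the mutation is on every tumor copy and therefore preceded the LOH /
doubling event ("early"); 0.5 means an ordinary heterozygous mutation.
`timing_summary()` counts samples whose MAD mutation is early at a cutoff
(default 0.85; 0.63 is the conventional choice for *ATRX*, whose chrX
location often needs no LOH second hit because of X-inactivation), and
`binomial_enrichment()` supplies the exact test. The two-sided p-value
uses the minimum-likelihood convention — the sum of the probabilities of
all outcomes no more likely than the observed count — which is the
convention that reproduces both published fixed points (35/39 early
samples, and the 8-vs-3 parental-skew split below); `p0 = 0.5` encodes
the null that a mutation is as likely to precede as to follow the event.

# Calling chromosome states from binned counts

`call_chromosome_states()` works at whole-chromosome resolution from
500 kb bins carrying a read count and a heterozygous-SNP count. The copy
state comes from the chromosome's median read count normalized to the
modal chromosome (taken as copy 2) and corrected for the purity mixture.
Zygosity comes from the het-SNP retention ratio $r$ = observed/expected:
under complete tumor LOH only the admixed normal DNA still shows both
alleles, so the expected floor is $2(1-p) / (p\,n + 2(1-p))$. We call LOH
below the midpoint between that floor and 1 (no threshold is stated in
the field for this; the midpoint is the equal-margin choice), HET above
the midpoint of the remaining interval, and unknown in between. Below
purity 0.3 the call is emitted but flagged, since the floor approaches 1
and the signal drowns.

`cohort_motif()` reports, per chromosome, the most recurrent zygosity and
copy states with frequencies; ties are reported as multi-modal, never
broken silently. `signature_from_motif()` turns a motif into signature
sets using a recurrence threshold (default 0.75 of samples): chromosomes
aberrant in only about half the cohort — the behaviour of chromosomes 15
and 18 — fall out as "variable" rather than being forced into either set.
Aberration co-occurrence uses the phi coefficient on per-sample binary
indicators (±0.5 flags synchronous/antagonistic pairs); the odds-ratio
alternative was considered and rejected as unbounded under zero cells.

# Monoallelic expression

`mae_test()` asks whether a gene's RNA SNP allelic fractions are jointly
skewed toward one allele relative to the sample. Allelic fractions are
first folded to $\max(\mathrm{AF}, 1-\mathrm{AF})$: monoallelic
expression shows up near 0 or 1 depending on which haplotype is silenced,
and without folding, SNPs skewed to opposite haplotypes cancel. The
statistic is a depth-weighted z: the weighted mean folded AF of the
gene's SNPs, displaced from the sample-wide weighted mean, scaled by the
background sd over $\sqrt{n_\mathrm{eff}}$, with
$n_\mathrm{eff} = (\sum w)^2 / \sum w^2$. The background supplies the
dispersion deliberately: with 2–3 SNPs per gene, a within-gene variance
estimate is so unstable that incidentally tight random SNP sets dominate
the null tail and destroy power. The gene's mean z over 1000 bootstrap
resamples is compared with a null distribution built from equally sized
random SNP sets; a gene is flagged above the null's 0.95 quantile. The
empirical null makes the procedure self-calibrating (the tests verify
type-I error within binomial tolerance of 5% and power ~1 at folded AF
0.95 with 3 SNPs at 50× depth). One consequence of folding worth knowing:
an exactly balanced gene sits slightly *below* the folded background
mean (z ≈ −2), which is harmless for a one-sided upper-tail flag.

# Parental skewing

Given tumor, child-germline and maternal SNP allelic fractions,
genotypes are discretized (homozygous at AF ≥ 0.8 or ≤ 0.2). Informative
SNPs are those heterozygous in the child and homozygous in the mother —
there the child's maternally inherited allele is known. Per LOH
chromosome we report the fractions of informative SNPs where the tumor
is homozygous matching the mother ("maternal" retained homolog),
homozygous for the other allele ("paternal"), or still heterozygous; the
chromosome is labelled by majority, and all-heterozygous chromosomes are
labelled no-LOH. "Origin" here names the *retained* homolog's parent (the
alternative reading — the lost homolog — simply swaps the labels). The
cohort-level question (does LOH favour one parental set?) is the exact
binomial test of maternal vs paternal chromosome counts at $p_0 = 0.5$.

# Pericentromeric repression

`gene_zscores()` compares MAD+ to MAD− expression per gene,
$z = (\bar{x}_{+} - \bar{x}_{-}) / s_{-}$, using the MAD− group alone as
the reference for both center and dispersion (genes with undefined MAD−
dispersion are dropped, with a message). `arm_percentiles()` places each
gene's z within its arm by the empirical CDF (rank/n, mid-ranks for
ties), removing arm-level trends so that "repressed relative to the rest
of the arm" is well-defined. `repression_curves()` fits loess (tricube,
degree 2, span 0.5 by default) of the percentile against fractional
centromere distance — 0 at the centromere boundary, 1 at the telomere —
separately for the LOH and heterozygous chromosome sets, and reports the
difference curve and its mean over the window [0, 0.025], the band
immediately adjacent to the centromere. A label-permutation null
(`repression_window_null()`) gives the reference band for that window
mean. Fitting percentiles rather than raw z is the default because it
matches the arm-relative phrasing of the question; `value = "z"` is
available. Genes are positioned by midpoint; genes whose midpoint falls
inside the centromere are dropped.

# CENP-A peaks and mis-segregation features

Peaks are compared between DAXX-depleted and control conditions by
any-overlap (≥ 1 bp): depleted-only peaks are acquired, overlapping
maintained, control-only lost. Heights of shared peaks are compared with
Welch's t. Per cytoband we report peak count, base coverage, RPKM
(reads per kilobase of peak per million mapped reads, with reads and
bases apportioned across band boundaries so splitting a peak changes
nothing), and the Kolmogorov–Smirnov D of the band's peak heights against
the genome-wide distribution (heights, not positions, are the default
quantity; positions carry band identity already).
`missegregation_correlations()` relates per-chromosome mis-segregation
fractions to centromere size, periCEN flank size ("periCEN" = the single
non-acen band adjacent to each acen band) and CENP-A levels, via Pearson
correlations with t-transform p-values, and to LOH-set membership via the
point-biserial correlation. Constant inputs return r = 0 by convention
rather than erroring.

# CGH meta-analysis

`ingest_cgh()` expands published per-sample gain/loss listings (whole
chromosome, arm, or band prefix) onto cytobands; a band reported both
gained and lost in one sample is flagged as a conflict and excluded from
concordance. `jaccard_concordance()` is state-matched — a loss only
matches a loss — and ignores joint absences, which is what makes the
measure "asymmetric binary": two near-diploid genomes are not similar
merely because both lack aberrations. Profiles cluster hierarchically on
1 − J with average linkage. `pooled_or()` pools per-study 2×2 tables
(CI stratum × metastasis) with the fixed-effect Mantel–Haenszel
estimator, the Robins–Breslow–Greenland variance for the confidence
interval, and Cochran's Q on inverse-variance-weighted per-study log
odds ratios; a Haldane 0.5 correction is applied only to studies with a
zero cell, and studies with an empty margin are dropped as uninformative.
The high-CI/low-CI cutoff is an aberrant genome (or band) fraction of
0.2 by default and is configurable, since published stratifications do
not state it.

# The synthetic cohort

`sim_config()` fixes the study conditions the generator emulates: purity
uniform on [0.4, 0.9] (mirroring the exclusion of sub-30% cellularity
samples), 200× depth at mutation loci, the signature chromosome sets
above, genome doubling in half the MAD+ samples, copy-neutral LOH on the
signature chromosomes with gains of the retained set upon doubling, a
truncal MAD mutation with $m = n$ on its LOH chromosome, Poisson read
counts and binomially thinned het-SNP counts in 500 kb bins, a
pericentromeric repression of 0.8 z-units within fractional distance
0.025, monoallelic genes at folded AF 0.95, trio genotypes with a known
retained parent per LOH chromosome, and an 8-study, 226-sample CGH
cohort whose true high-CI/metastasis odds ratio is 4.35. Noise models
(Poisson, binomial) are the minimal ones consistent with count data.
Ground-truth labels are always emitted next to the data, so tests
compare against truth, never against simulator internals.

The expression simulation defaults to 15,000 genes — microarray scale,
matching the ~122-sample expression cohorts this analysis is designed
for; at a few thousand genes the repression localization bound becomes
noise-limited. The ideogram used by simulation and tests is
`synthetic_cytobands()`: approximately-hg19 chromosome lengths and
centromere positions with one flank and three outer bands per arm. It is
explicitly a synthetic stand-in — any well-formed cytoBandIdeo file can
be supplied instead via `read_cytobands()`.

What the simulation does *not* emulate: segmental (sub-chromosomal)
aberrations, GC/mappability waves in read counts, overdispersed RNA-seq
noise, phasing structure, and cohort batch effects. Passing tests
demonstrate that the estimators recover the model that generated the
data at realistic noise levels; they do not certify performance on real
sequencing artifacts.

# Numerical and degenerate-input choices

Coordinates are 0-based half-open throughout (cytoband dialect); 1-based
inputs convert at the reader boundary. `implied_purity()` tolerates
floating-point spill just past 1. The exact binomial sums the mass
function directly with a relative guard of 1e-7 when comparing
likelihoods for the two-sided rule. Loess curves are evaluated on a
fixed grid; grid points outside the data range yield NA and are excluded
from window summaries. Empty inputs (no bands, no informative SNPs, all
tables degenerate) return typed empty results or explicit errors, never
silent zeros. Modal-state ties are reported; Jaccard of two profiles
with no aberrant bands at all is NA (undefined), while `jaccard_matrix()`
maps that to 0 for clustering. Acrocentric-like tiny p-arms are retained
in flank-size correlations by default; exclude them by filtering the arm
table if desired.

# Orchestration and reproducibility

`run_pipeline()` runs the stages (`simulate`, `cnstate`, `timing`,
`mae`, `skew`, `expression`, `chip`, `meta`, or `all`) against a
directory, writing TSV/JSON results, a line-delimited log, and a
deterministic provenance manifest (package version, seed, config hash,
record counts). One global seed fans out to per-stage child seeds by a
stable hash of the stage name, so stages are independently reproducible
and two runs with the same seed are file-identical (the log's wall times
aside). A thin command-line wrapper ships in `inst/scripts/panetsig`.
The test-suite problem sizes (cohorts of 30–122 samples, 15k genes, 500
null genes for MAE calibration) are the smallest at which the cohort
statistics stabilize, and mirror the cohort sizes this kind of study
actually uses.

# Known limitations

Chromosome-level calling assumes one dominant copy state per chromosome;
focal events are invisible at this resolution (and the input format has
no segmentation stage — inputs are pre-segmented or fixed-bin by
design). The modal-chromosome read-count anchor assumes the modal state
is diploid; a genome that is mostly tetraploid would need an explicit
ploidy prior. The MAE test assumes SNP calls are unbiased at
heterozygous sites (no reference-allele mapping bias model). The
Mantel–Haenszel pooling is fixed-effect by design; no random-effects
model or small-study bias diagnostics are provided.
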