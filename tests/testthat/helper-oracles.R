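# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (loops, full enumeration) and independent
# of the package implementation paths they check.

# Exact binomial p-value by full outcome enumeration: probability of each
# k computed from choose(); two-sided by the minimum-likelihood rule.
brute_binomial <- function(k, n, p0 = 0.5, sided = "two") {
  probs <- vapply(0:n, function(i) {
    choose(n, i) * p0^i * (1 - p0)^(n - i)
  }, numeric(1))
  if (sided == "greater") return(sum(probs[(k + 1):(n + 1)]))
  if (sided == "less") return(sum(probs[1:(k + 1)]))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Jaccard index by explicit set enumeration over band:status labels.
brute_jaccard <- function(a, b) {
  lab <- function(p) {
    keep <- p$status %in% c("loss", "gain")
    unique(paste(p$band[keep], p$status[keep]))
  }
  la <- lab(a); lb <- lab(b)
  inter <- 0
  for (x in la) if (x %in% lb) inter <- inter + 1
  uni <- length(unique(c(la, lb)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

# Two-sample KS D by checking the ECDF gap at every observed value.
brute_ks <- function(x, y) {
  pts <- c(x, y)
  gaps <- vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1))
  max(gaps)
}

# Three-band chromosome (p band, acen pair, q band) with known arithmetic.
toy_cytobands <- function() {
  tibble::tribble(
    ~chrom,  ~start, ~end, ~band,   ~stain,
    "chr1",  0,      100,  "p12",   "gneg",
    "chr1",  100,    120,  "p11.1", "acen",
    "chr1",  120,    150,  "q11.1", "acen",
    "chr1",  150,    400,  "q12",   "gneg"
  )
}

# Whole-chromosome segment profile builder for motif/group tests.
toy_profile <- function(sample_id, loh = character(), gain = character(),
                        loss = character()) {
  chroms <- paste0("chr", 1:22)
  tibble::tibble(
    sample_id = sample_id,
    chrom = chroms,
    start = 0,
    end = 1e8,
    total_cn = dplyr::case_when(
      chroms %in% gain ~ 3,
      chroms %in% loss ~ 1,
      TRUE ~ 2
    ),
    minor_cn = dplyr::case_when(
      chroms %in% loh ~ 0,
      chroms %in% loss ~ 0,
      TRUE ~ 1
    ),
    zygosity = ifelse(chroms %in% c(loh, loss), "LOH", "HET")
  )
}
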