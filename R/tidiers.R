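# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pooled odds-ratio meta-analysis
#'
#' @param x A `meta_or` object from [pooled_or()].
#' @param ... Unused.
#' @return Per-study tibble: `study_id`, counts, `estimate` (study OR),
#'   `log_or`, `std_error`, `continuity`.
#' @export
tidy.meta_or <- function(x, ...) {
  x$per_study %>%
    rename(estimate = "or") %>%
    mutate(std_error = sqrt(.data$var_log_or)) %>%
    select("study_id", "a", "b", "c", "d", "estimate", "log_or",
           "std_error", "continuity")
}

#' @rdname tidy.meta_or
#' @return For `glance()`: one row with pooled `estimate`, `conf_low`,
#'   `conf_high`, `q`, `q_df`, `q_p`, `n_studies`, `n_samples`.
#' @export
glance.meta_or <- function(x, ...) {
  tibble(
    estimate = x$or, conf_low = x$ci_low, conf_high = x$ci_high,
    conf_level = x$conf_level, q = x$q, q_df = x$q_df, q_p = x$q_p,
    n_studies = x$n_studies, n_samples = x$n_samples
  )
}

#' Tidy a parental-skew analysis
#'
#' @param x A `parental_skew` object.
#' @param ... Unused.
#' @return Per-chromosome tibble of informative-SNP fractions and labels.
#' @export
tidy.parental_skew <- function(x, ...) x$per_chromosome

#' @rdname tidy.parental_skew
#' @export
glance.parental_skew <- function(x, ...) {
  tibble(n_maternal = x$n_maternal, n_paternal = x$n_paternal,
         p_value = x$p_value)
}

#' Tidy pericentromeric repression curves
#'
#' @param x A `repression_curves` object.
#' @param ... Unused.
#' @return The evaluation-grid tibble (`frac_dist`, `fit_loh`, `fit_het`,
#'   `difference`).
#' @export
tidy.repression_curves <- function(x, ...) x$curves

#' @rdname tidy.repression_curves
#' @export
glance.repression_curves <- function(x, ...) {
  tibble(
    window_low = x$window[1], window_high = x$window[2],
    window_mean = x$window_mean, window_negative = x$window_negative,
    value = x$value, n_loh = x$n_loh, n_het = x$n_het
  )
}
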