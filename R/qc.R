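#' Noise-to-signal ratio
#'
#' Ratio of the standard deviation across technical-replicate (QC) samples
#' to the standard deviation across the biological cohort samples, computed
#' per entry. Lower is better: a well-behaved entry varies less across
#' replicate injections than across patients. Sample (n-1) standard
#' deviations are used.
#'
#' @param values_qc Entry values in the replicate/QC samples.
#' @param values_cohort Entry values in the cohort samples.
#' @return `sd(values_qc) / sd(values_cohort)`, or `NA` when either vector
#'   has fewer than two non-`NA` values or the cohort SD is zero.
#' @export
nsr <- function(values_qc, values_cohort) {
  q <- values_qc[!is.na(values_qc)]
  s <- values_cohort[!is.na(values_cohort)]
  if (length(q) < 2L || length(s) < 2L) return(NA_real_)
  denom <- sd(s)
  if (denom == 0) return(NA_real_)
  sd(q) / denom
}

#' Coefficient of variation (percent)
#'
#' @param values Numeric values; at least two.
#' @param log_scale_input When `TRUE`, values are log2 abundances and are
#'   exponentiated before computing the CV on the linear scale.
#' @return `100 * sd / mean` on the linear scale.
#' @export
cv <- function(values, log_scale_input = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  if (log_scale_input) values <- 2^values
  100 * sd(values) / mean(values)
}

#' Pairwise replicate R-squared
#'
#' Ordinary least-squares R-squared for every pair of replicate samples,
#' using the entries non-missing in both members of a pair. With `n`
#' replicates this yields `choose(n, 2)` comparisons.
#'
#' @param report An `iso_report`.
#' @param replicate_samples Character vector of at least two sample column
#'   names (see [sample_cols()]).
#' @return A tibble `sample_a`, `sample_b`, `r_squared`, `n_entries`.
#' @export
replicate_r2 <- function(report, replicate_samples) {
  stopifnot(inherits(report, "iso_report"))
  missing <- setdiff(replicate_samples, sample_cols(report))
  if (length(missing)) {
    abort(sprintf("replicate sample(s) not in report: %s", paste(missing, collapse = ", ")))
  }
  if (length(replicate_samples) < 2L) abort("need at least two replicate samples")
  m <- report_values(report)
  pairs <- combn(replicate_samples, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- m[, pairs[1, k]]; b <- m[, pairs[2, k]]
    ok <- !is.na(a) & !is.na(b)
    r2 <- if (sum(ok) >= 2L) cor(a[ok], b[ok])^2 else NA_real_
    tibble(sample_a = pairs[1, k], sample_b = pairs[2, k],
           r_squared = r2, n_entries = sum(ok))
  })
}
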