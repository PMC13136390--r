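#' IQR-based outlier removal within one group and sample
#'
#' For the ratio slice of one entry in one sample, values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are set to `NA`. Quartiles are computed on
#' the non-`NA` values by linear interpolation of order statistics (type-7
#' convention). Slices with fewer than four non-`NA` values are returned
#' unchanged.
#'
#' @param x Numeric vector of log2 ratios (`NA` allowed).
#' @return `x` with outliers set to `NA`.
#' @export
iqr_outlier_removal <- function(x) {
  obs <- !is.na(x)
  if (sum(obs) < 4L) return(x)
  q <- quantile(x[obs], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  x[obs & (x < lo | x > hi)] <- NA_real_
  x
}

#' Median roll-up of PSM ratios
#'
#' @param x Numeric vector of log2 ratios (`NA` allowed), after outlier
#'   removal.
#' @return The median of the non-`NA` values (even counts: mean of the two
#'   middle values), or `NA` if none remain.
#' @export
median_aggregate <- function(x) median_na(x)

#' Precursor-intensity-weighted median roll-up
#'
#' Each PSM is weighted by its raw-scale precursor (MS1) intensity,
#' normalized so the weights sum to 1. PSMs are sorted by ratio in ascending
#' order and weights are accumulated; the first ratio at which the cumulative
#' weight strictly exceeds 0.5 represents the group. If no cumulative weight
#' exceeds 0.5 (possible only in degenerate cases), the ratio with the
#' largest weight is returned, ties resolved toward the smaller ratio. When
#' every weight is zero and more than one distinct ratio remains, the
#' unweighted median is used instead (with a warning).
#'
#' @param x Numeric vector of log2 ratios (`NA` allowed).
#' @param w Non-negative precursor intensities aligned to `x`.
#' @return The representative log2 ratio, or `NA` if no ratio remains.
#' @export
weighted_median_aggregate <- function(x, w) {
  stopifnot(length(x) == length(w))
  obs <- !is.na(x)
  x <- x[obs]; w <- w[obs]
  if (!length(x)) return(NA_real_)
  if (any(is.na(w) | w < 0)) abort("precursor weights must be non-negative and non-missing")
  tot <- sum(w)
  if (tot == 0) {
    ux <- unique(x)
    if (length(ux) > 1L) {
      warn("all precursor intensities zero; falling back to unweighted median")
      return(median_na(x))
    }
    return(ux)
  }
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / tot
  cum <- cumsum(w)
  idx <- which(cum > 0.5)
  if (length(idx)) return(x[idx[1]])
  best <- which(w == max(w))
  x[best[1]]
}

#' Aggregate one plex's PSM ratios to entry-by-sample values
#'
#' For every entry and sample: optional IQR outlier removal
#' ([iqr_outlier_removal()]), then the chosen roll-up ([median_aggregate()]
#' or [weighted_median_aggregate()]).
#'
#' @param groups Entry assignment tibble from [assign_groups()].
#' @param ratios Long ratio tibble from [to_ratios()].
#' @param method `"median"` (default) or `"weighted_median"`.
#' @param outlier_removal Apply IQR outlier removal first (default `TRUE`).
#' @return A long tibble `index`, `plex_id`, `sample`, `value` plus an
#'   `entry_meta` attribute (per-entry supporting-PSM count for this plex).
#' @export
aggregate_plex <- function(groups, ratios, method = c("median", "weighted_median"),
                           outlier_removal = TRUE) {
  method <- match.arg(method)
  joined <- inner_join(groups, ratios, by = "spectrum_id")
  agg_one <- if (method == "median") {
    function(v, w) median_aggregate(if (outlier_removal) iqr_outlier_removal(v) else v)
  } else {
    function(v, w) {
      if (outlier_removal) {
        v <- iqr_outlier_removal(v)
      }
      weighted_median_aggregate(v, w)
    }
  }
  out <- joined |>
    group_by(.data$index, .data$plex_id, .data$sample) |>
    summarise(value = agg_one(.data$ratio, .data$precursor_intensity),
              .groups = "drop")
  meta <- joined |>
    distinct(.data$index, .data$spectrum_id, .keep_all = TRUE) |>
    group_by(.data$index) |>
    summarise(n_psms = dplyr::n_distinct(.data$spectrum_id), .groups = "drop")
  attr(out, "entry_meta") <- meta
  out
}
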