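#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_point geom_abline
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Per-sample value distributions of a report
#'
#' Box plots of the log2 values of every sample column, a quick visual check
#' that sample distributions are comparable after normalization.
#'
#' @param object An `iso_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iso_report <- function(object, ...) {
  long <- tidy(object)
  ggplot(long[!is.na(long$value), ], aes(x = .data$sample, y = .data$value)) +
    geom_boxplot(outlier.size = 0.4) +
    labs(
      x = NULL,
      y = sprintf("log2 %s (%s)", attr(object, "kind"), attr(object, "normalization")),
      title = sprintf("%s-level %s", attr(object, "level"), attr(object, "kind"))
    ) +
    theme_minimal()
}

#' Recovered versus designed log2 ratios on simulated data
#'
#' Compares a report's entry values with the simulation ground truth,
#' matching report indexes to simulated proteins (protein- or gene-level
#' reports). Points on the identity line indicate perfect fold-change
#' recovery; compression shows as a slope below 1.
#'
#' @param report An `iso_report` (ratio kind) from a pipeline run on
#'   simulated plexes.
#' @param sim The `iso_sim` the plexes came from.
#' @return A ggplot of recovered vs true log2 ratio per (entry, sample).
#' @export
plot_recovery <- function(report, sim) {
  stopifnot(inherits(report, "iso_report"), inherits(sim, "iso_sim"))
  long <- tidy(report)
  truth <- sim$truth
  if (attr(report, "level") == "gene") truth$protein <- paste0("g", truth$protein)
  joined <- inner_join(long, truth,
                       by = c(index = "protein", plex_id = "plex_id", sample = "sample"))
  ggplot(joined[!is.na(joined$value), ],
         aes(x = .data$true_log2_ratio, y = .data$value)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "designed log2 ratio to reference", y = "recovered log2 ratio") +
    theme_minimal()
}
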