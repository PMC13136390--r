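#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a report into long form
#'
#' @param x An `iso_report`.
#' @param ... Unused.
#' @return A tibble `index`, `plex_id`, `sample`, `value` with one row per
#'   report cell.
#' @export
tidy.iso_report <- function(x, ...) {
  smap <- attr(x, "samples")
  long <- tidyr::pivot_longer(as_tibble(x)[, c("index", sample_cols(x))],
                              cols = -"index", names_to = "column",
                              values_to = "value")
  left_join(long, smap, by = "column") |>
    select("index", "plex_id", "sample", "value")
}

#' One-row summary of a report
#'
#' @param x An `iso_report`.
#' @param ... Unused.
#' @return A tibble with the level, normalization, kind, entry and sample
#'   counts, and the fraction of missing cells.
#' @export
glance.iso_report <- function(x, ...) {
  m <- report_values(x)
  tibble(
    level = attr(x, "level"), normalization = attr(x, "normalization"),
    kind = attr(x, "kind"), n_entries = nrow(m), n_samples = ncol(m),
    frac_missing = if (length(m)) mean(is.na(m)) else NA_real_
  )
}

#' Summaries of every report in a run
#'
#' @param x An `iso_run` from [integrate_plexes()].
#' @param ... Unused.
#' @return `tidy()`: stacked long values for all reports (with a `report`
#'   column); `glance()`: one row per report.
#' @export
tidy.iso_run <- function(x, ...) {
  purrr::map_dfr(x$reports, tidy, .id = "report")
}

#' @rdname tidy.iso_run
#' @export
glance.iso_run <- function(x, ...) {
  purrr::map_dfr(x$reports, glance, .id = "report")
}
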