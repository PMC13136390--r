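#' Integrate plexes into quantification reports
#'
#' Runs the full roll-up on already-loaded plexes: PSM filtering
#' ([filter_psms()]), ratio-to-reference conversion ([to_ratios()], with
#' optional retention-time bin normalization), per-level grouping
#' ([assign_groups()]), per-sample IQR outlier removal and PSM aggregation
#' ([aggregate_plex()]), column-wise combination of plexes, the best-PSM
#' probability entry filter, MD/GN sample normalization, reference-intensity
#' estimation and ratio-to-abundance conversion, and the single-site
#' collapse for PTM data.
#'
#' @param plexes A [plex_table()] or list of them.
#' @param levels Report levels, a subset of `c("gene", "protein", "peptide",
#'   "multisite", "singlesite")`.
#' @param norms Normalizations to report, a subset of
#'   `c("None", "MD", "GN")`.
#' @param aggregation `"median"` (default) or `"weighted_median"`.
#' @param filter A [filter_config()].
#' @param outlier_removal Apply IQR outlier removal before aggregation.
#' @param min_best_prob Entry-level best supporting-PSM probability
#'   threshold (default 0.9).
#' @param abundance_source Reference-intensity source, see
#'   [reference_intensity()].
#' @param impute_missing_ref Impute missing per-plex reference intensities
#'   with the global minimum.
#' @param rt_normalization Apply retention-time bin normalization to PSM
#'   ratios (off by default).
#' @param n_rt_bins Retention-time bins when enabled.
#' @param ptm_only Restrict every level to PSMs carrying the target
#'   modification; defaults to `TRUE` whenever a PTM level is requested and
#'   a `mod_tag` is configured.
#' @param out_dir When given, every report is also written as a TSV named
#'   `<ratio|abundance>_<level>_<norm>.tsv` (see [write_report()]) together
#'   with a `run_log.txt`.
#' @return An `iso_run`: list with `reports` (named
#'   `<kind>_<level>_<norm>`), `filter_reports`, `samples`, `log` and the
#'   effective settings.
#' @export
integrate_plexes <- function(plexes,
                             levels = c("gene", "protein"),
                             norms = c("None", "MD"),
                             aggregation = c("median", "weighted_median"),
                             filter = filter_config(),
                             outlier_removal = TRUE,
                             min_best_prob = 0.9,
                             abundance_source = "ms1_top3",
                             impute_missing_ref = TRUE,
                             rt_normalization = FALSE,
                             n_rt_bins = 10L,
                             ptm_only = NULL,
                             out_dir = NULL) {
  if (inherits(plexes, "plex_table")) plexes <- list(plexes)
  stopifnot(length(plexes) >= 1L, all(vapply(plexes, inherits, logical(1), "plex_table")))
  aggregation <- match.arg(aggregation)
  all_levels <- c("gene", "protein", "peptide", "multisite", "singlesite")
  levels <- match.arg(levels, all_levels, several.ok = TRUE)
  norms <- match.arg(norms, c("None", "MD", "GN"), several.ok = TRUE)

  n_chan <- vapply(plexes, function(p) nrow(p$channels), integer(1))
  has_subplex <- any(vapply(plexes, n_subplexes, integer(1)) > 1L)
  if (length(unique(n_chan)) > 1L && !has_subplex) {
    abort("plexes have inconsistent channel counts; supply a subplex assignment")
  }
  ids <- vapply(plexes, function(p) p$plex_id, character(1))
  if (anyDuplicated(ids)) abort("plex ids must be unique")

  want_singlesite <- "singlesite" %in% levels
  if (want_singlesite && is.null(filter$mod_tag)) {
    abort("single-site reports need multi-site inputs: configure `mod_tag` in filter_config()")
  }
  group_levels <- setdiff(levels, "singlesite")
  if (want_singlesite && !"multisite" %in% group_levels) {
    group_levels <- c(group_levels, "multisite")
  }
  if (is.null(ptm_only)) {
    ptm_only <- !is.null(filter$mod_tag) && any(c("multisite", "singlesite") %in% levels)
  }

  log <- list()
  note <- function(step, plex, detail, n) {
    log[[length(log) + 1L]] <<- tibble(step = step, plex = plex, detail = detail, n = n)
  }

  filtered <- list(); ratios_by_plex <- list(); filter_reports <- list()
  for (p in plexes) {
    note("input", p$plex_id, "PSMs read", nrow(p$psms))
    fp <- filter_psms(p, filter)
    filter_reports[[p$plex_id]] <- filter_report(fp)
    note("filter", p$plex_id, "PSMs retained", nrow(fp$psms))
    r <- to_ratios(fp)
    if (rt_normalization) r <- rt_bin_normalize(r, n_rt_bins)
    filtered[[p$plex_id]] <- fp
    ratios_by_plex[[p$plex_id]] <- r
  }

  samples <- purrr::map_dfr(ratios_by_plex, function(r) {
    distinct(r, .data$plex_id, .data$sample)
  })
  samples$column <- if (anyDuplicated(samples$sample)) {
    paste(samples$plex_id, samples$sample, sep = ".")
  } else samples$sample

  reports <- list()
  for (level in group_levels) {
    groups_by_plex <- list(); blocks <- list(); metas <- list()
    for (id in names(filtered)) {
      g <- assign_groups(filtered[[id]], level, filter, ptm_only = ptm_only)
      groups_by_plex[[id]] <- g
      blocks[[id]] <- aggregate_plex(g, ratios_by_plex[[id]],
                                     method = aggregation,
                                     outlier_removal = outlier_removal)
      metas[[id]] <- entry_meta(g, filtered[[id]]$psms)
    }
    none <- combine_plexes(blocks, metas, samples, level)
    note("aggregate", NA_character_, sprintf("%s-level entries", level), nrow(none))
    none <- min_best_prob_filter(none, min_best_prob)
    note("min_best_prob", NA_character_, sprintf("%s-level entries retained", level), nrow(none))
    ref <- reference_intensity(groups_by_plex, ratios_by_plex,
                               source = abundance_source,
                               impute_missing = impute_missing_ref)

    level_reports <- list(None = none)
    if ("MD" %in% norms || "GN" %in% norms) level_reports$MD <- normalize_md(none)
    if ("GN" %in% norms) level_reports$GN <- normalize_gn(none)
    for (nm in intersect(norms, names(level_reports))) {
      if (level %in% levels) {
        reports[[sprintf("ratio_%s_%s", level, nm)]] <- level_reports[[nm]]
        reports[[sprintf("abundance_%s_%s", level, nm)]] <-
          ratios_to_abundance(level_reports[[nm]], ref)
      }
    }

    if (level == "multisite" && want_singlesite) {
      ss_none <- collapse_single_site(none, ref)
      site_ref <- attr(ss_none, "site_ref")
      note("collapse", NA_character_, "single-site entries", nrow(ss_none))
      ss_reports <- list(None = ss_none)
      if ("MD" %in% norms || "GN" %in% norms) ss_reports$MD <- normalize_md(ss_none)
      if ("GN" %in% norms) ss_reports$GN <- normalize_gn(ss_none)
      for (nm in intersect(norms, names(ss_reports))) {
        reports[[sprintf("ratio_singlesite_%s", nm)]] <- ss_reports[[nm]]
        reports[[sprintf("abundance_singlesite_%s", nm)]] <-
          ratios_to_abundance(ss_reports[[nm]], site_ref)
      }
    }
  }

  run <- structure(list(
    reports = reports, filter_reports = filter_reports, samples = samples,
    log = bind_rows(log),
    settings = list(levels = levels, norms = norms, aggregation = aggregation,
                    filter = filter, outlier_removal = outlier_removal,
                    min_best_prob = min_best_prob,
                    abundance_source = abundance_source,
                    impute_missing_ref = impute_missing_ref,
                    rt_normalization = rt_normalization, ptm_only = ptm_only)
  ), class = "iso_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Per-entry annotation: representative gene/protein/peptide and the best
# supporting-PSM probability within one plex.
entry_meta <- function(groups, psms) {
  probs <- tibble(spectrum_id = psms$spectrum_id, probability = psms$probability)
  g <- left_join(groups, probs, by = "spectrum_id")
  g |>
    group_by(.data$index) |>
    summarise(
      gene = first_nonempty(.data$gene),
      protein = first_nonempty(.data$protein),
      peptide = if ("peptide" %in% names(g)) first_nonempty(.data$peptide) else NA_character_,
      max_psm_prob = max_na(.data$probability),
      n_psms = dplyr::n_distinct(.data$spectrum_id),
      .groups = "drop"
    )
}

# Column-wise concatenation of per-plex blocks into one unnormalized report.
combine_plexes <- function(blocks, metas, samples, level) {
  long <- bind_rows(blocks)
  long <- left_join(long, samples, by = c("plex_id", "sample"))
  wide <- tidyr::pivot_wider(long[, c("index", "column", "value")],
                             names_from = "column", values_from = "value")
  for (col in setdiff(samples$column, names(wide))) wide[[col]] <- NA_real_
  meta <- bind_rows(metas) |>
    group_by(.data$index) |>
    summarise(
      gene = first_nonempty(.data$gene),
      protein = first_nonempty(.data$protein),
      peptide = first_nonempty(.data$peptide),
      max_psm_prob = max_na(.data$max_psm_prob),
      n_psms = sum(.data$n_psms),
      .groups = "drop"
    )
  df <- left_join(meta, wide, by = "index") |> arrange(.data$index)
  if (all(is.na(df$peptide) | !nzchar(df$peptide))) df$peptide <- NULL
  if (level == "gene") df$gene <- NULL
  df <- df[, c(intersect(c("index", "gene", "protein", "peptide", "max_psm_prob", "n_psms"),
                         names(df)), samples$column)]
  iso_report(df, level = level, normalization = "None", kind = "ratio",
             samples = samples)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(run$reports, write_report, character(1), out_dir = out_dir)
  s <- run$settings
  lines <- c(
    "isoplexr run log",
    sprintf("levels: %s", paste(s$levels, collapse = ", ")),
    sprintf("norms: %s", paste(s$norms, collapse = ", ")),
    sprintf("aggregation: %s", s$aggregation),
    sprintf("outlier_removal: %s", s$outlier_removal),
    sprintf("min_best_prob: %s", s$min_best_prob),
    sprintf("abundance_source: %s", s$abundance_source),
    sprintf("filter: %s", paste(sprintf("%s=%s", names(unclass(s$filter)),
      vapply(unclass(s$filter), function(v) paste(format(v), collapse = ","), character(1))),
      collapse = " ")),
    "",
    "step counts:",
    sprintf("  %-14s %-8s %-32s %s", run$log$step, ifelse(is.na(run$log$plex), "-", run$log$plex),
            run$log$detail, run$log$n),
    "",
    "reports written:",
    paste0("  ", basename(unname(paths)))
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(paths)
}

#' @export
print.iso_run <- function(x, ...) {
  cat(sprintf("<iso_run> %d report(s): %s\n", length(x$reports),
              paste(names(x$reports), collapse = ", ")))
  invisible(x)
}

#' Run the full pipeline from files
#'
#' File-level entry point mirroring the command-line tool: reads one PSM
#' table and one channel-annotation file per plex, builds [plex_table()]s,
#' and calls [integrate_plexes()].
#'
#' @param psm_paths Character vector of per-plex PSM table paths.
#' @param annotation_paths Matching channel-annotation paths.
#' @param reference Reference sample name (must appear in every plex's
#'   annotation) or `"virtual"`.
#' @param plex_ids Optional plex ids (default `plex1`, `plex2`, ...).
#' @param ... Passed on to [integrate_plexes()] (levels, norms, aggregation,
#'   filter, out_dir, ...).
#' @return An `iso_run`.
#' @export
run_pipeline <- function(psm_paths, annotation_paths, reference = "virtual",
                         plex_ids = NULL, ...) {
  if (length(psm_paths) != length(annotation_paths)) {
    abort("need one annotation file per PSM table")
  }
  if (is.null(plex_ids)) plex_ids <- sprintf("plex%d", seq_along(psm_paths))
  plexes <- purrr::pmap(list(psm_paths, annotation_paths, plex_ids),
    function(pp, ap, id) {
      ann <- read_annotation(ap)
      psms <- read_psm_table(pp, channel_labels = ann$channel)
      plex_table(psms, ann, plex_id = id, reference = reference)
    })
  integrate_plexes(plexes, ...)
}
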