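#' Median-centering (MD) normalization
#'
#' Shifts each sample column by its own non-`NA` median so that every
#' sample's median log2 ratio is zero. Idempotent.
#'
#' @param report An `iso_report` of ratios.
#' @return The report with normalization tag `MD`.
#' @export
normalize_md <- function(report) {
  stopifnot(inherits(report, "iso_report"))
  m <- report_values(report)
  med <- apply(m, 2, median_na)
  med[is.na(med)] <- 0
  m <- sweep(m, 2, med, "-")
  out <- set_report_values(report, m)
  attr(out, "normalization") <- "MD"
  out
}

#' MAD-based global (GN) normalization
#'
#' Median-centers each sample (as [normalize_md()]), computes each sample's
#' median absolute deviation `MAD_i = median(|R^MD|)` and the global factor
#' `MAD_0 = median(MAD_i)`, then rescales each sample by `MAD_0 / MAD_i` so
#' that all samples share the same robust spread while keeping zero medians.
#' Samples with `MAD_i = 0` are left unscaled (with a message).
#'
#' @param report An `iso_report` of ratios.
#' @return The report with normalization tag `GN`.
#' @export
normalize_gn <- function(report) {
  stopifnot(inherits(report, "iso_report"))
  md <- normalize_md(report)
  m <- report_values(md)
  mad_i <- apply(m, 2, function(col) median_na(abs(col)))
  mad0 <- median_na(mad_i)
  degenerate <- is.na(mad_i) | mad_i == 0
  if (any(degenerate)) {
    inform(sprintf("%d sample(s) with zero MAD left unscaled by GN", sum(degenerate)))
  }
  scale <- ifelse(degenerate, 1, mad0 / mad_i)
  m <- sweep(m, 2, scale, "*")
  out <- set_report_values(md, m)
  attr(out, "normalization") <- "GN"
  out
}

#' Estimate per-entry reference intensities
#'
#' For each entry and plex, the reference intensity `Ref_ik` is by default
#' the sum of the top 3 reference-weighted MS1 intensities
#' (`ref_weight * precursor intensity`) among the entry's PSMs in that plex
#' (all of them when fewer than 3). The overall `Ref_i` is the median of
#' `Ref_ik` over plexes; plexes in which the entry was not quantified are
#' imputed with the global minimum `Ref_ik` before taking the median (when
#' `impute_missing = TRUE`). Alternative sources: `"ms2_reference"` uses the
#' per-PSM reference-channel reporter intensity in place of the weighted MS1
#' intensity, and `"ms2_sum"` sums the reference-weighted MS1 intensity over
#' all PSMs instead of the top 3.
#'
#' @param groups_by_plex Named list (by plex id) of [assign_groups()]
#'   tibbles.
#' @param ratios_by_plex Named list (by plex id) of [to_ratios()] tibbles.
#' @param source `"ms1_top3"` (default), `"ms2_reference"`, or `"ms2_sum"`.
#' @param impute_missing Impute missing plexes with the global minimum
#'   `Ref_ik` (default `TRUE`).
#' @return A tibble `index`, `ref_intensity`.
#' @export
reference_intensity <- function(groups_by_plex, ratios_by_plex,
                                source = c("ms1_top3", "ms2_reference", "ms2_sum"),
                                impute_missing = TRUE) {
  source <- match.arg(source)
  n_plex <- length(groups_by_plex)
  per_plex <- purrr::map2(groups_by_plex, ratios_by_plex, function(groups, ratios) {
    psm_level <- ratios |>
      distinct(.data$spectrum_id, .keep_all = TRUE) |>
      select("spectrum_id", "ref_weighted_ms1", "ref_intensity")
    joined <- groups |>
      distinct(.data$index, .data$spectrum_id) |>
      inner_join(psm_level, by = "spectrum_id")
    val <- switch(source,
      ms1_top3 = joined |>
        group_by(.data$index) |>
        summarise(ref_ik = sum(sort(.data$ref_weighted_ms1, decreasing = TRUE)[
          seq_len(min(3L, dplyr::n()))]), .groups = "drop"),
      ms2_reference = joined |>
        group_by(.data$index) |>
        summarise(ref_ik = sum(sort(.data$ref_intensity, decreasing = TRUE)[
          seq_len(min(3L, dplyr::n()))]), .groups = "drop"),
      ms2_sum = joined |>
        group_by(.data$index) |>
        summarise(ref_ik = sum(.data$ref_weighted_ms1), .groups = "drop")
    )
    val
  })
  all_ik <- bind_rows(per_plex, .id = "plex_id")
  if (!nrow(all_ik)) return(tibble(index = character(0), ref_intensity = numeric(0)))
  global_min <- min(all_ik$ref_ik)
  all_ik |>
    group_by(.data$index) |>
    summarise(ref_intensity = {
      v <- .data$ref_ik
      if (impute_missing && n_plex > 1L && length(v) < n_plex) {
        v <- c(v, rep(global_min, n_plex - length(v)))
      }
      median_na(v)
    }, .groups = "drop")
}

#' Convert a ratio report to an abundance report
#'
#' Reconstructs log2 abundances by adding each entry's log2 reference
#' intensity to its (typically MD-normalized) log2 ratios:
#' `A = R + log2(Ref)`. Entries with no positive reference intensity are
#' dropped (with a message). `NA` cells are preserved and within-row
#' differences are unchanged.
#'
#' @param report An `iso_report` of ratios.
#' @param ref Tibble `index`, `ref_intensity` from [reference_intensity()].
#' @return An `iso_report` of kind `"abundance"` with a
#'   `reference_intensity` column.
#' @export
ratios_to_abundance <- function(report, ref) {
  stopifnot(inherits(report, "iso_report"))
  if (attr(report, "kind") != "ratio") abort("input must be a ratio report")
  ref <- ref[match(report$index, ref$index), , drop = FALSE]
  keep <- !is.na(ref$ref_intensity) & ref$ref_intensity > 0
  if (!all(keep)) {
    inform(sprintf("%d entries without a positive reference intensity dropped from abundance table",
                   sum(!keep)))
  }
  out <- report[keep, , drop = FALSE]
  refv <- ref$ref_intensity[keep]
  m <- report_values(out) + rep(log2(refv), times = length(sample_cols(out)))
  out <- set_report_values(out, m)
  out$reference_intensity <- refv
  out <- out[, c(meta_cols(out), sample_cols(out)), drop = FALSE]
  attr(out, "kind") <- "abundance"
  out
}

#' Collapse a multi-site report to single localized sites
#'
#' Builds the single-site report from a multi-site report by three rules:
#' entries without any confidently localized site are removed; a site
#' observed in a singly-modified localized form takes its value from that
#' form (the per-sample median when several singly-modified forms exist);
#' a site observed only together with other modifications takes the
#' per-sample median across all multi-site entries in which it is localized.
#' Single-site indexes are `<accession>_<residue><protein position>`.
#' Reference intensities (when supplied) follow the same precedence and are
#' returned as the `site_ref` attribute.
#'
#' @param multisite A multisite-level `iso_report` of ratios.
#' @param ref Optional tibble `index`, `ref_intensity` for the multisite
#'   entries.
#' @return A singlesite-level `iso_report`; when `ref` is given, with a
#'   `site_ref` attribute (tibble `index`, `ref_intensity`).
#' @export
collapse_single_site <- function(multisite, ref = NULL) {
  stopifnot(inherits(multisite, "iso_report"))
  if (attr(multisite, "level") != "multisite") abort("input must be a multisite report")
  parsed <- parse_multisite_index(multisite$index)
  sc <- sample_cols(multisite)

  rows <- purrr::map_dfr(seq_len(nrow(multisite)), function(i) {
    sites <- parsed$sites[[i]]
    if (is.null(sites) || nrow(sites) == 0L) return(NULL)
    tibble(row = i, protein = parsed$protein[i],
           residue = sites$residue, position = sites$position,
           n_mods = parsed$n_mods[i])
  })
  if (!nrow(rows)) {
    empty <- multisite[0, , drop = FALSE]
    attr(empty, "level") <- "singlesite"
    return(empty)
  }

  ref_map <- if (!is.null(ref)) ref$ref_intensity[match(multisite$index, ref$index)] else NULL
  m <- report_values(multisite)

  per_site <- rows |>
    group_by(.data$protein, .data$residue, .data$position) |>
    group_modify(function(d, key) {
      use <- if (any(d$n_mods == 1L)) d$row[d$n_mods == 1L] else d$row
      vals <- apply(m[use, , drop = FALSE], 2, median_na)
      out <- tibble(
        gene = first_nonempty(multisite$gene[use]),
        peptide = paste(sort(unique(multisite$peptide[use])), collapse = ";"),
        max_psm_prob = suppressWarnings(max(multisite$max_psm_prob[use], na.rm = TRUE)),
        n_psms = sum(multisite$n_psms[use])
      )
      if (!is.null(ref_map)) out$site_ref <- median_na(ref_map[use])
      bind_cols(out, as_tibble(as.list(setNames(vals, sc))))
    }) |>
    ungroup() |>
    arrange(.data$protein, .data$position, .data$residue)

  df <- per_site |>
    mutate(index = sprintf("%s_%s%d", .data$protein, .data$residue, .data$position))
  site_ref <- NULL
  if (!is.null(ref_map)) {
    site_ref <- tibble(index = df$index, ref_intensity = df$site_ref)
    df$site_ref <- NULL
  }
  df <- df[, c("index", "gene", "protein", "peptide", "max_psm_prob", "n_psms", sc)]
  out <- iso_report(df, level = "singlesite",
                    normalization = attr(multisite, "normalization"),
                    kind = "ratio", samples = attr(multisite, "samples"))
  if (!is.null(site_ref)) attr(out, "site_ref") <- site_ref
  out
}

first_nonempty <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x)) x[1] else ""
}

# Parse "<accession>|<peptide>|<config>" multisite indexes; config lists
# localized sites "S315,T320" with optional "+<k>u" unlocalized suffix.
parse_multisite_index <- function(index) {
  parts <- stringr::str_match(index, "^(.*)\\|([A-Za-z]+)\\|(.*)$")
  if (anyNA(parts[, 1])) abort("multisite index not parseable")
  config <- parts[, 4]
  unloc <- stringr::str_match(config, "\\+(\\d+)u$")[, 2]
  n_unloc <- ifelse(is.na(unloc), 0L, as.integer(unloc))
  site_part <- sub("\\+\\d+u$", "", config)
  sites <- lapply(site_part, function(s) {
    if (!nzchar(s)) return(NULL)
    toks <- strsplit(s, ",", fixed = TRUE)[[1]]
    tibble(residue = substr(toks, 1, 1),
           position = as.integer(sub("^[A-Z]", "", toks)))
  })
  n_loc <- vapply(sites, function(s) if (is.null(s)) 0L else nrow(s), integer(1))
  list(protein = parts[, 2], peptide = parts[, 3], config = config,
       sites = sites, n_unloc = n_unloc, n_mods = n_loc + n_unloc)
}
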