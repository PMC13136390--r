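#' Filtering configuration
#'
#' Thresholds for PSM-level quality filtering, applied by [filter_psms()] in
#' a fixed rule order. Defaults follow the whole-proteome workflow: minimum
#' precursor purity 0.5, minimum PSM probability 0.9, exclusion of the lowest
#' 5\% of summed reporter intensities (2.5\% is customary for
#' phosphoproteome data), best-PSM selection on, unique+razor peptides. For
#' high-resolution Astral acquisitions, `astral_mode` additionally requires a
#' summed signal-to-noise ratio of at least 1000 and flags any channel whose
#' resolution falls below 45000 while its SNR is at least 1.
#'
#' @param min_purity Minimum precursor-ion purity (default 0.5).
#' @param min_probability Minimum PSM posterior probability (default 0.9).
#' @param low_intensity_fraction Fraction of PSMs with the lowest summed
#'   reporter intensity to discard, in `[0, 1)` (default 0.05).
#' @param best_psm Keep only the highest summed-intensity PSM per
#'   (run, modified peptide, charge) group (default `TRUE`).
#' @param require_label Drop PSMs whose peptide carries no isobaric label.
#' @param require_reference_nonzero Drop PSMs with zero intensity in the real
#'   reference channel (ignored under a virtual reference).
#' @param astral_mode Enable SNR/resolution filtering (default `FALSE`).
#' @param min_summed_snr Minimum summed per-channel SNR in Astral mode.
#' @param min_resolution Minimum per-channel resolution in Astral mode.
#' @param uniqueness `"unique_plus_razor"` (default), `"unique_only"`, or
#'   `"unique_gene"` (drop peptides mapping to more than one gene symbol).
#' @param min_site_probability Localization probability at or above which a
#'   modification site counts as confidently localized (default 0.75).
#' @param mod_tag Target modification as `"<residues>:<delta mass>"`
#'   (e.g. `"S,T,Y:79.96633"`), or `NULL` when no PTM reports are requested.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_purity = 0.5, min_probability = 0.9,
                          low_intensity_fraction = 0.05, best_psm = TRUE,
                          require_label = TRUE, require_reference_nonzero = TRUE,
                          astral_mode = FALSE, min_summed_snr = 1000,
                          min_resolution = 45000,
                          uniqueness = c("unique_plus_razor", "unique_only", "unique_gene"),
                          min_site_probability = 0.75, mod_tag = NULL) {
  assert_scalar_number(min_purity, "min_purity", 0, 1)
  assert_scalar_number(min_probability, "min_probability", 0, 1)
  assert_scalar_number(low_intensity_fraction, "low_intensity_fraction", 0, Inf)
  if (low_intensity_fraction >= 1) abort("`low_intensity_fraction` must be < 1")
  assert_scalar_number(min_site_probability, "min_site_probability", 0, 1)
  assert_scalar_number(min_summed_snr, "min_summed_snr", 0)
  assert_scalar_number(min_resolution, "min_resolution", 0)
  structure(list(
    min_purity = min_purity, min_probability = min_probability,
    low_intensity_fraction = low_intensity_fraction, best_psm = isTRUE(best_psm),
    require_label = isTRUE(require_label),
    require_reference_nonzero = isTRUE(require_reference_nonzero),
    astral_mode = isTRUE(astral_mode), min_summed_snr = min_summed_snr,
    min_resolution = min_resolution, uniqueness = match.arg(uniqueness),
    min_site_probability = min_site_probability,
    mod_tag = mod_tag
  ), class = "filter_config")
}

#' Filter the PSMs of one plex
#'
#' Applies quality filters in a fixed order: (1) unlabeled peptides; (2) zero
#' intensity in the real reference channel; (3) precursor purity below
#' threshold; (4) PSM probability below threshold; (5) contaminants; (6) the
#' lowest `low_intensity_fraction` of summed reporter intensities, with the
#' percentile computed over the PSMs surviving rules 1-5 and removal strict
#' (a PSM exactly at the cutoff is retained); (7) best-PSM selection within
#' each (run, modified peptide, charge) group by maximum summed reporter
#' intensity (ties: higher probability, then smaller spectrum id); (8) in
#' Astral mode, summed SNR below `min_summed_snr`, or any channel with
#' resolution below `min_resolution` while that channel's SNR is >= 1;
#' (9) the uniqueness rule. The count removed by each rule is attached as the
#' `filter_report` attribute (see [filter_report()]).
#'
#' @param plex A [plex_table()].
#' @param cfg A [filter_config()].
#' @return The plex with filtered `psms` and a `filter_report` attribute.
#' @export
filter_psms <- function(plex, cfg = filter_config()) {
  stopifnot(inherits(plex, "plex_table"), inherits(cfg, "filter_config"))
  p <- plex$psms
  report <- list()
  note <- function(rule, n_before, n_after) {
    report[[length(report) + 1L]] <<- tibble(rule = rule, n_removed = n_before - n_after,
                                             n_remaining = n_after)
  }
  drop <- function(p, keep, rule) {
    keep[is.na(keep)] <- FALSE
    out <- p[keep, , drop = FALSE]
    note(rule, nrow(p), nrow(out))
    out
  }

  p <- drop(p, if (cfg$require_label) p$has_label else rep(TRUE, nrow(p)), "unlabeled")
  ref_keep <- rep(TRUE, nrow(p))
  if (plex$reference$mode == "real" && cfg$require_reference_nonzero && nrow(p)) {
    ref_keep <- p$reporter[, plex$reference$channel] > 0
  }
  p <- drop(p, ref_keep, "reference_zero")
  p <- drop(p, p$purity >= cfg$min_purity, "low_purity")
  p <- drop(p, p$probability >= cfg$min_probability, "low_probability")
  p <- drop(p, !p$is_contaminant, "contaminant")

  # low-intensity percentile over survivors of rules 1-5; strict removal
  if (nrow(p) && cfg$low_intensity_fraction > 0) {
    sums <- rowSums(p$reporter)
    cutoff <- quantile(sums, cfg$low_intensity_fraction, type = 7, names = FALSE)
    p <- drop(p, sums >= cutoff, "low_intensity")
  } else {
    note("low_intensity", nrow(p), nrow(p))
  }

  if (cfg$best_psm && nrow(p)) {
    sums <- rowSums(p$reporter)
    ord <- order(p$run_id, p$modified_peptide, p$charge,
                 -sums, -p$probability, p$spectrum_id)
    key <- paste(p$run_id, p$modified_peptide, p$charge, sep = "\r")
    best <- ord[!duplicated(key[ord])]
    p <- drop(p, seq_len(nrow(p)) %in% best, "best_psm")
  } else {
    note("best_psm", nrow(p), nrow(p))
  }

  if (cfg$astral_mode && nrow(p)) {
    if (!all(c("snr", "resolution") %in% names(p))) {
      abort("astral_mode requires per-channel `snr` and `resolution` columns")
    }
    snr_ok <- rowSums(p$snr) >= cfg$min_summed_snr
    res_bad <- rowSums(p$resolution < cfg$min_resolution & p$snr >= 1) > 0
    p <- drop(p, snr_ok & !res_bad, "astral_snr_resolution")
  } else {
    note("astral_snr_resolution", nrow(p), nrow(p))
  }

  keep <- switch(cfg$uniqueness,
    unique_plus_razor = rep(TRUE, nrow(p)),
    unique_only = p$is_unique,
    unique_gene = {
      n_genes <- mapply(function(g, mg) length(unique(c(g[nzchar(g)], mg))),
                        p$gene, p$mapped_genes)
      n_genes <= 1
    }
  )
  p <- drop(p, keep, "uniqueness")

  plex$psms <- p
  attr(plex, "filter_report") <- bind_rows(report)
  plex
}

#' Per-rule removal counts from the last [filter_psms()] call
#'
#' @param plex A filtered `plex_table`.
#' @return A tibble with columns `rule`, `n_removed`, `n_remaining`.
#' @export
filter_report <- function(plex) {
  attr(plex, "filter_report") %||%
    abort("no filter report: run filter_psms() first")
}

# Parse a "S,T,Y:79.96633" modification tag.
parse_mod_tag <- function(mod_tag) {
  if (is.null(mod_tag)) return(NULL)
  parts <- strsplit(mod_tag, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) abort("mod_tag must look like 'S,T,Y:79.96633'")
  residues <- toupper(trimws(strsplit(parts[1], ",", fixed = TRUE)[[1]]))
  mass <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(mass)) abort("mod_tag mass is not numeric")
  list(residues = residues, mass = mass)
}
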