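#' Convert reporter intensities to log2 ratios against the reference
#'
#' Implements ratio-to-reference conversion on a PSM-by-PSM basis. Reporter
#' intensities are log2-transformed and the reference intensity is
#' subtracted. With a real reference the reference is the designated bridge
#' channel of the plex, and the reference sample is excluded from the output.
#' With a virtual reference the per-spectrum reference intensity is the
#' arithmetic mean of the reporter intensities (zero channels excluded from
#' the mean), and with per-subplex virtual references the mean is taken
#' within each channel's subplex so that each subplex is normalized
#' independently. Channels with zero intensity yield `NA` ratios.
#'
#' Each PSM also receives a reference weight `ref_weight` (reference-channel
#' intensity divided by the PSM's summed reporter intensity) and a
#' reference-weighted MS1 intensity `ref_weighted_ms1`
#' (`ref_weight * precursor_intensity`), used later for reference-intensity
#' estimation.
#'
#' @param plex A filtered [plex_table()].
#' @return A tibble in long form with one row per (PSM, non-reference
#'   sample): `plex_id`, `spectrum_id`, `channel`, `sample`, `subplex`,
#'   `ratio` (log2), and per-PSM columns `ref_intensity` (linear reference
#'   intensity), `ref_weight`, `ref_weighted_ms1`, `precursor_intensity`,
#'   `retention_time`.
#' @export
to_ratios <- function(plex) {
  stopifnot(inherits(plex, "plex_table"))
  p <- plex$psms
  I <- p$reporter
  n <- nrow(I)
  chans <- plex$channels
  logI <- suppressWarnings(log2(I))
  logI[I == 0] <- NA_real_

  mode <- plex$reference$mode
  if (mode == "real") {
    ref_col <- plex$reference$channel
    ref_int <- I[, ref_col]
    if (any(ref_int == 0)) {
      abort("real reference with zero intensity encountered; filter_psms() with require_reference_nonzero should have removed it")
    }
    ratios <- logI - log2(ref_int)
    out_chans <- chans[chans$channel != ref_col, , drop = FALSE]
    ratios <- ratios[, out_chans$channel, drop = FALSE]
  } else if (mode == "virtual") {
    nz <- rowSums(I > 0)
    ref_int <- ifelse(nz > 0, rowSums(I) / pmax(nz, 1L), 0)
    ratios <- logI - log2(ref_int)
    out_chans <- chans
  } else { # virtual_subplex
    ratios <- logI
    for (sp in unique(chans$subplex)) {
      cols <- chans$channel[chans$subplex == sp]
      Isp <- I[, cols, drop = FALSE]
      nz <- rowSums(Isp > 0)
      ref_sp <- ifelse(nz > 0, rowSums(Isp) / pmax(nz, 1L), 0)
      ratios[, cols] <- logI[, cols, drop = FALSE] - log2(ref_sp)
    }
    # overall reference intensity for weighting: mean over non-zero channels
    nz <- rowSums(I > 0)
    ref_int <- ifelse(nz > 0, rowSums(I) / pmax(nz, 1L), 0)
    out_chans <- chans
  }

  tot <- rowSums(I)
  ref_weight <- ifelse(tot > 0, ref_int / tot, 0)
  ref_weighted_ms1 <- ref_weight * p$precursor_intensity

  k <- nrow(out_chans)
  tibble(
    plex_id = plex$plex_id,
    spectrum_id = rep(p$spectrum_id, times = k),
    channel = rep(out_chans$channel, each = n),
    sample = rep(out_chans$sample, each = n),
    subplex = rep(out_chans$subplex, each = n),
    ratio = as.vector(ratios),
    ref_intensity = rep(ref_int, times = k),
    ref_weight = rep(ref_weight, times = k),
    ref_weighted_ms1 = rep(ref_weighted_ms1, times = k),
    precursor_intensity = rep(p$precursor_intensity, times = k),
    retention_time = rep(p$retention_time, times = k)
  )
}

#' Retention-time bin normalization of PSM ratios
#'
#' Optional second-stage PSM normalization: within each sample, PSMs are
#' split into `n_bins` equal-count retention-time bins and the median ratio
#' of the bin is subtracted from each ratio in it. Off by default in the
#' pipeline.
#'
#' @param ratios Long ratio tibble from [to_ratios()] (carries
#'   `retention_time`).
#' @param n_bins Number of equal-count retention-time bins (default 10).
#' @return The ratio tibble with bin medians subtracted.
#' @export
rt_bin_normalize <- function(ratios, n_bins = 10L) {
  stopifnot(is.data.frame(ratios), n_bins >= 1L)
  n_psm <- length(unique(ratios$spectrum_id))
  if (n_psm < n_bins) {
    warn(sprintf("only %d PSMs for %d retention-time bins; using a single bin",
                 n_psm, n_bins))
    n_bins <- 1L
  }
  ratios |>
    group_by(.data$plex_id, .data$sample) |>
    mutate(.bin = dplyr::ntile(.data$retention_time, n_bins)) |>
    group_by(.data$plex_id, .data$sample, .data$.bin) |>
    mutate(ratio = .data$ratio - median_na(.data$ratio)) |>
    ungroup() |>
    select(-".bin")
}
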