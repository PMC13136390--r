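#' The spike-in benchmark fold-change series
#'
#' Designed linear fold changes used by the classic two-proteome spike-in
#' benchmark: 1, 2, 4, 5, 10, 20 and 40.
#'
#' @return Numeric vector of fold changes.
#' @export
spike_series <- function() c(1, 2, 4, 5, 10, 20, 40)

#' Simulation design for synthetic plexes
#'
#' Describes a multi-plex isobaric experiment with known ground truth:
#' background proteins present at equal amounts in every channel, optional
#' spike-in proteins with designed per-channel fold changes, an optional real
#' (pooled-mean) reference channel, lognormal multiplicative measurement
#' noise, intensity-dependent co-isolation interference, and missing values.
#'
#' Interference is modeled as a channel-uniform background (the mean channel
#' profile over all proteins) replacing a fraction of each PSM's reporter
#' signal; the fraction scales inversely with the PSM's precursor intensity,
#' so low-intensity PSMs suffer more ratio compression - mirroring
#' co-isolation in MS2 reporter data.
#'
#' @param n_plexes Number of plexes.
#' @param n_channels Channels per plex (default 10, TMT 10-plex).
#' @param channel_labels Channel labels; defaults to the TMT 10-plex labels
#'   (or `ch01...` beyond 11 channels).
#' @param n_background_proteins Background proteins at equal amounts in all
#'   channels.
#' @param spike_proteins Named list: protein name to linear fold-change
#'   vector of length `n_channels`.
#' @param reference_channel Optional channel index whose amounts are set to
#'   the pooled mean of all other channels (a real bridge sample); `NULL`
#'   for designs analysed with a virtual reference.
#' @param psms_per_protein PSMs simulated per protein per plex.
#' @param noise_cv Coefficient of variation of the lognormal reporter noise.
#' @param interference Interference level in `[0, 1)`.
#' @param missing_rate Probability that a reporter cell is not observed.
#' @param subplexes Optional character vector (length `n_channels`) of
#'   subplex ids, e.g. deuterated vs non-deuterated reagent blocks.
#' @param subplex_offsets Optional named numeric: multiplicative intensity
#'   offset applied to every channel of a subplex (a deliberate batch
#'   effect).
#' @param shared_peptide_rate Fraction of peptides additionally mapped to a
#'   second protein (razor assignment stays with the first).
#' @param ptm Optional PTM simulation: list with `residues` (e.g.
#'   `c("S","T")`), `mass` (delta mass), `rate` (fraction of PSMs modified)
#'   and `localized_rate` (fraction of modified PSMs with a confidently
#'   localized site).
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_plexes = 1L, n_channels = 10L, channel_labels = NULL,
                       n_background_proteins = 200L, spike_proteins = list(),
                       reference_channel = NULL, psms_per_protein = 20L,
                       noise_cv = 0.05, interference = 0, missing_rate = 0,
                       subplexes = NULL, subplex_offsets = NULL,
                       shared_peptide_rate = 0, ptm = NULL) {
  assert_scalar_number(n_plexes, "n_plexes", 1)
  assert_scalar_number(n_channels, "n_channels", 2)
  assert_scalar_number(noise_cv, "noise_cv", 0)
  assert_scalar_number(interference, "interference", 0, 1 - 1e-9)
  assert_scalar_number(missing_rate, "missing_rate", 0, 1 - 1e-9)
  assert_scalar_number(shared_peptide_rate, "shared_peptide_rate", 0, 1)
  if (is.null(channel_labels)) {
    tmt10 <- c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C", "131")
    channel_labels <- if (n_channels <= 10) tmt10[seq_len(n_channels)] else
      sprintf("ch%02d", seq_len(n_channels))
  }
  if (length(channel_labels) != n_channels) abort("channel_labels length must equal n_channels")
  for (nm in names(spike_proteins)) {
    fc <- spike_proteins[[nm]]
    if (length(fc) != n_channels) abort(sprintf("fold-change vector for '%s' must have %d entries", nm, n_channels))
    if (any(!is.finite(fc) | fc <= 0)) abort(sprintf("fold changes for '%s' must be positive", nm))
  }
  if (!is.null(reference_channel)) {
    assert_scalar_number(reference_channel, "reference_channel", 1, n_channels)
  }
  if (!is.null(subplexes) && length(subplexes) != n_channels) {
    abort("subplexes must assign every channel")
  }
  structure(list(
    n_plexes = as.integer(n_plexes), n_channels = as.integer(n_channels),
    channel_labels = as.character(channel_labels),
    n_background_proteins = as.integer(n_background_proteins),
    spike_proteins = spike_proteins, reference_channel = reference_channel,
    psms_per_protein = as.integer(psms_per_protein), noise_cv = noise_cv,
    interference = interference, missing_rate = missing_rate,
    subplexes = subplexes, subplex_offsets = subplex_offsets,
    shared_peptide_rate = shared_peptide_rate, ptm = ptm
  ), class = "sim_design")
}

#' Simulate multi-plex PSM tables with known ground truth
#'
#' Generates one [plex_table()] per plex under a [sim_design()], together
#' with the ground-truth per-protein channel amounts and the true log2
#' ratios to the design's reference (the bridge channel when
#' `reference_channel` is set, otherwise the per-protein channel mean, per
#' subplex when subplexes are defined). Deterministic given `seed`; the
#' caller's RNG state is untouched.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed controlling every stochastic draw.
#' @return A list of class `iso_sim`: `plexes` (list of `plex_table`),
#'   `truth` (tibble `protein`, `channel`, `sample`, `amount`,
#'   `true_log2_ratio`), and `design`.
#' @export
simulate_plexes <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(seed, simulate_plexes_impl(design))
}

simulate_plexes_impl <- function(design) {
  C <- design$n_channels
  prot_names <- c(sprintf("BG%04d", seq_len(design$n_background_proteins)),
                  names(design$spike_proteins))
  P <- length(prot_names)
  amounts <- rbind(
    matrix(1, nrow = design$n_background_proteins, ncol = C),
    do.call(rbind, unname(design$spike_proteins)) %||% matrix(0, 0, C)
  )
  rownames(amounts) <- prot_names
  if (!is.null(design$reference_channel)) {
    rc <- design$reference_channel
    amounts[, rc] <- rowMeans(amounts[, -rc, drop = FALSE])
  }

  # deterministic peptide repertoire per protein
  n_pep <- max(1L, ceiling(design$psms_per_protein / 4L))
  aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P", "Q", "S", "T", "V", "W", "Y")
  peptides <- lapply(seq_len(P), function(p) {
    vapply(seq_len(n_pep), function(j) {
      len <- sample(8:14, 1)
      paste0(paste(sample(aa, len - 1, replace = TRUE), collapse = ""), "K")
    }, character(1))
  })
  shared_with <- lapply(seq_len(P), function(p) {
    vapply(seq_len(n_pep), function(j) {
      if (P > 1 && stats::runif(1) < design$shared_peptide_rate) {
        prot_names[sample(setdiff(seq_len(P), p), 1)]
      } else NA_character_
    }, character(1))
  })

  channels <- tibble(
    channel = design$channel_labels,
    sample = paste0("S", formatC(seq_len(C), width = 2, flag = "0")),
    subplex = if (is.null(design$subplexes)) NA_character_ else as.character(design$subplexes)
  )
  if (!is.null(design$reference_channel)) {
    channels$sample[design$reference_channel] <- "Bridge"
  }

  offsets <- rep(1, C)
  if (!is.null(design$subplex_offsets)) {
    if (is.null(design$subplexes)) abort("subplex_offsets requires subplexes")
    offsets <- unname(design$subplex_offsets[channels$subplex])
  }

  sdlog <- sqrt(log(1 + design$noise_cv^2))
  plexes <- vector("list", design$n_plexes)
  truths <- vector("list", design$n_plexes)
  for (k in seq_len(design$n_plexes)) {
    plex_id <- sprintf("plex%d", k)
    n <- P * design$psms_per_protein
    prot_idx <- rep(seq_len(P), each = design$psms_per_protein)
    within <- rep(seq_len(design$psms_per_protein), times = P) - 1L
    pep_idx <- within %% n_pep + 1L
    frac <- within %/% n_pep + 1L

    base <- stats::rlnorm(n, meanlog = log(2^16), sdlog = 0.8)
    precursor <- base * stats::rlnorm(n, meanlog = log(20), sdlog = 0.3)

    f <- rep(0, n)
    if (design$interference > 0) {
      f <- pmin(0.9, design$interference * sqrt(stats::median(precursor) / precursor))
    }
    bg_profile <- colMeans(amounts)
    prof <- amounts[prot_idx, , drop = FALSE]
    mix <- prof * (1 - f) + outer(f, bg_profile)
    eps <- matrix(stats::rlnorm(n * C, meanlog = -sdlog^2 / 2, sdlog = sdlog), n, C)
    reporter <- base * mix * eps
    reporter <- sweep(reporter, 2, offsets, "*")
    if (design$missing_rate > 0) {
      reporter[matrix(stats::runif(n * C) < design$missing_rate, n, C)] <- 0
    }
    colnames(reporter) <- channels$channel

    peptide <- vapply(seq_len(n), function(i) peptides[[prot_idx[i]]][pep_idx[i]], character(1))
    modified_peptide <- peptide
    site_loc <- vector("list", n)
    if (!is.null(design$ptm)) {
      ptm <- design$ptm
      modded <- stats::runif(n) < (ptm$rate %||% 1)
      for (i in which(modded)) {
        pep <- peptide[i]
        cand <- which(strsplit(pep, "")[[1]] %in% ptm$residues)
        if (!length(cand)) next
        pos <- sample(cand, 1)
        res <- substr(pep, pos, pos)
        modified_peptide[i] <- paste0(substr(pep, 1, pos), sprintf("[%.4f]", ptm$mass),
                                      substr(pep, pos + 1, nchar(pep)))
        localized <- stats::runif(1) < (ptm$localized_rate %||% 0.8)
        p_top <- if (localized) stats::runif(1, 0.8, 1) else stats::runif(1, 0.3, 0.7)
        others <- setdiff(cand, pos)
        probs <- c(p_top, rep((1 - p_top) / max(1, length(others)), length(others)))
        posv <- c(pos, others)
        site_loc[[i]] <- tibble(
          residue = substr(rep(pep, length(posv)), posv, posv),
          peptide_position = as.integer(posv),
          protein_position = as.integer(100L + posv),
          probability = pmin(1, probs)
        )
      }
    }

    psms <- tibble(
      spectrum_id = sprintf("%s.f%02d.%05d", plex_id, frac, seq_len(n)),
      run_id = sprintf("%s_f%02d", plex_id, frac),
      peptide = peptide,
      modified_peptide = modified_peptide,
      charge = 2L,
      probability = stats::runif(n, 0.95, 1),
      purity = pmin(1, pmax(0, 1 - f + stats::rnorm(n, 0, 0.01))),
      precursor_intensity = precursor,
      retention_time = stats::runif(n, 0, 6000),
      protein = prot_names[prot_idx],
      gene = paste0("g", prot_names[prot_idx]),
      mapped_proteins = lapply(seq_len(n), function(i) {
        s <- shared_with[[prot_idx[i]]][pep_idx[i]]
        if (is.na(s)) character(0) else s
      }),
      mapped_genes = lapply(seq_len(n), function(i) {
        s <- shared_with[[prot_idx[i]]][pep_idx[i]]
        if (is.na(s)) character(0) else paste0("g", s)
      }),
      is_unique = vapply(seq_len(n), function(i) {
        is.na(shared_with[[prot_idx[i]]][pep_idx[i]])
      }, logical(1)),
      is_contaminant = FALSE, is_decoy = FALSE, has_label = TRUE,
      protein_start = 101L,
      site_localizations = site_loc
    )
    psms$reporter <- reporter

    reference <- if (!is.null(design$reference_channel)) "Bridge" else "virtual"
    plexes[[k]] <- plex_table(psms, channels, plex_id = plex_id, reference = reference)

    # ground truth: log2 ratio of amounts to the design's reference
    ref_amt <- if (!is.null(design$reference_channel)) {
      matrix(amounts[, design$reference_channel], P, C)
    } else if (!is.null(design$subplexes)) {
      sp <- as.character(design$subplexes)
      out <- matrix(NA_real_, P, C)
      for (s in unique(sp)) {
        cols <- which(sp == s)
        out[, cols] <- rowMeans(amounts[, cols, drop = FALSE])
      }
      out
    } else {
      matrix(rowMeans(amounts), P, C)
    }
    truths[[k]] <- tibble(
      plex_id = plex_id,
      protein = rep(prot_names, times = C),
      channel = rep(channels$channel, each = P),
      sample = rep(channels$sample, each = P),
      amount = as.vector(amounts),
      true_log2_ratio = as.vector(log2(amounts / ref_amt))
    )
  }
  structure(list(plexes = plexes, truth = bind_rows(truths), design = design),
            class = "iso_sim")
}

#' @export
print.iso_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf("<iso_sim> %d plex(es) x %d channels, %d proteins, %d PSMs/protein\n",
              d$n_plexes, d$n_channels,
              d$n_background_proteins + length(d$spike_proteins),
              d$psms_per_protein))
  invisible(x)
}
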