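#' Build a plex table
#'
#' A plex table bundles everything known about one isobaric plex: the PSM
#' tibble, the channel-to-sample annotation, an optional channel-to-subplex
#' assignment, and the reference designation used for ratio conversion.
#'
#' @param psms Tibble of PSMs as returned by [read_psm_table()]. Must carry a
#'   `reporter` matrix column with one column per annotated channel.
#' @param channels Tibble with columns `channel` and `sample` (and optionally
#'   `subplex`), as returned by [read_annotation()].
#' @param plex_id Identifier for the plex, used to label report columns.
#' @param reference Either the name of the reference (bridge) sample within
#'   this plex, or `"virtual"` for a per-spectrum virtual reference. When the
#'   annotation carries a `subplex` column with more than one subplex,
#'   `"virtual"` means an independent virtual reference per subplex.
#'
#' @return An object of class `plex_table`.
#' @export
plex_table <- function(psms, channels, plex_id = "plex1", reference = "virtual") {
  stopifnot(is.data.frame(psms), is.data.frame(channels))
  channels <- as_tibble(channels)
  if (!all(c("channel", "sample") %in% names(channels))) {
    abort("`channels` must have columns `channel` and `sample`")
  }
  channels$channel <- as.character(channels$channel)
  channels$sample <- as.character(channels$sample)
  if (anyDuplicated(channels$channel)) abort("duplicate channel labels in annotation")
  if (anyDuplicated(channels$sample)) abort("duplicate sample names within plex")
  if (!"subplex" %in% names(channels)) channels$subplex <- NA_character_
  if (anyNA(channels$subplex) && !all(is.na(channels$subplex))) {
    abort("either every channel or no channel must be assigned to a subplex")
  }

  if (!"reporter" %in% names(psms) || !is.matrix(psms$reporter)) {
    abort("`psms` must carry a `reporter` matrix column")
  }
  if (ncol(psms$reporter) != nrow(channels)) {
    abort(sprintf(
      "channel-count mismatch: reporter matrix has %d columns, annotation %d channels",
      ncol(psms$reporter), nrow(channels)
    ))
  }
  colnames(psms$reporter) <- channels$channel
  if (any(psms$reporter < 0, na.rm = TRUE)) abort("reporter intensities must be >= 0")
  if (anyDuplicated(psms$spectrum_id)) abort("spectrum_id must be unique within a plex")

  n_subplexes <- length(unique(channels$subplex[!is.na(channels$subplex)]))
  if (identical(reference, "virtual")) {
    ref <- list(mode = if (n_subplexes > 1L) "virtual_subplex" else "virtual",
                sample = NULL, channel = NULL)
  } else {
    if (!reference %in% channels$sample) {
      abort(sprintf("reference sample '%s' not found in annotation", reference))
    }
    ref <- list(mode = "real", sample = reference,
                channel = channels$channel[match(reference, channels$sample)])
  }

  structure(
    list(plex_id = plex_id, channels = channels, reference = ref,
         psms = as_tibble(psms)),
    class = "plex_table"
  )
}

#' @export
print.plex_table <- function(x, ...) {
  ref <- switch(x$reference$mode,
    real = sprintf("real (sample '%s', channel '%s')", x$reference$sample, x$reference$channel),
    virtual = "virtual (per-spectrum channel mean)",
    virtual_subplex = "virtual, per subplex"
  )
  cat(sprintf("<plex_table> %s: %d PSMs, %d channels, reference %s\n",
              x$plex_id, nrow(x$psms), nrow(x$channels), ref))
  invisible(x)
}

#' @export
dim.plex_table <- function(x) c(nrow(x$psms), nrow(x$channels))

n_subplexes <- function(plex) {
  sp <- plex$channels$subplex
  length(unique(sp[!is.na(sp)]))
}
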