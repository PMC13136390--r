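#' Read a per-plex PSM table
#'
#' Reads a FragPipe-style `psm.tsv` (tab-separated, one row per
#' peptide-spectrum match). Column headers are matched case-insensitively and
#' after collapsing punctuation to spaces, so header drift across versions
#' ("PeptideProphet Probability" vs "Probability") is tolerated; additional
#' aliases can be supplied. Reporter-ion intensity columns are located by
#' channel label. Decoy PSMs (accession prefix `decoy_prefix`) are dropped at
#' read time; contaminant PSMs (`contam_prefix`) are flagged and removed later
#' by [filter_psms()].
#'
#' @param path Path to the tab-separated PSM table (header row required).
#' @param channel_labels Character vector of reporter channel labels, in
#'   annotation order (e.g. `c("126","127N",...)`).
#' @param decoy_prefix,contam_prefix Accession prefixes marking decoy and
#'   contaminant proteins.
#' @param aliases Named list mapping canonical field names to extra header
#'   aliases (normalised form), merged over the built-in map.
#'
#' @return A tibble with one row per non-decoy PSM: identification fields,
#'   `precursor_intensity`, a `reporter` matrix column (one column per
#'   channel; missing cells read as 0), optional `snr` / `resolution` matrix
#'   columns, and a `site_localizations` list column of per-site tibbles
#'   (`residue`, `peptide_position`, `protein_position`, `probability`).
#' @export
read_psm_table <- function(path, channel_labels,
                           decoy_prefix = "rev_", contam_prefix = "contam_",
                           aliases = list()) {
  if (!file.exists(path)) abort(sprintf("PSM table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (nrow(raw) == 0L && ncol(raw) == 0L) abort(sprintf("empty PSM table: %s", path))
  channel_labels <- as.character(channel_labels)
  norm <- normalise_header(names(raw))

  alias_map <- utils::modifyList(default_psm_aliases(), aliases)
  find_col <- function(field) {
    hit <- which(norm %in% alias_map[[field]])
    if (length(hit)) hit[1] else NA_integer_
  }
  need <- function(field, label) {
    i <- find_col(field)
    if (is.na(i)) abort(sprintf("required column missing from %s: %s", path, label))
    i
  }

  col_pep   <- need("peptide", "peptide")
  col_mpep  <- need("modified_peptide", "modified peptide")
  col_prob  <- need("probability", "probability")
  col_pur   <- need("purity", "purity")
  col_int   <- need("precursor_intensity", "intensity")
  col_prot  <- need("protein", "protein")
  col_gene  <- need("gene", "gene")

  chan_idx <- match(normalise_header(channel_labels), norm)
  if (anyNA(chan_idx)) {
    abort(sprintf("reporter column(s) missing from %s: %s", path,
                  paste(channel_labels[is.na(chan_idx)], collapse = ", ")))
  }

  as_num <- function(x, what) {
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(sprintf("non-numeric %s value '%s' at row %d of %s",
                    what, x[bad[1]], bad[1], path))
    }
    out
  }

  reporter <- sapply(chan_idx, function(i) {
    v <- as_num(raw[[i]], sprintf("reporter intensity (%s)", names(raw)[i]))
    v[is.na(v)] <- 0  # missing reporter cell means not observed
    v
  })
  reporter <- matrix(reporter, nrow = nrow(raw), ncol = length(chan_idx),
                     dimnames = list(NULL, channel_labels))

  opt_matrix <- function(prefix) {
    idx <- match(paste(prefix, normalise_header(channel_labels)), norm)
    if (anyNA(idx)) return(NULL)
    m <- sapply(idx, function(i) as_num(raw[[i]], prefix))
    matrix(m, nrow = nrow(raw), ncol = length(idx),
           dimnames = list(NULL, channel_labels))
  }

  opt_chr <- function(field, default = "") {
    i <- find_col(field)
    if (is.na(i)) rep(default, nrow(raw)) else raw[[i]]
  }
  opt_num <- function(field, default = NA_real_) {
    i <- find_col(field)
    if (is.na(i)) rep(default, nrow(raw)) else as_num(raw[[i]], field)
  }

  spectrum <- opt_chr("spectrum_id", "")
  if (all(spectrum == "")) spectrum <- sprintf("psm%06d", seq_len(nrow(raw)))
  run <- opt_chr("run_id", "")
  if (all(run == "")) run <- sub("^([^.]+)\\..*$", "\\1", spectrum)

  split_list <- function(x) {
    lapply(strsplit(x, ",[ ]*"), function(v) v[nzchar(v)])
  }

  labeled_raw <- toupper(trimws(opt_chr("labeled", "true")))
  protein <- raw[[col_prot]]
  protein_start <- opt_num("protein_start")

  psms <- tibble(
    spectrum_id = spectrum,
    run_id = run,
    peptide = raw[[col_pep]],
    modified_peptide = dplyr::if_else(raw[[col_mpep]] == "", raw[[col_pep]], raw[[col_mpep]]),
    charge = as.integer(opt_num("charge", 2)),
    probability = as_num(raw[[col_prob]], "probability"),
    purity = as_num(raw[[col_pur]], "purity"),
    precursor_intensity = {
      v <- as_num(raw[[col_int]], "intensity"); v[is.na(v)] <- 0; v
    },
    retention_time = opt_num("retention_time", 0),
    protein = protein,
    gene = opt_chr("gene", ""),
    mapped_proteins = split_list(opt_chr("mapped_proteins")),
    mapped_genes = split_list(opt_chr("mapped_genes")),
    is_unique = toupper(trimws(opt_chr("is_unique", "true"))) %in% c("TRUE", "T", "1", "YES"),
    is_contaminant = startsWith(protein, contam_prefix),
    is_decoy = startsWith(protein, decoy_prefix),
    has_label = labeled_raw %in% c("TRUE", "T", "1", "YES"),
    protein_start = protein_start,
    site_localizations = parse_localizations(opt_chr("localization"), protein_start)
  )
  psms$gene[is.na(psms$gene)] <- ""
  psms$reporter <- reporter
  snr <- opt_matrix("snr"); resol <- opt_matrix("resolution")
  if (!is.null(snr)) psms$snr <- snr
  if (!is.null(resol)) psms$resolution <- resol

  bad_prob <- which(psms$probability < 0 | psms$probability > 1)
  if (length(bad_prob)) abort(sprintf("probability outside [0,1] at row %d of %s", bad_prob[1], path))
  bad_pur <- which(psms$purity < 0 | psms$purity > 1)
  if (length(bad_pur)) abort(sprintf("purity outside [0,1] at row %d of %s", bad_pur[1], path))

  psms[!psms$is_decoy, , drop = FALSE]
}

normalise_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", gsub("[^a-z0-9]+", " ", x))
}

default_psm_aliases <- function() {
  list(
    spectrum_id = c("spectrum", "spectrum id"),
    run_id = c("spectrum file", "run", "file"),
    peptide = "peptide",
    modified_peptide = c("modified peptide", "modified sequence"),
    charge = "charge",
    probability = c("probability", "peptideprophet probability", "psm probability"),
    purity = "purity",
    precursor_intensity = c("intensity", "precursor intensity", "ms1 intensity"),
    retention_time = c("retention", "retention time", "rt"),
    protein = "protein",
    gene = c("gene", "gene symbol"),
    mapped_proteins = "mapped proteins",
    mapped_genes = "mapped genes",
    is_unique = c("is unique", "unique"),
    protein_start = "protein start",
    labeled = c("labeled", "labeling state", "label"),
    localization = c("localization", "ptm localization", "site localization")
  )
}

# Parse "S4:0.93,T6:0.55" (peptide 1-based positions) into per-PSM tibbles.
parse_localizations <- function(x, protein_start) {
  purrr::map2(x, protein_start, function(s, start) {
    s <- trimws(s %||% "")
    if (is.na(s) || s == "") return(NULL)
    m <- regmatches(s, gregexpr("([A-Z])(\\d+):([0-9.]+)", s))[[1]]
    if (!length(m)) return(NULL)
    residue <- substr(m, 1, 1)
    pos <- as.integer(sub("^[A-Z](\\d+):.*$", "\\1", m))
    prob <- as.numeric(sub("^[A-Z]\\d+:", "", m))
    if (any(prob < 0 | prob > 1)) abort("localization probability outside [0,1]")
    tibble(residue = residue, peptide_position = pos,
           protein_position = if (is.na(start)) NA_integer_ else as.integer(start + pos - 1L),
           probability = prob)
  })
}

#' Read a channel annotation file
#'
#' Each non-empty line maps one reporter channel to one sample:
#' `channel<TAB>sample` with an optional third column naming the channel's
#' subplex (for plexes mixing reagent isotopologs).
#'
#' @param path Path to the annotation file (no header).
#' @return A tibble with columns `channel`, `sample` and `subplex`, in file
#'   order.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("no channels in annotation file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  channel <- vapply(parts, function(p) trimws(p[1]), character(1))
  sample <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else "", character(1))
  subplex <- vapply(parts, function(p) if (length(p) >= 3) trimws(p[3]) else NA_character_, character(1))
  if (any(!nzchar(sample))) {
    abort(sprintf("blank sample name for channel '%s' in %s",
                  channel[which(!nzchar(sample))[1]], path))
  }
  dup <- channel[duplicated(channel)]
  if (length(dup)) abort(sprintf("duplicate channel '%s' in %s", dup[1], path))
  if (all(is.na(subplex))) subplex <- rep(NA_character_, length(channel))
  tibble(channel = channel, sample = sample, subplex = subplex)
}

#' Write a plex back to psm.tsv / annotation files
#'
#' Serialises a [plex_table()] to a tab-separated PSM table plus annotation
#' file that round-trip through [read_psm_table()] and [read_annotation()].
#' Used mainly by the synthetic-data generator.
#'
#' @param plex A `plex_table`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`psm`, `annotation`).
#' @export
write_plex <- function(plex, dir) {
  stopifnot(inherits(plex, "plex_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- plex$psms
  fmt_list <- function(l) vapply(l, function(v) paste(v, collapse = ", "), character(1))
  fmt_loc <- function(l) {
    vapply(l, function(t) {
      if (is.null(t) || nrow(t) == 0) return("")
      paste(sprintf("%s%d:%s", t$residue, t$peptide_position,
                    formatC(t$probability, format = "g", digits = 6)), collapse = ",")
    }, character(1))
  }
  out <- data.frame(
    Spectrum = p$spectrum_id, `Spectrum File` = p$run_id,
    Peptide = p$peptide, `Modified Peptide` = p$modified_peptide,
    Charge = p$charge, Probability = p$probability, Purity = p$purity,
    Intensity = p$precursor_intensity, Retention = p$retention_time,
    Protein = p$protein, Gene = p$gene,
    `Mapped Proteins` = fmt_list(p$mapped_proteins),
    `Mapped Genes` = fmt_list(p$mapped_genes),
    `Is Unique` = p$is_unique, Labeled = p$has_label,
    `Protein Start` = p$protein_start,
    Localization = fmt_loc(p$site_localizations),
    check.names = FALSE
  )
  rep_df <- as.data.frame(p$reporter)
  names(rep_df) <- plex$channels$channel
  out <- cbind(out, rep_df)
  if ("snr" %in% names(p)) {
    m <- as.data.frame(p$snr); names(m) <- paste("SNR", plex$channels$channel); out <- cbind(out, m)
  }
  if ("resolution" %in% names(p)) {
    m <- as.data.frame(p$resolution); names(m) <- paste("Resolution", plex$channels$channel)
    out <- cbind(out, m)
  }
  psm_path <- file.path(dir, sprintf("%s_psm.tsv", plex$plex_id))
  readr::write_tsv(out, psm_path, progress = FALSE)
  ann <- plex$channels
  ann_lines <- if (all(is.na(ann$subplex))) {
    paste(ann$channel, ann$sample, sep = "\t")
  } else {
    paste(ann$channel, ann$sample, ann$subplex, sep = "\t")
  }
  ann_path <- file.path(dir, sprintf("%s_annotation.tsv", plex$plex_id))
  writeLines(ann_lines, ann_path)
  invisible(list(psm = psm_path, annotation = ann_path))
}
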