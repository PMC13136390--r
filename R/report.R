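#' Quantification report objects
#'
#' An `iso_report` is a tibble with one row per entry (gene, protein, peptide,
#' multi-site or single-site index) and one column per sample, plus annotation
#' columns. Attributes record the summarisation level, the normalization tag
#' (`None`, `MD` or `GN`), the kind (`ratio` or `abundance`, both log2) and a
#' sample map linking columns to `(plex_id, sample)`.
#'
#' @param df Tibble with an `index` column, optional annotation columns
#'   (`gene`, `protein`, `peptide`, `max_psm_prob`, `n_psms`,
#'   `reference_intensity`) and one numeric column per sample.
#' @param level One of `"gene"`, `"protein"`, `"peptide"`, `"multisite"`,
#'   `"singlesite"`.
#' @param normalization One of `"None"`, `"MD"`, `"GN"`.
#' @param kind `"ratio"` or `"abundance"`.
#' @param samples Tibble with columns `plex_id`, `sample`, `column` mapping
#'   report columns to samples.
#' @return An `iso_report` tibble.
#' @export
iso_report <- function(df, level, normalization = "None", kind = "ratio", samples) {
  level <- match.arg(level, c("gene", "protein", "peptide", "multisite", "singlesite"))
  normalization <- match.arg(normalization, c("None", "MD", "GN"))
  kind <- match.arg(kind, c("ratio", "abundance"))
  df <- as_tibble(df)
  if (!"index" %in% names(df)) abort("report must have an `index` column")
  missing_cols <- setdiff(samples$column, names(df))
  if (length(missing_cols)) {
    abort(sprintf("sample column(s) missing from report: %s", paste(missing_cols, collapse = ", ")))
  }
  structure(df,
    class = c("iso_report", class(tibble())),
    level = level, normalization = normalization, kind = kind,
    samples = as_tibble(samples)
  )
}

#' @rdname iso_report
#' @param x An `iso_report`.
#' @export
sample_cols <- function(x) attr(x, "samples")$column

#' @rdname iso_report
#' @export
report_values <- function(x) {
  m <- as.matrix(x[, sample_cols(x), drop = FALSE])
  rownames(m) <- x$index
  m
}

set_report_values <- function(x, m) {
  x[, sample_cols(x)] <- as_tibble(as.data.frame(m))[, seq_along(sample_cols(x))] |>
    setNames(sample_cols(x))
  x
}

#' @export
print.iso_report <- function(x, ...) {
  cat(sprintf("<iso_report> %s-level %s, normalization %s: %d entries x %d samples\n",
              attr(x, "level"), attr(x, "kind"), attr(x, "normalization"),
              nrow(x), length(sample_cols(x))))
  NextMethod()
}

meta_cols <- function(x) {
  setdiff(intersect(c("index", "gene", "protein", "peptide", "max_psm_prob",
                      "n_psms", "reference_intensity"), names(x)),
          sample_cols(x))
}

#' Write a report table
#'
#' Writes an `iso_report` as a TSV named
#' `<ratio|abundance>_<level>_<None|MD|GN>.tsv`: index and annotation columns
#' first (`Index`, `Gene`, `Protein`, `Peptide`, `MaxPSMProb`, `NumPSMs`, and
#' `ReferenceIntensity` for abundance tables), then one column per sample in
#' annotation order. Missing cells are written as `NA`; numeric values with 6
#' decimals.
#'
#' @param report An `iso_report`.
#' @param out_dir Output directory (created if needed).
#' @param digits Decimal places for numeric values.
#' @return The file path written, invisibly.
#' @export
write_report <- function(report, out_dir, digits = 6L) {
  stopifnot(inherits(report, "iso_report"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory: %s", out_dir))
  fname <- sprintf("%s_%s_%s.tsv", attr(report, "kind"), attr(report, "level"),
                   attr(report, "normalization"))
  path <- file.path(out_dir, fname)

  pretty <- c(index = "Index", gene = "Gene", protein = "Protein",
              peptide = "Peptide", max_psm_prob = "MaxPSMProb",
              n_psms = "NumPSMs", reference_intensity = "ReferenceIntensity")
  mc <- meta_cols(report)
  out <- as.data.frame(report[, c(mc, sample_cols(report)), drop = FALSE],
                       check.names = FALSE)
  names(out)[seq_along(mc)] <- pretty[mc]
  num <- vapply(out, is.numeric, logical(1))
  num[names(out) == "NumPSMs"] <- FALSE
  for (j in which(num)) {
    v <- out[[j]]
    out[[j]] <- ifelse(is.na(v), "NA", formatC(v, format = "f", digits = digits))
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a report table written by [write_report()]
#'
#' The level, normalization and kind are recovered from the file name.
#'
#' @param path Path to a `<kind>_<level>_<norm>.tsv` report.
#' @param samples Optional sample map; by default every non-annotation column
#'   is treated as a sample of one unnamed plex.
#' @return An `iso_report`.
#' @export
read_report <- function(path, samples = NULL) {
  fname <- basename(path)
  m <- regmatches(fname, regexec(
    "^(ratio|abundance)_(gene|protein|peptide|multisite|singlesite)_(None|MD|GN)\\.tsv$", fname))[[1]]
  if (!length(m)) abort(sprintf("report file name not recognised: %s", fname))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE, na = "NA")
  pretty <- c(Index = "index", Gene = "gene", Protein = "protein",
              Peptide = "peptide", MaxPSMProb = "max_psm_prob",
              NumPSMs = "n_psms", ReferenceIntensity = "reference_intensity")
  hit <- names(df) %in% names(pretty)
  names(df)[hit] <- pretty[names(df)[hit]]
  if (is.null(samples)) {
    sc <- setdiff(names(df), unname(pretty))
    samples <- tibble(plex_id = NA_character_, sample = sc, column = sc)
  }
  iso_report(df, level = m[3], normalization = m[4], kind = m[2], samples = samples)
}

#' Drop entries whose best supporting PSM is below a probability threshold
#'
#' Final report-level filter: entries are removed when the highest posterior
#' probability among all their supporting PSMs (across the whole dataset)
#' falls below `threshold`.
#'
#' @param report An `iso_report` carrying a `max_psm_prob` column.
#' @param threshold Minimum best supporting-PSM probability (default 0.9).
#' @return The filtered `iso_report`.
#' @export
min_best_prob_filter <- function(report, threshold = 0.9) {
  stopifnot(inherits(report, "iso_report"))
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (!"max_psm_prob" %in% names(report) || threshold <= 0) return(report)
  keep <- !is.na(report$max_psm_prob) & report$max_psm_prob >= threshold
  report[keep, , drop = FALSE]
}

#' @export
`[.iso_report` <- function(x, i, j, ...) {
  at <- attributes(x)[c("level", "normalization", "kind", "samples")]
  out <- NextMethod()
  if (is.data.frame(out) && all(at$samples$column %in% names(out))) {
    out <- structure(out, class = c("iso_report", class(tibble())),
                     level = at$level, normalization = at$normalization,
                     kind = at$kind, samples = at$samples)
  }
  out
}
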