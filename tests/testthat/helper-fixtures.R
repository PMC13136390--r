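# Fixtures are built in code: small plexes with hand-chosen reporter
# intensities, plus independent oracles for quartiles and the weighted
# median (kept deliberately separate from the package implementation).

`%||%` <- function(x, y) if (is.null(x)) y else x

make_psms <- function(reporter, probability = 1, purity = 1,
                      precursor = NULL, peptide = NULL, protein = NULL,
                      gene = NULL, run_id = "run1", charge = 2L,
                      modified_peptide = NULL, has_label = TRUE,
                      is_contaminant = FALSE, is_unique = TRUE,
                      retention_time = NULL, protein_start = 101L,
                      site_localizations = NULL, spectrum_id = NULL) {
  reporter <- as.matrix(reporter)
  n <- nrow(reporter)
  rep_len_chr <- function(x, d) if (is.null(x)) d else rep_len(x, n)
  peptide <- rep_len_chr(peptide, sprintf("PEPTIDEK%02d", seq_len(n)))
  psms <- tibble::tibble(
    spectrum_id = rep_len_chr(spectrum_id, sprintf("sp%03d", seq_len(n))),
    run_id = rep_len(run_id, n),
    peptide = peptide,
    modified_peptide = if (is.null(modified_peptide)) peptide else rep_len(modified_peptide, n),
    charge = rep_len(as.integer(charge), n),
    probability = rep_len(probability, n),
    purity = rep_len(purity, n),
    precursor_intensity = if (is.null(precursor)) rep(1e6, n) else rep_len(precursor, n),
    retention_time = if (is.null(retention_time)) seq_len(n) * 10 else rep_len(retention_time, n),
    protein = rep_len_chr(protein, rep("P1", n)),
    gene = rep_len_chr(gene, rep("G1", n)),
    mapped_proteins = rep(list(character(0)), n),
    mapped_genes = rep(list(character(0)), n),
    is_unique = rep_len(is_unique, n),
    is_contaminant = rep_len(is_contaminant, n),
    is_decoy = rep(FALSE, n),
    has_label = rep_len(has_label, n),
    protein_start = rep_len(as.integer(protein_start), n),
    site_localizations = site_localizations %||% rep(list(NULL), n)
  )
  psms$reporter <- reporter
  psms
}

make_plex <- function(reporter, reference = "virtual", samples = NULL,
                      subplex = NULL, plex_id = "plex1", ...) {
  reporter <- as.matrix(reporter)
  k <- ncol(reporter)
  channels <- tibble::tibble(
    channel = sprintf("ch%d", seq_len(k)),
    sample = samples %||% sprintf("S%02d", seq_len(k))
  )
  if (!is.null(subplex)) channels$subplex <- subplex
  plex_table(make_psms(reporter, ...), channels, plex_id = plex_id,
             reference = reference)
}

# Independent type-7 quartile oracle: linear interpolation of order
# statistics at h = (n - 1) p + 1, written from the definition.
oracle_quartile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_iqr_removal <- function(x) {
  if (sum(!is.na(x)) < 4) return(x)
  q1 <- oracle_quartile(x, 0.25)
  q3 <- oracle_quartile(x, 0.75)
  iqr <- q3 - q1
  ifelse(!is.na(x) & (x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr), NA_real_, x)
}

# Enumeration oracle for the cumulative-weight rule: walk the ratio-sorted
# list and report the first ratio whose cumulative normalized weight
# strictly exceeds one half.
oracle_weighted_median <- function(ratios, weights) {
  keep <- !is.na(ratios)
  ratios <- ratios[keep]; weights <- weights[keep]
  if (!length(ratios)) return(NA_real_)
  o <- order(ratios)
  ratios <- ratios[o]; weights <- weights[o]
  total <- sum(weights)
  if (total == 0) {
    if (length(unique(ratios)) == 1) return(ratios[1])
    return(stats::median(ratios))
  }
  acc <- 0
  for (i in seq_along(ratios)) {
    acc <- acc + weights[i] / total
    if (acc > 0.5) return(ratios[i])
  }
  ratios[which.max(weights)]
}
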