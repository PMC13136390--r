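#' Assign PSMs to entries at a summarisation level
#'
#' Groups the surviving PSMs of one plex into report entries. Protein-level
#' groups follow the razor/unique protein accession, gene-level groups its
#' gene symbol, peptide-level groups the stripped peptide sequence (all site
#' configurations of a sequence together). The multi-site level groups by
#' (accession, peptide, site configuration): a site counts as localized when
#' its localization probability is at least `cfg$min_site_probability`
#' (default 0.75), the number of localized sites is capped at the number of
#' target modifications on the peptide, and remaining modifications are
#' counted as unlocalized. When a PSM table carries no localization
#' probabilities, search-engine site assignments parsed from the modified
#' peptide are treated as localized.
#'
#' When `ptm_only = TRUE` (the pipeline sets this whenever PTM reports are
#' requested), every level uses only PSMs carrying at least one target
#' modification.
#'
#' @param plex A filtered [plex_table()].
#' @param level One of `"gene"`, `"protein"`, `"peptide"`, `"multisite"`.
#' @param cfg A [filter_config()]; `mod_tag` and `min_site_probability` are
#'   used for the PTM levels.
#' @param ptm_only Restrict all levels to PSMs carrying the target
#'   modification.
#' @return A tibble with one row per assigned PSM: `index`, `spectrum_id`,
#'   plus annotation columns `gene`, `protein` and (peptide level up)
#'   `peptide`.
#' @export
assign_groups <- function(plex, level = c("gene", "protein", "peptide", "multisite"),
                          cfg = filter_config(), ptm_only = FALSE) {
  stopifnot(inherits(plex, "plex_table"))
  level <- match.arg(level)
  p <- plex$psms
  mod <- parse_mod_tag(cfg$mod_tag)

  if (level == "multisite" || ptm_only) {
    if (is.null(mod)) abort("PTM-restricted grouping requires `mod_tag` in the filter config")
    info <- psm_mod_info(p, mod, cfg$min_site_probability)
    keep <- info$n_mods >= 1L
    p <- p[keep, , drop = FALSE]
    info <- info[keep, , drop = FALSE]
  }

  base <- tibble(spectrum_id = p$spectrum_id, gene = p$gene, protein = p$protein,
                 peptide = p$peptide)
  out <- switch(level,
    gene = {
      b <- base[nzchar(base$gene), , drop = FALSE]
      b$index <- b$gene
      b$peptide <- NULL
      b
    },
    protein = {
      base$index <- base$protein
      base$peptide <- NULL
      base
    },
    peptide = {
      base$index <- base$peptide
      base
    },
    multisite = {
      base$index <- paste0(base$protein, "|", base$peptide, "|", info$config)
      base
    }
  )
  select(out, "index", "spectrum_id", dplyr::everything())
}

# Per-PSM target-modification summary: number of target modifications on the
# peptide, localized sites (probability >= threshold, capped at the mod
# count), unlocalized count, and the multi-site configuration string.
psm_mod_info <- function(psms, mod, min_site_probability) {
  counts <- count_mods(psms$modified_peptide, mod)
  res <- purrr::pmap(
    list(psms$site_localizations, counts, psms$protein_start, psms$peptide),
    function(loc, n_mods, start, pep) {
      if (n_mods == 0L) {
        return(list(n_mods = 0L, config = "", sites = NULL))
      }
      if (is.null(loc) || nrow(loc) == 0L) {
        return(NULL) # search-engine fallback handled below
      }
      loc <- loc[loc$residue %in% mod$residues, , drop = FALSE]
      loc <- loc[order(-loc$probability, loc$peptide_position), , drop = FALSE]
      localized <- loc[loc$probability >= min_site_probability, , drop = FALSE]
      localized <- head(localized, n_mods)
      n_unloc <- n_mods - nrow(localized)
      list(n_mods = n_mods, localized = localized, n_unloc = n_unloc)
    }
  )
  # PSMs without localization data: parse site positions from the modified
  # peptide itself and treat them as localized
  fallback <- vapply(res, is.null, logical(1))
  if (any(fallback)) {
    for (i in which(fallback)) {
      sites <- mod_sites(psms$modified_peptide[i], mod)
      start <- psms$protein_start[i]
      localized <- tibble(
        residue = sites$residue, peptide_position = sites$position,
        protein_position = if (is.na(start)) NA_integer_ else as.integer(start + sites$position - 1L),
        probability = 1
      )
      res[[i]] <- list(n_mods = counts[i], localized = localized, n_unloc = 0L)
    }
  }
  config <- vapply(res, function(r) {
    if (r$n_mods == 0L) return("")
    site_config_string(r$localized, r$n_unloc)
  }, character(1))
  no_coord <- vapply(res, function(r) {
    r$n_mods > 0L && nrow(r$localized) > 0L && anyNA(r$localized$protein_position)
  }, logical(1))
  if (any(no_coord)) {
    abort("protein coordinates unavailable for localized sites; provide a Protein Start column or localization protein positions")
  }
  tibble(
    n_mods = vapply(res, function(r) as.integer(r$n_mods), integer(1)),
    n_unloc = vapply(res, function(r) as.integer(r$n_unloc %||% 0L), integer(1)),
    localized = lapply(res, function(r) r$localized),
    config = config
  )
}

# "S315,T320+1u" style configuration string
site_config_string <- function(localized, n_unloc) {
  parts <- character(0)
  if (!is.null(localized) && nrow(localized)) {
    localized <- localized[order(localized$protein_position), , drop = FALSE]
    parts <- sprintf("%s%d", localized$residue, localized$protein_position)
  }
  cfg <- paste(parts, collapse = ",")
  if (n_unloc > 0L) cfg <- paste0(cfg, sprintf("+%du", n_unloc))
  cfg
}

# Count tokens of the target modification in modified peptides. Accepts both
# delta-mass annotation S[79.9663] and total-residue-mass annotation
# S[166.998] (residue monoisotopic mass + delta).
count_mods <- function(modified_peptide, mod, tol = 0.02) {
  vapply(modified_peptide, function(mp) {
    m <- gregexpr("([A-Z])\\[([0-9.]+)\\]", mp)[[1]]
    if (m[1] == -1) return(0L)
    tokens <- regmatches(mp, gregexpr("([A-Z])\\[([0-9.]+)\\]", mp))[[1]]
    residue <- substr(tokens, 1, 1)
    mass <- as.numeric(sub("^[A-Z]\\[([0-9.]+)\\]$", "\\1", tokens))
    ok <- residue %in% mod$residues &
      (abs(mass - mod$mass) < tol |
         abs(mass - (aa_mono_mass(residue) + mod$mass)) < tol)
    sum(ok)
  }, integer(1), USE.NAMES = FALSE)
}

# Positions (within the stripped sequence) of target-mod tokens
mod_sites <- function(modified_peptide, mod, tol = 0.02) {
  tokens <- regmatches(modified_peptide,
                       gregexpr("([A-Z])(\\[[0-9.]+\\])?", modified_peptide))[[1]]
  residue <- substr(tokens, 1, 1)
  has_mass <- grepl("\\[", tokens)
  mass <- rep(NA_real_, length(tokens))
  mass[has_mass] <- as.numeric(sub("^[A-Z]\\[([0-9.]+)\\]$", "\\1", tokens[has_mass]))
  is_target <- has_mass & residue %in% mod$residues &
    (abs(mass - mod$mass) < tol |
       abs(mass - (aa_mono_mass(residue) + mod$mass)) < tol)
  is_target[is.na(is_target)] <- FALSE
  tibble(residue = residue[is_target], position = which(is_target))
}

aa_mono_mass <- function(aa) {
  masses <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  unname(masses[aa])
}
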