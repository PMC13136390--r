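write_psm_fixture <- function(path, rows, header = NULL) {
  header <- header %||% paste("Spectrum", "Peptide", "Modified Peptide",
                              "Probability", "Purity", "Intensity",
                              "Protein", "Gene", "126", "127N", "128C",
                              sep = "\t")
  writeLines(c(header, rows), path)
}

test_that("PSM rows parse with reporter intensities, flags and defaults", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_fixture(path, c(
    "r1.1.1.2\tAPEPTIDEK\tAPEPTIDEK\t0.99\t0.8\t1e6\tP12345\tTP53\t100\t200\t400",
    "r1.1.2.2\tBPEPTIDEK\t\t0.5\t0.3\t2e6\tcontam_P02769\tALB\t1\t\t3",
    "r1.1.3.2\tCPEPTIDEK\tCPEPTIDEK\t0.99\t0.9\t1e6\trev_P11111\tXX\t1\t2\t3"
  ))
  psms <- read_psm_table(path, c("126", "127N", "128C"))
  # decoy dropped at read time
  expect_equal(nrow(psms), 2L)
  expect_equal(unname(psms$reporter[1, ]), c(100, 200, 400))
  # missing reporter cell becomes zero, not NA
  expect_equal(unname(psms$reporter[2, ]), c(1, 0, 3))
  expect_false(psms$is_contaminant[1])
  expect_true(psms$is_contaminant[2])
  expect_equal(psms$modified_peptide[2], "BPEPTIDEK")
  expect_true(all(psms$has_label))
})

test_that("missing required and reporter columns are named in errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_fixture(path,
    "r1\tAPEPK\tAPEPK\t0.99\t1e6\tP1\tG1\t1\t2\t3",
    header = paste("Spectrum", "Peptide", "Modified Peptide", "Probability",
                   "Intensity", "Protein", "Gene", "126", "127N", "128C", sep = "\t"))
  expect_error(read_psm_table(path, c("126", "127N", "128C")), "purity")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_psm_fixture(path2, "r1\tAPEPK\tAPEPK\t0.99\t0.9\t1e6\tP1\tG1\t1\t2\t3")
  expect_error(read_psm_table(path2, c("126", "127N", "131")), "131")
})

test_that("non-numeric intensities are rejected with a row number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_fixture(path, c(
    "r1\tAPEPK\tAPEPK\t0.99\t0.9\t1e6\tP1\tG1\t1\t2\t3",
    "r2\tBPEPK\tBPEPK\t0.99\t0.9\tabc\tP1\tG1\t1\t2\t3"
  ))
  expect_error(read_psm_table(path, c("126", "127N", "128C")), "row 2")
})

test_that("headers are matched case-insensitively across dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_fixture(path,
    "r1\tAPEPK\tAPEPK\t0.99\t0.9\t1e6\tP1\tG1\t1\t2\t3",
    header = paste("SPECTRUM", "peptide", "MODIFIED_PEPTIDE",
                   "PeptideProphet Probability", "PURITY", "intensity",
                   "protein", "GENE", "126", "127N", "128C", sep = "\t"))
  psms <- read_psm_table(path, c("126", "127N", "128C"))
  expect_equal(psms$probability, 0.99)
})

test_that("annotation files parse in order and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("126\tBridge", "127N\tTumor01"), path)
  ann <- read_annotation(path)
  expect_equal(ann$channel, c("126", "127N"))
  expect_equal(ann$sample, c("Bridge", "Tumor01"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("126\tA", "126\tB"), dup)
  expect_error(read_annotation(dup), "duplicate channel")

  blank <- withr::local_tempfile(fileext = ".tsv")
  writeLines("126\t", blank)
  expect_error(read_annotation(blank), "blank sample")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_annotation(empty), "no channels")
})

test_that("report files follow the <kind>_<level>_<norm>.tsv naming scheme", {
  dir <- withr::local_tempdir()
  samples <- tibble::tibble(plex_id = "plex1", sample = c("A", "B"), column = c("A", "B"))
  df <- tibble::tibble(index = c("TP53", "EGFR"), protein = c("P1", "P2"),
                       max_psm_prob = c(1, 0.99), n_psms = c(3L, 2L),
                       reference_intensity = c(1000, 2000),
                       A = c(10.5, NA), B = c(11.25, 12))
  rep_md <- iso_report(df, level = "gene", normalization = "MD",
                       kind = "abundance", samples = samples)
  expect_equal(basename(write_report(rep_md, dir)), "abundance_gene_MD.tsv")

  df2 <- df; df2$reference_intensity <- NULL
  rep_none <- iso_report(df2, level = "protein", normalization = "None",
                         kind = "ratio", samples = samples)
  expect_equal(basename(write_report(rep_none, dir)), "ratio_protein_None.tsv")

  lines <- readLines(file.path(dir, "abundance_gene_MD.tsv"))
  expect_match(lines[1], "^Index\tProtein\tMaxPSMProb\tNumPSMs\tReferenceIntensity\tA\tB$")
  expect_match(lines[3], "\tNA\t", fixed = TRUE)
})

test_that("write then read round-trips report values at print precision", {
  dir <- withr::local_tempdir()
  set.seed(42)
  samples <- tibble::tibble(plex_id = "plex1", sample = sprintf("S%d", 1:4),
                            column = sprintf("S%d", 1:4))
  vals <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, samples$column))
  vals[2, 3] <- NA
  df <- dplyr::bind_cols(
    tibble::tibble(index = sprintf("P%d", 1:5), protein = sprintf("P%d", 1:5),
                   max_psm_prob = rep(1, 5), n_psms = 1:5),
    tibble::as_tibble(as.data.frame(vals))
  )
  rep0 <- iso_report(df, level = "protein", normalization = "MD",
                     kind = "ratio", samples = samples)
  path <- write_report(rep0, dir)
  back <- read_report(path)
  expect_equal(attr(back, "level"), "protein")
  expect_equal(attr(back, "normalization"), "MD")
  expect_equal(report_values(back), report_values(rep0), tolerance = 1e-6)
  expect_identical(is.na(report_values(back)), is.na(report_values(rep0)))
})

test_that("simulated plexes serialize and re-read losslessly downstream", {
  sim <- simulate_plexes(sim_design(n_background_proteins = 4, psms_per_protein = 6,
                                    noise_cv = 0.1, missing_rate = 0.05), seed = 3)
  plex <- sim$plexes[[1]]
  dir <- withr::local_tempdir()
  paths <- write_plex(plex, dir)
  ann <- read_annotation(paths$annotation)
  back <- read_psm_table(paths$psm, ann$channel)
  expect_equal(ann$channel, plex$channels$channel)
  expect_equal(back$peptide, plex$psms$peptide)
  expect_equal(back$probability, plex$psms$probability, tolerance = 1e-9)
  expect_equal(unname(back$reporter), unname(plex$psms$reporter), tolerance = 1e-9)
  # the rebuilt plex yields identical ratios
  plex2 <- plex_table(back, ann, plex_id = plex$plex_id, reference = "virtual")
  expect_equal(to_ratios(plex2)$ratio, to_ratios(plex)$ratio, tolerance = 1e-9)
})
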