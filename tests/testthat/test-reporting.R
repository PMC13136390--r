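ratio_report <- function(values, level = "protein", normalization = "None") {
  values <- as.matrix(values)
  k <- ncol(values)
  samples <- tibble::tibble(plex_id = "plex1", sample = sprintf("S%02d", 1:k),
                            column = sprintf("S%02d", 1:k))
  df <- dplyr::bind_cols(
    tibble::tibble(index = sprintf("E%03d", seq_len(nrow(values))),
                   protein = sprintf("E%03d", seq_len(nrow(values))),
                   max_psm_prob = 1, n_psms = 1L),
    tibble::as_tibble(as.data.frame(values)) |> setNames(samples$column)
  )
  iso_report(df, level = level, normalization = normalization, kind = "ratio",
             samples = samples)
}

test_that("median centering zeroes each sample and is idempotent", {
  rep0 <- ratio_report(cbind(c(1, 2, 3), c(0.3, NA, 0.7)))
  md <- normalize_md(rep0)
  m <- report_values(md)
  expect_equal(unname(m[, 1]), c(-1, 0, 1))
  expect_equal(unname(m[, 2]), c(-0.2, NA, 0.2)) # NA-skipping median 0.5
  expect_equal(report_values(normalize_md(md)), m)
  expect_equal(attr(md, "normalization"), "MD")
})

test_that("already-centered columns are unchanged by MD", {
  vals <- cbind(c(-1, 0, 1), c(-2, 0, 2))
  expect_equal(report_values(normalize_md(ratio_report(vals))), report_values(ratio_report(vals)))
})

test_that("global normalization equalizes sample MADs at MAD0", {
  # columns with MADs 1 and 3 -> MAD0 = 2; scale factors 2 and 2/3
  vals <- cbind(c(-1, 0, 1, 2, -2), 3 * c(-1, 0, 1, 2, -2))
  gn <- normalize_gn(ratio_report(vals))
  m <- report_values(gn)
  mads <- apply(m, 2, function(col) median(abs(col - median(col))))
  expect_equal(unname(mads), c(2, 2))
  expect_equal(unname(apply(m, 2, median)), c(0, 0))
  expect_equal(unname(m[, 1]), c(-2, 0, 2, 4, -4))
  expect_equal(unname(m[, 2]), c(-2, 0, 2, 4, -4))
})

test_that("single-column GN equals MD, and constant columns are guarded", {
  one <- ratio_report(cbind(c(0.1, 0.5, 0.9)))
  expect_equal(report_values(suppressMessages(normalize_gn(one))),
               report_values(normalize_md(one)))
  const <- ratio_report(cbind(c(2, 2, 2), c(1, 2, 3)))
  expect_message(gn <- normalize_gn(const), "zero MAD")
  expect_equal(unname(report_values(gn)[, 1]), c(0, 0, 0))
})

test_that("reference intensity sums the top-3 weighted MS1 intensities per plex", {
  mk <- function(vals) {
    list(
      groups = tibble::tibble(index = "P1", spectrum_id = sprintf("s%d", seq_along(vals))),
      ratios = tibble::tibble(spectrum_id = sprintf("s%d", seq_along(vals)),
                              ref_weighted_ms1 = vals, ref_intensity = vals * 2)
    )
  }
  a <- mk(c(10, 5, 2, 1))
  expect_equal(reference_intensity(list(p1 = a$groups), list(p1 = a$ratios))$ref_intensity, 17)
  b <- mk(c(4, 6))
  expect_equal(reference_intensity(list(p1 = b$groups), list(p1 = b$ratios))$ref_intensity, 10)
  # ms2_reference uses the reference-channel intensity instead
  expect_equal(reference_intensity(list(p1 = b$groups), list(p1 = b$ratios),
                                   source = "ms2_reference")$ref_intensity, 20)
  # ms2_sum adds every PSM, not just the top 3
  expect_equal(reference_intensity(list(p1 = a$groups), list(p1 = a$ratios),
                                   source = "ms2_sum")$ref_intensity, 18)
})

test_that("multi-plex reference intensities take the median, imputing missing plexes", {
  g1 <- tibble::tibble(index = c("P1", "P2"), spectrum_id = c("a1", "a2"))
  r1 <- tibble::tibble(spectrum_id = c("a1", "a2"), ref_weighted_ms1 = c(100, 7),
                       ref_intensity = c(100, 7))
  g2 <- tibble::tibble(index = "P1", spectrum_id = "b1")
  r2 <- tibble::tibble(spectrum_id = "b1", ref_weighted_ms1 = 300, ref_intensity = 300)
  g3 <- tibble::tibble(index = "P1", spectrum_id = "c1")
  r3 <- tibble::tibble(spectrum_id = "c1", ref_weighted_ms1 = 200, ref_intensity = 200)
  ref <- reference_intensity(list(p1 = g1, p2 = g2, p3 = g3),
                             list(p1 = r1, p2 = r2, p3 = r3))
  expect_equal(ref$ref_intensity[ref$index == "P1"], 200)
  # P2 seen once; its two missing plexes impute the global minimum (7)
  expect_equal(ref$ref_intensity[ref$index == "P2"], 7)
  no_imp <- reference_intensity(list(p1 = g1, p2 = g2, p3 = g3),
                                list(p1 = r1, p2 = r2, p3 = r3),
                                impute_missing = FALSE)
  expect_equal(no_imp$ref_intensity[no_imp$index == "P2"], 7)
  expect_equal(no_imp$ref_intensity[no_imp$index == "P1"], 200)
})

test_that("abundance conversion adds log2 reference and round-trips exactly", {
  rep0 <- ratio_report(cbind(c(1, NA), c(0.5, -0.5)))
  ref <- tibble::tibble(index = c("E001", "E002"), ref_intensity = c(1024, 2))
  ab <- ratios_to_abundance(rep0, ref)
  expect_equal(attr(ab, "kind"), "abundance")
  m <- report_values(ab)
  expect_equal(m["E001", "S01"], 11) # 1 + log2(1024)
  expect_true(is.na(m["E002", "S01"]))
  back <- m - log2(ab$reference_intensity)
  expect_equal(back, report_values(rep0), tolerance = 0)
  # within-row differences preserved exactly
  expect_identical(m[1, 2] - m[1, 1], report_values(rep0)[1, 2] - report_values(rep0)[1, 1])
})

test_that("entries without a positive reference intensity are dropped", {
  rep0 <- ratio_report(cbind(c(1, 2), c(3, 4)))
  ref <- tibble::tibble(index = "E001", ref_intensity = 8)
  expect_message(ab <- ratios_to_abundance(rep0, ref), "dropped")
  expect_equal(ab$index, "E001")
})

multisite_fixture <- function() {
  samples <- tibble::tibble(plex_id = "plex1", sample = c("S01", "S02"),
                            column = c("S01", "S02"))
  df <- tibble::tibble(
    index = c("P1|ASPK|S315",        # singly modified, localized S315
              "P1|ASPTK|S315,T320",  # doubly modified containing S315
              "P1|MSPTK|S315,T320",  # second doubly modified form
              "P1|CSPK|+1u",         # unlocalized only: dropped
              "P2|DDSK|S12"),
    gene = "G1", protein = c("P1", "P1", "P1", "P1", "P2"),
    peptide = c("ASPK", "ASPTK", "MSPTK", "CSPK", "DDSK"),
    max_psm_prob = c(0.99, 0.95, 0.9, 0.8, 1), n_psms = c(2L, 1L, 1L, 1L, 3L),
    S01 = c(0.5, 0.9, 0.2, 9, -1), S02 = c(1.5, 0.3, 0.7, 9, -2)
  )
  iso_report(df, level = "multisite", kind = "ratio", samples = samples)
}

test_that("single-site collapse follows the three-rule precedence", {
  ss <- collapse_single_site(multisite_fixture())
  expect_equal(attr(ss, "level"), "singlesite")
  v <- report_values(ss)
  # S315 has a singly-modified form: its value wins over the doubly forms
  expect_equal(v["P1_S315", "S01"], 0.5)
  expect_equal(v["P1_S315", "S02"], 1.5)
  # T320 only appears in doubly-modified forms: per-sample median of both
  expect_equal(v["P1_T320", "S01"], median(c(0.9, 0.2)))
  expect_equal(v["P1_T320", "S02"], median(c(0.3, 0.7)))
  # unlocalized-only entries disappear; other proteins keep their sites
  expect_setequal(rownames(v), c("P1_S315", "P1_T320", "P2_S12"))
  # supporting PSMs counted over the forms actually used
  expect_equal(ss$n_psms[ss$index == "P1_S315"], 2L)
  expect_equal(ss$n_psms[ss$index == "P1_T320"], 2L)
})

test_that("site reference intensities follow the same precedence", {
  ref <- tibble::tibble(index = multisite_fixture()$index,
                        ref_intensity = c(100, 40, 60, 5, 7))
  ss <- collapse_single_site(multisite_fixture(), ref)
  site_ref <- attr(ss, "site_ref")
  expect_equal(site_ref$ref_intensity[site_ref$index == "P1_S315"], 100)
  expect_equal(site_ref$ref_intensity[site_ref$index == "P1_T320"], 50)
})

test_that("collapse is deterministic and idempotent in its inputs", {
  a <- collapse_single_site(multisite_fixture())
  b <- collapse_single_site(multisite_fixture())
  expect_identical(report_values(a), report_values(b))
})

test_that("best-probability entry filter drops rows below threshold", {
  rep0 <- ratio_report(cbind(c(1, 2), c(3, 4)))
  rep0$max_psm_prob <- c(0.85, 0.95)
  expect_equal(min_best_prob_filter(rep0, 0)$index, c("E001", "E002"))
  expect_equal(min_best_prob_filter(rep0, 0.9)$index, "E002")
  expect_equal(nrow(min_best_prob_filter(rep0, 0.8)), 2L)
})
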