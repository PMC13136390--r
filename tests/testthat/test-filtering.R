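test_that("quality gates remove and retain PSMs as configured", {
  reporter <- matrix(c(10, 20, 30,
                       10, 20, 30,
                       10, 20, 30,
                       10, 20, 30), nrow = 4, byrow = TRUE)
  plex <- make_plex(reporter, purity = c(0.4, 0.9, 0.9, 0.9),
                    probability = c(0.95, 0.5, 0.95, 0.95),
                    has_label = c(TRUE, TRUE, FALSE, TRUE),
                    peptide = sprintf("PEP%dK", 1:4))
  out <- filter_psms(plex, filter_config(low_intensity_fraction = 0))
  expect_equal(out$psms$spectrum_id, "sp004")
  rep <- filter_report(out)
  expect_equal(rep$n_removed[rep$rule == "low_purity"], 1L)
  expect_equal(rep$n_removed[rep$rule == "low_probability"], 1L)
  expect_equal(rep$n_removed[rep$rule == "unlabeled"], 1L)
})

test_that("zero reference intensity removes PSMs only under a real reference", {
  reporter <- rbind(c(10, 0, 30), c(10, 20, 30))
  real <- make_plex(reporter, reference = "S02", peptide = c("AAK", "CCK"))
  out <- filter_psms(real, filter_config(low_intensity_fraction = 0))
  expect_equal(nrow(out$psms), 1L)
  virt <- make_plex(reporter, reference = "virtual", peptide = c("AAK", "CCK"))
  expect_equal(nrow(filter_psms(virt, filter_config(low_intensity_fraction = 0))$psms), 2L)
})

test_that("contaminants are removed", {
  plex <- make_plex(rbind(c(1, 2), c(1, 2)), is_contaminant = c(TRUE, FALSE),
                    peptide = c("AAK", "CCK"))
  out <- filter_psms(plex, filter_config(low_intensity_fraction = 0))
  expect_equal(nrow(out$psms), 1L)
  expect_false(out$psms$is_contaminant)
})

test_that("exactly the lowest 5% of summed intensities are removed (brute force)", {
  set.seed(11)
  sums <- sample(1000:100000, 100)
  reporter <- cbind(sums * 0.3, sums * 0.7)
  plex <- make_plex(reporter, peptide = sprintf("P%03dK", 1:100))
  out <- filter_psms(plex, filter_config(low_intensity_fraction = 0.05))
  removed <- setdiff(plex$psms$spectrum_id, out$psms$spectrum_id)
  lowest5 <- plex$psms$spectrum_id[order(sums)][1:5]
  expect_setequal(removed, lowest5)
  expect_equal(filter_report(out)$n_removed[filter_report(out)$rule == "low_intensity"], 5L)
})

test_that("a PSM exactly at the intensity cutoff is retained", {
  # 21 PSMs, fraction 0.05: type-7 percentile lands exactly on the 2nd
  # order statistic, which must survive the strict removal
  sums <- seq(100, 2100, by = 100)
  plex <- make_plex(cbind(sums / 2, sums / 2), peptide = sprintf("P%02dK", 1:21))
  out <- filter_psms(plex, filter_config(low_intensity_fraction = 0.05))
  expect_equal(nrow(out$psms), 20L)
  expect_true("sp002" %in% out$psms$spectrum_id)
})

test_that("best-PSM selection keeps the max summed intensity per (run, peptide, charge)", {
  reporter <- rbind(c(10, 10), c(50, 50), c(30, 30), c(5, 5))
  plex <- make_plex(reporter, peptide = c("AAK", "AAK", "AAK", "CCK"),
                    probability = c(0.99, 0.95, 0.99, 0.99))
  out <- filter_psms(plex, filter_config(low_intensity_fraction = 0))
  expect_setequal(out$psms$spectrum_id, c("sp002", "sp004"))
  # tie on sum: higher probability wins, then smaller spectrum id
  tie <- make_plex(rbind(c(10, 10), c(10, 10)), peptide = "AAK",
                   probability = c(0.90, 0.99))
  expect_equal(filter_psms(tie, filter_config(low_intensity_fraction = 0))$psms$spectrum_id, "sp002")
  tie2 <- make_plex(rbind(c(10, 10), c(10, 10)), peptide = "AAK")
  expect_equal(filter_psms(tie2, filter_config(low_intensity_fraction = 0))$psms$spectrum_id, "sp001")
})

test_that("Astral SNR and resolution rules follow the documented defaults", {
  psms <- make_psms(rbind(c(10, 10), c(10, 10), c(10, 10)),
                    peptide = c("AAK", "CCK", "DDK"))
  psms$snr <- rbind(c(600, 600), c(300, 400), c(0.5, 2000))
  psms$resolution <- rbind(c(60000, 60000), c(60000, 60000), c(30000, 60000))
  channels <- tibble::tibble(channel = c("ch1", "ch2"), sample = c("S01", "S02"))
  plex <- plex_table(psms, channels)
  cfg <- filter_config(low_intensity_fraction = 0, astral_mode = TRUE)
  out <- filter_psms(plex, cfg)
  # sp002 fails summed SNR (700 < 1000); sp003's low-resolution channel has
  # SNR < 1 and is therefore tolerated
  expect_setequal(out$psms$spectrum_id, c("sp001", "sp003"))

  psms$resolution[1, 2] <- 30000 # SNR 600 >= 1 at low resolution -> removed
  plex2 <- plex_table(psms, channels)
  expect_setequal(filter_psms(plex2, cfg)$psms$spectrum_id, "sp003")
})

test_that("uniqueness modes restrict shared peptides", {
  psms <- make_psms(rbind(c(10, 10), c(10, 10), c(10, 10)),
                    peptide = c("AAK", "CCK", "DDK"),
                    is_unique = c(TRUE, FALSE, FALSE))
  psms$mapped_genes <- list(character(0), "G2", character(0))
  channels <- tibble::tibble(channel = c("ch1", "ch2"), sample = c("S01", "S02"))
  plex <- plex_table(psms, channels)
  n_after <- function(uniq) {
    nrow(filter_psms(plex, filter_config(low_intensity_fraction = 0,
                                         uniqueness = uniq))$psms)
  }
  expect_equal(n_after("unique_plus_razor"), 3L)
  expect_equal(n_after("unique_only"), 1L)
  expect_equal(n_after("unique_gene"), 2L) # only the multi-gene peptide drops
})

test_that("disabling every rule returns the input unchanged", {
  sim <- simulate_plexes(sim_design(n_background_proteins = 5, psms_per_protein = 8,
                                    noise_cv = 0.2), seed = 5)
  plex <- sim$plexes[[1]]
  cfg <- filter_config(min_purity = 0, min_probability = 0,
                       low_intensity_fraction = 0, best_psm = FALSE,
                       require_label = FALSE, require_reference_nonzero = FALSE)
  out <- filter_psms(plex, cfg)
  expect_identical(out$psms, plex$psms)
  expect_true(all(filter_report(out)$n_removed == 0L))
})

test_that("filtered PSMs are a subset and order is preserved", {
  sim <- simulate_plexes(sim_design(n_background_proteins = 20, psms_per_protein = 10,
                                    noise_cv = 0.3, missing_rate = 0.1), seed = 9)
  plex <- sim$plexes[[1]]
  out <- filter_psms(plex, filter_config())
  expect_true(all(out$psms$spectrum_id %in% plex$psms$spectrum_id))
  expect_identical(out$psms$spectrum_id,
                   plex$psms$spectrum_id[plex$psms$spectrum_id %in% out$psms$spectrum_id])
})

test_that("degenerate configurations are rejected", {
  expect_error(filter_config(low_intensity_fraction = 1), "< 1")
  expect_error(filter_config(min_purity = 2), "min_purity")
})
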