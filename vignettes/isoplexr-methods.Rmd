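---
title: "Methods: integrating isobaric-labeling quantification with isoplexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating isobaric-labeling quantification with isoplexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoplexr)
```

## The problem

Isobaric labeling (TMT, TMTpro, iTRAQ) quantifies up to 35 samples per LC-MS
run by tagging each with a channel-specific reporter. The atomic measurement
is a peptide-spectrum match (PSM) with one reporter intensity per channel.
Getting from hundreds of thousands of PSMs across many plexes to one
comparable entry-by-sample matrix requires: quality filtering, conversion to
ratios against a common reference, grouping, robust roll-up, cross-plex
integration, sample normalization, and (for interpretability) reconstruction
of intensity-scale abundances. `isoplexr` implements this chain as
composable functions with a deliberately deterministic, documented behavior
at every step.

## Model and assumptions

The central quantity is the log2 ratio to reference,
$R_{ij} = \log_2 I_{ij} - \log_2 I_{i,\mathrm{ref}}$. The design assumptions
are the usual ones for ratio-to-reference workflows:

- **A bridge channel (or a virtual stand-in) makes plexes comparable.**
  When a pooled reference sample is present in every plex, ratios to it
  cancel plex-level effects. Without one, the per-spectrum mean of all
  reporter intensities serves as a virtual reference; this assumes the
  channel composition is similar across plexes.
- **Most entries do not change across samples.** Median centering (MD) and
  MAD-based global scaling (GN) both rest on this; they adjust location and
  robust spread only, preserving distribution shape. No quantile or
  variance-stabilizing normalization is attempted.
- **A reporter intensity of exactly 0 means "not observed"**, not a
  measured zero: log2 of 0 is undefined, and such channels become `NA`
  ratios rather than large negative values. Zero channels are likewise
  excluded from the virtual-reference mean (numerator and count), so a
  dropped channel does not drag the reference down.
- **Ratio compression from co-isolation is intensity-dependent.** The
  weighted-median roll-up exists because high-precursor-intensity PSMs are
  less contaminated; weighting by MS1 intensity pulls the representative
  ratio toward the cleaner measurements.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `min_purity` | 0.5 | minimum precursor-ion purity (fraction of isolation-window signal from the precursor); low purity flags co-isolation |
| `min_probability` | 0.9 | PSM posterior threshold, applied on top of upstream FDR filtering |
| `low_intensity_fraction` | 0.05 | lowest summed-reporter-intensity PSMs removed; 0.025 is customary for phospho-enriched data, which is scarcer |
| `best_psm` | on | one PSM per (run, modified peptide, charge), the highest summed reporter intensity |
| `min_summed_snr`, `min_resolution` | 1000, 45000 | Astral-mode gates; a low-resolution channel is only disqualifying when its own SNR ≥ 1 (otherwise it carried no usable signal anyway) |
| `uniqueness` | unique+razor | alternatives: unique-only (conservative), unique-gene (drops only peptides spanning >1 gene symbol) |
| `min_site_probability` | 0.75 | localization probability at which a PTM site counts as confidently localized |
| `aggregation` | median | weighted median available; see below |
| `min_best_prob` | 0.9 | entry-level filter on the best supporting PSM across the dataset |
| `sim_design(noise_cv)` | 0.05 | lognormal reporter noise CV, typical of well-behaved reporter measurements |
| `sim_design(psms_per_protein)` | 20 | a mid-sized protein's PSM support in one plex |

All thresholds are plain function arguments (`filter_config()`), echoed into
the run log for provenance.

## Procedure and numerical choices

**Filter order is fixed** (unlabeled → reference-zero → purity →
probability → contaminants → low-intensity → best-PSM → Astral →
uniqueness), and the low-intensity percentile is computed over the PSMs that
survive the preceding quality rules, so that junk PSMs cannot shift the
percentile. A PSM exactly at the percentile cutoff is retained (strict `<`
removal). The percentile uses type-7 (linear interpolation) quantiles — the
same convention as the IQR step, chosen because it is the most common
default and used consistently between implementation and test oracles.
Best-PSM ties resolve by higher probability, then lexicographically smaller
spectrum id, making the whole chain order-independent.

**Best-PSM identity** is (run, *modified* peptide, charge): using the
modified sequence avoids collapsing distinct PTM site configurations before
site-level grouping has seen them.

**Ratio conversion.** The virtual reference averages on the raw intensity
scale and is then log-transformed — the literal reading of "average of the
reporter intensities"; a geometric mean would systematically sit lower. In
subplex mode (mixed reagent isotopologs) the mean is computed within each
channel's subplex, which removes any multiplicative subplex batch offset
identically (exactly, when noise is zero — this is tested). The optional
retention-time normalization uses ten equal-count (quantile) bins rather
than equal-width bins, which is robust to gradient shape; with fewer PSMs
than bins it falls back to a single bin with a warning.

**Outlier removal** needs at least four observed ratios; with an IQR of 0
the bounds collapse onto the values themselves and nothing is removed.

**Weighted median.** The MS1 precursor weight is used on the raw intensity
scale. (Descriptions of this roll-up sometimes say the intensity is
"exponentiated" first — that reading only makes sense when undoing a log
transform; exponentiating raw intensities overflows and degenerates to an
argmax.) The representative is the first ratio, in ascending order, whose
cumulative normalized weight strictly exceeds 0.5. The largest-weight
fallback can only trigger in degenerate cases; when every weight is zero
and ratios disagree, the unweighted median is used and a warning emitted.

**Normalization and abundances.** MD/GN are computed per level,
independently. Samples with zero MAD are left unscaled by GN (with a
message). The entry filter on best supporting-PSM probability is applied
*before* normalization, so the published matrices keep exact zero medians.
Abundance tables are produced for each requested normalization from the
matching ratio table, `A = R + log2(Ref)`. `Ref` is the per-plex top-3 sum
of reference-weighted MS1 intensities, median across plexes; entries
missing from a plex are imputed with the global minimum per-plex reference
intensity (the literal "global minimum" reading) before the median.
Entries with no positive reference intensity are dropped from abundance
tables with a message. MS2-based alternatives (`ms2_reference`,
`ms2_sum` — the latter summing the reference-weighted MS1 over all PSMs)
are provided.

**PTM levels.** A site is localized when its probability is at least the
threshold; localized sites are capped at the number of target modifications
parsed from the modified peptide (both delta-mass and residue-plus-delta
annotations are recognized), and the remainder are counted as unlocalized
(`+ku` in the multi-site index `<accession>|<peptide>|<config>`). When no
localization probabilities exist, search-engine site assignments are
treated as localized — a documented fallback, not a re-scoring. The
single-site collapse precedence is: drop entries without localized sites;
prefer singly-modified localized forms (median across several such forms,
per sample — the multi-form case is our extension of the single-form rule);
otherwise the per-sample median across all multiply-modified forms
containing the site. Site reference intensities follow the same precedence.

**Determinism.** Nothing in the pipeline draws random numbers; identical
inputs give byte-identical reports (tested). The simulator takes a single
seed and restores the caller's RNG state.

## What the simulator emulates — and what it does not

`simulate_plexes()` generates plexes with known ground truth: background
proteins at equal amounts, spike-ins with designed per-channel fold
changes, an optional pooled bridge channel, lognormal multiplicative
reporter noise, missing values, shared peptides, optional phospho-site
configurations with localization probabilities, and co-isolation
interference modeled as a channel-uniform background replacing a fraction
of each PSM's signal, scaled inversely with precursor intensity. That last
choice makes the weighted-median roll-up demonstrably less compressed than
the plain median under interference — the qualitative behavior expected of
MS2 reporter data.

It does **not** simulate spectra (no m/z, peaks, or isolation windows), the
deuterium retention-time shift itself (subplex splitting is the
mitigation), peptide-level digestion chemistry, batch drift within a plex,
or realistic missingness mechanisms (cells are dropped uniformly at
random). Passing recovery tests on simulated data therefore demonstrates
the correctness of the integration arithmetic under the stated noise model,
not end-to-end accuracy on real instrument data.

## Test problem sizes

The property and contract suites run on small instances chosen to finish in
seconds while still exercising every code path: normalization contracts on
500 entries × 20 samples; fold-change recovery on a 10-channel plex with 20
background proteins, six spike-ins at the designed series (2–40), 50 PSMs
per protein and 20 simulation replicates; the interference-ordering check
on 200 PSMs per protein at interference 0.35; oracle equivalence on 1000
random ≤ 8-PSM groups; subplex cancellation on a 35-channel plex split
18/17.

## Known limitations

- Protein inference, FDR control, localization scoring and reporter-ion
  extraction are upstream; the package consumes their outputs as given.
- Gene-level grouping drops PSMs with an empty gene symbol rather than
  inventing a surrogate key.
- Protein coordinates for PTM sites come from the PSM table
  (`Protein Start` or localization positions); no FASTA lookup is
  performed, and PTM grouping errors out if coordinates are unavailable.
- The virtual reference assumes channels are not dominated by a few
  extreme samples; with highly unbalanced designs a real bridge channel
  remains preferable.
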