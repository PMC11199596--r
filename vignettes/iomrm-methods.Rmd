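---
title: "Methods: fit-for-purpose characterization of immuno-MRM panels"
author: "iomrm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fit-for-purpose characterization of immuno-MRM panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iomrm)
```

## The measurement model

An immuno-MRM assay quantifies a proteotypic tryptic peptide as a
stoichiometric surrogate for its parent protein. A stable-isotope-labeled
("heavy") version of each peptide is spiked into the sample at a known
amount before digestion, both forms are captured with an anti-peptide
monoclonal antibody, and the mass spectrometer records several
precursor/fragment transitions per peptide per isotope label. The
quantitative readout is the **peak-area ratio (PAR)**: the summed
transition intensity of the endogenous (light) peptide divided by that of
the heavy standard (or the inverse for response curves, where the heavy
standard is titrated against constant light peptide).

`iomrm` implements the full characterization chain:

1. **Quantification** (`summarize_measurements()`): per transition, total
   intensity is *peak area + background*. Shared light/heavy fragments are
   screened for interference — a fragment is used only if the two labels
   agree in retention time (default tolerance 0.2 min) and in relative
   transition area (default tolerance 0.20 absolute difference of
   within-label fragment proportions). At least two clean transitions are
   required; otherwise the measurement is unquantifiable, with a reason
   code. Missing is never coded as zero: zeros would corrupt CVs and
   regressions downstream.
2. **Response curves** (`response_curves()`): ordinary least squares of
   log2 mean PAR on log2 spiked amount over the points at or above the
   LLOQ. The **LLOQ** is the lowest designed concentration whose replicate
   CV is < 20% and whose log-log fit over all points at or above it keeps
   linear correlation >= 0.98; by default every higher point must also pass
   the CV rule ("maintained" precision; `strict = FALSE` restores a
   single-point rule). The **ULOQ** drops the top point while the fit
   including it has R^2 < 0.98 or a top-point studentized residual above 3;
   if the highest designed point survives, the ULOQ is only a minimum
   estimate. Dynamic range is `log10(ULOQ/LLOQ)`.
3. **Precision** (`precision_summary()`): intra-assay CV is the unweighted
   mean of within-day CVs; inter-assay CV is the CV of the day means. CVs
   use the sample (n-1) standard deviation on the *untransformed* PAR (the
   log2 transform is reserved for comparative statistics). A peptide fails
   validation when two or more (level x intra/inter) conditions exceed 20%
   CV; a single exceedance is a pass-with-flag (`classify_validation()`).
4. **Stability** (`stability_summary()`): percent difference of the mean
   PAR of a stored arm (24 h autosampler, 2 freeze-thaw cycles) against the
   fresh arm of the same sample.
5. **Sequential enrichment** (`summarize_position()`,
   `sequential_correlations()`): when several antibody panels are applied
   in series to one digest, per-peptide medians of light area, heavy area
   and PAR are compared across enrichment positions with Pearson
   correlation of log10 medians. The log scale is a deliberate choice —
   levels span orders of magnitude and depletion shifts level, not rank;
   pairwise-complete peptide sets maximize usable analytes.
6. **Detection and minimum input** (`detection_histogram()`,
   `minimum_input()`): a cohort peptide is detected in a sample when its
   inferred amount (`PAR x heavy spike`) exceeds the LLOQ. For minimum
   input, per-sample signal-to-noise is operationalized as
   `amount / LLOQ`, tested on the log2 scale with a one-sample, one-sided
   t-test against 0 at 95% confidence and `df = n_site - 1`. If the lower
   confidence bound of the mean log2 ratio is positive, linear-scale
   dilution converts it to the minimum input mass:
   `min_input = 500 ug / 2^lower_bound`, with the interval propagated from
   the t-interval on the mean. The log2 scale makes the null (exactly at
   LLOQ) zero; a linear-scale alternative would weight high-abundance
   samples more heavily, and the choice is recorded in the function
   contract.

## Peptide selection

`select_peptides()` reproduces the rule-based proteotypic selection used
for panel design. Fully tryptic in-silico digestion cleaves after K/R
except before proline, with no missed cleavages. Hard exclusions:
non-unique exact-substring matches across the proteome (Ile/Leu are *not*
treated as equivalent), NG/NP deamidation motifs, N-terminal Gln, protein
N-terminal peptides, length outside 5–30, hydrophobicity outside 10–40,
overlap with a sequence variant at minor allele frequency > 1%, and
annotated high-frequency PTM sites. Cys, Met, ragged cleavage ends
(adjacent K/R in the cleavage context), and protein C-terminal peptides are
deprioritized, not excluded. Ranking is by empirical MS evidence:
observation count, then median intensity, then fewest deprioritizations,
then sequence — a declared, deterministic convention, since the original
intensity/frequency weighting is not published.

The hydrophobicity index is the additive retention-coefficient model on
the packaged 100-Angstrom, TFA ion-pairing coefficient set
(`inst/extdata/hydrophobicity_coefficients_100A_tfa.csv`), with the
published length correction (`1 - 0.027 (10 - N)` below 10 residues,
`1 - 0.014 (N - 20)` above 20) and the damping `H - 0.3 (H - 38)` for
`H >= 38`. Later generations of sequence-specific retention calculators add
positional (e.g. N-terminal) corrections; those coefficient sets are not
redistributed as simple published constants, so this package implements the
first-generation additive model and applies the 10–40 selection window on
that scale. The choice is versioned in the data file name and the index is
only used as a window filter, where the additive model and the full
calculators agree on all but borderline peptides.

## The synthetic-data generator

`simulate_panel()` emits transition-level records for every
characterization design, plus the generating truth, so that each pipeline
stage can be tested as a parameter-recovery problem. The replication
structure matches the standard designs exactly: 8-level dilution series
(2000, 200, 20, 8, 3.2, 1.28, 0.512, 0.205 fmol) in process triplicate
with blanks; 3 spike levels x 3 replicates x 5 days; endogenous 5
replicates x 8 days (n = 40); stability triplicates under two storage
conditions; 3 panels x 3 enrichment positions x triplicate; cohorts of 77
tissue and 48 plasma samples.

The error model is multiplicative-plus-floor, the structure that produces
the CV-versus-concentration shape the LLOQ rule assumes:

* a lognormal **process effect** (`sigma_process`, default 0.15 log2,
  about 11% CV on areas) shared by light and heavy within a replicate —
  spiking the standard before digestion cancels process variation in the
  ratio;
* lognormal **replicate** (`sigma_intra`, default 0.09 log2, about 6.2%
  multiplicative CV) and **day** (`sigma_inter`, default 0.07 log2)
  effects acting on the ratio;
* fixed per-peptide fragment proportions with a small per-transition
  wobble, then additive Gaussian detector noise (`noise_floor`, default
  350 counts in tissue, 175 in plasma), truncated at zero, plus a small
  positive background;
* optional co-eluting contaminants on randomly chosen transitions (area
  plus a 0.5 min retention-time offset, light channel only), which the
  interference screen is expected to remove;
* sub-threshold intensities are emitted as missing rows (dropout), never
  zeros.

Defaults were fixed once, as the conditions of the characterization
experiments they emulate: `sigma_intra`/`sigma_inter` sit inside the
median intra/inter CV ranges typical of validated immuno-MRM panels
(roughly 4–9%); the response factor is lognormal around 1e4 counts/fmol;
the noise floors place the predicted 20% CV crossing of a median peptide
at 0.512 fmol in tissue and 0.205 fmol in plasma; stability shifts are
−2.5% (autosampler) and −3.5% (freeze-thaw); half of the peptides carry
measurable endogenous plasma levels, the rest only trace amounts.

`expected_lloq()` closes the loop analytically: the predicted replicate CV
at spike level *a* is
`sqrt(cv_mult^2 + cv_add(heavy)^2 + cv_add(light)^2)` with
`cv_mult = 100 sqrt(exp((ln2 sigma_intra)^2) - 1)` and
`cv_add = 100 noise_floor sqrt(n_transitions) / (response_factor x
amount)`; the expected LLOQ is the lowest designed level below 20%. For
inter-assay recovery the day means carry the day component plus the
replicate component divided by the number of replicates, so the reference
value is `100 sqrt(exp((ln2 sigma_inter)^2 + (ln2 sigma_intra)^2 / 3) - 1)`.

What the generator does **not** emulate: chromatographic peak shapes and
integration error, digestion kinetics, matrix-dependent ionization
suppression, antibody depletion/carryover mechanisms, and real
between-peptide correlation structure. Passing recovery tests therefore
demonstrates that the estimators implement their definitions and are
unbiased under the stated error model — not that real data meet the model.

## Numerical choices and degenerate inputs

* Sample (n-1) standard deviations everywhere; days with fewer than two
  usable replicates are skipped with a warning.
* "Linear correlation >= 0.98" in the LLOQ rule is applied to Pearson *r*
  (configurable to R^2); both are reported.
* LLOQ filtering is strictly greater-than, idempotent, and monotone in the
  threshold; peptides missing from an LLOQ table are dropped conservatively
  with a warning.
* Blanks never enter curve fits; they feed a diagnostic limit-of-detection
  estimate (mean blank + 3 sd, scaled by the low-end response).
* Zero denominators, empty inputs, and all-failing scans return missing
  values with reason codes rather than zeros or errors.
* Ranking ties break deterministically (deprioritization count, then
  sequence), so results are independent of input order everywhere; readers
  sort records into a canonical order on load.

## Problem sizes used in the tests

Unit tests run on a 6-peptide panel; recovery tests run 100 simulations of
the 43-peptide designs (repeatability and curve arms) and single
simulations of the sequential and cohort arms, sizes at which the Monte
Carlo error of the recovery checks is comfortably below their tolerances.
The complete acceptance run (`scripts/acceptance.R`) simulates all six
designs at full scale and reports the panel-level medians.

## Known limitations

* The characterization writer emits CSV (plus a JSON manifest); workbook
  output is not provided, though workbook *input* is supported via readxl.
* The precision model is the two-level mean-CV scheme standard in
  bioanalytical validation, not a mixed-effects variance decomposition.
* The minimum-input extrapolation assumes signal scales linearly with
  input mass down to the LLOQ, ignoring adsorptive losses at low input.
* Endogenous repeatability is computed on the PAR, not on back-calculated
  amounts; the two differ only by the constant spike.
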