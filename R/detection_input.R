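# Cohort detection profiling and minimum-input extrapolation.
#
# Applied to a biospecimen cohort, each peptide's detection profile is the
# number of samples in which its inferred endogenous amount exceeds the
# LLOQ. For tissue, the signal-to-noise (amount / LLOQ) measured at the
# 500 ug reference input is extrapolated by linear-scale dilution to the
# minimum input mass at which the analyte would still be confidently above
# the LLOQ.

#' Per-peptide cohort detection profiles and histogram
#'
#' @param measurements Cohort measurement tibble (light-over-heavy
#'   orientation), one measurement per peptide per sample, with `sample_id`
#'   and `matrix` annotations.
#' @param lloq_table Tibble `peptide_id` (, `matrix`), `lloq_fmol`;
#'   peptides absent from it are excluded with a warning.
#' @param heavy_spike_fmol Spike used for amount inference (default 200).
#' @return List with `profiles` (tibble `peptide_id`, `n_samples_total`,
#'   `n_samples_above_lloq`, `detection_fraction`) and `histogram` (tibble
#'   `n_samples_detected`, `n_peptides`).
#' @export
detection_histogram <- function(measurements, lloq_table,
                                heavy_spike_fmol = 200) {
  stopifnot("sample_id" %in% names(measurements))
  m <- infer_amounts(measurements, heavy_spike_fmol)
  by <- intersect(intersect(c("peptide_id", "matrix"), names(lloq_table)),
                  names(m))
  absent <- setdiff(unique(m$peptide_id), lloq_table$peptide_id)
  if (length(absent)) {
    warning("excluding peptide(s) absent from LLOQ table: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(m, lloq_table[unique(c(by, "lloq_fmol"))],
                              by = by)
  n_total <- dplyr::n_distinct(joined$sample_id)
  profiles <- joined %>%
    group_by(.data$peptide_id) %>%
    summarise(n_samples_total = n_total,
              n_samples_above_lloq = dplyr::n_distinct(
                .data$sample_id[!is.na(.data$amount_fmol) &
                                  .data$amount_fmol > .data$lloq_fmol]),
              .groups = "drop") %>%
    mutate(detection_fraction = .data$n_samples_above_lloq /
             .data$n_samples_total)
  histogram <- profiles %>%
    dplyr::count(n_samples_detected = .data$n_samples_above_lloq,
                 name = "n_peptides") %>%
    arrange(.data$n_samples_detected)
  list(profiles = profiles, histogram = histogram)
}

#' Minimum input mass for confident detection of one analyte
#'
#' One-sample t-test of the per-sample log2 signal-to-noise ratios
#' `log2(amount / lloq)` against 0 (i.e. against the LLOQ), one-sided at
#' the given confidence, with `df = n - 1`. When the lower one-sided
#' confidence bound of the mean log2 ratio is positive the analyte is
#' confidently above the LLOQ at the reference input, and linear-scale
#' dilution gives the minimum input at which the confident lower-bound
#' signal still equals the LLOQ:
#' `min_input = reference_input / 2^lower_bound`. The reported interval is
#' propagated from the t-interval on the mean
#' (`reference_input / 2^c(upper, lower)`).
#'
#' @param amounts_fmol Per-sample inferred endogenous amounts (fmol) at the
#'   reference input; non-positive amounts are dropped with a warning.
#' @param lloq_fmol The analyte's LLOQ in the cohort matrix.
#' @param reference_input_ug Input mass the amounts were measured at
#'   (default 500 ug).
#' @param confidence One-sided confidence level (default 0.95).
#' @return One-row tibble: `n`, `df`, `snr_mean` and `snr_sd` (log2
#'   domain), `t_statistic`, `lower_bound_log2`, `confident_above_lloq`,
#'   `min_input_ug`, `ci_low_ug`, `ci_high_ug`, `reason`.
#' @export
minimum_input <- function(amounts_fmol, lloq_fmol, reference_input_ug = 500,
                          confidence = 0.95) {
  x <- amounts_fmol[!is.na(amounts_fmol)]
  n_nonpos <- sum(x <= 0)
  if (n_nonpos > 0L) {
    warning("dropping ", n_nonpos, " sample(s) with non-positive amount",
            call. = FALSE)
    x <- x[x > 0]
  }
  miss <- tibble(n = length(x), df = NA_integer_, snr_mean = NA_real_,
                 snr_sd = NA_real_, t_statistic = NA_real_,
                 lower_bound_log2 = NA_real_, confident_above_lloq = FALSE,
                 min_input_ug = NA_real_, ci_low_ug = NA_real_,
                 ci_high_ug = NA_real_, reason = "fewer than 2 samples")
  if (length(x) < 2L || is.na(lloq_fmol) || lloq_fmol <= 0) return(miss)
  z <- log2(x / lloq_fmol)
  n <- length(z)
  m <- mean(z)
  s <- sd(z)
  se <- s / sqrt(n)
  tcrit <- qt(confidence, df = n - 1L)
  lower <- m - tcrit * se
  upper <- m + tcrit * se
  tstat <- if (se > 0) m / se else ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0))
  confident <- lower > 0
  tibble(n = n, df = n - 1L, snr_mean = m, snr_sd = s, t_statistic = tstat,
         lower_bound_log2 = lower, confident_above_lloq = confident,
         min_input_ug = if (confident) reference_input_ug / 2^lower
                        else NA_real_,
         ci_low_ug = if (confident) reference_input_ug / 2^upper
                     else NA_real_,
         ci_high_ug = if (confident) reference_input_ug / 2^lower
                      else NA_real_,
         reason = NA_character_)
}

#' Minimum-input results for a whole cohort, stratified by site
#'
#' @param measurements Cohort measurement tibble with `sample_id` and,
#'   optionally, `site` annotations (sites with one sample yield no
#'   result: `df = n - 1` would be zero).
#' @param lloq_table Tibble `peptide_id` (, `matrix`), `lloq_fmol`.
#' @param heavy_spike_fmol,reference_input_ug,confidence See
#'   [minimum_input()].
#' @return Tibble, one row per peptide x site, with the [minimum_input()]
#'   columns.
#' @export
minimum_input_by_site <- function(measurements, lloq_table,
                                  heavy_spike_fmol = 200,
                                  reference_input_ug = 500,
                                  confidence = 0.95) {
  m <- infer_amounts(measurements, heavy_spike_fmol)
  if (!"site" %in% names(m)) m$site <- "all"
  by <- intersect(intersect(c("peptide_id", "matrix"), names(lloq_table)),
                  names(m))
  joined <- dplyr::inner_join(m, lloq_table[unique(c(by, "lloq_fmol"))],
                              by = by)
  groups <- split(joined, list(joined$peptide_id, joined$site), drop = TRUE,
                  sep = "\r")
  rows <- lapply(groups, function(g) {
    res <- suppressWarnings(
      minimum_input(g$amount_fmol, g$lloq_fmol[1L], reference_input_ug,
                    confidence))
    dplyr::bind_cols(tibble(peptide_id = g$peptide_id[1L],
                            site = g$site[1L]), res)
  })
  arrange(bind_rows(rows), .data$peptide_id, .data$site)
}

#' Predicted number of detectable analytes at reduced input masses
#'
#' For each input mass on the grid, counts the analytes whose estimated
#' minimum input is at or below that mass. The interval columns count
#' analytes using the two ends of each analyte's propagated confidence
#' interval, so they bracket the point count. Counts are monotone
#' non-decreasing in input mass.
#'
#' @param minimum_input_results Tibble from [minimum_input_by_site()].
#' @param input_grid Input masses in ug (default `c(10, 50, 200, 500)`).
#' @return Tibble `site`, `input_ug`, `n_detected`, `n_detected_low`,
#'   `n_detected_high`, `n_confident`.
#' @export
predicted_detected_at_inputs <- function(minimum_input_results,
                                         input_grid = c(10, 50, 200, 500)) {
  if (length(input_grid) == 0L) stop("empty input grid", call. = FALSE)
  res <- minimum_input_results
  rows <- lapply(split(res, res$site), function(g) {
    bind_rows(lapply(sort(input_grid), function(m) {
      tibble(site = g$site[1L], input_ug = m,
             n_detected = sum(g$min_input_ug <= m, na.rm = TRUE),
             n_detected_low = sum(g$ci_high_ug <= m, na.rm = TRUE),
             n_detected_high = sum(g$ci_low_ug <= m, na.rm = TRUE),
             n_confident = sum(g$confident_above_lloq, na.rm = TRUE))
    }))
  })
  bind_rows(rows)
}
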