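# Transition-level records -> per-replicate peptide measurements.
#
# The quantitative readout of a stable-isotope-dilution MRM assay is the
# peak-area ratio (PAR) of the summed transition intensities of the
# endogenous (light) peptide and its spiked heavy-labelled standard.
# Before summation, each shared fragment is screened for interference by
# requiring the light and heavy signals to agree in retention time and in
# relative transition area.

#' Total intensity of one peptide/label/replicate
#'
#' Summed `area + background` over the used transitions. An empty input
#' yields a missing value, never zero: absence of signal must not masquerade
#' as a measured zero in CVs or regressions.
#'
#' @param area,background Numeric vectors of per-transition integrated peak
#'   areas and backgrounds (same length).
#' @return Single numeric total, or `NA` when no transitions remain.
#' @export
#' @examples
#' total_intensity(c(100, 200), c(10, 20))  # 330
total_intensity <- function(area, background = 0) {
  if (length(area) == 0L) return(NA_real_)
  if (length(background) == 1L) background <- rep(background, length(area))
  stopifnot(length(area) == length(background))
  sum(area + background)
}

#' Screen shared transitions for interference
#'
#' A transition is accepted only if the light and heavy signals agree in
#' retention time (`|RT_l - RT_h| <= rt_tolerance`) and in relative
#' transition area: with `p = area / sum(area)` computed within each label
#' over the shared fragments, the fragment is flagged `interfered` when
#' `|p_light - p_heavy| > proportion_tolerance`. Interfered fragments are
#' excluded from summation for both labels. If fewer than two clean shared
#' fragments remain the measurement is unquantifiable (the two-transition
#' minimum).
#'
#' @param light_records,heavy_records Tibbles with columns `fragment_name`,
#'   `area`, `retention_time`, one row per transition of one peptide in one
#'   replicate.
#' @param rt_tolerance Maximum light/heavy retention-time difference in
#'   minutes (default 0.2).
#' @param proportion_tolerance Maximum absolute difference in within-label
#'   fragment area proportions (default 0.20).
#' @return Tibble with one row per shared fragment: `fragment_name`,
#'   `rt_delta`, `proportion_delta`, `verdict` (`"clean"`/`"interfered"`),
#'   plus attributes `quantifiable` (logical) and `reason`.
#' @export
screen_interference <- function(light_records, heavy_records,
                                rt_tolerance = 0.2,
                                proportion_tolerance = 0.20) {
  shared <- intersect(light_records$fragment_name,
                      heavy_records$fragment_name)
  if (length(shared) == 0L) {
    out <- tibble(fragment_name = character(), rt_delta = numeric(),
                  proportion_delta = numeric(), verdict = character())
    attr(out, "quantifiable") <- FALSE
    attr(out, "reason") <- "no shared fragments between labels"
    return(out)
  }
  l <- light_records[match(shared, light_records$fragment_name), ]
  h <- heavy_records[match(shared, heavy_records$fragment_name), ]
  p_l <- l$area / sum(l$area)
  p_h <- h$area / sum(h$area)
  rt_delta <- abs(l$retention_time - h$retention_time)
  prop_delta <- abs(p_l - p_h)
  # an all-zero label gives NaN proportions: nothing to confirm against
  verdict <- ifelse(!is.finite(rt_delta) | !is.finite(prop_delta) |
                      rt_delta > rt_tolerance |
                      prop_delta > proportion_tolerance,
                    "interfered", "clean")
  out <- tibble(fragment_name = shared, rt_delta = rt_delta,
                proportion_delta = prop_delta, verdict = verdict)
  n_clean <- sum(verdict == "clean")
  attr(out, "quantifiable") <- n_clean >= 2L
  attr(out, "reason") <- if (n_clean >= 2L) NA_character_ else
    "fewer than 2 clean transitions"
  out
}

#' Light/heavy peak-area ratio
#'
#' @param light_total,heavy_total Summed intensities for the light and heavy
#'   channel.
#' @param orientation `"light_over_heavy"` (endogenous quantification) or
#'   `"heavy_over_light"` (response curves, where the heavy standard is
#'   titrated against constant light).
#' @return The ratio, or `NA` when the denominator is zero or missing
#'   (attribute `reason` explains which).
#' @export
peak_area_ratio <- function(light_total, heavy_total,
                            orientation = c("light_over_heavy",
                                            "heavy_over_light")) {
  orientation <- match.arg(orientation)
  num <- if (orientation == "light_over_heavy") light_total else heavy_total
  den <- if (orientation == "light_over_heavy") heavy_total else light_total
  if (is.na(den) || is.na(num)) {
    out <- NA_real_
    attr(out, "reason") <- "missing total"
    return(out)
  }
  if (den == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero denominator"
    return(out)
  }
  num / den
}

#' Summarize transition records into per-replicate peptide measurements
#'
#' For every (peptide, replicate): screens shared fragments for interference,
#' sums `area + background` over the clean fragments in each label, forms the
#' peak-area ratio in the requested orientation, and log2-transforms it.
#' Sample annotations (matrix, day, spike level, condition, position, panel,
#' sample id, ...) are carried through from the transition records. Results
#' are independent of input row order.
#'
#' @param records Tibble of transition records as returned by
#'   [read_transition_report()] or [simulate_panel()].
#' @param orientation Peak-area-ratio orientation, see [peak_area_ratio()].
#' @param rt_tolerance,proportion_tolerance Interference-screen thresholds,
#'   see [screen_interference()].
#' @return Tibble with one row per peptide x replicate: annotations,
#'   `light_total`, `heavy_total`, `par`, `log2_par`, `n_used`,
#'   `n_excluded`, `quantifiable`, `reason`.
#' @export
summarize_measurements <- function(records,
                                   orientation = c("light_over_heavy",
                                                   "heavy_over_light"),
                                   rt_tolerance = 0.2,
                                   proportion_tolerance = 0.20) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("peptide_id", "label", "replicate_id", "fragment_name",
                  "area") %in% names(records)))
  if (!"background" %in% names(records)) records$background <- 0
  if (!"retention_time" %in% names(records)) records$retention_time <- 0
  records <- arrange(records, .data$peptide_id, .data$replicate_id,
                     .data$label, .data$fragment_name)
  ann_cols <- intersect(names(records),
                        c(.annotation_numeric, .annotation_character))
  ann <- records %>%
    select(all_of(c("peptide_id", "replicate_id", ann_cols))) %>%
    distinct(.data$peptide_id, .data$replicate_id, .keep_all = TRUE)

  # Vectorized equivalent of screen_interference() + total_intensity() per
  # (peptide, replicate); the per-measurement functions remain the
  # reference implementation.
  cols <- c("peptide_id", "replicate_id", "fragment_name", "area",
            "background", "retention_time")
  l <- records[records$label == "light", cols]
  h <- records[records$label == "heavy", cols]
  paired <- dplyr::inner_join(l, h,
                              by = c("peptide_id", "replicate_id",
                                     "fragment_name"),
                              suffix = c("_l", "_h")) %>%
    group_by(.data$peptide_id, .data$replicate_id) %>%
    mutate(p_l = .data$area_l / sum(.data$area_l),
           p_h = .data$area_h / sum(.data$area_h),
           rt_delta = abs(.data$retention_time_l - .data$retention_time_h),
           prop_delta = abs(.data$p_l - .data$p_h),
           clean = is.finite(.data$rt_delta) & is.finite(.data$prop_delta) &
             .data$rt_delta <= rt_tolerance &
             .data$prop_delta <= proportion_tolerance)
  core <- paired %>%
    summarise(n_used = sum(.data$clean),
              n_excluded = sum(!.data$clean),
              light_total = ifelse(sum(.data$clean) >= 2L,
                                   sum((.data$area_l +
                                          .data$background_l)[.data$clean]),
                                   NA_real_),
              heavy_total = ifelse(sum(.data$clean) >= 2L,
                                   sum((.data$area_h +
                                          .data$background_h)[.data$clean]),
                                   NA_real_),
              .groups = "drop")
  out <- records %>%
    distinct(.data$peptide_id, .data$replicate_id) %>%
    left_join(core, by = c("peptide_id", "replicate_id"))
  out$n_used[is.na(out$n_used)] <- 0L
  out$n_excluded[is.na(out$n_excluded)] <- 0L
  num <- if (orientation == "light_over_heavy") out$light_total else
    out$heavy_total
  den <- if (orientation == "light_over_heavy") out$heavy_total else
    out$light_total
  out$par <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  out$log2_par <- ifelse(is.na(out$par) | out$par <= 0, NA_real_,
                         log2(out$par))
  out$quantifiable <- out$n_used >= 2L & !is.na(out$par)
  out$reason <- dplyr::case_when(
    out$n_used + out$n_excluded == 0L ~ "no shared fragments between labels",
    out$n_used < 2L ~ "fewer than 2 clean transitions",
    is.na(den) | den == 0 ~ "zero denominator",
    TRUE ~ NA_character_)
  out <- left_join(out, ann, by = c("peptide_id", "replicate_id"))
  out$par_orientation <- orientation
  arrange(out, .data$peptide_id, .data$replicate_id)
}

#' Inferred endogenous amount from a peak-area ratio
#'
#' Stable-isotope-dilution convention: `amount_fmol = PAR(light/heavy) x
#' heavy spike (fmol)`. Measurements in the heavy-over-light orientation are
#' inverted first.
#'
#' @param measurements Measurement tibble from [summarize_measurements()];
#'   must carry a `heavy_spike_fmol` annotation column (or supply
#'   `heavy_spike_fmol`).
#' @param heavy_spike_fmol Fallback spike amount when the annotation column
#'   is absent (default 200 fmol, the panel's standard spike).
#' @return The tibble with an added `amount_fmol` column.
#' @export
infer_amounts <- function(measurements, heavy_spike_fmol = 200) {
  spike <- if ("heavy_spike_fmol" %in% names(measurements)) {
    ifelse(is.na(measurements$heavy_spike_fmol), heavy_spike_fmol,
           measurements$heavy_spike_fmol)
  } else rep(heavy_spike_fmol, nrow(measurements))
  par_lh <- if (all(measurements$par_orientation == "heavy_over_light")) {
    1 / measurements$par
  } else measurements$par
  measurements$amount_fmol <- par_lh * spike
  measurements
}

#' Filter measurements by the lower limit of quantification
#'
#' Retains measurements whose inferred endogenous amount is strictly greater
#' than the peptide's LLOQ in the relevant matrix. Peptides absent from the
#' LLOQ table are dropped with a warning (conservative). The operation is
#' idempotent and monotone in the threshold.
#'
#' @param measurements Measurement tibble (light-over-heavy orientation) with
#'   `matrix` annotations; amounts are inferred via [infer_amounts()] if the
#'   `amount_fmol` column is absent.
#' @param lloq_table Tibble with columns `peptide_id`, `matrix`,
#'   `lloq_fmol`.
#' @param heavy_spike_fmol Passed to [infer_amounts()].
#' @return Filtered measurement tibble.
#' @export
filter_by_lloq <- function(measurements, lloq_table, heavy_spike_fmol = 200) {
  stopifnot(all(c("peptide_id", "lloq_fmol") %in% names(lloq_table)))
  if (!"amount_fmol" %in% names(measurements)) {
    measurements <- infer_amounts(measurements, heavy_spike_fmol)
  }
  by <- intersect(c("peptide_id", "matrix"), names(lloq_table))
  by <- intersect(by, names(measurements))
  joined <- left_join(measurements,
                      lloq_table[unique(c(by, "lloq_fmol"))], by = by)
  absent <- unique(joined$peptide_id[is.na(joined$lloq_fmol)])
  if (length(absent)) {
    warning("dropping measurements for peptide(s) absent from LLOQ table: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- joined[!is.na(joined$lloq_fmol) & !is.na(joined$amount_fmol) &
                  joined$amount_fmol > joined$lloq_fmol, ]
  out$lloq_fmol <- NULL
  out
}
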