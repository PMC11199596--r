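# Intra-/inter-assay precision, stability percent differences, and
# pass/fail validation calls.
#
# Precision follows the two-level scheme standard in bioanalytical
# validation: intra-assay variation is the mean of the within-day %CVs;
# inter-assay variation is the %CV of the per-day means. CVs are computed
# on the untransformed peak-area ratio with the sample (n-1) standard
# deviation.

#' Intra-assay coefficient of variation
#'
#' Per-day %CV (`100 * sd / mean` of the peak-area ratios within a day),
#' averaged (unweighted) over days. Days with fewer than two usable
#' replicates are skipped with a warning; if every day is skipped the
#' result is missing.
#'
#' @param par Numeric vector of peak-area ratios.
#' @param day Parallel vector identifying the day of each replicate.
#' @return Percent CV.
#' @export
intra_assay_cv <- function(par, day) {
  stopifnot(length(par) == length(day))
  keep <- !is.na(par) & !is.na(day)
  cvs <- tapply(par[keep], day[keep], cv_percent)
  skipped <- sum(is.na(cvs))
  if (skipped > 0L) {
    warning(skipped, " day(s) skipped (fewer than 2 usable replicates)",
            call. = FALSE)
  }
  if (all(is.na(cvs))) return(NA_real_)
  mean(cvs, na.rm = TRUE)
}

#' Inter-assay coefficient of variation
#'
#' %CV of the per-day mean peak-area ratios. Missing with fewer than two
#' days.
#'
#' @inheritParams intra_assay_cv
#' @return Percent CV.
#' @export
inter_assay_cv <- function(par, day) {
  stopifnot(length(par) == length(day))
  keep <- !is.na(par) & !is.na(day)
  day_means <- tapply(par[keep], day[keep], mean)
  if (length(day_means) < 2L) return(NA_real_)
  cv_percent(as.numeric(day_means))
}

#' Precision summary per peptide x matrix x level
#'
#' Groups repeatability-design measurements (spiked low/medium/high and the
#' endogenous arm) and computes intra- and inter-assay CVs.
#'
#' @param measurements Measurement tibble with `day`, `matrix`, and either a
#'   `spike_level` annotation (`"low"`, `"medium"`, `"high"`,
#'   `"endogenous"`) or a `spike_fmol` annotation mapped via `level_map`.
#' @param level_map Named numeric vector mapping level names to spike
#'   amounts (default `c(low = 20, medium = 200, high = 2000)`).
#' @return Tibble `peptide_id`, `matrix`, `level`, `intra_cv_percent`,
#'   `inter_cv_percent`, `n_days`, `n_reps_per_day`.
#' @export
precision_summary <- function(measurements,
                              level_map = c(low = 20, medium = 200,
                                            high = 2000)) {
  m <- measurements
  if (!"matrix" %in% names(m)) m$matrix <- "tissue"
  if (!"spike_level" %in% names(m) || all(is.na(m$spike_level))) {
    m$spike_level <- names(level_map)[match(m$spike_fmol, level_map)]
    m$spike_level[is.na(m$spike_level)] <- "endogenous"
  }
  m <- filter(m, !is.na(.data$day))
  m %>%
    group_by(.data$peptide_id, .data$matrix, level = .data$spike_level) %>%
    summarise(
      intra_cv_percent = suppressWarnings(
        intra_assay_cv(.data$par, .data$day)),
      inter_cv_percent = inter_assay_cv(.data$par, .data$day),
      n_days = n_distinct(.data$day),
      n_reps_per_day = as.integer(round(n() / n_distinct(.data$day))),
      .groups = "drop")
}

#' Stability percent difference
#'
#' `100 * (mean(stored) - mean(fresh)) / mean(fresh)` over process
#' replicates; missing when the fresh arm has no usable mean.
#'
#' @param stored_pars,fresh_pars Numeric vectors of peak-area ratios for the
#'   stored and immediately analyzed arms.
#' @return Percent difference.
#' @export
stability_percent_difference <- function(stored_pars, fresh_pars) {
  ms <- mean(stored_pars, na.rm = TRUE)
  mf <- mean(fresh_pars, na.rm = TRUE)
  if (!is.finite(ms) || !is.finite(mf) || mf == 0) return(NA_real_)
  100 * (ms - mf) / mf
}

#' Stability summary per peptide x matrix x condition
#'
#' Compares each storage condition (24 h at 4 degrees C in the autosampler;
#' two freeze-thaw cycles) against the fresh arm of the same sample.
#'
#' @param measurements Stability-design measurement tibble with `condition`
#'   annotations (`"fresh"` plus stored conditions).
#' @param fresh_label Condition value identifying the fresh arm.
#' @return Tibble `peptide_id`, `matrix`, `condition`,
#'   `percent_difference`, `n_stored`, `n_fresh`.
#' @export
stability_summary <- function(measurements, fresh_label = "fresh") {
  m <- measurements
  if (!"matrix" %in% names(m)) m$matrix <- "tissue"
  stopifnot("condition" %in% names(m))
  conds <- setdiff(unique(m$condition[!is.na(m$condition)]), fresh_label)
  rows <- lapply(split(m, list(m$peptide_id, m$matrix), drop = TRUE,
                       sep = "\r"), function(g) {
    fresh <- g$par[g$condition == fresh_label]
    bind_rows(lapply(conds, function(cc) {
      stored <- g$par[g$condition == cc]
      tibble(peptide_id = g$peptide_id[1L], matrix = g$matrix[1L],
             condition = cc,
             percent_difference = stability_percent_difference(stored, fresh),
             n_stored = sum(!is.na(stored)), n_fresh = sum(!is.na(fresh)))
    }))
  })
  arrange(bind_rows(rows), .data$peptide_id, .data$matrix, .data$condition)
}

#' Pass/fail validation call from precision results
#'
#' Within each matrix, every available (level x intra/inter) condition is
#' compared against `cv_threshold`. A peptide fails when at least
#' `fail_min_exceedances` conditions exceed the threshold ("multiple sample
#' concentrations showing CV > 20%"); exactly one exceedance is a
#' pass-with-flag; none is a clean pass. Reasons enumerate the offending
#' conditions.
#'
#' @param precision_results Tibble from [precision_summary()].
#' @param cv_threshold Percent CV bound (default 20).
#' @param fail_min_exceedances Number of offending conditions that means
#'   failure (default 2).
#' @return Tibble `peptide_id`, `matrix`, `n_exceedances`, `call`
#'   (`"pass"`, `"pass_with_flag"`, `"fail"`), `reasons`.
#' @export
classify_validation <- function(precision_results, cv_threshold = 20,
                                fail_min_exceedances = 2L) {
  long <- tidyr::pivot_longer(
    precision_results,
    cols = c("intra_cv_percent", "inter_cv_percent"),
    names_to = "type", values_to = "cv")
  long$type <- sub("_cv_percent$", "", long$type)
  long %>%
    group_by(.data$peptide_id, .data$matrix) %>%
    summarise(
      n_exceedances = sum(.data$cv > cv_threshold, na.rm = TRUE),
      reasons = paste(paste0(.data$level[!is.na(.data$cv) &
                                           .data$cv > cv_threshold], ":",
                             .data$type[!is.na(.data$cv) &
                                          .data$cv > cv_threshold]),
                      collapse = ","),
      .groups = "drop") %>%
    mutate(call = case_when(
      .data$n_exceedances >= fail_min_exceedances ~ "fail",
      .data$n_exceedances == 1L ~ "pass_with_flag",
      TRUE ~ "pass"),
      reasons = ifelse(.data$n_exceedances == 0L, NA_character_,
                       .data$reasons))
}
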