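# End-to-end orchestration: raw transition records -> characterization
# table, panel-level summaries, and a run manifest. Stage order matters
# only in that LLOQs are computed from the curve design before any
# LLOQ-dependent stage runs; each stage is a pure function of upstream
# tables.

.median_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else median(x)
}

#' Run the full fit-for-purpose characterization
#'
#' Consumes a transition-level record table whose `design` annotation
#' assigns rows to the validation designs (`curve`, `repeatability`,
#' `endogenous`, `stability`, `sequential`, `cohort`) and executes the
#' pipeline: quantification, response curves (LLOQ/ULOQ first), precision,
#' stability, validation calls, sequential-enrichment concordance, cohort
#' detection and minimum-input extrapolation. Panel-level medians exclude
#' peptides flagged unquantifiable, mirroring the above-LLOQ framing of the
#' figures of merit.
#'
#' @param records Transition records ([read_transition_report()] /
#'   [simulate_panel()] schema) with a `design` column.
#' @param stages Which stages to run (default: all present in the data);
#'   stages whose design arm is absent raise an error naming the arm
#'   unless they were excluded here.
#' @param heavy_spike_fmol Standard heavy spike (fmol) used when a record
#'   carries no `heavy_spike_fmol` annotation.
#' @param input_grid Input masses (ug) for the detection extrapolation.
#' @param rt_tolerance,proportion_tolerance Interference-screen thresholds.
#' @param cv_threshold Validation CV bound in percent.
#' @return List: `characterization` (one row per peptide x matrix),
#'   `curves`, `precision`, `stability`, `validation`, `sequential`
#'   (summaries + correlations), `detection` (per cohort matrix),
#'   `minimum_input`, `predicted_inputs`, `panel_summary`, `manifest`.
#' @export
run_full_characterization <- function(records,
                                      stages = c("curves", "precision",
                                                 "stability", "sequential",
                                                 "detection"),
                                      heavy_spike_fmol = 200,
                                      input_grid = c(10, 50, 200, 500),
                                      rt_tolerance = 0.2,
                                      proportion_tolerance = 0.20,
                                      cv_threshold = 20) {
  stopifnot("design" %in% names(records))
  stages <- match.arg(stages, several.ok = TRUE)
  have <- unique(records$design)
  need <- c(curves = "curve", precision = "repeatability",
            stability = "stability", sequential = "sequential",
            detection = "cohort")
  for (st in stages) {
    if (!need[[st]] %in% have) {
      stop("design arm '", need[[st]], "' required by stage '", st,
           "' is missing from the records", call. = FALSE)
    }
  }
  quant <- function(design, orientation) {
    summarize_measurements(records[records$design == design, ],
                           orientation = orientation,
                           rt_tolerance = rt_tolerance,
                           proportion_tolerance = proportion_tolerance)
  }
  out <- list()
  lloq_table <- NULL

  if ("curves" %in% stages) {
    m_curve <- quant("curve", "heavy_over_light")
    out$curves <- response_curves(m_curve)
    lloq_table <- out$curves[, c("peptide_id", "matrix", "lloq_fmol")]
  }

  if ("precision" %in% stages) {
    m_rep <- quant("repeatability", "light_over_heavy")
    prec_spiked <- suppressWarnings(precision_summary(m_rep))
    prec_endog <- NULL
    if ("endogenous" %in% have) {
      m_end <- quant("endogenous", "light_over_heavy")
      if (!is.null(lloq_table)) {
        m_end <- suppressWarnings(filter_by_lloq(m_end, lloq_table,
                                                 heavy_spike_fmol))
      }
      prec_endog <- suppressWarnings(precision_summary(m_end))
    }
    out$precision <- bind_rows(prec_spiked, prec_endog)
    out$validation <- classify_validation(out$precision,
                                          cv_threshold = cv_threshold)
  }

  if ("stability" %in% stages) {
    m_stab <- quant("stability", "light_over_heavy")
    out$stability <- stability_summary(m_stab)
  }

  if ("sequential" %in% stages) {
    m_seq <- quant("sequential", "light_over_heavy")
    seq_lloq <- NULL
    if (!is.null(lloq_table)) {
      # assay LLOQs are defined in tissue/plasma; apply the tissue limits
      # to the cell-lysate pool
      seq_lloq <- lloq_table[lloq_table$matrix == "tissue",
                             c("peptide_id", "lloq_fmol")]
    }
    positions <- sort(unique(m_seq$position))
    summaries <- summarize_position(m_seq, lloq_table = seq_lloq,
                                    heavy_spike_fmol = heavy_spike_fmol,
                                    positions = positions)
    out$sequential <- list(
      summaries = summaries,
      correlations = sequential_correlations(summaries,
                                             positions = positions))
  }

  if ("detection" %in% stages && !is.null(lloq_table)) {
    m_coh <- quant("cohort", "light_over_heavy")
    det <- list()
    for (mx in unique(m_coh$matrix)) {
      det[[mx]] <- suppressWarnings(
        detection_histogram(m_coh[m_coh$matrix == mx, ], lloq_table,
                            heavy_spike_fmol))
    }
    out$detection <- det
    if ("tissue" %in% names(det)) {
      out$minimum_input <- minimum_input_by_site(
        m_coh[m_coh$matrix == "tissue", ], lloq_table,
        heavy_spike_fmol = heavy_spike_fmol)
      out$predicted_inputs <- predicted_detected_at_inputs(
        out$minimum_input, input_grid = input_grid)
    }
  }

  out$characterization <- .assemble_characterization(out)
  out$panel_summary <- .panel_summary(out)
  out$manifest <- list(
    package = "iomrm",
    version = as.character(utils::packageVersion("iomrm")),
    stages = stages,
    n_records = nrow(records),
    settings = list(heavy_spike_fmol = heavy_spike_fmol,
                    rt_tolerance = rt_tolerance,
                    proportion_tolerance = proportion_tolerance,
                    cv_threshold = cv_threshold,
                    input_grid = input_grid),
    input_hash = rlang::hash(records))
  out
}

.assemble_characterization <- function(out) {
  base <- NULL
  if (!is.null(out$curves)) base <- out$curves
  if (!is.null(out$precision)) {
    wide <- tidyr::pivot_wider(
      out$precision[, c("peptide_id", "matrix", "level", "intra_cv_percent",
                        "inter_cv_percent")],
      names_from = "level",
      values_from = c("intra_cv_percent", "inter_cv_percent"))
    base <- if (is.null(base)) wide else
      dplyr::full_join(base, wide, by = c("peptide_id", "matrix"))
  }
  if (!is.null(out$stability)) {
    sw <- tidyr::pivot_wider(
      out$stability[, c("peptide_id", "matrix", "condition",
                        "percent_difference")],
      names_from = "condition", values_from = "percent_difference",
      names_prefix = "stability_pctdiff_")
    base <- if (is.null(base)) sw else
      dplyr::full_join(base, sw, by = c("peptide_id", "matrix"))
  }
  if (!is.null(out$validation)) {
    base <- dplyr::full_join(
      base, out$validation[, c("peptide_id", "matrix", "call", "reasons")],
      by = c("peptide_id", "matrix"))
  }
  if (is.null(base)) return(NULL)
  arrange(base, .data$peptide_id, .data$matrix)
}

.panel_summary <- function(out) {
  rows <- list()
  add <- function(matrix, metric, value, n) {
    rows[[length(rows) + 1L]] <<- tibble(matrix = matrix, metric = metric,
                                         median = value, n = n)
  }
  if (!is.null(out$curves)) {
    cv <- out$curves[out$curves$quantifiable, ]
    for (mx in unique(cv$matrix)) {
      g <- cv[cv$matrix == mx, ]
      add(mx, "lloq_fmol", .median_or_na(g$lloq_fmol), nrow(g))
      add(mx, "dynamic_range_log10", .median_or_na(g$dynamic_range_log10),
          nrow(g))
      add(mx, "slope", .median_or_na(g$slope), nrow(g))
      add(mx, "r_squared", .median_or_na(g$r_squared), nrow(g))
    }
  }
  if (!is.null(out$precision)) {
    pr <- out$precision
    for (mx in unique(pr$matrix)) {
      for (lv in unique(pr$level[pr$matrix == mx])) {
        g <- pr[pr$matrix == mx & pr$level == lv, ]
        add(mx, paste0("intra_cv_", lv), .median_or_na(g$intra_cv_percent),
            sum(is.finite(g$intra_cv_percent)))
        add(mx, paste0("inter_cv_", lv), .median_or_na(g$inter_cv_percent),
            sum(is.finite(g$inter_cv_percent)))
      }
    }
  }
  if (!is.null(out$stability)) {
    st <- out$stability
    for (mx in unique(st$matrix)) {
      for (cc in unique(st$condition[st$matrix == mx])) {
        g <- st[st$matrix == mx & st$condition == cc, ]
        add(mx, paste0("stability_pctdiff_", cc),
            .median_or_na(g$percent_difference),
            sum(is.finite(g$percent_difference)))
      }
    }
  }
  bind_rows(rows)
}

#' Write the run manifest as a JSON sidecar
#'
#' @param result Output of [run_full_characterization()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
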