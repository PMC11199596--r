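# Sequential multi-panel enrichment concordance.
#
# Several antibody panels can be applied to one digest in series, each
# capturing its analytes from the previous panel's flow-through. Validation
# is a concordance check: per-peptide medians of light area, heavy area and
# peak-area ratio must correlate across enrichment positions 1-3.

#' Per-position median summaries
#'
#' Medians over process replicates of light total, heavy total and
#' peak-area ratio, per panel x position x peptide. Only peptides
#' quantified above the LLOQ at a position are retained there; exclusion is
#' pairwise (a peptide below LLOQ at position 3 drops out of comparisons
#' involving position 3 only).
#'
#' @param measurements Sequential-design measurement tibble
#'   (light-over-heavy orientation) with `panel` and `position`
#'   annotations.
#' @param lloq_table Optional tibble `peptide_id` (, `matrix`),
#'   `lloq_fmol`; when supplied, positions where the median inferred amount
#'   is at or below the LLOQ are excluded.
#' @param heavy_spike_fmol Spike used for amount inference (default 200).
#' @param positions Positions that must be present (default 1:3); a
#'   missing position is an error naming it.
#' @return Tibble `panel`, `position`, `peptide_id`, `median_light_area`,
#'   `median_heavy_area`, `median_par`, `n_replicates`.
#' @export
summarize_position <- function(measurements, lloq_table = NULL,
                               heavy_spike_fmol = 200, positions = 1:3) {
  stopifnot(all(c("panel", "position") %in% names(measurements)))
  present <- unique(measurements$position)
  absent <- setdiff(positions, present)
  if (length(absent)) {
    stop("enrichment position(s) missing from the data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- measurements %>%
    group_by(.data$panel, .data$position, .data$peptide_id) %>%
    summarise(median_light_area = median(.data$light_total, na.rm = TRUE),
              median_heavy_area = median(.data$heavy_total, na.rm = TRUE),
              median_par = median(.data$par, na.rm = TRUE),
              n_replicates = sum(!is.na(.data$par)), .groups = "drop")
  if (!is.null(lloq_table)) {
    by <- intersect(c("peptide_id", "matrix"), names(lloq_table))
    by <- intersect(by, names(out))
    out <- left_join(out, lloq_table[unique(c(by, "lloq_fmol"))], by = by)
    amount <- out$median_par * heavy_spike_fmol
    out <- out[!is.na(out$lloq_fmol) & !is.na(amount) &
                 amount > out$lloq_fmol, ]
    out$lloq_fmol <- NULL
  }
  arrange(out, .data$panel, .data$position, .data$peptide_id)
}

#' Correlation of per-peptide summaries between two enrichment positions
#'
#' Pearson correlation of log10-transformed medians over the peptides
#' quantified at both positions (pairwise-complete). Signal levels span
#' orders of magnitude, so the log scale makes the coefficient reflect
#' rank/level concordance rather than the few largest analytes.
#'
#' @param summaries Tibble from [summarize_position()].
#' @param quantity `"light"`, `"heavy"`, or `"par"`.
#' @param pos_a,pos_b Enrichment positions to compare.
#' @param log_transform Correlate `log10` medians (default `TRUE`).
#' @return List `r`, `n`, `reason` (`NA` unless fewer than 3 shared
#'   peptides, in which case `r` is missing).
#' @export
position_correlation <- function(summaries, quantity = c("light", "heavy",
                                                         "par"),
                                 pos_a, pos_b, log_transform = TRUE) {
  quantity <- match.arg(quantity)
  col <- switch(quantity, light = "median_light_area",
                heavy = "median_heavy_area", par = "median_par")
  a <- summaries[summaries$position == pos_a, c("panel", "peptide_id", col)]
  b <- summaries[summaries$position == pos_b, c("panel", "peptide_id", col)]
  joined <- dplyr::inner_join(a, b, by = c("panel", "peptide_id"),
                              suffix = c("_a", "_b"))
  x <- joined[[paste0(col, "_a")]]
  y <- joined[[paste0(col, "_b")]]
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    return(list(r = NA_real_, n = length(x),
                reason = "fewer than 3 shared peptides"))
  }
  if (log_transform) { x <- log10(x); y <- log10(y) }
  list(r = cor(x, y), n = length(x), reason = NA_character_)
}

#' All pairwise position correlations
#'
#' @param summaries Tibble from [summarize_position()].
#' @param positions Positions to compare (default 1:3).
#' @param ... Passed to [position_correlation()].
#' @return Tibble `quantity`, `pos_a`, `pos_b`, `r`, `n` for every
#'   quantity x unordered position pair.
#' @export
sequential_correlations <- function(summaries, positions = 1:3, ...) {
  pairs <- utils::combn(sort(positions), 2L)
  rows <- list()
  for (q in c("light", "heavy", "par")) {
    for (j in seq_len(ncol(pairs))) {
      pc <- position_correlation(summaries, q, pairs[1L, j], pairs[2L, j],
                                 ...)
      rows[[length(rows) + 1L]] <-
        tibble(quantity = q, pos_a = pairs[1L, j], pos_b = pairs[2L, j],
               r = pc$r, n = pc$n)
    }
  }
  bind_rows(rows)
}
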