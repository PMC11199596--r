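# Response-curve fitting and empirical LLOQ/ULOQ determination.
#
# Curves titrate the heavy standard (2000 ... 0.205 fmol, plus blanks)
# against constant light peptide, in process triplicate. The peak-area
# ratio is taken heavy-over-light so it is proportional to the spiked
# amount. Figures of merit follow the empirical rules used for
# fit-for-purpose validation of immuno-MRM panels:
#   LLOQ  - lowest curve point with replicate CV < 20% whose log-log fit
#           over all points at or above it keeps linear correlation >= 0.98
#           (and, in the default strict mode, all higher points also pass
#           the CV rule);
#   ULOQ  - highest point still in the linear range; when the top designed
#           point is retained the ULOQ is only a minimum estimate.

#' The standard heavy-spike dilution series (fmol)
#' @export
curve_design_levels <- c(2000, 200, 20, 8, 3.2, 1.28, 0.512, 0.205)

#' Collapse curve measurements into per-concentration curve points
#'
#' @param measurements Measurement tibble (heavy-over-light orientation)
#'   for one peptide in one matrix, with a `spike_fmol` annotation giving
#'   the heavy amount (blanks: 0 or `NA`, excluded from points).
#' @return Tibble `spike_fmol`, `mean_par`, `cv_percent`, `n`, sorted by
#'   ascending concentration. The replicate CV is computed on the
#'   untransformed peak-area ratio.
#' @export
curve_points <- function(measurements) {
  pts <- measurements %>%
    filter(!is.na(.data$spike_fmol), .data$spike_fmol > 0) %>%
    group_by(.data$spike_fmol) %>%
    summarise(mean_par = mean(.data$par, na.rm = TRUE),
              cv_percent = cv_percent(.data$par),
              n = sum(!is.na(.data$par)), .groups = "drop") %>%
    arrange(.data$spike_fmol)
  pts$mean_par[!is.finite(pts$mean_par)] <- NA_real_
  pts
}

#' Log-log linear fit of a response curve
#'
#' Ordinary least squares of `log2(mean_par)` on `log2(spiked fmol)` over
#' the supplied points (by convention, all points at or above the LLOQ).
#'
#' @param fmol,par Numeric vectors of concentrations and mean peak-area
#'   ratios (positive; non-positive values are dropped).
#' @return List `slope`, `intercept`, `r_squared`, `pearson_r`, `n`; all
#'   `NA` (with a `reason`) when fewer than 3 distinct concentrations
#'   remain.
#' @export
fit_loglog <- function(fmol, par) {
  keep <- is.finite(fmol) & is.finite(par) & fmol > 0 & par > 0
  x <- log2(fmol[keep]); y <- log2(par[keep])
  if (length(unique(x)) < 3L) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, pearson_r = NA_real_,
                n = length(x), reason = "fewer than 3 distinct concentrations"))
  }
  # closed-form OLS (identical to lm(y ~ x), much cheaper in the LLOQ scan)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else NA_real_
  list(slope = slope, intercept = yb - slope * xb,
       r_squared = if (is.na(r)) NA_real_ else r^2, pearson_r = r,
       n = length(x), reason = NA_character_)
}

#' Determine the lower limit of quantification
#'
#' Scans candidates from the lowest concentration upward. A candidate is
#' accepted iff (i) its replicate CV is < `cv_max`, (ii) the log-log fit
#' over all points at or above it (at least 3) has linear correlation
#' >= `r_min`, and (iii) in strict mode every higher point also passes the
#' CV rule ("maintained" precision over the quantifiable region). The first
#' acceptable candidate is the LLOQ; if none qualifies the result is
#' missing.
#'
#' @param points Curve-point tibble from [curve_points()].
#' @param cv_max CV acceptance bound in percent (default 20).
#' @param r_min Minimum linear correlation (default 0.98).
#' @param use Which statistic the `r_min` rule applies to:
#'   `"pearson_r"` (default) or `"r_squared"`.
#' @param strict All higher points must also pass the CV rule
#'   (default `TRUE`); `FALSE` checks the candidate point only.
#' @return LLOQ in fmol, or `NA` if no point qualifies.
#' @export
determine_lloq <- function(points, cv_max = 20, r_min = 0.98,
                           use = c("pearson_r", "r_squared"),
                           strict = TRUE) {
  use <- match.arg(use)
  pts <- arrange(points, .data$spike_fmol)
  cv_ok <- !is.na(pts$cv_percent) & pts$cv_percent < cv_max
  for (i in seq_len(nrow(pts))) {
    if (!cv_ok[i]) next
    if (strict && !all(cv_ok[i:nrow(pts)])) next
    idx <- i:nrow(pts)
    if (length(idx) < 3L) next
    fit <- fit_loglog(pts$spike_fmol[idx], pts$mean_par[idx])
    stat <- fit[[use]]
    if (!is.na(stat) && stat >= r_min) return(pts$spike_fmol[i])
  }
  NA_real_
}

# studentized (internally) residuals of a simple log-log regression
.top_point_ok <- function(x, y, r2_min, resid_bound) {
  fit <- lm(y ~ x)
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  if (is.na(r2) || r2 < r2_min) return(FALSE)
  s <- sqrt(sum(res^2) / stats::df.residual(fit))
  if (s < 1e-10) return(TRUE)  # numerically exact fit
  h <- stats::hatvalues(fit)
  top <- which.max(x)
  rs <- res[top] / (s * sqrt(1 - h[top]))
  is.finite(rs) && abs(rs) <= resid_bound
}

#' Determine the upper limit of quantification
#'
#' Starting from all points in `[lloq, max]`, the top point is dropped
#' while the fit including it has `R^2 < r2_min` or the top point's
#' studentized residual exceeds `resid_bound` (saturation pulls the highest
#' point below the line). Returns the highest retained concentration;
#' `is_minimum_estimate` is `TRUE` when that equals the highest designed
#' concentration, i.e. the assay stayed linear over the whole tested range.
#'
#' @param points Curve-point tibble from [curve_points()].
#' @param lloq LLOQ in fmol (from [determine_lloq()]).
#' @param r2_min Minimum `R^2` for the linear range (default 0.98).
#' @param resid_bound Maximum absolute studentized residual of the top
#'   point (default 3).
#' @return List `uloq_fmol`, `is_minimum_estimate`.
#' @export
determine_uloq <- function(points, lloq, r2_min = 0.98, resid_bound = 3) {
  if (is.na(lloq)) {
    return(list(uloq_fmol = NA_real_, is_minimum_estimate = FALSE))
  }
  pts <- arrange(filter(points, .data$spike_fmol >= lloq,
                        is.finite(.data$mean_par), .data$mean_par > 0),
                 .data$spike_fmol)
  top_design <- max(points$spike_fmol)
  while (nrow(pts) >= 3L) {
    ok <- .top_point_ok(log2(pts$spike_fmol), log2(pts$mean_par),
                        r2_min, resid_bound)
    if (ok) {
      u <- max(pts$spike_fmol)
      return(list(uloq_fmol = u, is_minimum_estimate = u == top_design))
    }
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts)) {
    warning("fewer than 3 points in the linear range; ULOQ set to highest ",
            "remaining point", call. = FALSE)
    u <- max(pts$spike_fmol)
    return(list(uloq_fmol = u, is_minimum_estimate = u == top_design))
  }
  list(uloq_fmol = NA_real_, is_minimum_estimate = FALSE)
}

#' Linear dynamic range in orders of magnitude
#'
#' @param lloq,uloq Limits of quantification in fmol.
#' @return `log10(uloq / lloq)`, or `NA` when either limit is missing.
#' @export
dynamic_range <- function(lloq, uloq) {
  ifelse(is.na(lloq) | is.na(uloq) | lloq <= 0 | uloq <= 0, NA_real_,
         log10(uloq / lloq))
}

#' Fit response curves for every peptide x matrix
#'
#' Runs [curve_points()], [determine_lloq()], [fit_loglog()] (over the
#' points at or above the LLOQ), [determine_uloq()] and [dynamic_range()]
#' per peptide and matrix. Blanks (spike 0/NA) are never curve points; they
#' feed a reported limit-of-detection estimate (mean blank ratio + 3 sd,
#' converted to fmol with the low-end response), which is diagnostic only.
#'
#' @param measurements Curve-design measurement tibble in heavy-over-light
#'   orientation with `spike_fmol` and `matrix` annotations.
#' @param ... Rule parameters passed to [determine_lloq()] /
#'   [determine_uloq()].
#' @return Tibble, one row per peptide x matrix: `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `lloq_fmol`, `uloq_fmol`,
#'   `uloq_is_minimum_estimate`, `dynamic_range_log10`, `lod_fmol`,
#'   `quantifiable`.
#' @export
response_curves <- function(measurements, ...) {
  if (!"matrix" %in% names(measurements)) measurements$matrix <- "tissue"
  groups <- split(measurements,
                  list(measurements$peptide_id, measurements$matrix),
                  drop = TRUE, sep = "\r")
  rows <- lapply(groups, function(g) {
    pts <- curve_points(g)
    lloq <- determine_lloq(pts, ...)
    fit <- if (is.na(lloq)) {
      list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
           pearson_r = NA_real_)
    } else {
      sel <- pts[pts$spike_fmol >= lloq, ]
      fit_loglog(sel$spike_fmol, sel$mean_par)
    }
    ul <- determine_uloq(pts, lloq)
    blanks <- g$par[(is.na(g$spike_fmol) | g$spike_fmol == 0) & !is.na(g$par)]
    lod <- NA_real_
    if (length(blanks) >= 2L && nrow(pts) && !is.na(lloq)) {
      low <- pts[pts$spike_fmol == min(pts$spike_fmol), ]
      k <- low$mean_par / low$spike_fmol
      if (is.finite(k) && k > 0) {
        lod <- (mean(blanks) + 3 * sd(blanks)) / k
      }
    }
    tibble(peptide_id = g$peptide_id[1L], matrix = g$matrix[1L],
           slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared, pearson_r = fit$pearson_r,
           lloq_fmol = lloq, uloq_fmol = ul$uloq_fmol,
           uloq_is_minimum_estimate = ul$is_minimum_estimate,
           dynamic_range_log10 = dynamic_range(lloq, ul$uloq_fmol),
           lod_fmol = lod, quantifiable = !is.na(lloq))
  })
  arrange(bind_rows(rows), .data$peptide_id, .data$matrix)
}
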