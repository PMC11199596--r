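# Seeded generator of transition-level datasets emulating the standard
# fit-for-purpose validation designs: response curves, spiked and
# endogenous repeatability, stability, sequential multi-panel enrichment,
# and tissue/plasma cohorts. Ground truth is emitted alongside the data so
# parameter-recovery tests can compare pipeline estimates against the
# generating model.
#
# Error model per measurement: expected intensity = response_factor x
# amount; a lognormal process effect (log2 sd `sigma_process`) is shared by
# the light and heavy channel of a replicate (spiking the standard before
# digestion cancels process variation in the ratio); lognormal replicate
# (`sigma_intra`) and day (`sigma_inter`) effects act on the ratio; the
# summed intensity is split over transitions by fixed per-peptide fragment
# proportions with a small per-transition lognormal wobble
# (`sigma_transition`); each transition then receives additive Gaussian
# detector noise (`noise_floor`, truncated at zero) and a small positive
# background. Interfered transitions get a co-eluting contaminant (area
# plus retention-time offset) in the light channel only.

#' Simulation configuration with the standard validation-design defaults
#'
#' Defaults reproduce the replication structure of the characterization
#' designs exactly: an 8-level heavy dilution series (2000 ... 0.205 fmol)
#' in process triplicate with blanks; 3 spike levels x 3 replicates x
#' 5 days repeatability; 5 replicates x 8 days endogenous (n = 40);
#' stability in triplicate under two storage conditions; 3 panels x
#' 3 enrichment positions x triplicate; and cohorts of 77 tissue /
#' 48 plasma samples.
#'
#' @param panel_size Number of peptides (default 43).
#' @param n_transitions Transitions per peptide per label (default 3,
#'   minimum 2).
#' @param designs Which designs to emit.
#' @param matrices Matrices for curve/repeatability/endogenous/stability
#'   designs.
#' @param sigma_intra,sigma_inter Lognormal replicate and day standard
#'   deviations of the peak-area ratio, log2 domain.
#' @param sigma_process Lognormal process (digestion/enrichment) sd shared
#'   by both labels, log2 domain; cancels in the ratio.
#' @param sigma_transition Per-transition multiplicative wobble, log2
#'   domain.
#' @param noise_floor Named additive detector-noise sd (intensity counts)
#'   per matrix.
#' @param response_factor_meanlog,response_factor_sdlog Log-normal
#'   parameters of the per-peptide response factor (counts per fmol).
#' @param heavy_spike_fmol,light_spike_fmol Standard spike amounts.
#' @param curve_levels,curve_reps,n_blanks Response-curve design.
#' @param repeat_levels,repeat_reps,repeat_days Spiked repeatability design.
#' @param endog_reps,endog_days Endogenous repeatability design.
#' @param stability_effects Named multiplicative shifts of the stored-arm
#'   ratio (negative = loss), applied on top of a fresh triplicate.
#' @param stability_reps Replicates per stability arm.
#' @param seq_panels,seq_positions,seq_reps,seq_position_effect Sequential
#'   enrichment design; `seq_position_effect` is the per-position capture
#'   multiplier (1 = carryover-free).
#' @param cohort_tissue_n,cohort_tissue_sites,cohort_plasma_n,cohort_plasma_sites
#'   Cohort sizes and number of collection sites.
#' @param endog_tissue_meanlog2,endog_tissue_sdlog2 Between-peptide
#'   distribution of endogenous tissue amounts (fmol per 500 ug input),
#'   log2 domain.
#' @param endog_sample_sdlog2 Between-sample biological sd, log2 domain.
#' @param site_shift_sdlog2 Between-site shift sd, log2 domain.
#' @param plasma_detectable_rate Fraction of peptides with measurable
#'   endogenous plasma levels; the rest are present only at trace level.
#' @param endog_plasma_meanlog2,endog_plasma_sdlog2 Amount distribution of
#'   the detectable plasma peptides.
#' @param endog_cell_meanlog2,endog_cell_sdlog2 Endogenous amounts in the
#'   cell-line pool used for sequential enrichment.
#' @param interference_rate Fraction of peptide x fragment pairs carrying a
#'   co-eluting contaminant.
#' @param interference_rt_offset Retention-time shift of interfered
#'   transitions, minutes.
#' @param dropout_threshold Intensities below this are emitted as missing
#'   rows, not zeros.
#' @param background_range Uniform range of per-transition backgrounds.
#' @param rt_range Range of peptide retention times, minutes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    panel_size = 43L, n_transitions = 3L,
    designs = c("curve", "repeatability", "endogenous", "stability",
                "sequential", "cohort"),
    matrices = c("tissue", "plasma"),
    sigma_intra = 0.09, sigma_inter = 0.07, sigma_process = 0.15,
    sigma_transition = 0.02,
    noise_floor = c(tissue = 350, plasma = 175, cell = 250),
    response_factor_meanlog = log(1e4), response_factor_sdlog = 0.5,
    heavy_spike_fmol = 200, light_spike_fmol = 200,
    curve_levels = c(2000, 200, 20, 8, 3.2, 1.28, 0.512, 0.205),
    curve_reps = 3L, n_blanks = 3L,
    repeat_levels = c(low = 20, medium = 200, high = 2000),
    repeat_reps = 3L, repeat_days = 5L,
    endog_reps = 5L, endog_days = 8L,
    stability_effects = c(autosampler_24h = -0.025, freeze_thaw_x2 = -0.035),
    stability_reps = 3L,
    seq_panels = c("IO-1", "IO-2", "IO-3"), seq_positions = 3L,
    seq_reps = 3L, seq_position_effect = 1.0,
    cohort_tissue_n = 77L, cohort_tissue_sites = 11L,
    cohort_plasma_n = 48L, cohort_plasma_sites = 3L,
    endog_tissue_meanlog2 = log2(20), endog_tissue_sdlog2 = 1.5,
    endog_sample_sdlog2 = 1.2, site_shift_sdlog2 = 0.5,
    plasma_detectable_rate = 0.5,
    endog_plasma_meanlog2 = log2(3), endog_plasma_sdlog2 = 1.0,
    endog_cell_meanlog2 = log2(10), endog_cell_sdlog2 = 1.5,
    interference_rate = 0.02, interference_rt_offset = 0.5,
    dropout_threshold = 10, background_range = c(5, 15),
    rt_range = c(8, 35)) {
  cfg <- as.list(environment())
  stopifnot(cfg$panel_size >= 1L, cfg$n_transitions >= 2L,
            cfg$curve_reps >= 1L, cfg$repeat_reps >= 1L,
            cfg$endog_reps >= 1L,
            all(c(cfg$sigma_intra, cfg$sigma_inter, cfg$sigma_process,
                  cfg$sigma_transition) >= 0),
            all(cfg$noise_floor >= 0))
  if (any(c(cfg$curve_reps, cfg$repeat_reps, cfg$endog_reps,
            cfg$stability_reps, cfg$seq_reps) == 0L)) {
    stop("impossible design: zero replicates", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# per-peptide and per-fragment ground truth
.make_truth <- function(config) {
  p <- config$panel_size
  tags <- replicate(p, paste(sample(LETTERS, 4L, replace = TRUE),
                             collapse = ""))
  peptides <- tibble(
    peptide_id = sprintf("PEP%02d_%s", seq_len(p), tags),
    response_factor = rlnorm(p, config$response_factor_meanlog,
                             config$response_factor_sdlog),
    rt_base = runif(p, config$rt_range[1L], config$rt_range[2L]),
    endog_tissue_fmol = 2^rnorm(p, config$endog_tissue_meanlog2,
                                config$endog_tissue_sdlog2),
    endog_cell_fmol = 2^rnorm(p, config$endog_cell_meanlog2,
                              config$endog_cell_sdlog2))
  n_det <- round(config$plasma_detectable_rate * p)
  detectable <- sample(seq_len(p), n_det)
  plasma <- rep(0.01, p)
  plasma[detectable] <- 2^rnorm(n_det, config$endog_plasma_meanlog2,
                                config$endog_plasma_sdlog2)
  peptides$endog_plasma_fmol <- plasma
  nt <- config$n_transitions
  prop <- matrix(stats::rgamma(p * nt, shape = 5), nrow = p)
  prop <- prop / rowSums(prop)
  fragments <- tibble(
    peptide_id = rep(peptides$peptide_id, each = nt),
    fragment_name = rep(paste0("y", seq(4L, length.out = nt)), times = p),
    proportion = as.numeric(t(prop)))
  fragments$interfered <- runif(nrow(fragments)) < config$interference_rate
  list(peptides = peptides, fragments = fragments)
}

#' Predicted LLOQ of a simulated peptide from the generating model
#'
#' The replicate CV of the peak-area ratio at spike level `a` predicted by
#' the error model is
#' `sqrt(cv_mult^2 + cv_add(heavy)^2 + cv_add(light)^2)` where
#' `cv_mult = 100 * sqrt(exp((ln 2 * sigma_intra)^2) - 1)` is the
#' multiplicative (ratio) CV and
#' `cv_add = 100 * noise_floor * sqrt(n_transitions) / (response_factor *
#' amount)` is the additive-noise CV of a summed channel. The expected LLOQ
#' is the smallest designed level at which the predicted CV drops below
#' `cv_max`; it is the ground truth for LLOQ-recovery tests.
#'
#' @param truth Truth object from [simulate_panel()].
#' @param peptide_id Peptide to evaluate.
#' @param matrix Matrix whose noise floor applies.
#' @param cv_max CV bound in percent (default 20).
#' @return Expected LLOQ in fmol (`NA` if no designed level qualifies).
#' @export
expected_lloq <- function(truth, peptide_id, matrix = "tissue",
                          cv_max = 20) {
  config <- truth$config
  pep <- truth$peptides[truth$peptides$peptide_id == peptide_id, ]
  stopifnot(nrow(pep) == 1L)
  nf <- config$noise_floor[[matrix]]
  nt <- config$n_transitions
  rf <- pep$response_factor
  light_amt <- config$light_spike_fmol +
    switch(matrix, tissue = pep$endog_tissue_fmol,
           plasma = pep$endog_plasma_fmol, cell = pep$endog_cell_fmol, 0)
  cv_mult <- 100 * sqrt(exp((log(2) * config$sigma_intra)^2) - 1)
  levels <- sort(config$curve_levels)
  for (a in levels) {
    cv_add_h <- 100 * nf * sqrt(nt) / (rf * a)
    cv_add_l <- 100 * nf * sqrt(nt) / (rf * light_amt)
    cv <- sqrt(cv_mult^2 + cv_add_h^2 + cv_add_l^2)
    if (cv < cv_max) return(a)
  }
  NA_real_
}

# Emit transition rows for a measurement grid. The grid has one row per
# peptide x replicate with columns: peptide_id, replicate_id, design,
# matrix, day, spike_level, spike_fmol, condition, position, panel,
# sample_id, site, light_amount, heavy_amount, ratio_extra.
.emit_transitions <- function(grid, truth, config) {
  if (nrow(grid) == 0L) return(NULL)
  pep <- truth$peptides
  idx <- match(grid$peptide_id, pep$peptide_id)
  rf <- pep$response_factor[idx]
  n <- nrow(grid)
  process <- 2^rnorm(n, 0, config$sigma_process)
  rep_ratio <- 2^rnorm(n, 0, config$sigma_intra)
  day_key <- paste(grid$peptide_id, grid$design, grid$matrix, grid$day)
  has_day <- !is.na(grid$day)
  uk <- unique(day_key[has_day])
  day_eff <- setNames(2^rnorm(length(uk), 0, config$sigma_inter), uk)
  day_mult <- ifelse(has_day, day_eff[day_key], 1)
  light_total <- rf * grid$light_amount * process * rep_ratio * day_mult *
    grid$ratio_extra
  heavy_total <- rf * grid$heavy_amount * process
  rt_shift <- rnorm(n, 0, 0.02)

  frag <- truth$fragments
  nt <- config$n_transitions
  fidx <- rep(seq_len(n), each = nt)
  # fragments are stored in panel order, nt rows per peptide
  frows <- (match(grid$peptide_id[fidx], pep$peptide_id) - 1L) * nt +
    rep(seq_len(nt), times = n)
  prop <- frag$proportion[frows]
  interfered <- frag$interfered[frows]
  fragment_name <- frag$fragment_name[frows]
  rt_base <- pep$rt_base[match(grid$peptide_id[fidx], pep$peptide_id)]
  nf <- unname(config$noise_floor[grid$matrix[fidx]])
  nf[is.na(nf)] <- mean(config$noise_floor)

  make_label <- function(total, label) {
    nl <- length(fidx)
    base <- total[fidx] * prop * 2^rnorm(nl, 0, config$sigma_transition)
    area <- pmax(0, base + rnorm(nl, 0, nf))
    rt <- rt_base + rt_shift[fidx] + rnorm(nl, 0, 0.01)
    if (label == "light") {
      hit <- interfered
      if (any(hit)) {
        contaminant <- runif(sum(hit), 0.5, 1.5) *
          (total[fidx][hit] / nt)
        area[hit] <- area[hit] + contaminant
        rt[hit] <- rt[hit] + config$interference_rt_offset
      }
    }
    tibble(peptide_id = grid$peptide_id[fidx],
           label = label,
           replicate_id = grid$replicate_id[fidx],
           fragment_name = fragment_name,
           area = area,
           background = runif(nl, config$background_range[1L],
                              config$background_range[2L]),
           retention_time = rt,
           design = grid$design[fidx], matrix = grid$matrix[fidx],
           day = grid$day[fidx], spike_level = grid$spike_level[fidx],
           spike_fmol = grid$spike_fmol[fidx],
           condition = grid$condition[fidx],
           position = grid$position[fidx], panel = grid$panel[fidx],
           sample_id = grid$sample_id[fidx], site = grid$site[fidx],
           heavy_spike_fmol = grid$heavy_spike_fmol[fidx])
  }
  out <- bind_rows(make_label(light_total, "light"),
                   make_label(heavy_total, "heavy"))
  # dropout: sub-threshold intensities are missing rows, never zeros
  out[out$area >= config$dropout_threshold, ]
}

.grid_template <- function(n) {
  tibble(peptide_id = character(n), replicate_id = character(n),
         design = character(n), matrix = NA_character_, day = NA_real_,
         spike_level = NA_character_, spike_fmol = NA_real_,
         condition = NA_character_, position = NA_real_,
         panel = NA_character_, sample_id = NA_character_,
         site = NA_character_, light_amount = NA_real_,
         heavy_amount = NA_real_, heavy_spike_fmol = NA_real_,
         ratio_extra = 1)
}

.expand_grid_rows <- function(peptides, ...) {
  combos <- expand.grid(..., stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[rep(seq_len(nrow(combos)), each = length(peptides)), ,
                   drop = FALSE]
  combos$peptide_id <- rep(peptides, times = nrow(combos) / length(peptides))
  as_tibble(combos)
}

#' Simulate a full panel characterization dataset
#'
#' Generates transition-level records for the configured designs along with
#' the ground truth of the generating model. Deterministic under a fixed
#' seed; records are returned in a canonical sort order so emission order
#' carries no information.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `records` (transition tibble, same schema as
#'   [read_transition_report()] output) and `truth` (list: `peptides`,
#'   `fragments`, `cohort`, `config`, `seed`).
#' @export
simulate_panel <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  truth <- .make_truth(config)
  pep <- truth$peptides
  endog_of <- function(matrix) {
    switch(matrix, tissue = pep$endog_tissue_fmol,
           plasma = pep$endog_plasma_fmol, cell = pep$endog_cell_fmol)
  }
  grids <- list()

  if ("curve" %in% config$designs) {
    for (mx in config$matrices) {
      g <- .expand_grid_rows(pep$peptide_id,
                             level = c(config$curve_levels,
                                       if (config$n_blanks > 0L) 0),
                             rep = seq_len(max(config$curve_reps,
                                               config$n_blanks)))
      g <- g[(g$level > 0 & g$rep <= config$curve_reps) |
               (g$level == 0 & g$rep <= config$n_blanks), ]
      tmpl <- .grid_template(nrow(g))
      tmpl$peptide_id <- g$peptide_id
      tmpl$design <- "curve"
      tmpl$matrix <- mx
      tmpl$spike_fmol <- g$level
      tmpl$spike_level <- ifelse(g$level == 0, "blank",
                                 as.character(g$level))
      tmpl$replicate_id <- sprintf("curve_%s_L%s_r%d", mx,
                                   ifelse(g$level == 0, "blank",
                                          format(g$level, trim = TRUE)),
                                   g$rep)
      tmpl$light_amount <- config$light_spike_fmol +
        endog_of(mx)[match(g$peptide_id, pep$peptide_id)]
      tmpl$heavy_amount <- g$level
      tmpl$heavy_spike_fmol <- NA_real_
      grids[[length(grids) + 1L]] <- tmpl
    }
  }

  if ("repeatability" %in% config$designs) {
    for (mx in config$matrices) {
      g <- .expand_grid_rows(pep$peptide_id,
                             level = names(config$repeat_levels),
                             day = seq_len(config$repeat_days),
                             rep = seq_len(config$repeat_reps))
      tmpl <- .grid_template(nrow(g))
      tmpl$peptide_id <- g$peptide_id
      tmpl$design <- "repeatability"
      tmpl$matrix <- mx
      tmpl$day <- g$day
      tmpl$spike_level <- g$level
      tmpl$spike_fmol <- unname(config$repeat_levels[g$level])
      tmpl$replicate_id <- sprintf("rep_%s_%s_d%d_r%d", mx, g$level, g$day,
                                   g$rep)
      tmpl$light_amount <- config$light_spike_fmol +
        endog_of(mx)[match(g$peptide_id, pep$peptide_id)]
      tmpl$heavy_amount <- unname(config$repeat_levels[g$level])
      tmpl$heavy_spike_fmol <- unname(config$repeat_levels[g$level])
      grids[[length(grids) + 1L]] <- tmpl
    }
  }

  if ("endogenous" %in% config$designs) {
    for (mx in config$matrices) {
      g <- .expand_grid_rows(pep$peptide_id,
                             day = seq_len(config$endog_days),
                             rep = seq_len(config$endog_reps))
      tmpl <- .grid_template(nrow(g))
      tmpl$peptide_id <- g$peptide_id
      tmpl$design <- "endogenous"
      tmpl$matrix <- mx
      tmpl$day <- g$day
      tmpl$spike_level <- "endogenous"
      tmpl$replicate_id <- sprintf("endog_%s_d%d_r%d", mx, g$day, g$rep)
      tmpl$light_amount <- endog_of(mx)[match(g$peptide_id, pep$peptide_id)]
      tmpl$heavy_amount <- config$heavy_spike_fmol
      tmpl$heavy_spike_fmol <- config$heavy_spike_fmol
      grids[[length(grids) + 1L]] <- tmpl
    }
  }

  if ("stability" %in% config$designs) {
    conds <- c(fresh = 0, config$stability_effects)
    for (mx in config$matrices) {
      g <- .expand_grid_rows(pep$peptide_id, condition = names(conds),
                             rep = seq_len(config$stability_reps))
      tmpl <- .grid_template(nrow(g))
      tmpl$peptide_id <- g$peptide_id
      tmpl$design <- "stability"
      tmpl$matrix <- mx
      tmpl$condition <- g$condition
      tmpl$spike_level <- "medium"
      tmpl$spike_fmol <- unname(config$repeat_levels[["medium"]])
      tmpl$replicate_id <- sprintf("stab_%s_%s_r%d", mx, g$condition, g$rep)
      tmpl$light_amount <- config$light_spike_fmol +
        endog_of(mx)[match(g$peptide_id, pep$peptide_id)]
      tmpl$heavy_amount <- unname(config$repeat_levels[["medium"]])
      tmpl$heavy_spike_fmol <- unname(config$repeat_levels[["medium"]])
      tmpl$ratio_extra <- 1 + unname(conds[g$condition])
      grids[[length(grids) + 1L]] <- tmpl
    }
  }

  if ("sequential" %in% config$designs) {
    g <- .expand_grid_rows(pep$peptide_id, panel = config$seq_panels,
                           position = seq_len(config$seq_positions),
                           rep = seq_len(config$seq_reps))
    tmpl <- .grid_template(nrow(g))
    tmpl$peptide_id <- g$peptide_id
    tmpl$design <- "sequential"
    tmpl$matrix <- "cell"
    tmpl$panel <- g$panel
    tmpl$position <- g$position
    tmpl$replicate_id <- sprintf("seq_%s_p%d_r%d", g$panel, g$position,
                                 g$rep)
    eff <- config$seq_position_effect^(g$position - 1L)
    tmpl$light_amount <- pep$endog_cell_fmol[
      match(g$peptide_id, pep$peptide_id)] * eff
    tmpl$heavy_amount <- config$heavy_spike_fmol * eff
    tmpl$heavy_spike_fmol <- config$heavy_spike_fmol
    grids[[length(grids) + 1L]] <- tmpl
  }

  cohort_truth <- NULL
  if ("cohort" %in% config$designs) {
    cohorts <- list(
      tissue = list(n = config$cohort_tissue_n,
                    sites = config$cohort_tissue_sites),
      plasma = list(n = config$cohort_plasma_n,
                    sites = config$cohort_plasma_sites))
    ct <- list()
    for (mx in names(cohorts)) {
      cc <- cohorts[[mx]]
      site_of <- sort(rep_len(seq_len(cc$sites), cc$n))
      site_names <- sprintf("%s_site%02d", mx, site_of)
      sample_ids <- sprintf("%s_s%03d", mx, seq_len(cc$n))
      site_shift <- setNames(2^rnorm(cc$sites, 0, config$site_shift_sdlog2),
                             seq_len(cc$sites))
      base <- endog_of(mx)
      g <- .expand_grid_rows(pep$peptide_id, sample = seq_len(cc$n))
      pidx <- match(g$peptide_id, pep$peptide_id)
      amt <- base[pidx] * unname(site_shift[as.character(site_of[g$sample])]) *
        2^rnorm(nrow(g), 0, config$endog_sample_sdlog2)
      tmpl <- .grid_template(nrow(g))
      tmpl$peptide_id <- g$peptide_id
      tmpl$design <- "cohort"
      tmpl$matrix <- mx
      tmpl$sample_id <- sample_ids[g$sample]
      tmpl$site <- site_names[g$sample]
      tmpl$replicate_id <- sprintf("cohort_%s", sample_ids[g$sample])
      tmpl$light_amount <- amt
      tmpl$heavy_amount <- config$heavy_spike_fmol
      tmpl$heavy_spike_fmol <- config$heavy_spike_fmol
      grids[[length(grids) + 1L]] <- tmpl
      ct[[mx]] <- tibble(peptide_id = g$peptide_id, matrix = mx,
                         sample_id = sample_ids[g$sample],
                         site = site_names[g$sample],
                         true_amount_fmol = amt)
    }
    cohort_truth <- bind_rows(ct)
  }

  grid <- bind_rows(grids)
  records <- .emit_transitions(grid, truth, config)
  records <- arrange(records, .data$design, .data$matrix, .data$peptide_id,
                     .data$replicate_id, .data$label, .data$fragment_name)
  truth$cohort <- cohort_truth
  truth$config <- config
  truth$seed <- seed
  truth$peptides$expected_lloq_tissue <- vapply(
    truth$peptides$peptide_id, function(p) {
      expected_lloq(truth, p, "tissue")
    }, numeric(1))
  truth$peptides$expected_lloq_plasma <- vapply(
    truth$peptides$peptide_id, function(p) {
      expected_lloq(truth, p, "plasma")
    }, numeric(1))
  list(records = records, truth = truth)
}
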