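# Fixture builders used across test files. Everything is generated in code;
# no stored data.

# Hand-built transition rows for one or more peptide/replicate measurements.
make_records <- function(peptide_id = "PEP01_AAAA", replicate_id = "r1",
                         fragments = c("y4", "y5", "y6"),
                         light_areas = c(100, 200, 300),
                         heavy_areas = c(50, 100, 150),
                         light_bg = 0, heavy_bg = 0,
                         rt = 15, rt_heavy = rt, ...) {
  ann <- list(...)
  base <- tibble::tibble(
    peptide_id = peptide_id,
    replicate_id = replicate_id,
    fragment_name = rep(fragments, 2L),
    label = rep(c("light", "heavy"), each = length(fragments)),
    area = c(light_areas, heavy_areas),
    background = c(rep(light_bg, length.out = length(fragments)),
                   rep(heavy_bg, length.out = length(fragments))),
    retention_time = c(rep(rt, length.out = length(fragments)),
                       rep(rt_heavy, length.out = length(fragments))))
  for (nm in names(ann)) base[[nm]] <- ann[[nm]]
  base
}

# A small simulation configuration for fast end-to-end tests.
small_config <- function(...) {
  simulation_config(panel_size = 6L, cohort_tissue_n = 12L,
                    cohort_tissue_sites = 3L, cohort_plasma_n = 8L,
                    cohort_plasma_sites = 2L, ...)
}

# Exact zero-variance configuration: every replicate identical.
noiseless_config <- function(...) {
  simulation_config(sigma_intra = 0, sigma_inter = 0, sigma_process = 0,
                    sigma_transition = 0,
                    noise_floor = c(tissue = 0, plasma = 0, cell = 0),
                    interference_rate = 0, dropout_threshold = 0,
                    background_range = c(0, 0),
                    endog_sample_sdlog2 = 0, site_shift_sdlog2 = 0, ...)
}

# Ideal curve-point table: par = k * fmol with given replicate CVs.
make_curve_points <- function(cv = rep(5, 8), k = 0.005,
                              levels = sort(iomrm::curve_design_levels),
                              mean_par = k * levels) {
  tibble::tibble(spike_fmol = levels, mean_par = mean_par,
                 cv_percent = cv, n = 3L)
}
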