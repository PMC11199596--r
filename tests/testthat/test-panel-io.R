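# Panel definition / transition report readers and the characterization
# round trip.

write_panel_csv <- function(rows, path = withr::local_tempfile(
  fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(rows, path)
  path
}

test_that("panel reader derives ids, normalizes sequence, keeps extras", {
  path <- write_panel_csv(tibble::tibble(
    `Gene Symbol` = c("MUTYH", "CD8A"),
    `Target Peptide Sequence` = c("MGQQVLDNFFR", "AAEGLDTQR"),
    `Extended Peptide Sequence` = c("LSMGQQVLDNFFRSK", "DFAAEGLDTQRFS"),
    `Antibody ID` = c("Ab-1", "Ab-2"),
    Reference = c("x", "y")))
  pd <- read_panel_table(path, panel_name = "IO-3")
  expect_s3_class(pd, "panel_definition")
  expect_equal(pd$targets$peptide_id, c("MUTYH_MGQQ", "CD8A_AAEG"))
  expect_equal(pd$panel_name, "IO-3")
  expect_true("Reference" %in% names(pd$targets))
})

test_that("panel reader rejects duplicates and bad schemas, warns on
           non-tryptic termini", {
  dup <- write_panel_csv(tibble::tibble(
    gene_symbol = c("A", "A"), sequence = c("AAAGLDTQK", "AAAGLDTQR")))
  expect_error(read_panel_table(dup), "duplicate")
  nohdr <- write_panel_csv(tibble::tibble(gene_symbol = "A", foo = "SEQK"))
  expect_error(read_panel_table(nohdr), "sequence")
  nontryp <- write_panel_csv(tibble::tibble(
    gene_symbol = "B", sequence = "AAAGLDTQS"))
  expect_warning(read_panel_table(nontryp), "non-tryptic")
  bad_ext <- write_panel_csv(tibble::tibble(
    gene_symbol = "C", sequence = "AAAGLDTQK",
    extended_heavy_sequence = "WWWWWW"))
  expect_error(read_panel_table(bad_ext), "extended")
})

test_that("empty panel table yields zero targets with a log message", {
  path <- write_panel_csv(tibble::tibble(gene_symbol = character(),
                                         sequence = character()))
  expect_message(pd <- read_panel_table(path), "empty")
  expect_equal(nrow(pd$targets), 0L)
})

test_that("transition report parses both header dialects identically", {
  base <- make_records(matrix = "tissue", day = 1)
  a <- withr::local_tempfile(fileext = ".csv")
  b <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(base, a)
  renamed <- dplyr::rename(base, `Peptide Modified Sequence` = peptide_id,
                           `Isotope Label Type` = label,
                           `Replicate Name` = replicate_id,
                           `Fragment Ion` = fragment_name,
                           `Total Area` = area,
                           `Retention Time` = retention_time)
  readr::write_csv(renamed, b)
  ra <- read_transition_report(a)
  rb <- read_transition_report(b)
  expect_equal(nrow(ra), 6L)
  expect_equal(ra[order(ra$label, ra$fragment_name), names(rb)],
               rb[order(rb$label, rb$fragment_name), ])
})

test_that("transition report validation enumerates offending rows", {
  bad <- make_records()
  bad$area[2] <- -5
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_error(read_transition_report(path), "negative area")
  bad2 <- make_records()
  bad2$area <- as.character(bad2$area)
  bad2$area[3] <- "not-a-number"
  readr::write_csv(bad2, path)
  expect_error(read_transition_report(path), "unparseable area")
})

test_that("downstream results are invariant to row order and replicate
           renaming", {
  sim <- simulate_panel(small_config(designs = "repeatability",
                                     matrices = "tissue"), seed = 7)
  rec <- sim$records
  shuffled <- rec[sample(nrow(rec)), ]
  m1 <- summarize_measurements(rec)
  m2 <- summarize_measurements(shuffled)
  expect_equal(m1, m2)
  # renaming replicates permutes labels only
  renamed <- rec
  renamed$replicate_id <- paste0("x_", renamed$replicate_id)
  m3 <- summarize_measurements(renamed)
  expect_equal(sort(m1$par), sort(m3$par))
})

test_that("characterization table round-trips and refuses to clobber", {
  sim <- simulate_panel(small_config(designs = c("curve", "repeatability",
                                                 "endogenous", "stability"),
                                     matrices = "tissue"), seed = 3)
  res <- run_full_characterization(sim$records,
                                   stages = c("curves", "precision",
                                              "stability"))
  tab <- res$characterization
  expect_equal(nrow(tab), 6L)  # one row per peptide x matrix
  path <- withr::local_tempfile(fileext = ".csv")
  write_characterization_table(tab, path)
  expect_error(write_characterization_table(tab, path), "refusing")
  back <- read_characterization_table(path)
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  for (cc in num) {
    expect_equal(signif(back[[cc]], 6), signif(tab[[cc]], 6),
                 tolerance = 1e-6)
  }
})

test_that("a panel-scale run yields one characterization row per
           peptide and matrix", {
  sim <- simulate_panel(simulation_config(designs = "curve"), seed = 11)
  res <- run_full_characterization(sim$records, stages = "curves")
  expect_equal(nrow(res$characterization), 43L * 2L)
  expect_equal(dplyr::n_distinct(res$characterization$peptide_id), 43L)
})
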