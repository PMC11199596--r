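# Transition summation, interference screening, peak-area ratios, and
# LLOQ filtering.

test_that("total intensity is the sum of area + background", {
  expect_equal(total_intensity(c(100, 200), c(10, 20)), 330)
  expect_equal(total_intensity(50, 0), 50)
  expect_true(is.na(total_intensity(numeric())))
  # exclusion of a flagged transition = summing the remaining rows by hand
  areas <- c(100, 200, 300); bgs <- c(1, 2, 3)
  keep <- c(TRUE, FALSE, TRUE)
  expect_equal(total_intensity(areas[keep], bgs[keep]),
               sum((areas + bgs)[keep]))
})

test_that("peak-area ratio respects orientation and the inverse identity", {
  expect_equal(peak_area_ratio(1000, 500, "light_over_heavy"), 2.0)
  expect_equal(peak_area_ratio(1000, 500, "heavy_over_light"), 0.5)
  zero <- peak_area_ratio(1000, 0, "light_over_heavy")
  expect_true(is.na(zero))
  expect_equal(attr(zero, "reason"), "zero denominator")
  set.seed(1)
  for (i in 1:200) {
    l <- runif(1, 1, 1e6); h <- runif(1, 1, 1e6)
    p1 <- peak_area_ratio(l, h, "light_over_heavy")
    p2 <- peak_area_ratio(l, h, "heavy_over_light")
    expect_equal(p1 * p2, 1, tolerance = 1e-12)
  }
})

test_that("interference screen flags RT and proportion disagreement", {
  l <- tibble::tibble(fragment_name = c("y4", "y5", "y6"),
                      area = c(100, 200, 300),
                      retention_time = c(15, 15, 15))
  h <- l
  clean <- screen_interference(l, h)
  expect_true(all(clean$verdict == "clean"))
  expect_true(attr(clean, "quantifiable"))

  # one fragment with light proportion 0.70 vs heavy 0.30
  l2 <- tibble::tibble(fragment_name = c("y4", "y5"),
                       area = c(700, 300), retention_time = 15)
  h2 <- tibble::tibble(fragment_name = c("y4", "y5"),
                       area = c(300, 700), retention_time = 15)
  fl <- screen_interference(l2, h2)
  expect_equal(fl$proportion_delta, c(0.4, 0.4))
  expect_true(all(fl$verdict == "interfered"))
  expect_false(attr(fl, "quantifiable"))

  # all RT deltas above tolerance: unquantifiable
  h3 <- l
  h3$retention_time <- 15.5
  fl3 <- screen_interference(l, h3, rt_tolerance = 0.2)
  expect_true(all(fl3$verdict == "interfered"))
  expect_false(attr(fl3, "quantifiable"))
  expect_match(attr(fl3, "reason"), "fewer than 2 clean")

  none <- screen_interference(
    l, tibble::tibble(fragment_name = "b2", area = 10, retention_time = 15))
  expect_equal(attr(none, "reason"), "no shared fragments between labels")
})

test_that("interference screening is symmetric in label", {
  set.seed(42)
  for (i in 1:50) {
    nfrag <- sample(2:5, 1)
    l <- tibble::tibble(fragment_name = paste0("y", seq_len(nfrag)),
                        area = runif(nfrag, 10, 1000),
                        retention_time = 15 + rnorm(nfrag, 0, 0.2))
    h <- tibble::tibble(fragment_name = l$fragment_name,
                        area = runif(nfrag, 10, 1000),
                        retention_time = 15 + rnorm(nfrag, 0, 0.2))
    f1 <- screen_interference(l, h)
    f2 <- screen_interference(h, l)
    expect_equal(f1$verdict, f2$verdict)
  }
})

test_that("vectorized summarization equals the per-measurement reference", {
  sim <- simulate_panel(small_config(designs = "curve", matrices = "tissue",
                                     interference_rate = 0.15), seed = 5)
  rec <- sim$records
  m <- summarize_measurements(rec)
  # oracle: per-group screen_interference + total_intensity
  key <- paste(rec$peptide_id, rec$replicate_id)
  for (k in sample(unique(key), 25)) {
    g <- rec[key == k, ]
    l <- g[g$label == "light", ]
    h <- g[g$label == "heavy", ]
    fl <- screen_interference(l, h)
    clean <- fl$fragment_name[fl$verdict == "clean"]
    row <- m[paste(m$peptide_id, m$replicate_id) == k, ]
    expect_equal(row$n_used, length(clean))
    if (attr(fl, "quantifiable")) {
      li <- l[l$fragment_name %in% clean, ]
      hi <- h[h$fragment_name %in% clean, ]
      expect_equal(row$light_total, total_intensity(li$area, li$background))
      expect_equal(row$heavy_total, total_intensity(hi$area, hi$background))
      expect_equal(row$par, row$light_total / row$heavy_total)
    } else {
      expect_true(is.na(row$par))
    }
  }
})

test_that("LLOQ filter keeps strictly-above measurements and is monotone
           and idempotent", {
  meas <- tibble::tibble(peptide_id = "P1",
                         replicate_id = paste0("r", 1:3),
                         matrix = "tissue",
                         par = c(0.1, 0.3, 5.0) / 200,
                         par_orientation = "light_over_heavy",
                         heavy_spike_fmol = 200)
  lloq <- tibble::tibble(peptide_id = "P1", matrix = "tissue",
                         lloq_fmol = 0.205)
  kept <- filter_by_lloq(meas, lloq)
  expect_equal(sort(kept$amount_fmol), c(0.3, 5.0), tolerance = 1e-12)

  lloq0 <- lloq; lloq0$lloq_fmol <- 0
  expect_equal(nrow(filter_by_lloq(meas, lloq0)), 3L)

  hi <- lloq; hi$lloq_fmol <- 3.2
  kept_hi <- filter_by_lloq(meas, hi)
  expect_true(all(kept_hi$replicate_id %in% kept$replicate_id))

  twice <- filter_by_lloq(kept, lloq)
  expect_equal(nrow(twice), nrow(kept))
  expect_equal(sort(twice$amount_fmol), sort(kept$amount_fmol))

  # unknown peptide dropped with a warning
  meas2 <- meas; meas2$peptide_id <- "P2"
  expect_warning(out <- filter_by_lloq(dplyr::bind_rows(meas, meas2), lloq),
                 "absent from LLOQ table")
  expect_true(all(out$peptide_id == "P1"))
})

test_that("measurement totals match independent recomputation from raw
           rows", {
  sim <- simulate_panel(small_config(designs = "endogenous",
                                     matrices = "tissue",
                                     interference_rate = 0), seed = 9)
  rec <- sim$records
  m <- summarize_measurements(rec)
  agg <- dplyr::summarise(
    dplyr::group_by(rec, peptide_id, replicate_id, label),
    tot = sum(area + background), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = label, values_from = tot)
  j <- dplyr::inner_join(m, wide, by = c("peptide_id", "replicate_id"))
  ok <- j$quantifiable
  expect_gt(sum(ok), 0)
  expect_equal(j$light_total[ok], j$light[ok])
  expect_equal(j$heavy_total[ok], j$heavy[ok])
})
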