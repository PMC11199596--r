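# Tryptic digestion, the hydrophobicity index, and the selection rules.

test_that("tryptic digestion honors the KP/RP rule and sets termini flags", {
  d <- digest_tryptic("MAKRPSTKGLR", protein_id = "P1")
  expect_equal(d$sequence, c("MAK", "RPSTK", "GLR"))
  expect_equal(d$start, c(1L, 4L, 9L))
  expect_equal(d$end, c(3L, 8L, 11L))
  expect_equal(d$is_n_terminal_peptide, c(TRUE, FALSE, FALSE))
  expect_equal(d$is_c_terminal_peptide, c(FALSE, FALSE, TRUE))

  a <- digest_tryptic("AAAA")
  expect_equal(a$sequence, "AAAA")
  expect_true(a$is_c_terminal_peptide)

  expect_equal(nrow(digest_tryptic("")), 0L)
})

test_that("digestion is a partition of the protein", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    prot <- paste(sample(aas, sample(10:200, 1), replace = TRUE),
                  collapse = "")
    d <- digest_tryptic(prot)
    expect_equal(paste(d$sequence, collapse = ""), prot)
    expect_equal(d$start, c(1L, head(d$end, -1L) + 1L))
    expect_equal(d$end[nrow(d)], nchar(prot))
    # every internal peptide ends in K/R
    internal <- !d$is_c_terminal_peptide
    expect_true(all(grepl("[KR]$", d$sequence[internal])))
  }
})

test_that("ragged ends flag adjacent K/R in the cleavage context", {
  # peptide after the KK pair has a ragged N-side context; the peptide
  # ending before the second K of KK has a ragged C-side context
  d2 <- digest_tryptic("AAAKKGGGR")
  expect_equal(d2$sequence, c("AAAK", "K", "GGGR"))
  expect_true(d2$has_ragged_end[1])  # followed by K
  expect_true(d2$has_ragged_end[3])  # preceded-by-cleavage context has K
})

test_that("hydrophobicity index matches an independent recomputation from
           the packaged coefficient table", {
  path <- system.file("extdata", "hydrophobicity_coefficients_100A_tfa.csv",
                      package = "iomrm")
  tb <- read.csv(path)
  rc <- setNames(tb$coefficient, tb$residue)
  oracle <- function(s) {
    aa <- strsplit(s, "")[[1]]
    n <- length(aa)
    kl <- if (n < 10) 1 - 0.027 * (10 - n) else
      if (n > 20) 1 - 0.014 * (n - 20) else 1
    h <- kl * sum(rc[aa])
    if (h >= 38) h <- h - 0.3 * (h - 38)
    h
  }
  for (s in c("LLLLLLLL", "MGQQVLDNFFR", "GGGGG", "AAEGLDTQR",
              "WWWWWWWWWWWWWWWWWWWWWWWWW")) {
    expect_equal(ssrcalc_hydrophobicity(s), oracle(s), tolerance = 0.01)
  }
  expect_gt(ssrcalc_hydrophobicity("GGGGW"), ssrcalc_hydrophobicity("GGGGG"))
  expect_error(ssrcalc_hydrophobicity("AAZAA"), "Z")
})

make_flags <- function(protein, sequence, ...) {
  idx <- proteome_index(c(P1 = protein))
  d <- digest_tryptic(protein, protein_id = "P1")
  evaluate_candidate(d[d$sequence == sequence, ][1, ], idx, ...)
}

test_that("selection rules fire exactly as documented", {
  # MGQQVLDNFFR: tryptic, length 11, no NG/NP, not N-terminal Q ->
  # selectable with Met deprioritized
  prot <- paste0("AAAK", "MGQQVLDNFFR", "GGGK")
  fl <- make_flags(prot, "MGQQVLDNFFR")
  expect_true(fl$selectable)
  expect_match(fl$deprioritizations, "contains_M")
  expect_equal(fl$hard_exclusions, "")

  fl_ng <- make_flags(paste0("AAAK", "LNGTK", "GGGK"), "LNGTK")
  expect_match(fl_ng$hard_exclusions, "has_NG")
  fl_np <- make_flags(paste0("AAAK", "LTNPGK", "GGGK"), "LTNPGK")
  expect_match(fl_np$hard_exclusions, "has_NP")
  fl_q <- make_flags(paste0("AAAK", "QLDNFFK", "GGGK"), "QLDNFFK")
  expect_match(fl_q$hard_exclusions, "n_terminal_Q")
  fl_nt <- make_flags("MLDNFFKGGGK", "MLDNFFK")
  expect_match(fl_nt$hard_exclusions, "protein_n_terminal")
})

test_that("variant overlap excludes only above the 1% MAF threshold", {
  prot <- paste0("AAAK", "LDNFFVR", "GGGK")
  common <- tibble::tibble(protein_id = "P1", position = 6L,
                           minor_allele_frequency = 0.05)
  rare <- tibble::tibble(protein_id = "P1", position = 6L,
                         minor_allele_frequency = 0.005)
  expect_match(make_flags(prot, "LDNFFVR",
                          variants = common)$hard_exclusions,
               "common_variant")
  expect_false(grepl("common_variant",
                     make_flags(prot, "LDNFFVR",
                                variants = rare)$hard_exclusions))
  # variant outside the peptide span never excludes
  far <- tibble::tibble(protein_id = "P1", position = 14L,
                        minor_allele_frequency = 0.5)
  expect_false(grepl("common_variant",
                     make_flags(prot, "LDNFFVR",
                                variants = far)$hard_exclusions))
})

test_that("length and hydrophobicity windows are inclusive 5-30 / 10-40", {
  # length 4 out, 5 in
  fl4 <- make_flags(paste0("AAAK", "LDVR", "GGGK"), "LDVR")
  expect_match(fl4$hard_exclusions, "length_out_of_range")
  fl5 <- make_flags(paste0("AAAK", "LDVVR", "GGGK"), "LDVVR")
  expect_false(grepl("length_out_of_range", fl5$hard_exclusions))
  # very hydrophobic peptide exceeds the window
  hyd <- make_flags(paste0("AAAK", "LLLLLLLLLLWFK", "GGGK"), "LLLLLLLLLLWFK")
  expect_gt(hyd$hydrophobicity, 40)
  expect_match(hyd$hard_exclusions, "hydrophobicity_out_of_range")
  # very hydrophilic peptide falls below it
  phil <- make_flags(paste0("AAAK", "GSGSGSGSK", "GGGK"), "GSGSGSGSK")
  expect_lt(phil$hydrophobicity, 10)
  expect_match(phil$hard_exclusions, "hydrophobicity_out_of_range")
})

test_that("uniqueness is exact substring matching without I/L equivalence", {
  prots <- c(P1 = "AAAKLDNFFVRGGGK", P2 = "CCCCKLDNFFVRWWWK")
  idx <- proteome_index(prots)
  d <- digest_tryptic(prots[["P1"]], protein_id = "P1")
  shared <- evaluate_candidate(d[d$sequence == "LDNFFVR", ], idx)
  expect_match(shared$hard_exclusions, "not_unique")
  # I/L substitution does NOT collapse: LDNFFVR vs IDNFFVR are distinct
  prots2 <- c(P1 = "AAAKLDNFFVRGGGK", P2 = "CCCCKIDNFFVRWWWK")
  idx2 <- proteome_index(prots2)
  uniq <- evaluate_candidate(d[d$sequence == "LDNFFVR", ], idx2)
  expect_false(grepl("not_unique", uniq$hard_exclusions))
})

test_that("ranking follows count, intensity, deprioritization, sequence", {
  flags <- tibble::tibble(
    protein_id = "P1",
    sequence = c("AAAGLDTQK", "CCDGLDTQK", "EEFGLDTQK", "BBBGLDTQK"),
    n_deprioritizations = c(0L, 1L, 0L, 0L),
    selectable = TRUE)
  ev <- tibble::tibble(sequence = c("AAAGLDTQK", "CCDGLDTQK", "EEFGLDTQK"),
                       observation_count = c(5L, 30L, 30L),
                       median_intensity = c(1e6, 1e5, 1e5))
  rk <- rank_candidates(flags, ev)
  # equal count/intensity: fewer deprioritizations first; missing evidence
  # ranks last; count dominates intensity
  expect_equal(rk$sequence, c("EEFGLDTQK", "CCDGLDTQK", "AAAGLDTQK",
                              "BBBGLDTQK"))
})

test_that("select_peptides agrees with a brute-force sort oracle and never
           selects a rule violator", {
  set.seed(99)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prots <- setNames(
    vapply(1:3, function(i) paste(sample(aas, 120, replace = TRUE),
                                  collapse = ""), character(1)),
    paste0("P", 1:3))
  digests <- unlist(lapply(prots, function(p) digest_tryptic(p)$sequence))
  ev <- tibble::tibble(sequence = sample(unique(digests)),
                       observation_count = sample(0:50,
                                                  length(unique(digests)),
                                                  replace = TRUE),
                       median_intensity = runif(length(unique(digests)),
                                                1e3, 1e7))
  ranked <- select_peptides(prots, evidence = ev)
  expect_true(all(ranked$selectable))
  expect_true(all(nchar(ranked$sequence) >= 5 &
                    nchar(ranked$sequence) <= 30))
  expect_true(all(ranked$hydrophobicity >= 10 & ranked$hydrophobicity <= 40))
  expect_false(any(grepl("NG", ranked$sequence, fixed = TRUE)))
  expect_false(any(grepl("NP", ranked$sequence, fixed = TRUE)))
  expect_false(any(startsWith(ranked$sequence, "Q")))
  expect_false(any(ranked$is_n_terminal_peptide))
  # brute-force ordering oracle within each protein
  for (pid in names(prots)) {
    sub <- ranked[ranked$protein_id == pid, ]
    ord <- order(-sub$observation_count, -sub$median_intensity,
                 sub$n_deprioritizations, sub$sequence)
    expect_equal(sub$sequence[ord], sub$sequence)
  }
})
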