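# Rule-based proteotypic-peptide candidate generation: in silico tryptic
# digestion, an additive hydrophobicity index for retention-window
# filtering, hard exclusion / deprioritization rules, and deterministic
# ranking by empirical MS observation evidence.

.kr <- c("K", "R")

#' In silico fully tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is proline
#' (internal KP/RP sites are left intact), with zero missed cleavages. The
#' returned peptides tile the protein exactly: concatenating them in order
#' reconstructs the input.
#'
#' A "ragged end" is flagged when the residue adjacent to a cleavage context
#' is itself K/R: the residue immediately preceding the peptide's preceding
#' cleavage site, or the residue immediately following the peptide's
#' C-terminus.
#'
#' @param protein_sequence Single amino-acid string (uppercase; `X`
#'   tolerated but flagged in downstream evaluation).
#' @param protein_id Optional identifier copied onto each row.
#' @return Tibble with `protein_id`, `sequence`, `start`, `end` (1-based,
#'   inclusive), `is_n_terminal_peptide`, `is_c_terminal_peptide`,
#'   `has_ragged_end`.
#' @export
#' @examples
#' digest_tryptic("MAKRPSTKGLR")$sequence  # "MAK" "RPSTK" "GLR"
digest_tryptic <- function(protein_sequence, protein_id = NA_character_) {
  s <- toupper(protein_sequence)
  n <- nchar(s)
  empty <- tibble(protein_id = character(), sequence = character(),
                  start = integer(), end = integer(),
                  is_n_terminal_peptide = logical(),
                  is_c_terminal_peptide = logical(),
                  has_ragged_end = logical())
  if (n == 0L) return(empty)
  aa <- strsplit(s, "", fixed = TRUE)[[1L]]
  # cut after position i when aa[i] is K/R and aa[i+1] is not P
  cut_after <- which(aa %in% .kr & c(aa[-1L], "") != "P" &
                       seq_len(n) < n)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  ragged <- vapply(seq_along(starts), function(i) {
    st <- starts[i]; en <- ends[i]
    before <- st >= 3L && aa[st - 2L] %in% .kr
    after <- en < n && aa[en + 1L] %in% .kr
    before || after
  }, logical(1))
  tibble(protein_id = protein_id,
         sequence = substring(s, starts, ends),
         start = starts, end = ends,
         is_n_terminal_peptide = starts == 1L,
         is_c_terminal_peptide = ends == n,
         has_ragged_end = ragged)
}

.hydro_env <- new.env(parent = emptyenv())

#' Residue coefficients of the packaged hydrophobicity scale
#'
#' The packaged scale is the published 100-Angstrom-pore, TFA ion-pairing
#' additive retention-coefficient set used by sequence-specific retention
#' calculators for reversed-phase chromatography; see
#' `inst/extdata/hydrophobicity_coefficients_100A_tfa.csv`.
#'
#' @return Named numeric vector, one coefficient per standard residue.
#' @export
hydrophobicity_coefficients <- function() {
  if (is.null(.hydro_env$coef)) {
    path <- system.file("extdata", "hydrophobicity_coefficients_100A_tfa.csv",
                        package = "iomrm", mustWork = TRUE)
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
    .hydro_env$coef <- setNames(tb$coefficient, tb$residue)
  }
  .hydro_env$coef
}

#' Peptide hydrophobicity index
#'
#' Additive retention-coefficient model with the published length
#' correction: `H = KL * sum(Rc)`, where `KL = 1 - 0.027 * (10 - N)` for
#' peptides shorter than 10 residues, `1 - 0.014 * (N - 20)` for longer
#' than 20, and 1 otherwise; strongly hydrophobic peptides are damped by
#' `H - 0.3 * (H - 38)` when `H >= 38`. The index is dimensionless and the
#' selection window 10-40 used for panel design is applied on this scale.
#'
#' @param sequence Character vector of peptide sequences (standard residues
#'   only; a nonstandard residue is an error naming the residue).
#' @return Numeric vector of hydrophobicity indices.
#' @export
#' @examples
#' ssrcalc_hydrophobicity("MGQQVLDNFFR")
ssrcalc_hydrophobicity <- function(sequence) {
  rc <- hydrophobicity_coefficients()
  vapply(toupper(sequence), function(s) {
    if (is.na(s) || nchar(s) < 1L) stop("empty sequence", call. = FALSE)
    aa <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(aa), names(rc))
    if (length(bad)) {
      stop("nonstandard residue(s) in '", s, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    n <- length(aa)
    kl <- if (n < 10L) 1 - 0.027 * (10 - n)
          else if (n > 20L) 1 - 0.014 * (n - 20)
          else 1
    h <- kl * sum(rc[aa])
    if (h >= 38) h <- h - 0.3 * (h - 38)
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build an exact-substring proteome index
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein ids).
#' @return Object usable as `proteome_index` in [evaluate_candidate()].
#' @export
proteome_index <- function(proteins) {
  stopifnot(!is.null(names(proteins)), all(nzchar(names(proteins))))
  structure(list(proteins = toupper(proteins)), class = "proteome_index")
}

#' Read a proteome FASTA into a named character vector
#'
#' @param path FASTA file of protein sequences.
#' @return Named character vector suitable for [proteome_index()].
#' @export
read_proteome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_proteome_fasta() requires the Biostrings package",
         call. = FALSE)
  }
  aas <- Biostrings::readAAStringSet(path)
  out <- as.character(aas)
  names(out) <- sub("\\s.*$", "", names(aas))
  out
}

.hard_rules <- c("not_unique", "has_NG", "has_NP", "n_terminal_Q",
                 "protein_n_terminal", "length_out_of_range",
                 "hydrophobicity_out_of_range", "common_variant",
                 "frequent_ptm", "nonstandard_residue")
.soft_rules <- c("contains_C", "contains_M", "ragged_end",
                 "protein_c_terminal")

#' Evaluate one digestion peptide against the panel selection rules
#'
#' Hard exclusions (any one disqualifies): not unique to its protein by
#' exact substring match (Ile/Leu equivalence deliberately not applied),
#' deamidation-prone NG or NP motifs, N-terminal Gln (pyroglutamate
#' formation), protein N-terminal peptide, length outside 5-30,
#' hydrophobicity outside 10-40, overlap with a sequence variant at minor
#' allele frequency above 1%, or overlap with a frequently observed PTM
#' site. Deprioritizations (penalties in ranking only): Cys, Met
#' (oxidation), ragged cleavage ends, protein C-terminal peptide.
#'
#' @param peptide One-row tibble from [digest_tryptic()].
#' @param proteome_index From [proteome_index()]; used for the uniqueness
#'   test.
#' @param variants Optional tibble `protein_id`, `position` (1-based residue
#'   index), `minor_allele_frequency`.
#' @param ptm_annotations Optional tibble `protein_id`, `position`,
#'   `frequency`.
#' @param maf_threshold Variant exclusion threshold (default 0.01).
#' @param ptm_frequency_threshold Minimum annotated frequency that excludes
#'   (default 0: any annotated site excludes).
#' @param length_range,hydrophobicity_range Inclusive selection windows.
#' @return One-row tibble: peptide fields plus `hydrophobicity`,
#'   `hard_exclusions`, `deprioritizations` (comma-separated),
#'   `n_deprioritizations`, `selectable`.
#' @export
evaluate_candidate <- function(peptide, proteome_index, variants = NULL,
                               ptm_annotations = NULL, maf_threshold = 0.01,
                               ptm_frequency_threshold = 0,
                               length_range = c(5L, 30L),
                               hydrophobicity_range = c(10, 40)) {
  stopifnot(inherits(proteome_index, "proteome_index"), nrow(peptide) == 1L)
  seqp <- peptide$sequence
  hard <- character()
  soft <- character()

  nonstd <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqp)
  if (nonstd) hard <- c(hard, "nonstandard_residue")

  # uniqueness: exact substring occurrences across the whole proteome
  hits <- vapply(proteome_index$proteins, function(p) {
    g <- gregexpr(seqp, p, fixed = TRUE)[[1L]]
    if (g[1L] == -1L) 0L else length(g)
  }, integer(1))
  n_occurrences <- sum(hits)
  other <- sum(hits[names(hits) != peptide$protein_id])
  if (n_occurrences > 1L || other > 0L) hard <- c(hard, "not_unique")

  if (grepl("NG", seqp, fixed = TRUE)) hard <- c(hard, "has_NG")
  if (grepl("NP", seqp, fixed = TRUE)) hard <- c(hard, "has_NP")
  if (startsWith(seqp, "Q")) hard <- c(hard, "n_terminal_Q")
  if (isTRUE(peptide$is_n_terminal_peptide)) {
    hard <- c(hard, "protein_n_terminal")
  }
  len <- nchar(seqp)
  if (len < length_range[1L] || len > length_range[2L]) {
    hard <- c(hard, "length_out_of_range")
  }
  hydro <- if (nonstd) NA_real_ else ssrcalc_hydrophobicity(seqp)
  if (!is.na(hydro) &&
      (hydro < hydrophobicity_range[1L] || hydro > hydrophobicity_range[2L])) {
    hard <- c(hard, "hydrophobicity_out_of_range")
  }
  if (!is.null(variants) && nrow(variants)) {
    hit <- variants$protein_id == peptide$protein_id &
      variants$position >= peptide$start & variants$position <= peptide$end &
      variants$minor_allele_frequency > maf_threshold
    if (any(hit, na.rm = TRUE)) hard <- c(hard, "common_variant")
  }
  if (!is.null(ptm_annotations) && nrow(ptm_annotations)) {
    freq <- if ("frequency" %in% names(ptm_annotations)) {
      ptm_annotations$frequency
    } else rep(1, nrow(ptm_annotations))
    hit <- ptm_annotations$protein_id == peptide$protein_id &
      ptm_annotations$position >= peptide$start &
      ptm_annotations$position <= peptide$end &
      freq >= ptm_frequency_threshold
    if (any(hit, na.rm = TRUE)) hard <- c(hard, "frequent_ptm")
  }
  if (grepl("C", seqp, fixed = TRUE)) soft <- c(soft, "contains_C")
  if (grepl("M", seqp, fixed = TRUE)) soft <- c(soft, "contains_M")
  if (isTRUE(peptide$has_ragged_end)) soft <- c(soft, "ragged_end")
  if (isTRUE(peptide$is_c_terminal_peptide)) {
    soft <- c(soft, "protein_c_terminal")
  }
  out <- peptide
  out$hydrophobicity <- hydro
  out$hard_exclusions <- paste(hard, collapse = ",")
  out$deprioritizations <- paste(soft, collapse = ",")
  out$n_deprioritizations <- length(soft)
  out$selectable <- length(hard) == 0L
  out
}

#' Rank selectable candidates by empirical MS evidence
#'
#' Ordering: observation count (descending), then median observed intensity
#' (descending), then number of deprioritizations (ascending), then
#' sequence (alphabetical) as the final deterministic tiebreak. Candidates
#' without evidence count as zero observations. Excluded candidates are
#' dropped from the ranking but retained, with reasons, in the
#' `"excluded"` attribute.
#'
#' @param flags Tibble of evaluated candidates from [evaluate_candidate()].
#' @param evidence Optional tibble `sequence`, `observation_count`,
#'   `median_intensity`.
#' @return Ranked tibble of selectable candidates with a `rank` column.
#' @export
rank_candidates <- function(flags, evidence = NULL) {
  if (is.null(evidence)) {
    evidence <- tibble(sequence = character(), observation_count = integer(),
                       median_intensity = numeric())
  }
  joined <- left_join(flags, evidence, by = "sequence")
  joined$observation_count[is.na(joined$observation_count)] <- 0L
  joined$median_intensity[is.na(joined$median_intensity)] <- 0
  kept <- joined[joined$selectable, , drop = FALSE]
  excluded <- joined[!joined$selectable, , drop = FALSE]
  ord <- order(-kept$observation_count, -kept$median_intensity,
               kept$n_deprioritizations, kept$sequence)
  kept <- kept[ord, , drop = FALSE]
  kept$rank <- seq_len(nrow(kept))
  attr(kept, "excluded") <- excluded
  kept
}

#' Digest, evaluate and rank proteotypic candidates for a set of proteins
#'
#' Convenience wrapper running [digest_tryptic()], [evaluate_candidate()]
#' and [rank_candidates()] over every protein.
#'
#' @param proteins Named character vector of protein sequences.
#' @param variants,ptm_annotations,evidence See [evaluate_candidate()] and
#'   [rank_candidates()].
#' @param ... Passed to [evaluate_candidate()].
#' @return Tibble of ranked candidates across proteins (rank within each
#'   protein), with the full flag ledger of excluded candidates in the
#'   `"excluded"` attribute.
#' @export
select_peptides <- function(proteins, variants = NULL,
                            ptm_annotations = NULL, evidence = NULL, ...) {
  idx <- proteome_index(proteins)
  all_flags <- bind_rows(lapply(names(proteins), function(id) {
    dig <- digest_tryptic(proteins[[id]], protein_id = id)
    bind_rows(lapply(seq_len(nrow(dig)), function(i) {
      evaluate_candidate(dig[i, ], idx, variants = variants,
                         ptm_annotations = ptm_annotations, ...)
    }))
  }))
  if (nrow(all_flags) == 0L) return(all_flags)
  ranked <- bind_rows(lapply(split(all_flags, all_flags$protein_id),
                             rank_candidates, evidence = evidence))
  attr(ranked, "excluded") <- all_flags[!all_flags$selectable, , drop = FALSE]
  ranked
}
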