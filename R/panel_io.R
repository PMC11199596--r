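# Readers and writers for panel definitions, MRM parameter tables,
# transition-level reports, and characterization output tables.
#
# Header aliasing: exported Skyline reports and hand-curated reagent tables
# disagree on column names, so every reader resolves columns through an
# explicit case-insensitive alias map and keeps unrecognized columns as
# pass-through annotations.

.panel_aliases <- list(
  gene_symbol   = c("gene symbol", "gene", "gene_symbol", "protein"),
  peptide_id    = c("peptide id", "peptide_id", "analyte", "assay id"),
  sequence      = c("target peptide sequence", "peptide sequence", "sequence",
                    "peptide"),
  extended_heavy_sequence = c("extended peptide sequence",
                              "extended heavy sequence",
                              "extended_heavy_sequence", "extended sequence",
                              "heavy standard sequence"),
  modification  = c("modification", "ptm", "modified residue"),
  antibody_id   = c("antibody id", "antibody", "antibody_id", "mab id"),
  assay_portal_id    = c("assay portal id", "assay_portal_id", "assay portal"),
  antibody_portal_id = c("antibody portal id", "antibody_portal_id",
                         "antibody portal")
)

.mrm_aliases <- list(
  peptide_id       = c("peptide id", "peptide_id", "peptide", "analyte"),
  precursor_mz     = c("precursor m/z", "precursor mz", "precursor_mz", "q1"),
  precursor_charge = c("precursor charge", "precursor_charge", "precursor z"),
  fragment_name    = c("fragment", "fragment ion", "fragment_name",
                       "product ion"),
  fragment_mz      = c("fragment m/z", "product m/z", "fragment_mz", "q3"),
  fragment_charge  = c("fragment charge", "product charge", "fragment_charge"),
  collision_energy = c("collision energy", "collision_energy", "ce"),
  label            = c("isotope label type", "isotope label", "label")
)

.report_aliases <- list(
  peptide_id     = c("peptide id", "peptide_id", "peptide",
                     "peptide modified sequence"),
  label          = c("isotope label type", "isotope label", "label"),
  replicate_id   = c("replicate name", "replicate", "replicate_id"),
  fragment_name  = c("fragment ion", "fragment", "fragment_name", "transition"),
  area           = c("area", "total area"),
  background     = c("background", "total background"),
  retention_time = c("retention time", "best retention time", "rt",
                     "retention_time")
)

.map_columns <- function(tbl, aliases, mandatory, what) {
  found <- vapply(aliases, function(a) .resolve_alias(names(tbl), a),
                  character(1))
  missing <- intersect(mandatory, names(found)[is.na(found)])
  if (length(missing)) {
    stop("schema error in ", what, ": missing mandatory column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble(.rows = nrow(tbl))
  for (nm in names(found)) {
    out[[nm]] <- if (is.na(found[[nm]])) NA_character_ else tbl[[found[[nm]]]]
  }
  extra <- setdiff(names(tbl), stats::na.omit(unname(found)))
  list(table = out, extra = tbl[extra])
}

#' Derive a panel peptide identifier from gene symbol and sequence
#'
#' Panel analytes are conventionally labelled `GENE_XXXX`, the gene symbol
#' joined to the first four residues of the target peptide
#' (e.g. `MUTYH_MGQQ` for MGQQVLDNFFR).
#'
#' @param gene_symbol Character vector of gene symbols.
#' @param sequence Character vector of peptide sequences.
#' @return Character vector of identifiers.
#' @export
peptide_id_from <- function(gene_symbol, sequence) {
  paste0(gene_symbol, "_", substr(toupper(sequence), 1L, 4L))
}

#' Read a panel definition table
#'
#' Reads a target/reagent table (CSV or XLSX) with one row per target
#' peptide: gene symbol, peptide sequence, the extended sequence used for the
#' cleavable heavy standard, optional modification, and reagent identifiers.
#' Peptide identifiers are taken from the table when present, otherwise
#' derived with [peptide_id_from()].
#'
#' Validation: duplicate peptide identifiers are rejected; sequences must use
#' the 20-letter amino-acid alphabet; a non-tryptic C-terminus (not K/R) is a
#' logged warning, not an error, because modified targets are allowed; the
#' extended heavy sequence must contain the target sequence as a contiguous
#' substring.
#'
#' @param path Path to a CSV or XLSX file.
#' @param panel_name Name to attach to the panel (default `"custom"`).
#' @param sheet Optional sheet name for workbooks.
#' @return A `panel_definition`: list with `targets` (tibble), `transitions`
#'   (tibble or `NULL` until [read_mrm_table()] output is attached), and
#'   `panel_name`.
#' @export
read_panel_table <- function(path, panel_name = "custom", sheet = NULL) {
  raw <- .read_table_any(path, sheet = sheet)
  if (nrow(raw) == 0L) {
    .log_msg("panel table '", basename(path), "' is empty")
    targets <- tibble(gene_symbol = character(), peptide_id = character(),
                      sequence = character(),
                      modification = character(),
                      extended_heavy_sequence = character(),
                      antibody_id = character(), assay_portal_id = character(),
                      antibody_portal_id = character())
    return(new_panel_definition(targets, NULL, panel_name))
  }
  mapped <- .map_columns(raw, .panel_aliases,
                         mandatory = c("gene_symbol", "sequence"),
                         what = "panel table")
  tb <- mapped$table
  tb$sequence <- toupper(trimws(tb$sequence))
  bad_alpha <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", tb$sequence)
  if (any(bad_alpha)) {
    stop("panel table: non-standard residues in sequence row(s) ",
         paste(which(bad_alpha), collapse = ", "), call. = FALSE)
  }
  no_id <- is.na(tb$peptide_id)
  tb$peptide_id[no_id] <- peptide_id_from(tb$gene_symbol[no_id],
                                          tb$sequence[no_id])
  if (anyDuplicated(tb$peptide_id)) {
    stop("panel table: duplicate peptide_id(s): ",
         paste(unique(tb$peptide_id[duplicated(tb$peptide_id)]),
               collapse = ", "), call. = FALSE)
  }
  nontryptic <- !grepl("[KR]$", tb$sequence)
  if (any(nontryptic)) {
    warning("panel table: non-tryptic C-terminus for ",
            paste(tb$peptide_id[nontryptic], collapse = ", "),
            " (allowed, flagged)", call. = FALSE)
  }
  ext <- toupper(trimws(tb$extended_heavy_sequence))
  has_ext <- !is.na(ext)
  not_sub <- has_ext & !mapply(grepl, tb$sequence, ext, fixed = TRUE)
  if (any(not_sub)) {
    stop("panel table: extended heavy sequence does not contain the target ",
         "sequence for ", paste(tb$peptide_id[not_sub], collapse = ", "),
         call. = FALSE)
  }
  tb$extended_heavy_sequence <- ext
  if (ncol(mapped$extra)) tb <- dplyr::bind_cols(tb, mapped$extra)
  new_panel_definition(tb, NULL, panel_name)
}

#' Construct a validated panel definition
#'
#' @param targets Tibble of panel targets (one row per peptide).
#' @param transitions Optional tibble of MRM transitions; every transition's
#'   `peptide_id` must appear among the targets.
#' @param panel_name Panel label, e.g. `"IO-3"`.
#' @return An object of class `panel_definition`.
#' @export
new_panel_definition <- function(targets, transitions = NULL,
                                 panel_name = "custom") {
  if (!is.null(transitions)) {
    orphan <- setdiff(unique(transitions$peptide_id), targets$peptide_id)
    if (length(orphan)) {
      stop("transitions reference peptide_id(s) absent from targets: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(targets = as_tibble(targets),
                 transitions = if (is.null(transitions)) NULL
                               else as_tibble(transitions),
                 panel_name = panel_name),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition> ", x$panel_name, ": ", nrow(x$targets),
      " target peptide(s), ",
      if (is.null(x$transitions)) 0L else nrow(x$transitions),
      " transition(s)\n", sep = "")
  invisible(x)
}

#' Read an MRM parameter table
#'
#' One row per monitored transition: precursor m/z and charge, fragment name,
#' m/z and charge, collision energy, and isotope label. At least two
#' transitions per peptide per label are required for a quantifiable assay;
#' peptides falling short are reported with a warning.
#'
#' @inheritParams read_panel_table
#' @return Tibble of typed transitions.
#' @export
read_mrm_table <- function(path, sheet = NULL) {
  raw <- .read_table_any(path, sheet = sheet)
  mapped <- .map_columns(raw, .mrm_aliases,
                         mandatory = c("peptide_id", "precursor_mz",
                                       "fragment_name", "fragment_mz",
                                       "label"),
                         what = "MRM parameter table")
  tb <- mapped$table
  for (col in c("precursor_mz", "fragment_mz", "collision_energy")) {
    tb[[col]] <- .parse_numeric(tb[[col]])
  }
  for (col in c("precursor_charge", "fragment_charge")) {
    tb[[col]] <- as.integer(.parse_numeric(tb[[col]]))
  }
  tb$label <- .normalize_label(tb$label)
  bad <- which(tb$precursor_mz <= 0 | tb$fragment_mz <= 0)
  if (length(bad)) {
    stop("MRM parameter table: non-positive m/z in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::count(tb, .data$peptide_id, .data$label)
  short <- counts$peptide_id[counts$n < 2L]
  if (length(short)) {
    warning("fewer than 2 transitions per label for: ",
            paste(unique(short), collapse = ", "), call. = FALSE)
  }
  tb
}

.normalize_label <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[out %in% c("light", "l", "endogenous", "analyte")] <- "light"
  out[out %in% c("heavy", "h", "standard", "internal standard")] <- "heavy"
  bad <- which(!out %in% c("light", "heavy") & !is.na(out))
  if (length(bad)) {
    stop("unmappable isotope label value(s) in row(s) ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  out
}

# Annotation columns recognized in transition reports and carried, typed,
# onto downstream measurement tables.
.annotation_numeric <- c("day", "spike_fmol", "heavy_spike_fmol", "position")
.annotation_character <- c("matrix", "spike_level", "condition", "sample_id",
                           "panel", "design", "site")

#' Read a transition-level report
#'
#' Reads a CSV export of integrated transition peak areas: one row per
#' peptide x isotope label x replicate x fragment, with `area`,
#' `background`, and `retention_time`, plus any sample-annotation columns
#' (`matrix`, `day`, `spike_fmol`, `condition`, `position`, `panel`,
#' `sample_id`, `site`, `design`, ...) which are carried through unchanged.
#' Row order never affects downstream results: records are sorted into a
#' canonical order on read.
#'
#' @param path Path to a CSV file.
#' @return Tibble of transition records.
#' @export
read_transition_report <- function(path) {
  raw <- .read_table_any(path)
  mapped <- .map_columns(raw, .report_aliases,
                         mandatory = c("peptide_id", "label", "replicate_id",
                                       "fragment_name", "area"),
                         what = "transition report")
  tb <- mapped$table
  tb$label <- .normalize_label(tb$label)
  for (col in c("area", "background", "retention_time")) {
    v <- .parse_numeric(tb[[col]])
    bad <- attr(v, "bad_rows")
    if (length(bad)) {
      stop("transition report: unparseable ", col, " in row(s) ",
           paste(head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    tb[[col]] <- as.numeric(v)
  }
  tb$background[is.na(tb$background)] <- 0
  neg <- which(tb$area < 0 | tb$background < 0)
  if (length(neg)) {
    stop("transition report: negative area/background in row(s) ",
         paste(head(neg, 10L), collapse = ", "), call. = FALSE)
  }
  extra <- mapped$extra
  for (col in intersect(names(extra), .annotation_numeric)) {
    extra[[col]] <- as.numeric(.parse_numeric(extra[[col]]))
  }
  if (ncol(extra)) tb <- dplyr::bind_cols(tb, extra)
  dup <- duplicated(tb[c("peptide_id", "label", "replicate_id",
                         "fragment_name")])
  if (any(dup)) {
    stop("transition report: duplicate (peptide, label, replicate, fragment) ",
         "in row(s) ", paste(head(which(dup), 10L), collapse = ", "),
         call. = FALSE)
  }
  arrange(tb, .data$peptide_id, .data$replicate_id, .data$label,
          .data$fragment_name)
}

#' Write / read a characterization results table
#'
#' Writes one row per peptide x matrix with the full set of figures of merit
#' (curve fit, LLOQ/ULOQ/dynamic range, intra/inter CVs per level, endogenous
#' CVs, stability percent differences, validation call) as CSV. The matching
#' reader restores column types so the round trip is lossless at full
#' numeric precision.
#'
#' @param results Tibble as produced by [run_full_characterization()]
#'   (`$characterization` element) or any per-peptide results table.
#' @param path Output CSV path.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_characterization_table <- function(results, path, overwrite = FALSE) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  if (file.exists(path) && !overwrite) {
    stop("refusing to overwrite existing file '", path,
         "' (use overwrite = TRUE)", call. = FALSE)
  }
  readr::write_csv(results, path, na = "NA")
  invisible(path)
}

#' @rdname write_characterization_table
#' @export
read_characterization_table <- function(path) {
  readr::read_csv(path, na = .na_tokens, progress = FALSE,
                  show_col_types = FALSE)
}
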