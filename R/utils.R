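# Internal helpers shared across modules.

# Tokens that mean "missing" in tables of mixed provenance.
.na_tokens <- c("", "#N/A", "NA", "N/A", "na", "#n/a")

#' Sample coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation, the
#' convention used throughout bioanalytical assay validation. Returns `NA`
#' for fewer than two non-missing values or a zero/missing mean.
#'
#' @param x Numeric vector (e.g. peak-area ratios of process replicates).
#' @param na.rm Drop missing values first (default `TRUE`).
#' @return Percent CV as a single numeric value.
#' @export
#' @examples
#' cv_percent(c(1, 1.2, 0.8))
cv_percent <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * sd(x) / m
}

# Resolve one logical column from a set of case-insensitive header aliases.
# Returns the matched name or NA.
.resolve_alias <- function(headers, aliases) {
  low <- tolower(trimws(headers))
  for (a in tolower(aliases)) {
    hit <- which(low == a)
    if (length(hit)) return(headers[hit[1L]])
  }
  NA_character_
}

# Read a delimited or Excel table into a tibble of character columns,
# mapping the usual missing-value tokens to NA. Sheets are matched by name
# with a positional fallback.
.read_table_any <- function(path, sheet = NULL) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading '", path, "' requires the readxl package", call. = FALSE)
    }
    sheets <- readxl::excel_sheets(path)
    use <- if (is.null(sheet)) sheets[1L] else if (sheet %in% sheets) sheet else sheets[1L]
    out <- readxl::read_excel(path, sheet = use, col_types = "text",
                              na = .na_tokens)
  } else {
    out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           na = .na_tokens, progress = FALSE,
                           show_col_types = FALSE)
  }
  as_tibble(out)
}

# Strict numeric parser: returns NA for unparseable strings and reports
# which rows failed via attribute "bad_rows".
.parse_numeric <- function(x) {
  x0 <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x0))
  bad <- which(!is.na(x0) & is.na(out))
  attr(out, "bad_rows") <- bad
  out
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# log a structured message to stderr without making it a condition the
# caller must handle
.log_msg <- function(...) message("[iomrm] ", ...)
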