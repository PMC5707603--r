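#' Construct a Raman spectrum
#'
#' A Raman spectrum is an ordered set of (shift, intensity) pairs. Shifts are
#' Raman shifts in cm^-1 and must be strictly increasing after construction;
#' duplicated shifts (instrument re-scans) are collapsed by averaging their
#' intensities. Negative intensities are clipped to zero with a warning.
#'
#' @param shifts numeric vector of Raman shifts (cm^-1).
#' @param intensities numeric vector of intensities (arbitrary units), same
#'   length as `shifts`.
#' @param label free-text identifier of the measured sample (e.g. a CNT id).
#' @return An object of class `raman_spectrum` with elements `shifts`,
#'   `intensities` (strictly increasing shifts, non-negative finite
#'   intensities) and `label`.
#' @examples
#' sp <- raman_spectrum(c(1580, 1350), c(25, 10), label = "CNT1")
#' sp$shifts  # sorted ascending
#' @export
raman_spectrum <- function(shifts, intensities, label = "") {
  if (!is.numeric(shifts) || !is.numeric(intensities)) {
    stop("shifts and intensities must be numeric")
  }
  if (length(shifts) != length(intensities)) {
    stop("shifts and intensities must have the same length")
  }
  if (length(shifts) < 1L) {
    stop("a spectrum needs at least one point")
  }
  if (any(!is.finite(shifts)) || any(!is.finite(intensities))) {
    stop("shifts and intensities must be finite")
  }
  if (any(intensities < 0)) {
    warning("negative intensities clipped to 0")
    intensities <- pmax(intensities, 0)
  }
  ord <- order(shifts)
  shifts <- shifts[ord]
  intensities <- intensities[ord]
  if (anyDuplicated(shifts)) {
    intensities <- as.numeric(tapply(intensities, factor(shifts, levels = unique(shifts)), mean))
    shifts <- unique(shifts)
  }
  structure(
    list(shifts = shifts, intensities = intensities, label = as.character(label)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "Raman spectrum%s: %d points, %.0f-%.0f cm^-1, max intensity %.3g\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$shifts), min(x$shifts), max(x$shifts), max(x$intensities)
  ))
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(shift = x$shifts, intensity = x$intensities)
}

.detect_delimiter <- function(line) {
  counts <- vapply(c(",", "\t", ";"), function(d) {
    length(gregexpr(d, line, fixed = TRUE)[[1L]][gregexpr(d, line, fixed = TRUE)[[1L]] > 0])
  }, integer(1))
  if (all(counts == 0L)) {
    stop("could not detect a delimiter (comma, tab or semicolon) in: ", line)
  }
  names(counts)[which.max(counts)]
}

#' Read a Raman spectrum from two-column delimited text
#'
#' Column 1 is the Raman shift (cm^-1), column 2 the intensity. The delimiter
#' is auto-detected among comma, tab and semicolon unless given, and a single
#' header line is skipped when its fields are non-numeric. Rows may arrive in
#' any order; the result is sorted by ascending shift and duplicate shifts are
#' averaged (see [raman_spectrum()]).
#'
#' @param path path to the file.
#' @param delimiter optional delimiter override (`","`, `"\t"` or `";"`).
#' @param label spectrum label; defaults to the file name without extension.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, delimiter = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectrum file: ", path)
  if (is.null(delimiter)) delimiter <- .detect_delimiter(lines[[1L]])
  first <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
  start <- if (any(is.na(suppressWarnings(as.numeric(first))))) 2L else 1L
  if (start > length(lines)) stop("no data rows in ", path)
  n <- length(lines) - start + 1L
  shifts <- numeric(n)
  intens <- numeric(n)
  for (i in seq_len(n)) {
    fields <- trimws(strsplit(lines[[start + i - 1L]], delimiter, fixed = TRUE)[[1L]])
    if (length(fields) < 2L) {
      stop(sprintf("line %d of %s: expected two columns", start + i - 1L, path))
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (any(is.na(vals))) {
      stop(sprintf("line %d of %s: non-numeric value '%s'",
                   start + i - 1L, path, fields[which(is.na(vals))[1L]]))
    }
    shifts[i] <- vals[1L]
    intens[i] <- vals[2L]
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  raman_spectrum(shifts, intens, label = label)
}

#' Controlled vocabularies of the experimental conditions
#'
#' The four experimental conditions attached to each oxygen-flux case:
#' replicate flag, CNT type, chemical functionalization and solvent. Level
#' `"0"` marks control assays (blank solution, no CNT).
#'
#' @return Named list of allowed levels per condition field.
#' @export
condition_levels <- function() {
  list(
    rep       = c("0", "1"),
    cnt_type  = c("0", "MWCNT", "SW+DWCNT", "SWCNT"),
    func_type = c("0", "COOH", "OH"),
    solvent   = c("H2O", "DMSO")
  )
}

#' Default column-name mapping for case tables
#'
#' Maps the package's internal field names to the column headers expected in a
#' case-table CSV. The defaults follow the field names used in the deposited
#' dataset description (flux `Jm`, identifier `CNT`, `rep`, `CNTtype`,
#' `FuncType`, `Solvent`, time `t`); pass a modified copy to
#' [read_case_table()] when headers differ.
#'
#' @return Named character vector internal name -> column header.
#' @export
default_case_columns <- function() {
  c(flux = "Jm", cnt_id = "CNT", rep = "rep", cnt_type = "CNTtype",
    func_type = "FuncType", solvent = "Solvent", time = "t")
}

.validate_cases <- function(df) {
  vocab <- condition_levels()
  df$rep <- as.character(df$rep)
  df$cnt_type <- as.character(df$cnt_type)
  df$func_type <- as.character(df$func_type)
  df$solvent <- as.character(df$solvent)
  df$cnt_id <- as.character(df$cnt_id)
  for (field in names(vocab)) {
    bad <- which(!df[[field]] %in% vocab[[field]])
    if (length(bad) > 0L) {
      stop(sprintf("row %d: value '%s' not allowed for column '%s' (allowed: %s)",
                   bad[1L], df[[field]][bad[1L]], field,
                   paste(vocab[[field]], collapse = ", ")))
    }
  }
  bad_id <- which(!grepl("^(0|CNT[0-9]+)$", df$cnt_id))
  if (length(bad_id) > 0L) {
    stop(sprintf("row %d: cnt_id '%s' is not 'CNT<n>' or control '0'",
                 bad_id[1L], df$cnt_id[bad_id[1L]]))
  }
  if (!is.numeric(df$flux) || any(!is.finite(df$flux))) {
    stop("flux must be finite numeric")
  }
  if (!is.numeric(df$time) || any(df$time < 0)) {
    stop("time must be numeric and >= 0")
  }
  df
}

#' Read a case table of respirometry measurements
#'
#' Each row is one measurement of the mitochondrial oxygen mass flux
#' J_m(O2) (pmol/s) together with its experimental conditions: CNT id,
#' replicate flag, CNT type, functionalization, solvent and the time since the
#' start of the assay. Categorical columns are checked against
#' [condition_levels()].
#'
#' @param path CSV file with a header row.
#' @param col_map named character vector mapping internal field names to the
#'   file's column headers; see [default_case_columns()].
#' @param delimiter optional delimiter override; auto-detected by default.
#' @return data.frame with columns `flux`, `cnt_id`, `rep`, `cnt_type`,
#'   `func_type`, `solvent`, `time`.
#' @export
read_case_table <- function(path, col_map = default_case_columns(), delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    delimiter <- .detect_delimiter(first)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing) > 0L) {
    stop("case table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- stats::setNames(raw[unname(col_map)], names(col_map))
  df <- .validate_cases(df)
  message(sprintf("read %d case(s) from %s", nrow(df), path))
  df
}

#' Write a feature table (or any numeric table) to CSV
#'
#' Values are written with full double precision so that a write/read
#' round-trip reproduces them to at least 12 significant digits.
#'
#' @param table data.frame to write.
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(format(table, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
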