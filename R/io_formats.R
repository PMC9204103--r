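# Readers and writers: FASTA (via Biostrings), peak lists (MGF and
# two-column text), fixture tables, TSV/JSON reports. MGF is parsed here
# directly -- it is a line-oriented text format and no installed R package
# reads it.

#' Construct a peak list
#'
#' @param mz Numeric vector of m/z values.
#' @param intensity Numeric vector of intensities (>= 0, finite).
#' @param label Free-text label (e.g. state name or scan title).
#' @param level "MS1" or "MS2".
#' @param precursor_mz Precursor m/z (MS2 only).
#' @param precursor_charge Precursor charge (MS2 only).
#' @param mz_range Declared acquisition window, default c(500, 3500)
#'   (reflector-mode MALDI); peaks must fall inside it when declared.
#'   Use NULL for no window.
#' @return A \code{PeakList}: data.frame(mz, intensity) sorted ascending by
#'   m/z, with metadata attributes.
#' @export
peak_list <- function(mz, intensity, label = "", level = c("MS1", "MS2"),
                      precursor_mz = NA_real_, precursor_charge = NA_integer_,
                      mz_range = c(500, 3500)) {
  level <- match.arg(level)
  stopifnot(length(mz) == length(intensity))
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("peak m/z and intensity must be finite")
  if (any(intensity < 0)) stop("negative intensity rejected")
  if (any(mz <= 0)) stop("non-positive m/z rejected")
  if (!is.null(mz_range) && length(mz) > 0L &&
      (min(mz) < mz_range[1] || max(mz) > mz_range[2]))
    stop("peaks outside the declared m/z range [", mz_range[1], ", ",
         mz_range[2], "]")
  o <- order(mz)
  df <- data.frame(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
  structure(df, class = c("PeakList", "data.frame"), label = label,
            level = level, precursor_mz = precursor_mz,
            precursor_charge = precursor_charge, mz_range = mz_range)
}

#' @export
print.PeakList <- function(x, ...) {
  cat(sprintf("PeakList '%s' (%s, %d peaks", attr(x, "label"),
              attr(x, "level"), nrow(x)))
  if (!is.na(attr(x, "precursor_mz")))
    cat(sprintf(", precursor %.4f", attr(x, "precursor_mz")))
  cat(")\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read peak lists from MGF or two-column text
#'
#' The two-column dialect is whitespace-separated m/z and intensity with
#' \code{#} comments, one MS1 spectrum per file. MGF files may hold several
#' BEGIN IONS/END IONS blocks; each becomes an MS2 \code{PeakList} with the
#' PEPMASS (and CHARGE, if present) recorded as precursor metadata.
#' Unsorted input is sorted with a warning.
#'
#' @param path File path.
#' @param format "mgf", "tsv", or "auto" (by extension).
#' @param mz_range Declared window to stamp on the result, or NULL.
#' @return A list of \code{PeakList} (possibly empty, with a warning).
#' @export
read_peaklist <- function(path, format = c("auto", "mgf", "tsv"),
                          mz_range = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak-list file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "tsv"
  lines <- readLines(path, warn = FALSE)
  if (format == "tsv") .read_peaks_tsv(lines, path, mz_range)
  else .read_peaks_mgf(lines, path, mz_range)
}

.parse_peak_rows <- function(lines, lineno, path) {
  mz <- numeric(0); it <- numeric(0); bad <- integer(0)
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[k])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) < 2L || any(is.na(v[1:2]))) { bad <- c(bad, lineno[k]); next }
    mz <- c(mz, v[1]); it <- c(it, v[2])
  }
  if (length(bad) > 0L)
    warning("malformed peak line(s) in ", path, " at line(s): ",
            paste(bad, collapse = ", "))
  if (any(it < 0)) stop("negative intensity in ", path)
  list(mz = mz, intensity = it)
}

.read_peaks_tsv <- function(lines, path, mz_range) {
  pk <- .parse_peak_rows(lines, seq_along(lines), path)
  if (length(pk$mz) == 0L) {
    warning("empty peak list: ", path)
    return(list())
  }
  if (is.unsorted(pk$mz)) warning("unsorted peak list ", path, "; sorting")
  list(peak_list(pk$mz, pk$intensity, label = basename(path), level = "MS1",
                 mz_range = mz_range))
}

.read_peaks_mgf <- function(lines, path, mz_range) {
  out <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      j <- i + 1L
      title <- ""; pepmass <- NA_real_; charge <- NA_integer_
      body <- character(0); bodyln <- integer(0)
      while (j <= n && trimws(lines[j]) != "END IONS") {
        ln <- trimws(lines[j])
        if (grepl("^TITLE=", ln)) title <- sub("^TITLE=", "", ln)
        else if (grepl("^PEPMASS=", ln))
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "[[:space:]]+")[[1]][1])
        else if (grepl("^CHARGE=", ln))
          charge <- as.integer(gsub("[^0-9]", "", ln))
        else if (!grepl("=", ln) && nzchar(ln)) {
          body <- c(body, ln); bodyln <- c(bodyln, j)
        }
        j <- j + 1L
      }
      if (j > n) stop("MGF block starting at line ", i, " lacks END IONS")
      pk <- .parse_peak_rows(body, bodyln, path)
      if (is.unsorted(pk$mz)) warning("unsorted MGF block in ", path, "; sorting")
      out[[length(out) + 1L]] <-
        peak_list(pk$mz, pk$intensity, label = title, level = "MS2",
                  precursor_mz = pepmass, precursor_charge = charge,
                  mz_range = mz_range)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L) warning("no spectra found in ", path)
  out
}

#' Write peak lists
#'
#' @param peaklists List of \code{PeakList} (or one).
#' @param path Output path.
#' @param format "mgf" or "tsv" (tsv writes the first MS1 list only).
#' @export
write_peaklist <- function(peaklists, path, format = c("auto", "mgf", "tsv")) {
  format <- match.arg(format)
  if (inherits(peaklists, "PeakList")) peaklists <- list(peaklists)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "tsv"
  if (format == "tsv") {
    pl <- peaklists[[1]]
    writeLines(c(sprintf("# %s", attr(pl, "label")),
                 sprintf("%.6f %.6f", pl$mz, pl$intensity)), path)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    for (pl in peaklists) {
      writeLines("BEGIN IONS", con)
      writeLines(sprintf("TITLE=%s", attr(pl, "label")), con)
      if (!is.na(attr(pl, "precursor_mz")))
        writeLines(sprintf("PEPMASS=%.6f", attr(pl, "precursor_mz")), con)
      if (!is.na(attr(pl, "precursor_charge")))
        writeLines(sprintf("CHARGE=%d+", attr(pl, "precursor_charge")), con)
      writeLines(sprintf("%.6f %.6f", pl$mz, pl$intensity), con)
      writeLines("END IONS", con)
    }
  }
  invisible(path)
}

#' Read protein records from FASTA
#'
#' Sequences are uppercased; the first header token becomes the id; an
#' optional \code{offset=<int>} tag anywhere in the header sets
#' \code{numbering_offset} (the label of the first residue).
#'
#' @param path FASTA file.
#' @return List of \code{ProteinRecord}, in file order.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  lapply(seq_along(aas), function(i) {
    header <- names(aas)[i]
    id <- strsplit(header, "[[:space:]]+")[[1]][1]
    off <- 1L
    m <- regmatches(header, regexpr("offset=-?[0-9]+", header))
    if (length(m) == 1L) off <- as.integer(sub("offset=", "", m))
    protein_record(id, as.character(aas[[i]]), numbering_offset = off)
  })
}

#' Write protein records to FASTA
#' @param proteins List of \code{ProteinRecord} (or one).
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "ProteinRecord")) proteins <- list(proteins)
  lines <- unlist(lapply(proteins, function(p) {
    c(sprintf(">%s offset=%d", p$id, p$numbering_offset),
      substring(p$sequence, seq(1, nchar(p$sequence), 60),
                pmin(seq(60, nchar(p$sequence) + 59, 60), nchar(p$sequence))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular report
#'
#' TSV via \code{write.table}; JSON via \code{jsonlite}. Round-trip stable:
#' \code{read_report(write_report(x))} reproduces the table.
#'
#' @param report A data.frame.
#' @param path Output path.
#' @param format "tsv" or "json" ("auto" by extension).
#' @export
write_report <- function(report, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv")
    utils::read.delim(path, stringsAsFactors = FALSE)
  else
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Read a printed peptide-list fixture
#'
#' Fixture TSVs transcribe published peptide tables: columns
#' \code{isoform}, \code{sequence} (as printed, lowercase letters marking
#' modified residues), and \code{range_label} (the printed residue range,
#' kept as a label, not coordinates).
#'
#' @param path Fixture TSV.
#' @return data.frame(isoform, sequence, range_label).
#' @export
read_peptide_fixture <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("isoform", "sequence", "range_label")
  if (!all(need %in% names(df)))
    stop("peptide fixture must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a domain-annotation table
#' @param path TSV with columns name, start, end.
#' @return data.frame(name, start, end).
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(df)))
    stop("domain table must have columns name, start, end")
  if (any(df$start > df$end)) stop("domain start > end")
  df
}
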