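#' Column mapping (dialect) for capillary-electrophoresis peak tables
#'
#' Peak tables exported from fragment-analysis software differ only in
#' delimiters and column headers, so ingestion is parameterised by a small
#' dialect object. The canonical dialect is comma-separated UTF-8 with a
#' header row and columns \code{sample_id, conversion, amplification,
#' locus, base, height, area, size_nt}.
#'
#' @param sep Field delimiter.
#' @param sample_id,conversion,amplification,locus,base,height,area,size_nt
#'   Column names in the file holding each field; \code{area} and
#'   \code{size_nt} are optional columns and may be absent from the file.
#' @return A named list of class \code{"peakDialect"}.
#' @examples
#' peakDialect()
#' peakDialect(sep = "\t", sample_id = "Sample Name")
#' @export
peakDialect <- function(sep = ",", sample_id = "sample_id",
                        conversion = "conversion",
                        amplification = "amplification", locus = "locus",
                        base = "base", height = "height", area = "area",
                        size_nt = "size_nt") {
  structure(list(sep = sep, sample_id = sample_id, conversion = conversion,
                 amplification = amplification, locus = locus, base = base,
                 height = height, area = area, size_nt = size_nt),
            class = "peakDialect")
}

.peakColumns <- c("sample_id", "conversion", "amplification", "locus",
                  "base", "height", "area", "size_nt")

#' Read a peak table into a canonical peak data.frame
#'
#' Each row of a peak table is one called fluorescence peak: which sample
#' and replicate (conversion x amplification) it came from, which locus
#' and base channel it belongs to, and its height (RFU), with optional
#' peak area and fragment size. In \code{strict} mode any malformed row
#' (unknown locus, non-numeric or negative height) aborts the read with a
#' line-numbered error; in lenient mode such rows are dropped with a
#' warning and their count is attached as attribute \code{"rejected"}.
#'
#' @param path Path to a delimited text file.
#' @param dialect A \code{\link{peakDialect}} mapping file columns to
#'   canonical names.
#' @param strict Logical; reject the whole file on a bad row (default)
#'   or skip bad rows with a warning.
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{conversion}, \code{amplification}, \code{locus}, \code{base},
#'   \code{height}, \code{area}, \code{size_nt}, in file row order.
#' @seealso \code{\link{writePeakTable}}, \code{\link{quantifyPeakTable}}
#' @export
readPeakTable <- function(path, dialect = peakDialect(), strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = dialect$sep, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  required <- c("sample_id", "conversion", "amplification", "locus",
                "base", "height")
  for (col in required) {
    if (!dialect[[col]] %in% names(raw)) {
      stop("peak table is missing required column '", dialect[[col]],
           "' (", col, ")")
    }
  }
  out <- data.frame(
    sample_id = as.character(raw[[dialect$sample_id]]),
    conversion = suppressWarnings(as.integer(raw[[dialect$conversion]])),
    amplification =
      suppressWarnings(as.integer(raw[[dialect$amplification]])),
    locus = as.character(raw[[dialect$locus]]),
    base = toupper(as.character(raw[[dialect$base]])),
    height = suppressWarnings(as.numeric(raw[[dialect$height]])),
    area = rep(NA_real_, nrow(raw)), size_nt = rep(NA_real_, nrow(raw)),
    stringsAsFactors = FALSE
  )
  if (dialect$area %in% names(raw)) {
    out$area <- suppressWarnings(as.numeric(raw[[dialect$area]]))
  }
  if (dialect$size_nt %in% names(raw)) {
    out$size_nt <- suppressWarnings(as.numeric(raw[[dialect$size_nt]]))
  }
  if (nrow(out) == 0L) {
    warning("peak table '", basename(path), "' contains no data rows")
    attr(out, "rejected") <- 0L
    return(out)
  }
  badHeight <- is.na(out$height) | out$height < 0
  badLocus <- !out$locus %in% snapshotLoci()$locus
  badRep <- is.na(out$conversion) | is.na(out$amplification)
  bad <- badHeight | badLocus | badRep
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (strict) {
      what <- c(
        if (any(badHeight)) "non-numeric/negative height",
        if (any(badLocus)) paste0("unknown locus (",
          paste(unique(out$locus[badLocus]), collapse = ", "), ")"),
        if (any(badRep)) "non-integer replicate id"
      )
      stop("invalid peak rows at line(s) ",
           paste(utils::head(lines, 10L), collapse = ", "), ": ",
           paste(what, collapse = "; "))
    }
    warning("skipped ", sum(bad), " invalid peak row(s) at line(s) ",
            paste(utils::head(lines, 10L), collapse = ", "))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejected") <- if (strict) 0L else sum(bad)
  out
}

#' Write a canonical peak table
#'
#' Writes peaks in the canonical comma-separated dialect so that
#' \code{\link{readPeakTable}} round-trips them unchanged.
#'
#' @param peaks A peak \code{data.frame} (canonical columns).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(peaks, path) {
  stopifnot(all(c("sample_id", "conversion", "amplification", "locus",
                  "base", "height") %in% names(peaks)))
  for (col in setdiff(.peakColumns, names(peaks))) peaks[[col]] <- NA_real_
  utils::write.csv(peaks[, .peakColumns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read cohort metadata (sample id, age, sex)
#'
#' @param path CSV file with columns \code{sample_id}, \code{age_years}
#'   and optionally \code{sex}.
#' @return A \code{data.frame} with those columns.
#' @export
readCohortMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "age_years")) {
    if (!col %in% names(meta)) {
      stop("cohort metadata is missing required column '", col, "'")
    }
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$age_years <- as.numeric(meta$age_years)
  if (any(!is.na(meta$age_years) & meta$age_years <= 0)) {
    stop("cohort metadata contains non-positive ages")
  }
  meta
}

#' Select the methylated/unmethylated peak pair for one locus measurement
#'
#' Given all peaks called for one sample x replicate x locus, picks the
#' intensity of the methylated-allele channel and of the
#' unmethylated-allele channel according to the locus chemistry (C/T for
#' ELOVL2 and FHL2, G/A for KLF14, C1orf132, TRIM59). A channel with no
#' peak contributes intensity 0 — single-base extension of a fully
#' methylated or fully unmethylated template legitimately produces one
#' peak. If several peaks share a channel, peaks inside the locus size
#' window are preferred, then the tallest, ties broken by smaller
#' fragment size. If neither channel has a peak the measurement is absent
#' and both intensities are returned as \code{NA}.
#'
#' @param records Peak \code{data.frame} rows for a single sample,
#'   replicate and locus.
#' @param locusDef One-row locus definition from
#'   \code{\link{snapshotLoci}}; defaults to the definition matching the
#'   records' locus.
#' @param intensity \code{"height"} (default, the standard choice) or
#'   \code{"area"}.
#' @return Named numeric vector \code{c(meth = , unmeth = )} in RFU, or
#'   both \code{NA} when no peak is present in either channel.
#' @examples
#' pk <- data.frame(sample_id = "s1", conversion = 1, amplification = 1,
#'                  locus = "ELOVL2", base = c("C", "T"),
#'                  height = c(812, 390), area = NA, size_nt = NA)
#' selectLocusPair(pk)
#' @export
selectLocusPair <- function(records, locusDef = NULL,
                            intensity = c("height", "area")) {
  intensity <- match.arg(intensity)
  if (nrow(records) == 0L) {
    return(c(meth = NA_real_, unmeth = NA_real_))
  }
  loc <- unique(records$locus)
  if (length(loc) != 1L) stop("records span more than one locus")
  if (is.null(locusDef)) locusDef <- snapshotLoci(loc)
  vals <- records[[intensity]]
  if (intensity == "area" && all(is.na(vals))) {
    stop("intensity = 'area' requested but no area values are present")
  }

  pickChannel <- function(baseWanted) {
    idx <- which(records$base == baseWanted & !is.na(vals))
    if (length(idx) == 0L) return(0)
    if (length(idx) > 1L) {
      inWindow <- idx[!is.na(records$size_nt[idx]) &
                      records$size_nt[idx] >= locusDef$size_min &
                      records$size_nt[idx] <= locusDef$size_max]
      if (length(inWindow) > 0L) idx <- inWindow
      best <- idx[vals[idx] == max(vals[idx])]
      if (length(best) > 1L) {
        sz <- records$size_nt[best]
        if (all(is.na(sz))) best <- best[1L]
        else best <- best[order(sz)][1L]
      }
      idx <- best
    }
    vals[idx]
  }

  meth <- pickChannel(locusDef$methylated_base)
  unmeth <- pickChannel(locusDef$unmethylated_base)
  hasMeth <- any(records$base == locusDef$methylated_base & !is.na(vals))
  hasUnmeth <- any(records$base == locusDef$unmethylated_base & !is.na(vals))
  if (!hasMeth && !hasUnmeth) {
    return(c(meth = NA_real_, unmeth = NA_real_))
  }
  c(meth = meth, unmeth = unmeth)
}
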