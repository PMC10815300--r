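#' Construct a MethCohort from levels, ages and sex
#'
#' Assembles averaged methylation profiles and cohort metadata into a
#' \linkS4class{MethCohort}. Input levels may be a loci-by-samples matrix
#' or a wide per-sample \code{data.frame} as produced by
#' \code{\link{averageReplicates}} (one row per sample, one column per
#' locus plus \code{sample_id}).
#'
#' @param levels Numeric matrix (rows = loci, columns = samples) or a wide
#'   \code{data.frame} with a \code{sample_id} column and one column per
#'   locus.
#' @param age Numeric vector of chronological ages in years, one per
#'   sample, or a metadata \code{data.frame} with columns
#'   \code{sample_id}, \code{age_years} and optionally \code{sex};
#'   metadata rows are matched to samples by \code{sample_id}.
#' @param sex Optional character vector (ignored when \code{age} is a
#'   metadata table that carries sex).
#' @param loci Locus order for the rows; defaults to
#'   \code{\link{locusOrder}()}.
#' @return A \linkS4class{MethCohort}.
#' @examples
#' m <- matrix(runif(10), nrow = 5,
#'             dimnames = list(locusOrder(), c("s1", "s2")))
#' MethCohort(m, age = c(30, 62))
#' @export
MethCohort <- function(levels, age, sex = NULL, loci = locusOrder()) {
  if (is.data.frame(levels)) {
    if (!"sample_id" %in% names(levels)) {
      stop("wide level table must contain a 'sample_id' column")
    }
    missing_loci <- setdiff(loci, names(levels))
    if (length(missing_loci) > 0L) {
      stop("wide level table lacks loci: ",
           paste(missing_loci, collapse = ", "))
    }
    ids <- as.character(levels$sample_id)
    mat <- t(as.matrix(levels[, loci, drop = FALSE]))
    colnames(mat) <- ids
  } else {
    mat <- as.matrix(levels)
    if (is.null(rownames(mat))) rownames(mat) <- loci
    mat <- mat[loci, , drop = FALSE]
    if (is.null(colnames(mat))) {
      colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
    }
  }
  if (is.data.frame(age)) {
    meta <- age
    if (!all(c("sample_id", "age_years") %in% names(meta))) {
      stop("metadata must contain 'sample_id' and 'age_years'")
    }
    idx <- match(colnames(mat), as.character(meta$sample_id))
    if (anyNA(idx)) {
      stop("metadata is missing samples: ",
           paste(colnames(mat)[is.na(idx)], collapse = ", "))
    }
    age_years <- meta$age_years[idx]
    sex <- if ("sex" %in% names(meta)) as.character(meta$sex[idx]) else sex
  } else {
    age_years <- age
  }
  if (length(age_years) != ncol(mat)) {
    stop("need one age per sample")
  }
  cd <- S4Vectors::DataFrame(age_years = as.numeric(age_years),
                             row.names = colnames(mat))
  if (!is.null(sex)) cd$sex <- as.character(sex)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(methylation = mat),
    colData = cd
  )
  new("MethCohort", se)
}

#' Methylation level matrix of a cohort
#'
#' @param x A \linkS4class{MethCohort}.
#' @param ... Unused.
#' @return Numeric matrix, loci in rows (canonical order), samples in
#'   columns.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 4, seed = 1))
#' methLevels(cohort)[, 1:2]
#' @export
setMethod("methLevels", "MethCohort", function(x, ...) {
  SummarizedExperiment::assay(x, "methylation")
})

#' Chronological ages of a cohort
#'
#' @param x A \linkS4class{MethCohort}.
#' @param ... Unused.
#' @return Named numeric vector of ages in years.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 4, seed = 1))
#' ages(cohort)
#' @export
setMethod("ages", "MethCohort", function(x, ...) {
  setNames(SummarizedExperiment::colData(x)$age_years, colnames(x))
})

setMethod("show", "MethCohort", function(object) {
  a <- ages(object)
  cat("MethCohort with", ncol(object), "samples x", nrow(object), "loci\n")
  cat("  loci:", paste(rownames(object), collapse = ", "), "\n")
  if (length(a)) {
    cat(sprintf("  ages: %.0f-%.0f years (median %.0f)\n",
                min(a, na.rm = TRUE), max(a, na.rm = TRUE),
                stats::median(a, na.rm = TRUE)))
  }
  nmiss <- sum(is.na(methLevels(object)))
  if (nmiss > 0) cat("  missing levels:", nmiss, "\n")
  invisible(NULL)
})

#' Keep only samples with a complete five-locus profile
#'
#' @param x A \linkS4class{MethCohort}.
#' @return A \linkS4class{MethCohort} restricted to samples without any
#'   missing locus level.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 4, seed = 1))
#' completeProfiles(cohort)
#' @export
completeProfiles <- function(x) {
  stopifnot(is(x, "MethCohort"))
  keep <- colSums(is.na(methLevels(x))) == 0L
  x[, keep]
}
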